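#' Specification of a synthetic PPIX sample scene
#'
#' Describes a dark-background image of circular liquid wells, one per
#' nominal PPIX concentration, emulating calibration sample images taken
#' under a surgical microscope's blue-light fluorescence mode. The default
#' ladder spans 5 ug/mL (clearly visible fluorescence) down to 0.01 ug/mL
#' (no visible signal) plus a PPIX-free reference well.
#'
#' The red-channel response inside a well of concentration `c` is the
#' saturating curve `bg_red + gain * A * c / (c + K)`; green receives a
#' small bleed-through fraction of the same signal and blue stays at the
#' background level. With the defaults (`A = 220`, `K = 5`, noise sd 3) the
#' visibility boundary falls between 0.5 and 0.2 ug/mL and concentrations
#' at or below 0.05 ug/mL stay within about one noise standard deviation of
#' the background.
#'
#' @param concentrations Ladder of well concentrations in ug/mL.
#' @param well_radius Well radius in pixels.
#' @param image_size Optional `c(height, width)`; by default sized so the
#'   wells sit on a grid with 3-radius spacing.
#' @param centers Optional matrix of well centers (`(row, col)` per well,
#'   one row per concentration) overriding the default grid layout. Wells
#'   must not overlap and must lie inside the image.
#' @param gain Illumination gain multiplying the fluorescence signal.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   units, i.i.d. per channel).
#' @param K Half-saturation constant of the concentration response, ug/mL.
#' @param A Red-signal amplitude at full saturation, intensity units.
#' @param background Background mean intensities `c(r, g, b)` (dark blue
#'   cast).
#' @param green_bleed Fraction of the red signal leaking into green.
#' @return A `sample_scene_spec` list.
#' @export
sample_scene_spec <- function(concentrations = c(5, 2, 1, 0.5, 0.2, 0.1,
                                                 0.05, 0.025, 0.01, 0),
                              well_radius = 34L, image_size = NULL,
                              gain = 1, noise_sd = 3, K = 5, A = 220,
                              background = c(8, 12, 30), green_bleed = 0.12,
                              centers = NULL) {
  stopifnot(all(concentrations >= 0), well_radius >= 1, noise_sd >= 0,
            K > 0, A > 0, gain > 0, length(background) == 3L)
  n <- length(concentrations)
  ncol <- min(n, 4L)
  nrow <- ceiling(n / ncol)
  pitch <- 3L * well_radius
  if (is.null(image_size)) image_size <- c(nrow * pitch, ncol * pitch)
  if (is.null(centers)) {
    centers <- cbind(
      x = (((seq_len(n) - 1L) %/% ncol) + 0.5) * pitch,
      y = (((seq_len(n) - 1L) %% ncol) + 0.5) * pitch
    )
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != n || ncol(centers) != 2L)
      stop("centers must be one (row, col) pair per concentration",
           call. = FALSE)
  }
  if (any(centers - well_radius < 1) ||
      any(centers[, 1] + well_radius > image_size[1]) ||
      any(centers[, 2] + well_radius > image_size[2]))
    stop("image_size too small for the well layout", call. = FALSE)
  if (n > 1L && min(stats::dist(centers)) <= 2 * well_radius)
    stop("overlapping wells", call. = FALSE)
  structure(list(concentrations = concentrations, well_radius = well_radius,
                 image_size = image_size, centers = centers, gain = gain,
                 noise_sd = noise_sd, K = K, A = A, background = background,
                 green_bleed = green_bleed),
            class = "sample_scene_spec")
}

# saturating concentration -> signal response shared by both renderers
concentration_response <- function(c, A, K, gain) gain * A * c / (c + K)

finish_frame <- function(r, g, b, noise_sd) {
  h <- nrow(r); w <- ncol(r)
  noisy <- function(m) pmin(pmax(round(m + stats::rnorm(h * w, 0, noise_sd)), 0), 255)
  rgb_frame(array(c(noisy(r), noisy(g), noisy(b)), c(h, w, 3L)))
}

ground_truth <- function(concentration_map, artifact_mask = NULL, wells = NULL) {
  if (is.null(artifact_mask))
    artifact_mask <- matrix(FALSE, nrow(concentration_map), ncol(concentration_map))
  list(fluorescence_mask = concentration_map > 0,
       concentration_map = concentration_map,
       artifact_mask = artifact_mask,
       wells = wells)
}

#' Render a synthetic PPIX sample scene
#'
#' Draws the wells of a [sample_scene_spec()] on a dark blue-cast
#' background, adds i.i.d. Gaussian pixel noise, clips to 8 bits, and
#' returns the frame together with its per-pixel ground truth. Rendering is
#' bit-reproducible for a fixed seed.
#'
#' @param spec A [sample_scene_spec()].
#' @param seed Integer seed.
#' @return List with `frame` (an [rgb_frame()]) and `truth`, a ground-truth
#'   list holding `fluorescence_mask` (true where the underlying
#'   concentration is positive), `concentration_map` (ug/mL per pixel),
#'   `artifact_mask` (all false here) and a `wells` table with per-well
#'   concentration and center.
#' @export
render_sample_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sample_scene_spec"))
  set.seed(seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  conc <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_along(spec$concentrations)) {
    inside <- (rows - spec$centers[i, 1])^2 + (cols - spec$centers[i, 2])^2 <=
      spec$well_radius^2
    conc[inside] <- spec$concentrations[i]
  }
  # c = 0 wells are part of the scene but carry no signal; mark only the
  # well interiors in the well table, the concentration map is the oracle
  signal <- concentration_response(conc, spec$A, spec$K, spec$gain)
  r <- spec$background[1] + signal
  g <- spec$background[2] + spec$green_bleed * signal
  b <- matrix(spec$background[3], h, w)
  wells <- data.frame(concentration = spec$concentrations,
                      cx = spec$centers[, 1], cy = spec$centers[, 2],
                      radius = spec$well_radius)
  list(frame = finish_frame(r, g, b, spec$noise_sd),
       truth = ground_truth(conc, wells = wells))
}

#' Specification of a synthetic intraoperative scene
#'
#' Describes a full-resolution surgical frame under blue-light fluorescence
#' mode: low-frequency tissue texture in dark blue/violet tones, optional
#' Gaussian-profile fluorescent blobs (red signal following the same
#' saturating concentration response as the sample scenes), near-saturated
#' specular reflection discs carrying no fluorescence, a dark image
#' fraction, and optional injection of 8x8 block-quantization compression
#' artifacts into dark regions. A specification with zero blobs renders a
#' negative (non-fluorescence-guided) frame.
#'
#' @param image_size `c(height, width)`; the default 1080 x 1920 matches a
#'   2,073,600-pixel video frame.
#' @param n_blobs Number of fluorescent blobs (0 for a negative frame).
#' @param blob_peaks Peak concentrations (ug/mL), recycled over blobs.
#' @param blob_sigma Range of blob Gaussian radii in pixels.
#' @param n_reflections Number of specular reflection discs.
#' @param reflection_radius Range of disc radii in pixels.
#' @param dark_fraction Fraction of the frame forced to near-black.
#' @param inject_artifacts Logical: quantize 8x8 blocks in dark regions and
#'   record them in the artifact mask.
#' @param base Mean tissue color `c(r, g, b)` before modulation.
#' @inheritParams sample_scene_spec
#' @return A `surgical_scene_spec` list.
#' @export
surgical_scene_spec <- function(image_size = c(1080L, 1920L), n_blobs = 3L,
                                blob_peaks = c(5, 1, 0.2),
                                blob_sigma = c(20, 60),
                                n_reflections = 3L,
                                reflection_radius = c(4, 12),
                                dark_fraction = 0.25,
                                inject_artifacts = FALSE,
                                base = c(30, 22, 60), noise_sd = 3,
                                K = 5, A = 220, gain = 1, green_bleed = 0.12) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16L),
            n_blobs >= 0L, all(blob_peaks >= 0), n_reflections >= 0L,
            dark_fraction >= 0, dark_fraction < 1, noise_sd >= 0, K > 0)
  structure(list(image_size = image_size, n_blobs = n_blobs,
                 blob_peaks = blob_peaks, blob_sigma = blob_sigma,
                 n_reflections = n_reflections,
                 reflection_radius = reflection_radius,
                 dark_fraction = dark_fraction,
                 inject_artifacts = inject_artifacts, base = base,
                 noise_sd = noise_sd, K = K, A = A, gain = gain,
                 green_bleed = green_bleed),
            class = "surgical_scene_spec")
}

# smooth random field in [0, 1] from a few low-frequency cosine modes
smooth_field <- function(h, w, n_modes = 3L, freq = c(0.5, 2)) {
  rows <- matrix(seq_len(h) / h, h, w)
  cols <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (k in seq_len(n_modes)) {
    f <- f + cos(2 * pi * (stats::runif(1, freq[1], freq[2]) * rows +
                           stats::runif(1, freq[1], freq[2]) * cols +
                           stats::runif(1)))
  }
  u <- (f - min(f)) / (max(f) - min(f) + 1e-12)
  # arcsine reshaping thins the density at the range boundaries, so the
  # rendered intensity histogram has no hard edges a spike detector would
  # mistake for quantization artifacts
  0.5 + asin(2 * u - 1) / pi
}

#' Render a synthetic intraoperative scene
#'
#' @param spec A [surgical_scene_spec()].
#' @param seed Integer seed.
#' @return List with `frame` and `truth` as in [render_sample_scene()];
#'   `truth$artifact_mask` marks the pixels whose 8x8 block was quantized
#'   when `inject_artifacts` is on, and `truth$dark_mask` records the
#'   generator's own dark-region map.
#' @export
render_surgical_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "surgical_scene_spec"))
  set.seed(seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)

  # coarse anatomy plus a fine-scale component so the intensity histogram
  # has no single-level pile-ups at texture extrema
  tex <- 0.55 + 0.33 * smooth_field(h, w) +
    0.12 * smooth_field(h, w, 6L, freq = c(4, 10))
  r <- spec$base[1] * tex
  g <- spec$base[2] * tex
  b <- spec$base[3] * tex

  conc <- matrix(0, h, w)
  if (spec$n_blobs > 0L) {
    peaks <- rep_len(spec$blob_peaks, spec$n_blobs)
    for (i in seq_len(spec$n_blobs)) {
      sg <- stats::runif(1, spec$blob_sigma[1], spec$blob_sigma[2])
      cx <- stats::runif(1, sg, h - sg)
      cy <- stats::runif(1, sg, w - sg)
      blob <- peaks[i] * exp(-((rows - cx)^2 + (cols - cy)^2) / (2 * sg^2))
      blob[blob < 0.01] <- 0
      conc <- conc + blob
    }
  }

  dark <- matrix(FALSE, h, w)
  if (spec$dark_fraction > 0) {
    field <- smooth_field(h, w)
    # fluorescent areas emit light: they are never part of the dark region
    field[conc > 0] <- max(field) + 1
    if (spec$inject_artifacts) {
      # block-align the dark region: JPEG darkness artifacts are structured
      # on the 8x8 compression grid, so the emulated dark area is too
      bh <- h %/% 8L; bw <- w %/% 8L
      bfield <- matrix(NA_real_, bh, bw)
      for (bi in seq_len(bh)) for (bj in seq_len(bw))
        bfield[bi, bj] <- mean(field[((bi - 1L) * 8L + 1L):(bi * 8L),
                                     ((bj - 1L) * 8L + 1L):(bj * 8L)])
      bdark <- bfield <= stats::quantile(bfield, spec$dark_fraction)
      dark[1:(bh * 8L), 1:(bw * 8L)] <-
        bdark[rep(seq_len(bh), each = 8L), rep(seq_len(bw), each = 8L)]
    } else {
      dark <- field <= stats::quantile(field, spec$dark_fraction)
    }
    # dark but not clipped: keeps the level-0 bin free of a clipping spike,
    # so histogram spikes in dark regions are attributable to quantization
    r[dark] <- r[dark] * 0.25
    g[dark] <- g[dark] * 0.25
    b[dark] <- b[dark] * 0.25
  }

  signal <- concentration_response(conc, spec$A, spec$K, spec$gain)
  r <- r + signal
  g <- g + spec$green_bleed * signal

  if (spec$n_reflections > 0L) {
    for (i in seq_len(spec$n_reflections)) {
      rad <- stats::runif(1, spec$reflection_radius[1], spec$reflection_radius[2])
      cx <- stats::runif(1, rad + 1, h - rad)
      cy <- stats::runif(1, rad + 1, w - rad)
      d2 <- (rows - cx)^2 + (cols - cy)^2
      disc <- d2 <= rad^2
      # radial falloff from full saturation: specular highlights bloom
      # rather than cut out a constant plateau
      glare <- 255 - 25 * sqrt(d2[disc]) / rad
      r[disc] <- glare; g[disc] <- glare - 2; b[disc] <- glare - 4
    }
  }

  frame <- finish_frame(r, g, b, spec$noise_sd)

  artifact <- matrix(FALSE, h, w)
  if (spec$inject_artifacts && any(dark)) {
    # emulate JPEG DC quantization: every fully dark 8x8 block collapses to
    # a single per-channel level on a coarse (step 6) grid, producing the
    # histogram spikes the preprocess module is built to remove
    planes <- unclass(frame)
    q <- 6L
    for (bi in seq_len(h %/% 8L)) {
      for (bj in seq_len(w %/% 8L)) {
        ri <- ((bi - 1L) * 8L + 1L):(bi * 8L)
        ci <- ((bj - 1L) * 8L + 1L):(bj * 8L)
        if (all(dark[ri, ci]) && max(planes[ri, ci, ]) < 40L) {
          for (ch in 1:3)
            planes[ri, ci, ch] <- as.integer(
              min(255, round(mean(planes[ri, ci, ch]) / q) * q))
          artifact[ri, ci] <- TRUE
        }
      }
    }
    frame <- rgb_frame(planes)
  }

  truth <- ground_truth(conc, artifact)
  truth$dark_mask <- dark
  list(frame = frame, truth = truth)
}
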