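#' Names of the 10 per-pixel features
#'
#' The feature vector extends a raw RGB pixel to 10 dimensions before clVAE
#' training and quantification: rescaled channel intensities (R, G, B),
#' channel proportions (pR, pG, pB), HSV hue/saturation/value (H, S, V) and
#' a rescaled red-excess term (E). Only single-pixel information enters; no
#' neighborhood or global context.
#'
#' @format Character vector of length 10.
#' @export
pixel_feature_names <- c("R", "G", "B", "pR", "pG", "pB", "H", "S", "V", "E")

#' Extract the 10-dimensional pixel feature vector
#'
#' Maps 8-bit RGB intensities to the feature set used by the clVAE and the
#' quantification models. All components lie in `[0, 1]`:
#' `R = r/255` (similarly G, B); channel proportions `pC = c/(r+g+b)` with
#' the uninformative fallback 1/3 for exactly-black pixels; standard HSV
#' conversion with hue scaled to `[0, 1]` (hue of achromatic pixels is 0);
#' red excess `E = ((r - (g+b)/2)/255 + 0.5)/1.5`, an affine rescaling of
#' the raw red-excess term chosen so that black maps to 1/3 and pure red to
#' 1; strongly blue/green pixels, whose raw excess falls below -0.5, are
#' clamped at 0 so every feature stays in the unit interval.
#'
#' @param r,g,b Intensities in `[0, 255]`; equal-length vectors are accepted
#'   and processed element-wise.
#' @return A numeric matrix with one row per input pixel and columns
#'   [pixel_feature_names].
#' @examples
#' extract_features(255, 0, 0)   # pure red: R = pR = E = 1
#' extract_features(0, 0, 0)     # black: proportions fall back to 1/3
#' @export
extract_features <- function(r, g, b) {
  if (anyNA(c(r, g, b)) || min(r, g, b) < 0 || max(r, g, b) > 255)
    stop("r, g, b must lie in [0, 255]", call. = FALSE)
  n <- length(r)
  stopifnot(length(g) == n, length(b) == n)
  s <- r + g + b
  pos <- s > 0
  pR <- pG <- pB <- rep(1 / 3, n)
  pR[pos] <- r[pos] / s[pos]
  pG[pos] <- g[pos] / s[pos]
  pB[pos] <- b[pos] / s[pos]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  E <- pmin(pmax(((r - (g + b) / 2) / 255 + 0.5) / 1.5, 0), 1)
  out <- cbind(R = r / 255, G = g / 255, B = b / 255,
               pR = pR, pG = pG, pB = pB,
               H = hsv[1, ], S = hsv[2, ], V = hsv[3, ], E = E)
  rownames(out) <- NULL
  out
}

#' Per-pixel feature planes for a whole frame
#'
#' Vectorized equivalent of [extract_features()] over every pixel of a
#' frame.
#'
#' @param frame An [rgb_frame()].
#' @return A `height x width x 10` numeric array; plane `k` holds feature
#'   `pixel_feature_names[k]`.
#' @export
extract_features_frame <- function(frame) {
  stopifnot(is_rgb_frame(frame))
  d <- dim(frame)
  feats <- extract_features(as.vector(frame[, , 1]),
                            as.vector(frame[, , 2]),
                            as.vector(frame[, , 3]))
  array(feats, c(d[1], d[2], 10L),
        dimnames = list(NULL, NULL, pixel_feature_names))
}

# features for the pixel records of a labeled pixel set (data.frame with
# r, g, b columns)
pixel_set_features <- function(pixels) {
  extract_features(pixels$r, pixels$g, pixels$b)
}
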