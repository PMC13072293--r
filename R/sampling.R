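#' Extract labeled pixels under an ROI mask
#'
#' Turns every true element of a region-of-interest mask into one labeled
#' pixel record carrying the frame's RGB values at that coordinate. Records
#' from several calls are stacked with `rbind()` to assemble class pools.
#'
#' @param frame An [rgb_frame()].
#' @param mask Logical matrix with the frame's dimensions.
#' @param label Class label, `"positive"` or `"negative"`.
#' @param concentration Optional known PPIX concentration (ug/mL) of the
#'   region, attached to every record.
#' @param frame_id Optional source-frame identifier.
#' @return A `data.frame` (labeled pixel set) with columns `x` (row), `y`
#'   (column), `r`, `g`, `b`, `label`, `concentration`, `frame_id`.
#' @export
extract_roi_pixels <- function(frame, mask, label,
                               concentration = NA_real_,
                               frame_id = NA_character_) {
  stopifnot(is_rgb_frame(frame), is.logical(mask))
  if (!identical(dim(mask), dim(frame)[1:2]))
    stop("mask dimensions do not match the frame", call. = FALSE)
  label <- match.arg(label, c("positive", "negative"))
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  plane_at <- function(ch)
    if (n == 0L) integer(0) else frame[cbind(idx, rep(ch, n))]
  data.frame(
    x = idx[, 1L], y = idx[, 2L],
    r = plane_at(1L), g = plane_at(2L), b = plane_at(3L),
    label = rep(label, n),
    concentration = rep(as.numeric(concentration), n),
    frame_id = rep(frame_id, n),
    stringsAsFactors = FALSE
  )
}

sample_rows <- function(pixels, n, what) {
  if (nrow(pixels) < n)
    stop(sprintf("%s pool has %d pixels but %d were requested",
                 what, nrow(pixels), n), call. = FALSE)
  pixels[sample.int(nrow(pixels), n), , drop = FALSE]
}

#' Balanced training set for the baseline classifiers
#'
#' Samples `n_per_class` records without replacement from each class pool,
#' mirroring the balanced composition used to train the traditional
#' classifiers (default 10,000 per class, 20,000 records in total).
#'
#' @param positives,negatives Labeled pixel sets (see
#'   [extract_roi_pixels()]) of the respective class.
#' @param n_per_class Records to draw from each pool.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A labeled pixel set with exactly `n_per_class` records per class.
#' @export
build_balanced_training_set <- function(positives, negatives,
                                        n_per_class = 10000L, seed = 1L) {
  stopifnot(all(positives$label == "positive"),
            all(negatives$label == "negative"))
  set.seed(seed)
  pos <- sample_rows(positives, n_per_class, "positive")
  neg <- sample_rows(negatives, n_per_class, "negative")
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Normal set and contrastive pairs for anomaly-detector training
#'
#' Draws `n_normal` non-fluorescent (normal) records without replacement,
#' then pairs `n_pairs` of them, drawn from that normal set, with `n_pairs`
#' fluorescent (anomaly) records for the contrastive term. Default study
#' sizes: 60,000 normals with 10,000 pairs on the sample bench; 500,000 /
#' 50,000 for the intraoperative transfer configuration.
#'
#' @param normal_pool Labeled pixel set of class `"negative"`.
#' @param anomaly_pool Labeled pixel set of class `"positive"`.
#' @param n_normal Size of the normal training set.
#' @param n_pairs Number of normal-anomaly pairs; at most `n_normal` and at
#'   most the anomaly pool size.
#' @param seed Integer seed.
#' @return List with `normal` (labeled pixel set of size `n_normal`) and
#'   `pairs`, itself a list of two aligned pixel sets `normal` and
#'   `anomaly`, each of size `n_pairs`.
#' @export
build_anomaly_training_set <- function(normal_pool, anomaly_pool,
                                       n_normal = 60000L, n_pairs = 10000L,
                                       seed = 1L) {
  stopifnot(all(normal_pool$label == "negative"),
            all(anomaly_pool$label == "positive"))
  if (n_pairs > n_normal)
    stop("n_pairs cannot exceed n_normal", call. = FALSE)
  set.seed(seed)
  normal <- sample_rows(normal_pool, n_normal, "normal")
  pair_normal <- sample_rows(normal, n_pairs, "pair-normal")
  pair_anomaly <- sample_rows(anomaly_pool, n_pairs, "anomaly")
  rownames(normal) <- rownames(pair_normal) <- rownames(pair_anomaly) <- NULL
  list(normal = normal,
       pairs = list(normal = pair_normal, anomaly = pair_anomaly))
}
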