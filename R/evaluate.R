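#' ROC curve over all distinct score thresholds
#'
#' Builds the receiver operating characteristic of a continuous
#' fluorescence score under the decision rule "flag iff score > threshold".
#' One curve point is produced per distinct score value plus a final
#' all-flagged point, so the curve runs from (FPR, TPR) = (0, 0) to (1, 1).
#' The AUC is the trapezoidal area, which equals the tie-adjusted
#' probability that a random positive outscores a random negative.
#'
#' @param scores Numeric score vector.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive class.
#' @return A `roc_curve`: list with `threshold`, `sensitivity`,
#'   `specificity`, `tp`, `fp` vectors, class counts `n_pos`/`n_neg`, and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  n <- length(s)
  ends <- c(which(diff(s) != 0), n)
  cum_tp <- cumsum(l); cum_fp <- cumsum(!l)
  # counts strictly above each distinct threshold value
  tp <- c(0L, cum_tp[ends])[seq_along(ends)]
  fp <- c(0L, cum_fp[ends])[seq_along(ends)]
  threshold <- c(s[ends], -Inf)
  tp <- c(tp, n_pos)
  fp <- c(fp, n_neg)
  sens <- tp / n_pos
  spec <- 1 - fp / n_neg
  fpr <- fp / n_neg
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(threshold = threshold, sensitivity = sens,
                 specificity = spec, tp = tp, fp = fp,
                 n_pos = n_pos, n_neg = n_neg, auc = auc),
            class = "roc_curve")
}

#' Optimal operating point of a ROC curve
#'
#' The threshold maximizing Youden's `J = sensitivity + specificity - 1`;
#' ties are broken toward the higher-specificity (more conservative)
#' point. Accuracy is computed from the underlying counts at that
#' threshold.
#'
#' @param curve A [roc_curve()].
#' @return List with `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `j`.
#' @export
optimal_operating_point <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L)
    best <- best[which.max(curve$specificity[best])]
  tn <- curve$n_neg - curve$fp[best]
  list(threshold = curve$threshold[best],
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       accuracy = (curve$tp[best] + tn) / (curve$n_pos + curve$n_neg),
       j = j[best])
}

#' Detection rate per concentration at a fixed threshold
#'
#' For each distinct true concentration, the percentage of its pixels
#' scored above the threshold — the layout of the fixed-specificity
#' comparison of models down the dilution ladder.
#'
#' @param scores Score vector.
#' @param concentrations Per-pixel true concentration (ug/mL), same length.
#' @param tau Decision threshold (flag iff score > tau).
#' @return `data.frame` with `concentration` (descending) and
#'   `detection_rate` (percent, 0-100).
#' @export
detection_rate_table <- function(scores, concentrations, tau) {
  stopifnot(length(scores) == length(concentrations))
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  levels <- sort(unique(concentrations), decreasing = TRUE)
  rate <- vapply(levels, function(cc)
    100 * mean(scores[concentrations == cc] > tau), numeric(1))
  data.frame(concentration = levels, detection_rate = rate)
}

# exactly-black pixels carry no information; detection there is defined
# away so specificity-excluding-black is well posed
black_pixel_mask <- function(frame) {
  frame[, , 1] == 0L & frame[, , 2] == 0L & frame[, , 3] == 0L
}

#' Detection mask from a score plane
#'
#' Applies the calibrated threshold to a per-pixel score plane. Scores of
#' exactly-black pixels (r = g = b = 0) are forced below any threshold
#' first, so black pixels are never flagged.
#'
#' @param score_plane Numeric matrix of pixel scores.
#' @param frame The [rgb_frame()] the scores were computed from.
#' @param tau Threshold (flag iff score > tau).
#' @return Logical detection mask.
#' @export
detection_mask <- function(score_plane, frame, tau) {
  stopifnot(is_rgb_frame(frame),
            identical(dim(score_plane), dim(frame)[1:2]))
  score_plane > tau & !black_pixel_mask(frame)
}

#' Specificity on negative (non-fluorescence-guided) frames
#'
#' Every detection on a frame from a procedure without 5-ALA is a false
#' positive. Reports, per frame, the FP pixel count, the specificity over
#' all pixels, and the specificity excluding exactly-black pixels
#' (r = g = b = 0), plus the pooled specificity over all frames.
#'
#' @param masks List of logical detection masks.
#' @param frames List of matching [rgb_frame()]s.
#' @return A `specificity_report`: `data.frame` with columns `frame`,
#'   `fp`, `total`, `black`, `specificity_all`, `specificity_excl_black`;
#'   attributes `pooled` and `pooled_excl_black`.
#' @export
negative_frame_specificity <- function(masks, frames) {
  stopifnot(length(masks) == length(frames))
  rows <- lapply(seq_along(masks), function(i) {
    mask <- masks[[i]]; frame <- frames[[i]]
    stopifnot(is.logical(mask), is_rgb_frame(frame),
              identical(dim(mask), dim(frame)[1:2]))
    total <- length(mask)
    black <- sum(black_pixel_mask(frame))
    if (total == black)
      stop("frame ", i, " is entirely black: specificity excluding black ",
           "pixels is undefined", call. = FALSE)
    fp <- sum(mask)
    data.frame(frame = i, fp = fp, total = total, black = black,
               specificity_all = 1 - fp / total,
               specificity_excl_black = 1 - fp / (total - black))
  })
  report <- do.call(rbind, rows)
  attr(report, "pooled") <- 1 - sum(report$fp) / sum(report$total)
  attr(report, "pooled_excl_black") <-
    1 - sum(report$fp) / (sum(report$total) - sum(report$black))
  class(report) <- c("specificity_report", class(report))
  report
}

#' Overlap between a model detection mask and an annotation mask
#'
#' Compares the area the model flags with a (surgeon-) annotated area:
#' area ratio (model / annotated, undefined for an empty annotation) and
#' annotation coverage (fraction of annotated pixels the model detects).
#'
#' @param model_mask,annot_mask Logical matrices of equal dimensions.
#' @return List with `model_area`, `annot_area`, `ratio`, `coverage`.
#' @export
annotation_overlap <- function(model_mask, annot_mask) {
  stopifnot(is.logical(model_mask), is.logical(annot_mask))
  if (!identical(dim(model_mask), dim(annot_mask)))
    stop("mask dimensions differ", call. = FALSE)
  model_area <- sum(model_mask)
  annot_area <- sum(annot_mask)
  list(model_area = model_area, annot_area = annot_area,
       ratio = if (annot_area > 0) model_area / annot_area else NA_real_,
       coverage = if (annot_area > 0) sum(model_mask & annot_mask) / annot_area
                  else NA_real_)
}

#' Qualitative 2-D embedding of pixel data
#'
#' Thin wrapper around exact t-SNE on a precomputed Minkowski distance
#' matrix, used to eyeball class separability of the sample-ladder pixels
#' (not a quantitative instrument). Deterministic for a fixed seed.
#'
#' @param pixels Labeled pixel set (embedded on its 10 features) or a
#'   numeric matrix.
#' @param perplexity t-SNE perplexity (default 200; scale down with
#'   the input).
#' @param minkowski_p Order of the Minkowski distance (2 = Euclidean).
#' @param seed Integer seed.
#' @param max_iter t-SNE iterations.
#' @return An `n x 2` coordinate matrix.
#' @export
embed_qualitative <- function(pixels, perplexity = 200, minkowski_p = 2,
                              seed = 1L, max_iter = 500L) {
  X <- as_feature_matrix(pixels)
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stop("need more than 3 * perplexity points", call. = FALSE)
  d <- stats::dist(X, method = "minkowski", p = minkowski_p)
  set.seed(seed)
  fit <- Rtsne::Rtsne(d, is_distance = TRUE, perplexity = perplexity,
                      theta = 0, max_iter = max_iter, pca = FALSE)
  fit$Y
}
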