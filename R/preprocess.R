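#' Per-channel intensity histogram
#'
#' Counts how often each 8-bit intensity level occurs in one channel of a
#' frame. The histogram is the input to quantization-artifact detection:
#' JPEG block artifacts in dark regions concentrate pixel mass on a few
#' intensity levels, which show up as spikes against the smoothed frequency
#' distribution.
#'
#' @param frame An [rgb_frame()].
#' @param channel One of `"red"`, `"green"`, `"blue"`.
#' @return A `channel_histogram`: list with `counts` (integer vector of
#'   length 256, index k+1 holds the frequency of level k) and `channel`.
#' @examples
#' f <- rgb_frame(array(17L, c(4, 4, 3)))
#' h <- build_channel_histogram(f, "red")
#' h$counts[18]  # level 17
#' @export
build_channel_histogram <- function(frame, channel) {
  stopifnot(is_rgb_frame(frame))
  plane <- frame[, , channel_index(channel)]
  channel_histogram(tabulate(as.integer(plane) + 1L, nbins = 256L), channel)
}

#' @rdname build_channel_histogram
#' @param counts Non-negative frequency vector; `counts[k + 1]` is the
#'   frequency of intensity level `k`. A full-range histogram has 256
#'   entries, but shorter vectors are accepted for hand-built inputs.
#' @export
channel_histogram <- function(counts, channel = "red") {
  stopifnot(all(counts >= 0), length(counts) >= 1L)
  channel_index(channel)
  structure(list(counts = as.numeric(counts), channel = channel),
            class = "channel_histogram")
}

# moving average with edge windows truncated to the in-range portion
moving_average <- function(x, window) {
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect quantization-artifact intensity levels
#'
#' Approximates a density from the channel histogram with a moving-average
#' filter and flags every intensity level whose raw frequency exceeds that
#' local density by more than `factor` (default 1.5). The moving average at
#' the histogram edges is taken over the in-range portion of the window, so
#' no counts are fabricated beyond levels 0 and 255.
#'
#' @param hist A `channel_histogram` from [build_channel_histogram()].
#' @param window Odd number of bins for the moving average, at least 3.
#' @param factor Flagging ratio, greater than 1.
#' @return Integer vector of flagged levels (possibly empty), values in
#'   0..255.
#' @export
detect_artifact_levels <- function(hist, window = 5L, factor = 1.5) {
  stopifnot(inherits(hist, "channel_histogram"))
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  if (factor <= 1) stop("factor must exceed 1", call. = FALSE)
  dens <- moving_average(hist$counts, as.integer(window))
  which(hist$counts > factor * dens) - 1L
}

# median with the lower-middle convention for even counts: the result is
# always an order statistic of the (8-bit) input
lower_median <- function(v) {
  n <- length(v)
  k <- (n + 1L) %/% 2L
  sort.int(v, partial = k)[k]
}

#' Zero flagged levels and interpolate with a 9x9 median
#'
#' In each channel, pixels whose intensity sits on a flagged level are set
#' to 0 and then replaced by the median of their 9x9 neighborhood in the
#' zeroed channel (windows at image borders are truncated to the in-image
#' intersection; an even-count window takes the lower middle order
#' statistic). Pixels not on a flagged level are returned unchanged; only
#' the offending channel of a flagged pixel is touched.
#'
#' @param frame An [rgb_frame()].
#' @param levels Named list with components `red`, `green`, `blue`, each an
#'   integer vector of flagged levels (as from [detect_artifact_levels()]).
#'   Missing components are treated as empty.
#' @return An [rgb_frame()].
#' @export
suppress_and_interpolate <- function(frame, levels) {
  stopifnot(is_rgb_frame(frame))
  out <- unclass(frame)
  h <- dim(out)[1]; w <- dim(out)[2]
  for (ch in c("red", "green", "blue")) {
    lv <- levels[[ch]]
    if (is.null(lv) || length(lv) == 0L) next
    plane <- out[, , channel_index(ch)]
    flagged <- which(matrix(plane %in% lv, h, w), arr.ind = TRUE)
    if (nrow(flagged) == 0L) next
    plane[flagged] <- 0L
    filled <- integer(nrow(flagged))
    for (i in seq_len(nrow(flagged))) {
      r <- flagged[i, 1L]; cc <- flagged[i, 2L]
      win <- plane[max(1L, r - 4L):min(h, r + 4L),
                   max(1L, cc - 4L):min(w, cc + 4L)]
      filled[i] <- lower_median(as.integer(win))
    }
    plane[flagged] <- filled
    out[, , channel_index(ch)] <- plane
  }
  rgb_frame(out)
}

#' Remove JPEG quantization artifacts from a frame
#'
#' Composition of the two preprocessing steps, applied independently per
#' channel: histogram-spike detection of artifact levels followed by
#' zeroing and 9x9 median interpolation, after which the channels are
#' reassembled into an RGB frame.
#'
#' @inheritParams build_channel_histogram
#' @inheritParams detect_artifact_levels
#' @return An [rgb_frame()].
#' @seealso [detect_artifact_levels()], [suppress_and_interpolate()]
#' @export
preprocess_frame <- function(frame, window = 5L, factor = 1.5) {
  levels <- lapply(c(red = "red", green = "green", blue = "blue"), function(ch)
    detect_artifact_levels(build_channel_histogram(frame, ch), window, factor))
  suppress_and_interpolate(frame, levels)
}
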