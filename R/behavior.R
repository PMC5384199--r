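#' Movement / immobility trace
#'
#' Uniformly sampled behavioral trace. Either a logical immobility flag per
#' frame, or a continuous activity score that is binarized against
#' `threshold` (immobile when activity <= threshold). Thresholding a
#' continuous score is a user decision, never inferred from the data.
#'
#' @param values Logical immobility flags or numeric activity scores.
#' @param fs Behavioral sampling rate in Hz (default 30, video-like).
#' @param threshold Activity threshold for binarization (required when
#'   `values` is numeric).
#' @return Object of class `movement_trace` with `immobile` (logical),
#'   `fs`, `time` (frame start times, s).
#' @export
movement_trace <- function(values, fs = 30, threshold = NULL) {
  stopifnot(fs > 0, length(values) >= 1)
  if (is.logical(values)) {
    immobile <- values
  } else {
    if (is.null(threshold))
      stop("a numeric activity trace needs an explicit threshold")
    immobile <- values <= threshold
  }
  structure(list(immobile = immobile, fs = fs,
                 time = (seq_along(values) - 1) / fs),
            class = "movement_trace")
}

#' @export
print.movement_trace <- function(x, ...) {
  cat(sprintf("<movement_trace> %d frames @ %g Hz (%.1f s), %.1f%% immobile\n",
              length(x$immobile), x$fs, length(x$immobile) / x$fs,
              100 * mean(x$immobile)))
  invisible(x)
}

#' Score freezing bouts from an immobility trace
#'
#' Freezing is the lack of movement lasting longer than `min_bout` seconds
#' (strictly: a maximal immobility run of exactly `min_bout` seconds is not
#' a bout). Returns the bout list, the total freezing time, and the
#' freezing percentage per time bin; a bout spanning a bin boundary is
#' split across bins.
#'
#' @param trace A `movement_trace`.
#' @param min_bout Minimum bout duration in seconds, exclusive (default 1).
#' @param bin Bin width in seconds for per-bin percentages (default 60).
#' @param strict Treat the threshold as strict (`> min_bout`, default). Set
#'   `FALSE` for an inclusive `>= min_bout` reading.
#' @return Object of class `freezing_summary`: `bouts` (data frame
#'   start/duration in s), `total` (s), `bins` (data frame bin_start,
#'   freezing_s, freezing_pct), `duration` (trace length, s).
#' @export
score_freezing <- function(trace, min_bout = 1, bin = 60, strict = TRUE) {
  stopifnot(inherits(trace, "movement_trace"), min_bout >= 0, bin > 0)
  fs <- trace$fs
  r <- rle(trace$immobile)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dur <- r$lengths / fs
  keep <- r$values & (if (strict) dur > min_bout + 1e-9
                      else dur >= min_bout - 1e-9)
  bouts <- data.frame(start = (starts[keep] - 1) / fs,
                      duration = dur[keep])
  total_s <- length(trace$immobile) / fs
  # distribute each bout over bins
  edges <- seq(0, total_s + bin, by = bin)
  freeze_in_bin <- numeric(length(edges) - 1)
  for (i in seq_len(nrow(bouts))) {
    b0 <- bouts$start[i]; b1 <- b0 + bouts$duration[i]
    for (j in seq_along(freeze_in_bin)) {
      lo <- edges[j]; hi <- edges[j + 1]
      ov <- min(b1, hi) - max(b0, lo)
      if (ov > 0) freeze_in_bin[j] <- freeze_in_bin[j] + ov
    }
  }
  nb <- ceiling(total_s / bin - 1e-9)
  bins <- data.frame(bin_start = edges[seq_len(nb)],
                     freezing_s = freeze_in_bin[seq_len(nb)])
  bins$freezing_pct <- 100 * bins$freezing_s /
    pmin(bin, total_s - bins$bin_start)
  structure(list(bouts = bouts, total = sum(bouts$duration),
                 bins = bins, duration = total_s, min_bout = min_bout,
                 strict = strict),
            class = "freezing_summary")
}

#' @export
print.freezing_summary <- function(x, ...) {
  cat(sprintf("<freezing_summary> %d bouts, %.2f s total over %.1f s (%.1f%%)\n",
              nrow(x$bouts), x$total, x$duration,
              100 * x$total / x$duration))
  invisible(x)
}

#' Outlier exclusion by deviation from the group mean
#'
#' A value is excluded when it lies more than `k` standard deviations from
#' the mean; mean and sample SD are computed once over all values (single
#' pass, candidate included). With zero variance nothing is excluded.
#'
#' @param values Per-animal totals (n >= 3).
#' @param k SD multiplier (default 2).
#' @return Logical inclusion mask (`TRUE` = keep).
#' @export
exclude_outliers <- function(values, k = 2) {
  stopifnot(is.numeric(values), length(values) >= 3, all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= k * s
}

#' Distance travelled per time bin
#'
#' Sums Euclidean step lengths of an (x, y, t) track per time bin; the step
#' from t\[i\] to t\[i+1\] is assigned to the bin containing t\[i\]. A 30-min
#' open-field session with the default 5-min bin yields 6 bins.
#'
#' @param track Data frame with numeric columns `x`, `y`, `t` (t monotone
#'   non-decreasing, seconds).
#' @param bin Bin width in seconds (default 300).
#' @return Data frame `bin_start`, `distance`.
#' @export
bin_locomotion <- function(track, bin = 300) {
  stopifnot(all(c("x", "y", "t") %in% names(track)), bin > 0)
  t <- track$t
  if (is.unsorted(t)) stop("timestamps must be monotone")
  n <- nrow(track)
  total_t <- max(t[n], 0)
  nb <- max(1L, ceiling(total_t / bin - 1e-9))
  out <- data.frame(bin_start = (seq_len(nb) - 1) * bin, distance = 0)
  if (n < 2) return(out)
  step <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  b <- pmin(nb, floor(t[-n] / bin + 1e-12) + 1)
  agg <- tapply(step, b, sum)
  out$distance[as.integer(names(agg))] <- as.numeric(agg)
  out
}
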