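#' Observational fear conditioning session protocol
#'
#' Describes the timeline of an OFC session: a habituation phase followed by
#' a conditioning phase in which the demonstrator receives a foot shock at
#' the start of every shock cycle. Analysis windows are derived from this
#' protocol: habituation is tiled into `hab_window`-second windows, and each
#' conditioning shock cycle contributes one guard-trimmed window of
#' `shock_period - shock_duration - 2 * guard` seconds, excluding the shock
#' itself plus a guard margin at each end contaminated by the shock artifact.
#'
#' Defaults follow the standard OFC design: 5 min habituation, then a 2-s
#' shock every 12 s for 4 min, a 1-s guard at each end of the inter-shock
#' interval, 10-s habituation windows — giving twenty 8-s conditioning
#' windows.
#'
#' @param habituation_duration Habituation phase length in seconds.
#' @param conditioning_duration Conditioning phase length in seconds; must be
#'   a positive multiple of `shock_period`.
#' @param shock_period Shock cycle length in seconds (one shock per cycle).
#' @param shock_duration Foot-shock duration in seconds.
#' @param guard Guard margin in seconds excluded at each end of the
#'   inter-shock interval.
#' @param hab_window Habituation analysis-window length in seconds.
#' @param first_shock_offset Latency of the first shock after conditioning
#'   onset, in seconds (default 0: shock at each cycle start).
#' @return An object of class `session_protocol`.
#' @examples
#' p <- session_protocol()
#' conditioning_epochs(p)  # twenty 8-s windows
#' @export
session_protocol <- function(habituation_duration = 300,
                             conditioning_duration = 240,
                             shock_period = 12,
                             shock_duration = 2,
                             guard = 1,
                             hab_window = 10,
                             first_shock_offset = 0) {
  stopifnot(habituation_duration >= 0, conditioning_duration > 0,
            shock_period > 0, shock_duration >= 0, guard >= 0,
            hab_window > 0, first_shock_offset >= 0)
  if (shock_period <= shock_duration + 2 * guard)
    stop("shock_period must exceed shock_duration + 2*guard; the ",
         "guard-trimmed analysis window would be empty")
  n_cycles <- conditioning_duration / shock_period
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("conditioning_duration must be a positive multiple of shock_period")
  structure(list(habituation_duration = habituation_duration,
                 conditioning_duration = conditioning_duration,
                 shock_period = shock_period,
                 shock_duration = shock_duration,
                 guard = guard,
                 hab_window = hab_window,
                 first_shock_offset = first_shock_offset,
                 cond_window = shock_period - shock_duration - 2 * guard),
            class = "session_protocol")
}

#' @export
print.session_protocol <- function(x, ...) {
  cat("OFC session protocol\n")
  cat(sprintf("  habituation : %g s (windows of %g s)\n",
              x$habituation_duration, x$hab_window))
  cat(sprintf("  conditioning: %g s, %g-s shock every %g s, guard %g s\n",
              x$conditioning_duration, x$shock_duration, x$shock_period,
              x$guard))
  cat(sprintf("  -> %d conditioning windows of %g s\n",
              as.integer(round(x$conditioning_duration / x$shock_period)),
              x$cond_window))
  invisible(x)
}

#' Shock onset times
#'
#' Onset times (seconds from recording start) of each foot shock under a
#' protocol, assuming the recording starts at habituation onset.
#'
#' @param p A `session_protocol`.
#' @return Numeric vector of shock onsets in seconds.
#' @export
shock_onsets <- function(p) {
  stopifnot(inherits(p, "session_protocol"))
  n <- as.integer(round(p$conditioning_duration / p$shock_period))
  p$habituation_duration + p$first_shock_offset +
    (seq_len(n) - 1) * p$shock_period
}

new_epoch_set <- function(phase, start, end) {
  stopifnot(length(start) == length(end), all(end > start))
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop("epochs overlap")
  len <- unique(round(end - start, 9))
  if (length(len) != 1) stop("epochs must share a common length")
  structure(data.frame(phase = phase, start = start, end = end),
            window = len, class = c("epoch_set", "data.frame"))
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d x %g-s '%s' windows in [%g, %g) s\n",
              nrow(x), attr(x, "window"), x$phase[1],
              min(x$start), max(x$end)))
  invisible(x)
}

#' Guard-trimmed conditioning analysis windows
#'
#' One window per shock cycle: the inter-shock interval with the shock and a
#' `guard`-second margin at each end removed, i.e. cycle k (0-based) maps to
#' the half-open interval
#' `[k*period + shock_duration + guard, (k+1)*period - guard)` relative to
#' conditioning onset. Under the default protocol this yields twenty 8-s
#' windows over the 4-min conditioning session.
#'
#' @param p A `session_protocol`.
#' @param relative If `TRUE`, times are relative to conditioning onset;
#'   otherwise (default) to recording start (habituation onset at 0).
#' @return An `epoch_set` data frame (phase, start, end) with a `window`
#'   attribute giving the common window length in seconds.
#' @export
conditioning_epochs <- function(p, relative = FALSE) {
  stopifnot(inherits(p, "session_protocol"))
  if (p$cond_window <= 0) stop("guard-trimmed window length is not positive")
  n <- as.integer(round(p$conditioning_duration / p$shock_period))
  k <- seq_len(n) - 1
  off <- if (relative) 0 else p$habituation_duration
  start <- off + p$first_shock_offset + k * p$shock_period +
    p$shock_duration + p$guard
  end <- off + p$first_shock_offset + (k + 1) * p$shock_period - p$guard
  new_epoch_set("conditioning", start, end)
}

#' Habituation analysis windows
#'
#' Tiles the habituation phase with non-overlapping `hab_window`-second
#' windows starting at recording onset; any remainder shorter than one
#' window is dropped. `n_windows` restricts the tiling to the first n tiles.
#'
#' @param p A `session_protocol`.
#' @param n_windows Optional cap on the number of windows.
#' @return An `epoch_set` data frame.
#' @export
habituation_epochs <- function(p, n_windows = NULL) {
  stopifnot(inherits(p, "session_protocol"))
  if (p$hab_window > p$habituation_duration)
    stop("hab_window exceeds the habituation duration")
  n <- floor(p$habituation_duration / p$hab_window + 1e-9)
  if (!is.null(n_windows)) {
    stopifnot(n_windows >= 1)
    if (n_windows > n) stop("n_windows exceeds the number of full tiles")
    n <- n_windows
  }
  k <- seq_len(n) - 1
  new_epoch_set("habituation", k * p$hab_window, (k + 1) * p$hab_window)
}

#' Partition conditioning epochs into session quarters
#'
#' Assigns conditioning epochs to four quarters by shock-cycle index, so
#' quarters align with shock-cycle boundaries (60 s each under the default
#' protocol: 4 quarters x 5 epochs). If the epoch count is not divisible by
#' 4, the last quarter absorbs the remainder and a warning is raised.
#'
#' @param epochs An `epoch_set` of conditioning epochs.
#' @return A list of four `epoch_set` objects named `Q1`..`Q4`.
#' @export
quarter_partition <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- nrow(epochs)
  if (n < 4) stop("need at least 4 epochs to form quarters")
  per <- n %/% 4
  if (n %% 4 != 0)
    warning(sprintf(
      "%d epochs are not divisible by 4; last quarter carries %d epochs",
      n, n - 3 * per))
  idx <- c(rep(1:3, each = per), rep(4, n - 3 * per))
  out <- lapply(1:4, function(q) {
    e <- epochs[idx == q, , drop = FALSE]
    new_epoch_set(e$phase[1], e$start, e$end)
  })
  names(out) <- paste0("Q", 1:4)
  out
}

#' Convert epoch times to sample index ranges
#'
#' Discretizes an epoch set against a sampling rate: for the half-open
#' interval `[start, end)`, samples `floor(start*fs) .. floor(end*fs) - 1`
#' (1-based indices `floor(start*fs)+1 .. floor(end*fs)`) are included.
#'
#' @param epochs An `epoch_set`.
#' @param fs Sampling rate in Hz.
#' @return Integer matrix with columns `first`, `last` (1-based, inclusive).
#' @export
epoch_samples <- function(epochs, fs) {
  stopifnot(inherits(epochs, "epoch_set"), fs > 0)
  first <- floor(epochs$start * fs + 1e-9) + 1
  last <- floor(epochs$end * fs + 1e-9)
  cbind(first = as.integer(first), last = as.integer(last))
}
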