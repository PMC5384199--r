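#' Multichannel LFP recording
#'
#' Container for a multichannel local field potential recording: a
#' channel-by-time sample matrix, sampling rate, unique channel labels
#' (convention `REGION_HEMI`, e.g. `AI_L`, `BLA_R`), and optional
#' annotations (phase intervals, shock schedule). Time origin is recording
#' start (t = 0); all intervals are half-open `[start, end)` in seconds.
#'
#' @param samples Numeric matrix, channels x time samples.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique channel labels, one per row.
#' @param annotations Optional named list (e.g. `protocol`, `shocks`).
#' @return An object of class `ofc_recording`.
#' @export
ofc_recording <- function(samples, fs, labels = rownames(samples),
                          annotations = list()) {
  samples <- as.matrix(samples)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  stopifnot(is.numeric(samples), fs > 0,
            length(labels) == nrow(samples))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(is.finite(samples))) stop("samples must be finite")
  rownames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels,
                 annotations = annotations),
            class = "ofc_recording")
}

#' @export
print.ofc_recording <- function(x, ...) {
  cat(sprintf("<ofc_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Default eight-region channel label set
#'
#' Bilateral anterior cingulate (ACC), anterior insula (AI), retrosplenial
#' cortex (RSC) and basolateral amygdala (BLA).
#'
#' @return Character vector of eight `REGION_HEMI` labels.
#' @export
default_regions <- function() {
  c("ACC_L", "ACC_R", "AI_L", "AI_R", "RSC_L", "RSC_R", "BLA_L", "BLA_R")
}

#' Extract epoch sample blocks from a recording
#'
#' @param rec An `ofc_recording`.
#' @param epochs An `epoch_set`.
#' @return List of channel x time matrices, one per epoch.
#' @export
extract_epochs <- function(rec, epochs) {
  stopifnot(inherits(rec, "ofc_recording"))
  idx <- epoch_samples(epochs, rec$fs)
  if (max(idx[, "last"]) > ncol(rec$samples))
    stop("epochs extend past the end of the recording")
  lapply(seq_len(nrow(idx)), function(i)
    rec$samples[, idx[i, "first"]:idx[i, "last"], drop = FALSE])
}
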