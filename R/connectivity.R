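#' Epoch-wise pairwise coefficient between two band-filtered signals
#'
#' Default mode `"zero-lag"` is the zero-lag Pearson correlation of the two
#' epochs. Mode `"lagged-max"` returns the maximum of the normalized
#' cross-correlation over lags within `max_lag` seconds (default 0.1 s),
#' useful when a small conduction delay between regions is plausible.
#'
#' @param x,y Equal-length numeric vectors (band-filtered epoch signals).
#' @param mode `"zero-lag"` or `"lagged-max"`.
#' @param fs Sampling rate in Hz; required for `"lagged-max"`.
#' @param max_lag Lag window in seconds for `"lagged-max"`.
#' @return Coefficient in `[-1, 1]`.
#' @export
pair_coefficient <- function(x, y, mode = c("zero-lag", "lagged-max"),
                             fs = NULL, max_lag = 0.1) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y), length(x) > 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: coefficient undefined")
  if (mode == "zero-lag") return(stats::cor(x, y))
  stopifnot(!is.null(fs))
  lag_max <- max(1L, as.integer(round(max_lag * fs)))
  cc <- stats::ccf(x, y, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  max(cc)
}

new_connectivity_matrix <- function(mat, labels, band, phase, mode,
                                    n_epochs, epoch_stack = NULL) {
  dimnames(mat) <- list(labels, labels)
  structure(list(matrix = mat, labels = labels, band = band, phase = phase,
                 mode = mode, n_epochs = n_epochs,
                 epoch_stack = epoch_stack),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<connectivity_matrix> %s, band %g-%g Hz, %s, %d epochs\n",
              x$phase, x$band[1], x$band[2], x$mode, x$n_epochs))
  print(round(x$matrix, digits))
  invisible(x)
}

#' @export
plot.connectivity_matrix <- function(x, zlim = c(-1, 1), ...) {
  p <- nrow(x$matrix)
  graphics::image(seq_len(p), seq_len(p), t(x$matrix[p:1, ]), zlim = zlim,
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  main = sprintf("%s (%g-%g Hz)", x$phase,
                                 x$band[1], x$band[2]), ...)
  graphics::axis(1, seq_len(p), x$labels, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(p), rev(x$labels), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Region-by-region connectivity matrix for one subject and phase
#'
#' For each epoch, every channel is band-filtered (zero-phase Butterworth)
#' and the pairwise coefficient is computed for each unordered channel pair;
#' per-epoch coefficients are then aggregated across epochs (arithmetic mean
#' by default; Fisher-z mean via `fisher_z = TRUE`). Epochs are sliced from
#' the raw recording and filtered individually, so samples outside the
#' analysis windows — including shock artifacts excluded by the guard —
#' cannot influence any matrix entry.
#'
#' @param rec An `ofc_recording` (raw, unfiltered).
#' @param epochs An `epoch_set` within the recording.
#' @param band Band in Hz (default theta, 3-8 Hz).
#' @param mode Coefficient mode, see [pair_coefficient()].
#' @param fisher_z Aggregate per-epoch coefficients on the Fisher-z scale.
#' @param channels Optional subset/order of channel labels; all must exist.
#' @return A `connectivity_matrix` (symmetric, unit diagonal) retaining the
#'   per-epoch coefficient stack in `$epoch_stack` (pairs x epochs).
#' @export
subject_matrix <- function(rec, epochs, band = theta_band(),
                           mode = c("zero-lag", "lagged-max"),
                           fisher_z = FALSE, channels = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "ofc_recording"))
  if (is.null(channels)) channels <- rec$labels
  missing <- setdiff(channels, rec$labels)
  if (length(missing))
    stop("recording is missing channel(s): ", paste(missing, collapse = ", "))
  check_band(band, rec$fs)
  blocks <- extract_epochs(rec, epochs)
  p <- length(channels)
  pairs <- utils::combn(p, 2)
  stack <- matrix(NA_real_, ncol(pairs), length(blocks),
                  dimnames = list(paste(channels[pairs[1, ]],
                                        channels[pairs[2, ]], sep = "~"),
                                  NULL))
  # filter every (epoch, channel) series in one matrix pass
  L <- min(vapply(blocks, ncol, 1L))   # discretization can differ by 1
  big <- matrix(0, L, length(blocks) * p)
  for (e in seq_along(blocks))
    big[, (e - 1) * p + seq_len(p)] <- t(blocks[[e]][channels, seq_len(L),
                                                     drop = FALSE])
  big <- butter_filtfilt_mat(big, rec$fs, band)
  for (e in seq_along(blocks)) {
    filt <- big[, (e - 1) * p + seq_len(p), drop = FALSE]
    sds <- apply(filt, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance epoch signal in channel(s): ",
           paste(channels[sds == 0], collapse = ", "))
    if (mode == "zero-lag") {
      cm <- stats::cor(filt)
      stack[, e] <- cm[t(pairs)]
    } else {
      for (j in seq_len(ncol(pairs)))
        stack[j, e] <- pair_coefficient(filt[, pairs[1, j]],
                                        filt[, pairs[2, j]],
                                        mode = mode, fs = rec$fs)
    }
  }
  agg <- if (fisher_z) tanh(rowMeans(atanh(pmin(pmax(stack, -1 + 1e-12),
                                                1 - 1e-12))))
         else rowMeans(stack)
  mat <- diag(1, p)
  mat[t(pairs)] <- agg
  mat[t(pairs)[, 2:1, drop = FALSE]] <- agg
  new_connectivity_matrix(mat, channels, band, epochs$phase[1],
                          if (fisher_z) paste0(mode, "+fisher-z") else mode,
                          length(blocks), stack)
}

#' Group-average connectivity matrix
#'
#' Element-wise mean across subject matrices, plus the per-pair subject
#' values for export to external statistics.
#'
#' @param matrices List of `connectivity_matrix` objects with identical
#'   labels, band and phase.
#' @return A `connectivity_matrix` whose `$subject_values` is a pairs x
#'   subjects matrix of per-subject coefficients.
#' @export
group_matrix <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "connectivity_matrix")))
  ref <- matrices[[1]]
  for (m in matrices) {
    if (!identical(m$labels, ref$labels))
      stop("connectivity matrices have mismatched region labels")
    if (!identical(m$band, ref$band) || !identical(m$phase, ref$phase))
      stop("connectivity matrices have mismatched band/phase")
  }
  arr <- vapply(matrices, function(m) m$matrix,
                matrix(0, length(ref$labels), length(ref$labels)))
  avg <- apply(arr, 1:2, mean)
  out <- new_connectivity_matrix(avg, ref$labels, ref$band, ref$phase,
                                 ref$mode,
                                 sum(vapply(matrices, `[[`, 0, "n_epochs")))
  ut <- upper.tri(avg)
  pair_names <- outer(ref$labels, ref$labels,
                      function(a, b) paste(a, b, sep = "~"))
  # upper triangle of the transpose walks pairs row-major (i < j)
  out$subject_values <- vapply(matrices, function(m) t(m$matrix)[t(ut)],
                               numeric(sum(ut)))
  out$subject_values <- matrix(out$subject_values, nrow = sum(ut),
                               dimnames = list(t(pair_names)[t(ut)], NULL))
  out
}

#' Per-quarter connectivity matrices from a retained epoch stack
#'
#' Splits the per-epoch coefficient stack of a conditioning
#' `connectivity_matrix` into four consecutive blocks of shock cycles
#' (remainder absorbed by the last quarter, as in [quarter_partition()])
#' and re-aggregates each block into its own matrix.
#'
#' @param cm A `connectivity_matrix` with a retained `$epoch_stack`.
#' @return List of four `connectivity_matrix` objects named `Q1`..`Q4`.
#' @export
quarter_matrices <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"), !is.null(cm$epoch_stack))
  n <- ncol(cm$epoch_stack)
  if (n < 4) stop("need at least 4 epochs to form quarters")
  per <- n %/% 4
  idx <- c(rep(1:3, each = per), rep(4, n - 3 * per))
  p <- length(cm$labels)
  pairs <- utils::combn(p, 2)
  out <- lapply(1:4, function(q) {
    sub <- cm$epoch_stack[, idx == q, drop = FALSE]
    agg <- rowMeans(sub)
    mat <- diag(1, p)
    mat[t(pairs)] <- agg
    mat[t(pairs)[, 2:1, drop = FALSE]] <- agg
    new_connectivity_matrix(mat, cm$labels, cm$band,
                            paste0(cm$phase, "-Q", q), cm$mode,
                            ncol(sub), sub)
  })
  names(out) <- paste0("Q", 1:4)
  out
}

#' Euclidean dissimilarity between two connectivity matrices
#'
#' Euclidean norm of the element-wise difference over the strict upper
#' triangle: each unordered region pair counts once and the unit diagonal
#' is excluded. Zero if and only if the matrices are identical off the
#' diagonal.
#'
#' @param m1,m2 `connectivity_matrix` objects or plain symmetric matrices
#'   with identical labels/shape.
#' @return Non-negative scalar.
#' @export
matrix_dissimilarity <- function(m1, m2) {
  a <- if (inherits(m1, "connectivity_matrix")) m1$matrix else as.matrix(m1)
  b <- if (inherits(m2, "connectivity_matrix")) m2$matrix else as.matrix(m2)
  if (!identical(dim(a), dim(b)))
    stop("matrices have different shapes")
  if (!is.null(dimnames(a)) && !is.null(dimnames(b)) &&
      !identical(dimnames(a), dimnames(b)))
    stop("matrices have different region labels")
  d <- (a - b)[upper.tri(a)]
  sqrt(sum(d^2))
}

#' Habituation-to-quarter dissimilarity trajectory
#'
#' Dissimilarity from the habituation matrix to each conditioning-quarter
#' matrix, with an ordinary least-squares trend over the quarter index
#' (1..4). A sustained network change shows as an elevated, non-decreasing
#' trajectory; a transient one returns toward zero.
#'
#' @param hab Habituation `connectivity_matrix`.
#' @param quarters List of per-quarter `connectivity_matrix` objects (>= 2).
#' @return Object of class `dissimilarity_trajectory`: `values`, `slope`,
#'   `intercept` (trend evaluated at quarter index 1..k).
#' @export
dissimilarity_trajectory <- function(hab, quarters) {
  stopifnot(length(quarters) >= 2)
  vals <- vapply(quarters, matrix_dissimilarity, 0, m1 = hab)
  tr <- linear_trend(vals)  # x = 0..k-1: intercept is the trend at Q1
  structure(list(values = unname(vals), slope = tr$slope,
                 intercept = tr$intercept,
                 reference = if (inherits(hab, "connectivity_matrix"))
                   hab$phase else "reference"),
            class = "dissimilarity_trajectory")
}

#' @export
print.dissimilarity_trajectory <- function(x, ...) {
  cat("<dissimilarity_trajectory> from", x$reference, "matrix\n")
  cat("  d:", paste(sprintf("%.4f", x$values), collapse = ", "), "\n")
  cat(sprintf("  trend: slope %.4f, intercept %.4f\n", x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.dissimilarity_trajectory <- function(x, ...) {
  q <- seq_along(x$values)
  graphics::plot(q, x$values, type = "b", pch = 16, xlab = "Quarter",
                 ylab = "Matrix dissimilarity", xaxt = "n", ...)
  graphics::axis(1, q, paste0("Q", q))
  graphics::abline(x$intercept - x$slope, x$slope, lty = 3)
  invisible(x)
}
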