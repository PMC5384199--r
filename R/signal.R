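#' Frequency band definitions
#'
#' The band table used throughout: delta 1-3 Hz, theta 3-8 Hz, alpha
#' 8-13 Hz, beta 14-30 Hz, gamma 30-55 Hz; each band is the half-open
#' interval `[low, high)`. The 13-14 Hz gap between alpha and beta is part
#' of the definition and is deliberately not bridged.
#'
#' @return Data frame with columns `band`, `low`, `high`.
#' @export
band_table <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low  = c(1, 3, 8, 14, 30),
             high = c(3, 8, 13, 30, 55))
}

#' The theta band (3-8 Hz)
#' @return Numeric length-2 vector `c(low, high)` in Hz.
#' @export
theta_band <- function() c(3, 8)

check_band <- function(band, fs) {
  stopifnot(is.numeric(band), length(band) == 2)
  if (band[1] >= band[2]) stop("invalid band: low must be < high")
  if (band[2] >= fs / 2)
    stop(sprintf("invalid band: high edge %g Hz is at/above Nyquist (%g Hz)",
                 band[2], fs / 2))
  if (band[1] <= 0) stop("invalid band: low edge must be > 0")
  invisible(band)
}

# Butterworth bandpass designed as cascaded second-order sections.
# The single-polynomial transfer-function form is numerically
# ill-conditioned for narrow bands at high sampling rates (3-8 Hz at
# 1600 Hz puts 8 poles on top of each other near z = 1), so the analog
# prototype is lowpass->bandpass transformed and bilinear-mapped pole by
# pole, and the filter is applied one biquad at a time.
butter_bp_sos <- function(order, low, high, fs) {
  N <- order
  w1 <- 2 * fs * tan(pi * low / fs)       # pre-warped analog edges
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(N)
  p_lp <- exp(1i * pi * (2 * k + N - 1) / (2 * N))   # LP prototype poles
  a <- 0.5 * bw * p_lp                                # LP -> BP doubling
  p_bp <- c(a + sqrt(a^2 - w0^2), a - sqrt(a^2 - w0^2))
  zp <- (2 * fs + p_bp) / (2 * fs - p_bp)             # bilinear transform
  zp <- zp[order(Re(zp), abs(Im(zp)))]                # conjugates adjacent
  sos <- list()
  used <- rep(FALSE, length(zp))
  for (i in seq_along(zp)) {
    if (used[i]) next
    j <- which(!used & abs(zp - Conj(zp[i])) < 1e-8 &
                 seq_along(zp) != i)[1]
    used[c(i, j)] <- TRUE
    # numerator (z-1)(z+1): one zero from s=0, one from s=Inf, per biquad
    sos[[length(sos) + 1]] <- list(b = c(1, 0, -1),
                                   a = Re(c(1, -(zp[i] + zp[j]),
                                            zp[i] * zp[j])))
  }
  # normalize to unit gain at the geometric center frequency
  zc <- exp(1i * 2 * pi * sqrt(low * high) / fs)
  g <- 1 + 0i
  for (s in sos)
    g <- g * sum(s$b * c(1, zc^-1, zc^-2)) / sum(s$a * c(1, zc^-1, zc^-2))
  sos[[1]]$b <- sos[[1]]$b / abs(g)
  sos
}

# |H(f)| of an SOS cascade (single pass)
sos_gain <- function(sos, f, fs) {
  vapply(f, function(fi) {
    zc <- exp(1i * 2 * pi * fi / fs)
    g <- 1 + 0i
    for (s in sos)
      g <- g * sum(s$b * c(1, zc^-1, zc^-2)) /
        sum(s$a * c(1, zc^-1, zc^-2))
    abs(g)
  }, 0)
}

# Zero-phase Butterworth bandpass on the columns of a matrix
# (forward-backward per biquad, so the lag structure feeding
# cross-correlation is preserved). Zero-padded at the tail to flush the
# filter before the reversed pass; the cascade runs in compiled code.
butter_filtfilt_mat <- function(x, fs, band, order = 4) {
  sos <- butter_bp_sos(order, band[1], band[2], fs)
  sos_mat <- do.call(rbind, lapply(sos, function(s) c(s$b, s$a[2:3])))
  sos_filtfilt_cpp(x, sos_mat, pad = min(nrow(x), 1024L))
}

butter_filtfilt <- function(x, fs, band, order = 4) {
  as.numeric(butter_filtfilt_mat(matrix(x, ncol = 1), fs, band, order))
}

#' Zero-phase band-pass filtering
#'
#' Applies a 4th-order Butterworth band-pass (prototype order 4, i.e.
#' 2 x 4 poles after the band transform, -3 dB at the band edges) forward
#' and backward (zero phase) to every channel of a recording or to a
#' numeric vector / channel x time matrix. The filter runs as cascaded
#' second-order sections for numerical stability at narrow normalized
#' bands. Zero-phase filtering is required because lag structure feeds the
#' cross-correlation stage.
#'
#' @param x An `ofc_recording`, numeric vector, or channel x time matrix.
#' @param band `c(low, high)` in Hz; both edges must lie below Nyquist.
#' @param fs Sampling rate in Hz (taken from the recording if `x` is one).
#' @param order Filter order (default 4).
#' @return Same shape/class as the input, band-limited.
#' @export
bandpass <- function(x, band = theta_band(), fs = NULL, order = 4) {
  if (inherits(x, "ofc_recording")) {
    check_band(band, x$fs)
    out <- x
    out$samples <- t(butter_filtfilt_mat(t(x$samples), x$fs, band, order))
    rownames(out$samples) <- x$labels
    return(out)
  }
  stopifnot(!is.null(fs))
  check_band(band, fs)
  if (is.matrix(x))
    t(butter_filtfilt_mat(t(x), fs, band, order))
  else
    butter_filtfilt(x, fs, band, order)
}

# One-sided Welch periodogram of a set of segments (columns); returns
# power density so that sum(psd) * df ~= var(x) (Parseval, up to window
# edge effects). Segments are demeaned, Hann-windowed and FFT'd in one
# mvfft call.
welch_psd_segments <- function(segs, fs) {
  seg_len <- nrow(segs)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  segs <- sweep(segs, 2, colMeans(segs)) * w
  X <- stats::mvfft(segs)[seq_len(seg_len %/% 2 + 1), , drop = FALSE]
  p <- rowMeans(Mod(X)^2) / (fs * sum(w^2))
  # fold two-sided density into one-sided (all bins except DC/Nyquist)
  inner <- 2:(length(p) - if (seg_len %% 2 == 0) 1 else 0)
  p[inner] <- 2 * p[inner]
  list(freq = seq(0, by = fs / seg_len, length.out = length(p)), psd = p,
       n_segments = ncol(segs))
}

#' Welch power spectral density over epochs
#'
#' Averaged spectral estimate per channel over the epochs of one phase:
#' each epoch is cut into Hann-windowed segments (default 2 s, 50% overlap),
#' and the modified periodograms of all segments of all epochs are averaged.
#' At 2-s segments the frequency resolution is 0.5 Hz.
#'
#' @param epoch_list List of channel x time matrices (see
#'   [extract_epochs()]), or a single matrix/vector.
#' @param fs Sampling rate in Hz.
#' @param seg_sec Welch segment length in seconds (default 2).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return List with `freq` (Hz), `psd` (channels x frequency matrix of
#'   power density, signal units^2/Hz) and `n_segments`.
#' @export
psd <- function(epoch_list, fs, seg_sec = 2, overlap = 0.5) {
  if (!is.list(epoch_list)) epoch_list <- list(epoch_list)
  epoch_list <- lapply(epoch_list, function(e)
    if (is.matrix(e)) e else matrix(e, nrow = 1))
  seg_len <- as.integer(round(seg_sec * fs))
  if (any(vapply(epoch_list, ncol, 1L) < seg_len))
    stop("every epoch must be at least one Welch segment (",
         seg_sec, " s) long")
  n_ch <- nrow(epoch_list[[1]])
  labels <- rownames(epoch_list[[1]])
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  seg_of <- function(v) {
    starts <- seq(1L, length(v) - seg_len + 1L, by = step)
    vapply(starts, function(s) v[s:(s + seg_len - 1L)], numeric(seg_len))
  }
  acc <- NULL
  for (ch in seq_len(n_ch)) {
    segs <- do.call(cbind, lapply(epoch_list, function(e) seg_of(e[ch, ])))
    w <- welch_psd_segments(segs, fs)
    if (is.null(acc)) {
      acc <- matrix(0, n_ch, length(w$psd))
      freq <- w$freq
    }
    acc[ch, ] <- w$psd
  }
  rownames(acc) <- labels
  list(freq = freq, psd = acc, n_segments = w$n_segments)
}

#' Min-max normalization
#'
#' Maps a vector onto `[0, 1]` by `(x_i - min(x)) / (max(x) - min(x))`.
#' Order-preserving; the output always attains both 0 and 1.
#'
#' @param x Numeric vector, length >= 2, not all equal.
#' @return Normalized vector of the same length.
#' @examples
#' minmax_normalize(c(2, 4, 6))  # 0 0.5 1
#' @export
minmax_normalize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  r <- range(x)
  if (r[1] == r[2]) stop("cannot min-max normalize a constant vector")
  (x - r[1]) / (r[2] - r[1])
}

#' Normalized band powers from a PSD
#'
#' Min-max normalizes the PSD bins within `flim` (default 1-55 Hz) per
#' channel, then summarizes each band of the band table as the mean of the
#' normalized bins whose frequency falls in `[low, high)`. Normalization is
#' per channel and per phase (each call normalizes one phase's PSD), so
#' phase comparisons compare two independently normalized spectra.
#'
#' @param spec A PSD as returned by [psd()].
#' @param bands Band table (default [band_table()]).
#' @param flim Frequency range of the normalization group, Hz.
#' @return Data frame: `channel`, `band`, `power` (normalized, in `[0,1]`).
#' @export
band_powers <- function(spec, bands = band_table(), flim = c(1, 55)) {
  stopifnot(is.list(spec), !is.null(spec$freq), !is.null(spec$psd))
  keep <- spec$freq >= flim[1] & spec$freq <= flim[2]
  if (min(spec$freq) > flim[1] || max(spec$freq) < flim[2])
    stop(sprintf("PSD does not cover %g-%g Hz", flim[1], flim[2]))
  f <- spec$freq[keep]
  labels <- rownames(spec$psd)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(spec$psd)))
  out <- do.call(rbind, lapply(seq_len(nrow(spec$psd)), function(ch) {
    z <- minmax_normalize(spec$psd[ch, keep])
    data.frame(channel = labels[ch], band = bands$band,
               power = vapply(seq_len(nrow(bands)), function(b)
                 mean(z[f >= bands$low[b] & f < bands$high[b]]), 0))
  }))
  rownames(out) <- NULL
  out
}
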