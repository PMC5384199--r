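#' Simulated LFP configuration
#'
#' Describes a synthetic multichannel LFP recording spanning one OFC
#' session (habituation then conditioning, per the protocol). Selected
#' channel pairs share a common narrowband source during a given phase:
#' within the coupling window each coupled channel carries
#' `x_k = gain * s + sd * n_k`, where `s` is a shared band-limited Gaussian
#' process (unit variance in the carrier band) and `n_k` is independent
#' band-limited noise of unit variance. The zero-lag in-band correlation of
#' an equally mixed pair is therefore `gain^2 / (gain^2 + sd^2)` in closed
#' form — with `gain = 1` this is `1 / (1 + sd^2)`, which calibrates the
#' simulator. Channels and windows without coupling carry 1/f ("pink")
#' background noise, scaled by `sd`.
#'
#' @param labels Channel labels (default the eight bilateral regions).
#' @param fs Sampling rate in Hz (default 1600).
#' @param protocol A `session_protocol` giving phase timing.
#' @param coupling List of coupling specs, each a list with `pair`
#'   (two channel labels), `phase` (`"habituation"`, `"conditioning"`, or
#'   `"Q1"`..`"Q4"` for a conditioning quarter), `gain` in `[0, 1]`, and
#'   `band` `c(low, high)` Hz (default theta).
#' @param noise List with `exponent` (pink-noise spectral exponent,
#'   default 1) and `sd` (noise mixing coefficient sigma, default 1).
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   recordings.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(labels = default_regions(), fs = 1600,
                       protocol = session_protocol(),
                       coupling = list(),
                       noise = list(exponent = 1, sd = 1),
                       seed = 1) {
  stopifnot(fs > 0, inherits(protocol, "session_protocol"),
            length(labels) >= 1, !anyDuplicated(labels))
  noise$exponent <- noise$exponent %||% 1
  noise$sd <- noise$sd %||% 1
  stopifnot(noise$sd >= 0)
  for (cs in coupling) {
    stopifnot(length(cs$pair) == 2, all(cs$pair %in% labels))
    if (is.null(cs$gain) || cs$gain < 0 || cs$gain > 1)
      stop("coupling gain must lie in [0, 1]")
    band <- cs$band %||% theta_band()
    check_band(band, fs)
  }
  structure(list(labels = labels, fs = fs, protocol = protocol,
                 coupling = coupling, noise = noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# named phase windows [start, end) in seconds from recording start
phase_windows <- function(p) {
  hab <- c(0, p$habituation_duration)
  cond <- c(p$habituation_duration,
            p$habituation_duration + p$conditioning_duration)
  qlen <- p$conditioning_duration / 4
  w <- list(habituation = hab, conditioning = cond)
  for (q in 1:4)
    w[[paste0("Q", q)]] <- cond[1] + c(q - 1, q) * qlen
  w
}

# unit-sd 1/f^exponent-power noise, synthesized directly in the frequency
# domain (Hermitian spectrum with Gaussian coefficients shaped by
# f^(-exponent/2), one inverse FFT)
pink_noise <- function(n, exponent = 1) {
  h <- n %/% 2
  re <- stats::rnorm(h)
  im <- stats::rnorm(h)
  amp <- seq_len(h)^(-exponent / 2)
  Xh <- complex(real = re * amp, imaginary = im * amp)
  if (n %% 2 == 0) Xh[h] <- complex(real = re[h] * amp[h], imaginary = 0)
  X <- c(0, Xh, Conj(rev(Xh[seq_len(h - (n + 1) %% 2)])))
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

# unit-sd band-limited Gaussian process
unit_band_noise <- function(n, fs, band) {
  x <- butter_filtfilt(stats::rnorm(n), fs, band)
  x / stats::sd(x)
}

#' Generate a coupled multichannel LFP recording
#'
#' Realizes a [sim_config()]: background pink noise on every channel, with
#' shared narrowband sources mixed into the coupled channel pairs inside
#' their phase windows (see [sim_config()] for the mixing model).
#' Deterministic under the config seed.
#'
#' @param config A `sim_config`.
#' @return An `ofc_recording` spanning habituation + conditioning, with the
#'   protocol attached as an annotation.
#' @export
generate_coupled_lfp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$protocol
  fs <- config$fs
  n <- as.integer(round((p$habituation_duration + p$conditioning_duration)
                        * fs))
  n_ch <- length(config$labels)
  sigma <- config$noise$sd
  samples <- matrix(0, n_ch, n, dimnames = list(config$labels, NULL))
  for (k in seq_len(n_ch))
    samples[k, ] <- sigma * pink_noise(n, config$noise$exponent)
  wins <- phase_windows(p)
  # group coupling specs by phase window, preserving list order
  win_names <- unique(vapply(config$coupling, function(cs)
    cs$phase %||% "conditioning", ""))
  for (wn in win_names) {
    if (is.null(wins[[wn]]))
      stop("unknown coupling phase: ", wn)
    i0 <- floor(wins[[wn]][1] * fs + 1e-9) + 1
    i1 <- floor(wins[[wn]][2] * fs + 1e-9)
    len <- i1 - i0 + 1
    contrib <- list()
    bands <- list()
    for (cs in config$coupling) {
      if (!identical(cs$phase %||% "conditioning", wn)) next
      band <- cs$band %||% theta_band()
      s <- cs$gain * unit_band_noise(len, fs, band)
      for (ch in cs$pair) {
        contrib[[ch]] <- (contrib[[ch]] %||% 0) + s
        bands[[ch]] <- band  # in-band channel noise uses this carrier band
      }
    }
    for (ch in sort(names(contrib))) {
      noise_k <- if (sigma > 0)
        sigma * unit_band_noise(len, fs, bands[[ch]]) else 0
      samples[ch, i0:i1] <- contrib[[ch]] + noise_k
    }
  }
  ofc_recording(samples, fs, config$labels,
                annotations = list(protocol = p, config_seed = config$seed))
}

#' Shock schedule of a protocol
#'
#' @param p A `session_protocol`.
#' @return Data frame `onset`, `duration` (seconds from recording start).
#' @export
shock_schedule <- function(p) {
  data.frame(onset = shock_onsets(p), duration = p$shock_duration)
}

#' Inject shock artifacts into a recording
#'
#' Adds a large deterministic transient (a Hann-windowed 10-Hz burst of the
#' given amplitude) to every channel strictly within each shock window
#' `[onset, onset + duration)`. Samples outside the shock windows are
#' unchanged bit-exact, so guard-trimmed analysis windows are unaffected by
#' construction.
#'
#' @param rec An `ofc_recording`.
#' @param schedule Data frame with `onset` and `duration` columns in
#'   seconds (see [shock_schedule()]).
#' @param amplitude Artifact amplitude in signal units.
#' @return The recording with artifacts added.
#' @export
inject_shock_artifacts <- function(rec, schedule, amplitude) {
  stopifnot(inherits(rec, "ofc_recording"), amplitude >= 0,
            all(c("onset", "duration") %in% names(schedule)))
  dur_total <- ncol(rec$samples) / rec$fs
  o <- order(schedule$onset)
  schedule <- schedule[o, , drop = FALSE]
  if (any(schedule$onset < 0) ||
      any(schedule$onset + schedule$duration > dur_total + 1e-9))
    stop("shock schedule extends outside the recording")
  ends <- schedule$onset + schedule$duration
  if (nrow(schedule) > 1 && any(schedule$onset[-1] < ends[-nrow(schedule)]))
    stop("shock windows overlap")
  if (amplitude == 0) return(rec)
  s_mat <- rec$samples
  for (i in seq_len(nrow(schedule))) {
    i0 <- floor(schedule$onset[i] * rec$fs + 1e-9) + 1
    i1 <- floor(ends[i] * rec$fs + 1e-9)
    len <- i1 - i0 + 1
    t <- (seq_len(len) - 1) / rec$fs
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
    burst <- amplitude * w * sin(2 * pi * 10 * t)
    s_mat[, i0:i1] <- s_mat[, i0:i1, drop = FALSE] +
      rep(burst, each = nrow(s_mat))
  }
  rec$samples <- s_mat
  rec$annotations$shocks <- schedule
  rec
}

#' Generate a binary movement trace from a bout specification
#'
#' Builds a uniformly sampled immobility trace that is immobile exactly
#' during the listed bouts (frame i, covering
#' `[i/fs_beh, (i+1)/fs_beh)`, is immobile when its start time falls in a
#' bout).
#'
#' @param bouts Data frame or 2-column matrix of `start`, `duration` in
#'   seconds; non-overlapping, within `[0, total]`.
#' @param total Trace length in seconds.
#' @param fs_beh Behavioral sampling rate in Hz (default 30).
#' @return A `movement_trace`.
#' @export
generate_movement_trace <- function(bouts, total, fs_beh = 30) {
  stopifnot(total > 0, fs_beh > 0)
  bouts <- as.data.frame(bouts)
  if (nrow(bouts) == 0)
    return(movement_trace(rep(FALSE, round(total * fs_beh)), fs_beh))
  names(bouts)[1:2] <- c("start", "duration")
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  ends <- bouts$start + bouts$duration
  if (any(bouts$start < 0) || any(ends > total + 1e-9))
    stop("bouts extend outside [0, total]")
  if (nrow(bouts) > 1 && any(bouts$start[-1] < ends[-nrow(bouts)] - 1e-9))
    stop("bouts overlap")
  t <- (seq_len(round(total * fs_beh)) - 1) / fs_beh
  imm <- rep(FALSE, length(t))
  for (i in seq_len(nrow(bouts)))
    imm <- imm | (t >= bouts$start[i] - 1e-9 & t < ends[i] - 1e-9)
  movement_trace(imm, fs_beh)
}

#' Generate a synthetic plaque image with known burden
#'
#' Places bright compact blobs inside a region mask until the plaque pixel
#' count equals `round(target_fraction/100 * region area)` exactly (the
#' last blob is trimmed to size, nearest-to-center pixels first), then
#' renders an image with optional Gaussian noise. The truth mask's burden
#' therefore matches the target to well within 0.5 percentage points for
#' any reasonably sized region.
#'
#' @param region_mask Logical (or 0/1) matrix; `TRUE` = inside the region.
#' @param target_fraction Target burden in percent, in `[0, 100]`.
#' @param blob_params List: `r_min`, `r_max` blob radius range in pixels
#'   (defaults 3, 8), `intensity` blob brightness in `[0, 1]` (default
#'   0.8), `max_iter` placement attempts (default 10000).
#' @param noise_sd Gaussian pixel noise SD (default 0: noiseless).
#' @param seed Integer seed.
#' @return List with `image` (matrix in `[0, 1]`) and `truth_mask`
#'   (logical matrix).
#' @export
generate_plaque_image <- function(region_mask, target_fraction,
                                  blob_params = list(), noise_sd = 0,
                                  seed = 1) {
  region_mask <- as.matrix(region_mask) > 0
  if (target_fraction < 0 || target_fraction > 100)
    stop("target_fraction must lie in [0, 100]")
  bp <- utils::modifyList(list(r_min = 3, r_max = 8, intensity = 0.8,
                               max_iter = 10000), blob_params)
  set.seed(seed)
  area <- sum(region_mask)
  if (area == 0) stop("region mask is empty")
  target_px <- round(target_fraction / 100 * area)
  truth <- matrix(FALSE, nrow(region_mask), ncol(region_mask))
  reg_idx <- which(region_mask, arr.ind = TRUE)
  iter <- 0
  while (sum(truth) < target_px) {
    iter <- iter + 1
    if (iter > bp$max_iter)
      stop("target fraction unreachable with these blob parameters")
    c_rc <- reg_idx[sample.int(nrow(reg_idx), 1), ]
    r <- stats::runif(1, bp$r_min, bp$r_max)
    rr <- max(1, floor(c_rc[1] - r)):min(nrow(truth), ceiling(c_rc[1] + r))
    cc <- max(1, floor(c_rc[2] - r)):min(ncol(truth), ceiling(c_rc[2] + r))
    d2 <- outer((rr - c_rc[1])^2, (cc - c_rc[2])^2, `+`)
    cand <- which(d2 <= r^2, arr.ind = TRUE)
    cand_lin <- cbind(rr[cand[, 1]], cc[cand[, 2]])
    keep <- region_mask[cand_lin] & !truth[cand_lin]
    cand_lin <- cand_lin[keep, , drop = FALSE]
    need <- target_px - sum(truth)
    if (nrow(cand_lin) > need) {
      o <- order(d2[cand][keep])   # trim outermost pixels first
      cand_lin <- cand_lin[o[seq_len(need)], , drop = FALSE]
    }
    truth[cand_lin] <- TRUE
  }
  img <- matrix(0, nrow(truth), ncol(truth))
  img[truth] <- bp$intensity
  if (noise_sd > 0)
    img[] <- pmin(1, pmax(0, img + stats::rnorm(length(img), 0, noise_sd)))
  list(image = img, truth_mask = truth)
}

#' Cohort specification for the synthetic study
#'
#' Describes one group of subjects: the coupled pair, its habituation gain
#' and per-quarter conditioning gains, the noise model, and the monotone
#' plaque-to-freezing link. The `"Tg"`-like default elevates AI_L~BLA_R
#' coupling during conditioning with gains that keep rising across
#' quarters (a sustained network change); the `"Wt"`-like default uses
#' equal gains in both phases (no systematic change).
#'
#' @param label Group label.
#' @param n_subjects Number of subjects.
#' @param pair The coupled channel pair.
#' @param hab_gain Habituation coupling gain.
#' @param cond_gains Length-4 vector of per-quarter conditioning gains (a
#'   scalar is recycled).
#' @param noise Noise model, see [sim_config()].
#' @param fs,fs_beh LFP and behavioral sampling rates, Hz.
#' @param protocol A `session_protocol`.
#' @param shock_amplitude Injected shock-artifact amplitude (signal units).
#' @param plaque List: `burden_range` (uniform AI burden range, %),
#'   `freeze_base`, `freeze_per_burden`, `freeze_noise` (fraction of the
#'   conditioning session frozen: base + per_burden * burden + noise).
#' @param seed Base seed; subject s uses `seed + 7919 * s`.
#' @return Object of class `group_spec`.
#' @export
group_spec <- function(label = "Tg", n_subjects = 10,
                       pair = c("AI_L", "BLA_R"),
                       hab_gain = 0.3,
                       cond_gains = c(0.5, 0.65, 0.8, 0.9),
                       noise = list(exponent = 1, sd = 1),
                       fs = 1600, fs_beh = 30,
                       protocol = session_protocol(),
                       shock_amplitude = 25,
                       plaque = list(burden_range = c(0.5, 12),
                                     freeze_base = 0.08,
                                     freeze_per_burden = 0.03,
                                     freeze_noise = 0.04),
                       seed = 1) {
  cond_gains <- rep(cond_gains, length.out = 4)
  stopifnot(hab_gain >= 0, hab_gain <= 1,
            all(cond_gains >= 0), all(cond_gains <= 1),
            n_subjects >= 1)
  structure(list(label = label, n_subjects = n_subjects, pair = pair,
                 hab_gain = hab_gain, cond_gains = cond_gains,
                 noise = noise, fs = fs, fs_beh = fs_beh,
                 protocol = protocol, shock_amplitude = shock_amplitude,
                 plaque = plaque, seed = as.integer(seed)),
            class = "group_spec")
}

#' Wild-type-like cohort spec: equal coupling gains in both phases
#' @param ... Overrides passed to [group_spec()].
#' @export
wt_group_spec <- function(...) {
  args <- utils::modifyList(
    list(label = "Wt", n_subjects = 7, hab_gain = 0.3, cond_gains = 0.3,
         plaque = list(burden_range = c(0, 0), freeze_base = 0.08,
                       freeze_per_burden = 0, freeze_noise = 0.04)),
    list(...))
  do.call(group_spec, args)
}

#' Transgenic-like cohort spec: sustained elevated conditioning coupling
#' @param ... Overrides passed to [group_spec()].
#' @export
tg_group_spec <- function(...) do.call(group_spec, list(...))

# place bouts totalling ~target_s seconds of freezing in [t0, t0+window)
make_bouts <- function(target_s, t0, window, min_len = 1.5, max_len = 6) {
  if (target_s <= 0) return(data.frame(start = numeric(), duration = numeric()))
  target_s <- min(target_s, 0.9 * window)
  lens <- numeric()
  while (sum(lens) < target_s - min_len) {
    lens <- c(lens, stats::runif(1, min_len, max_len))
  }
  rem <- target_s - sum(lens)
  if (rem > 0) {
    if (rem >= min_len) lens <- c(lens, rem)
    else lens[length(lens)] <- lens[length(lens)] + rem
  }
  mobile <- window - sum(lens)
  gaps <- stats::runif(length(lens) + 1)
  gaps <- gaps / sum(gaps) * mobile
  starts <- t0 + cumsum(gaps)[seq_along(lens)] +
    c(0, cumsum(lens))[seq_along(lens)]
  data.frame(start = starts, duration = lens)
}

#' Generate a full synthetic cohort
#'
#' Realizes a [group_spec()]: per subject, one LFP recording (with the
#' group's phase-dependent coupling and injected shock artifacts), one
#' movement trace whose conditioning-session freezing follows a monotone
#' noisy function of the subject's AI plaque burden, and a per-region
#' plaque burden table (BLA/RSC/ACC burdens are attenuated noisy copies of
#' the AI burden). Deterministic under the spec seed.
#'
#' @param spec A `group_spec`.
#' @param include_recordings Generate the LFP recordings (default `TRUE`).
#'   When `FALSE`, `recording` is `NULL` for every subject; the behavioral
#'   and plaque draws use an independent RNG stream and are bit-identical
#'   either way.
#' @return Object of class `group_dataset`: `label`, `spec`, and
#'   `subjects`, a list with per-subject `id`, `recording`, `trace`,
#'   `plaque` (data frame region/burden), `freezing_target_s`.
#' @export
generate_group_dataset <- function(spec, include_recordings = TRUE) {
  stopifnot(inherits(spec, "group_spec"))
  p <- spec$protocol
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    sseed <- spec$seed + 7919L * s
    rec <- NULL
    if (include_recordings) {
      coupling <- c(
        if (spec$hab_gain > 0)
          list(list(pair = spec$pair, phase = "habituation",
                    gain = spec$hab_gain, band = theta_band())),
        lapply(1:4, function(q)
          list(pair = spec$pair, phase = paste0("Q", q),
               gain = spec$cond_gains[q], band = theta_band())))
      cfg <- sim_config(fs = spec$fs, protocol = p, coupling = coupling,
                        noise = spec$noise, seed = sseed)
      rec <- generate_coupled_lfp(cfg)
      if (spec$shock_amplitude > 0)
        rec <- inject_shock_artifacts(rec, shock_schedule(p),
                                      spec$shock_amplitude)
    }
    set.seed(sseed + 1L)
    pl <- spec$plaque
    ai_burden <- stats::runif(1, pl$burden_range[1], pl$burden_range[2])
    atten <- c(AI = 1, BLA = 0.7, RSC = 0.45, ACC = 0.4)
    burdens <- pmax(0, ai_burden * atten +
                      stats::rnorm(4, 0, 0.05 * max(ai_burden, 1)))
    frac <- pl$freeze_base + pl$freeze_per_burden * ai_burden +
      stats::rnorm(1, 0, pl$freeze_noise)
    frac <- min(max(frac, 0.01), 0.9)
    target <- frac * p$conditioning_duration
    bouts <- rbind(
      make_bouts(0.02 * p$habituation_duration, 0, p$habituation_duration),
      make_bouts(target, p$habituation_duration, p$conditioning_duration))
    trace <- generate_movement_trace(
      bouts, p$habituation_duration + p$conditioning_duration, spec$fs_beh)
    list(id = sprintf("%s-%02d", spec$label, s), recording = rec,
         trace = trace,
         plaque = data.frame(region = names(atten),
                             burden = unname(burdens)),
         freezing_target_s = target)
  })
  structure(list(label = spec$label, spec = spec, subjects = subjects),
            class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("<group_dataset> '%s', %d subjects\n", x$label,
              length(x$subjects)))
  invisible(x)
}
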