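# shared fixture builders (everything is generated in code at test time)

# pure tone as a one-channel recording-like vector
make_tone <- function(freq, fs = 1600, dur = 10, amp = 1) {
  t <- (seq_len(round(fs * dur)) - 1) / fs
  amp * sin(2 * pi * freq * t)
}

# conditioning-only protocol (habituation collapsed to zero)
cond_only_protocol <- function(...) {
  session_protocol(habituation_duration = 0, hab_window = 1e-3, ...)
}

# two-channel shared-source recording with mixing x_k = s + sigma * n_k
make_coupled_pair <- function(sigma, seed, gain = 1, fs = 1600) {
  p <- cond_only_protocol()
  cfg <- sim_config(labels = c("A", "B"), fs = fs, protocol = p,
                    coupling = list(list(pair = c("A", "B"),
                                         phase = "conditioning",
                                         gain = gain)),
                    noise = list(exponent = 1, sd = sigma), seed = seed)
  list(rec = generate_coupled_lfp(cfg), protocol = p)
}

# circular disk region mask
disk_mask <- function(n = 200, r = 80) {
  d2 <- outer((seq_len(n) - n / 2)^2, (seq_len(n) - n / 2)^2, `+`)
  d2 <= r^2
}
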