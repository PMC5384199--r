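test_that("generation is bit-identical under the same seed and diverges otherwise", {
  p <- cond_only_protocol()
  cfg <- function(seed) sim_config(labels = c("A", "B"), protocol = p,
                                   coupling = list(list(pair = c("A", "B"),
                                                        phase = "conditioning",
                                                        gain = 0.5)),
                                   seed = seed)
  r1 <- generate_coupled_lfp(cfg(99))
  r2 <- generate_coupled_lfp(cfg(99))
  expect_identical(r1$samples, r2$samples)
  expect_false(identical(r1$samples, generate_coupled_lfp(cfg(100))$samples))
})

test_that("noiseless coupling gives perfectly correlated theta channels", {
  d <- make_coupled_pair(sigma = 0, seed = 3)
  ep <- conditioning_epochs(d$protocol)
  blocks <- extract_epochs(d$rec, ep)
  # with sd = 0 both channels carry the identical shared source
  expect_equal(blocks[[1]]["A", ], blocks[[1]]["B", ])
  cm <- subject_matrix(d$rec, ep)
  expect_equal(cm$matrix["A", "B"], 1)
})

test_that("pink background noise has a falling spectrum", {
  p <- cond_only_protocol()
  cfg <- sim_config(labels = "A", protocol = p, coupling = list(), seed = 6)
  rec <- generate_coupled_lfp(cfg)
  sp <- psd(rec$samples, rec$fs)
  lo <- mean(sp$psd[1, sp$freq >= 2 & sp$freq < 6])
  hi <- mean(sp$psd[1, sp$freq >= 40 & sp$freq < 60])
  expect_gt(lo / hi, 3)
  expect_equal(sd(rec$samples[1, ]), 1, tolerance = 1e-6)
})

test_that("coupling configs are validated", {
  p <- cond_only_protocol()
  expect_error(sim_config(labels = c("A", "B"), protocol = p,
                          coupling = list(list(pair = c("A", "Z"),
                                               gain = 0.5))),
               "pair")
  expect_error(sim_config(labels = c("A", "B"), protocol = p,
                          coupling = list(list(pair = c("A", "B"),
                                               gain = 1.5))),
               "gain")
  expect_error(sim_config(labels = c("A", "B"), protocol = p,
                          coupling = list(list(pair = c("A", "B"),
                                               gain = 0.5,
                                               band = c(3, 900)))),
               "Nyquist")
  bad <- sim_config(labels = c("A", "B"), protocol = p,
                    coupling = list(list(pair = c("A", "B"), gain = 0.5,
                                         phase = "Q9")))
  expect_error(generate_coupled_lfp(bad), "phase")
})

test_that("shock artifacts leave samples outside shock windows bit-exact", {
  p <- session_protocol()
  cfg <- sim_config(labels = c("A", "B"), protocol = p, coupling = list(),
                    seed = 12)
  clean <- generate_coupled_lfp(cfg)
  dirty <- inject_shock_artifacts(clean, shock_schedule(p), amplitude = 25)
  sched <- shock_schedule(p)
  in_shock <- rep(FALSE, ncol(clean$samples))
  for (i in seq_len(nrow(sched))) {
    i0 <- floor(sched$onset[i] * 1600) + 1
    i1 <- floor((sched$onset[i] + sched$duration[i]) * 1600)
    in_shock[i0:i1] <- TRUE
  }
  expect_identical(clean$samples[, !in_shock], dirty$samples[, !in_shock])
  expect_gt(max(abs(dirty$samples[, in_shock] - clean$samples[, in_shock])),
            10)
  # consequently the connectivity analysis is artifact-invariant to
  # machine precision
  ep <- conditioning_epochs(p)
  expect_equal(subject_matrix(dirty, ep)$matrix,
               subject_matrix(clean, ep)$matrix, tolerance = 1e-12)
  # amplitude 0 is the identity
  expect_identical(inject_shock_artifacts(clean, sched, 0)$samples,
                   clean$samples)
  bad <- data.frame(onset = 539.5, duration = 2)
  expect_error(inject_shock_artifacts(clean, bad, 25), "outside")
})

test_that("movement traces round-trip through freezing scoring", {
  bouts <- data.frame(start = c(5, 20.5, 40), duration = c(3, 2.5, 6))
  tr <- generate_movement_trace(bouts, total = 60, fs_beh = 30)
  fr <- score_freezing(tr, bin = 60)
  expect_equal(nrow(fr$bouts), 3)
  expect_equal(fr$total, sum(bouts$duration), tolerance = 0.1)
  expect_equal(fr$bouts$start, bouts$start, tolerance = 1 / 30)
  expect_error(generate_movement_trace(data.frame(start = c(0, 1),
                                                  duration = c(2, 2)),
                                       total = 10), "overlap")
  expect_error(generate_movement_trace(data.frame(start = 9, duration = 2),
                                       total = 10), "outside")
})

test_that("plaque images hit the target burden exactly in the truth mask", {
  mask <- disk_mask()
  for (f in c(1, 5, 12)) {
    out <- generate_plaque_image(mask, f, seed = f)
    got <- 100 * sum(out$truth_mask) / sum(mask)
    expect_equal(got, 100 * round(f / 100 * sum(mask)) / sum(mask))
    expect_lt(abs(got - f), 0.5)
    expect_true(all(out$truth_mask[!mask] == FALSE))
  }
  blank <- generate_plaque_image(mask, 0)
  expect_equal(sum(blank$truth_mask), 0)
  expect_true(all(blank$image == 0))
})

test_that("unreachable plaque targets fail loudly instead of looping", {
  mask <- disk_mask(30, 12)
  expect_error(generate_plaque_image(mask, 90,
                                     blob_params = list(r_min = 0.5,
                                                        r_max = 0.6,
                                                        max_iter = 50)),
               "unreachable")
  expect_error(generate_plaque_image(mask, 101), "0, 100")
})

test_that("cohort freezing rises monotonically with plaque burden by design", {
  spec <- tg_group_spec(n_subjects = 12, seed = 200)
  ds <- generate_group_dataset(spec, include_recordings = FALSE)
  expect_null(ds$subjects[[1]]$recording)
  burden <- vapply(ds$subjects, function(s)
    s$plaque$burden[s$plaque$region == "AI"], 0)
  target <- vapply(ds$subjects, `[[`, 0, "freezing_target_s")
  expect_gt(spearman(burden, target, p_mode = "approx")$estimate, 0.5)
  # scored freezing from the generated traces tracks the target
  scored <- vapply(ds$subjects, function(s) {
    fr <- score_freezing(s$trace, bin = 60)
    sum(fr$bins$freezing_s[fr$bins$bin_start >= 300])
  }, 0)
  expect_equal(scored, target, tolerance = 0.1)
  # wild-type-like spec: zero burden everywhere
  wt <- generate_group_dataset(wt_group_spec(n_subjects = 3, seed = 201),
                               include_recordings = FALSE)
  wb <- vapply(wt$subjects, function(s) max(s$plaque$burden), 0)
  expect_lt(max(wb), 0.2)
})

test_that("cohort datasets are reproducible and recordings match the flag", {
  spec <- tg_group_spec(n_subjects = 2, seed = 77)
  a <- generate_group_dataset(spec, include_recordings = FALSE)
  b <- generate_group_dataset(spec, include_recordings = FALSE)
  expect_identical(vapply(a$subjects, `[[`, 0, "freezing_target_s"),
                   vapply(b$subjects, `[[`, 0, "freezing_target_s"))
  expect_identical(a$subjects[[2]]$plaque, b$subjects[[2]]$plaque)
  expect_identical(a$subjects[[1]]$trace$immobile,
                   b$subjects[[1]]$trace$immobile)
})
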