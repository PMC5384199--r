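test_that("pair coefficient hits the +/-1 boundaries for (anti)copies", {
  set.seed(7)
  x <- rnorm(500)
  expect_equal(pair_coefficient(x, x), 1)
  expect_equal(pair_coefficient(x, -x), -1)
  expect_error(pair_coefficient(x, numeric(500)), "zero-variance")
})

test_that("lagged-max mode recovers correlation hidden by a conduction delay", {
  fs <- 1600
  x <- make_tone(5, fs, dur = 4)
  y <- make_tone(5, fs, dur = 4)
  lag <- round(fs * 0.05)                       # 50 ms = quarter theta cycle
  y <- c(y[-seq_len(lag)], y[seq_len(lag)])
  expect_lt(abs(pair_coefficient(x, y)), 0.1)   # zero-lag sees the shift
  # ccf normalizes by n, so a perfect lagged copy peaks at (n - lag) / n
  expect_equal(pair_coefficient(x, y, mode = "lagged-max", fs = fs),
               (length(x) - lag) / length(x), tolerance = 0.01)
})

test_that("shared-source mixing yields the closed-form theta coupling", {
  # x_k = s + sigma * n_k with unit-variance components:
  # cor(x_1, x_2) = 1 / (1 + sigma^2)
  got <- vapply(c(0, 1, 2), function(sigma) {
    d <- make_coupled_pair(sigma, seed = 41)
    cm <- subject_matrix(d$rec, conditioning_epochs(d$protocol))
    cm$matrix["A", "B"]
  }, 0)
  expect_lt(max(abs(got - 1 / (1 + c(0, 1, 2)^2))), 0.05)
})

test_that("uncoupled channels give near-zero off-diagonal coupling", {
  p <- cond_only_protocol()
  cfg <- sim_config(labels = c("A", "B", "C"), protocol = p,
                    coupling = list(), seed = 17)
  cm <- subject_matrix(generate_coupled_lfp(cfg), conditioning_epochs(p))
  expect_equal(diag(cm$matrix), c(A = 1, B = 1, C = 1))
  expect_lt(max(abs(cm$matrix[upper.tri(cm$matrix)])), 0.05)
  expect_equal(cm$matrix, t(cm$matrix))
})

test_that("a two-channel matrix keeps a unit diagonal", {
  # single-pair case: the symmetric assignment must not fall back to
  # linear indexing and overwrite the diagonal
  d <- make_coupled_pair(1, seed = 19)
  cm <- subject_matrix(d$rec, conditioning_epochs(d$protocol))
  expect_equal(diag(cm$matrix), c(A = 1, B = 1))
  expect_equal(cm$matrix["A", "B"], cm$matrix["B", "A"])
  q <- quarter_matrices(cm)
  expect_equal(diag(q$Q3$matrix), c(A = 1, B = 1))
})

test_that("aggregated matrix equals the mean of the retained epoch stack", {
  d <- make_coupled_pair(1, seed = 5)
  ep <- conditioning_epochs(d$protocol)
  cm <- subject_matrix(d$rec, ep)
  expect_equal(dim(cm$epoch_stack), c(1L, nrow(ep)))
  expect_equal(cm$matrix["A", "B"], mean(cm$epoch_stack["A~B", ]))
  zm <- subject_matrix(d$rec, ep, fisher_z = TRUE)
  expect_equal(zm$matrix["A", "B"], tanh(mean(atanh(cm$epoch_stack["A~B", ]))))
})

test_that("channel subsetting reorders and missing channels error", {
  d <- make_coupled_pair(1, seed = 9)
  ep <- conditioning_epochs(d$protocol)
  cm <- subject_matrix(d$rec, ep, channels = c("B", "A"))
  expect_equal(cm$labels, c("B", "A"))
  expect_equal(cm$matrix["B", "A"],
               subject_matrix(d$rec, ep)$matrix["A", "B"])
  expect_error(subject_matrix(d$rec, ep, channels = c("A", "Z")), "Z")
})

test_that("group matrix averages element-wise and records subject values", {
  d1 <- make_coupled_pair(1, seed = 21)
  d2 <- make_coupled_pair(2, seed = 22)
  ep <- conditioning_epochs(d1$protocol)
  m1 <- subject_matrix(d1$rec, ep)
  m2 <- subject_matrix(d2$rec, ep)
  g <- group_matrix(list(m1, m2))
  expect_equal(g$matrix, (m1$matrix + m2$matrix) / 2)
  expect_equal(g$subject_values["A~B", ],
               c(m1$matrix["A", "B"], m2$matrix["A", "B"]))
  expect_equal(group_matrix(list(m1))$matrix, m1$matrix)
  m3 <- m2
  m3$labels <- c("A", "C")
  dimnames(m3$matrix) <- list(m3$labels, m3$labels)
  expect_error(group_matrix(list(m1, m3)), "label")
})

test_that("matrix dissimilarity matches hand-computed upper-triangle norms", {
  a <- diag(1, 8)
  b <- matrix(1, 8, 8)
  # 8 regions -> 28 unordered pairs each differing by 1
  expect_equal(matrix_dissimilarity(a, b), sqrt(28))
  expect_equal(matrix_dissimilarity(a, a), 0)
  a2 <- diag(1, 3)
  b2 <- a2
  b2[1, 2] <- b2[2, 1] <- 0.6
  b2[1, 3] <- b2[3, 1] <- -0.8
  expect_equal(matrix_dissimilarity(a2, b2), sqrt(0.6^2 + 0.8^2))
  expect_error(matrix_dissimilarity(diag(1, 3), diag(1, 4)), "shape")
})

test_that("dissimilarity is invariant under a common relabeling permutation", {
  set.seed(31)
  m <- diag(1, 5)
  m[upper.tri(m)] <- runif(10, -1, 1)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m2 <- diag(1, 5)
  m2[upper.tri(m2)] <- runif(10, -1, 1)
  m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
  perm <- sample(5)
  expect_equal(matrix_dissimilarity(m[perm, perm], m2[perm, perm]),
               matrix_dissimilarity(m, m2))
})

test_that("trajectory trend is exact for a linear-by-construction series", {
  hab <- diag(1, 3)
  quarters <- lapply(1:4, function(q) {
    m <- diag(1, 3)
    m[1, 2] <- m[2, 1] <- 0.1 * q   # d(Q_q) = 0.1 * q exactly
    m
  })
  tr <- dissimilarity_trajectory(hab, quarters)
  expect_equal(tr$values, 0.1 * (1:4))
  expect_equal(tr$slope, 0.1)
  expect_equal(tr$intercept, 0.1)   # trend evaluated at Q1
})

test_that("quarter matrices partition the epoch stack consistently", {
  d <- make_coupled_pair(1, seed = 13)
  cm <- subject_matrix(d$rec, conditioning_epochs(d$protocol))
  q <- quarter_matrices(cm)
  expect_equal(names(q), paste0("Q", 1:4))
  expect_equal(unname(vapply(q, `[[`, 0, "n_epochs")), rep(5, 4))
  # quarter means recombine to the full-phase mean (equal-size quarters)
  expect_equal(mean(vapply(q, function(m) m$matrix["A", "B"], 0)),
               cm$matrix["A", "B"])
  expect_equal(q$Q2$matrix["A", "B"], mean(cm$epoch_stack["A~B", 6:10]))
})
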