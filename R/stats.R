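new_corr_result <- function(estimate, n, p, method) {
  structure(list(estimate = unname(estimate), n = n, p.value = unname(p),
                 method = method),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("%s: r = %.4f, n = %d, p = %.4g\n",
              x$method, x$estimate, x$n, x$p.value))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with a two-sided p-value from the t-transform
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return A `corr_result` with `estimate`, `n`, `p.value`, `method`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  new_corr_result(r, n, p, "Pearson")
}

# r_s via Pearson on midranks (handles ties)
spearman_rho <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# all permutations of 1..n, one per row
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation
#'
#' r_s is Pearson's correlation of the average ranks (midranks under ties).
#' The two-sided p-value is, by default, computed by exhaustive enumeration
#' of all n! permutations of one variable's ranks for n <= `exact_max`
#' (p = proportion of permutations with |r_s| at least as large as
#' observed), and by the t-approximation on n - 2 degrees of freedom
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); neither may be
#'   entirely tied.
#' @param p_mode `"auto"` (exact for n <= exact_max), `"exact"`, or
#'   `"approx"`.
#' @param exact_max Largest n for which the exhaustive permutation null is
#'   enumerated (default 8).
#' @return A `corr_result`.
#' @export
spearman <- function(x, y, p_mode = c("auto", "exact", "approx"),
                     exact_max = 8) {
  p_mode <- match.arg(p_mode)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("all-tied input: rank correlation undefined")
  rho <- spearman_rho(x, y)
  exact <- switch(p_mode, exact = TRUE, approx = FALSE, auto = n <= exact_max)
  if (exact && n > 10)
    stop("exact permutation p is only feasible for small n (<= 10)")
  if (exact) {
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    pm <- perms(n)
    null_r <- apply(pm, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(null_r) >= abs(rho) - 1e-12)
    method <- "Spearman (exact permutation)"
  } else {
    p <- if (abs(rho) >= 1) 0 else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(t), df = n - 2)
    }
    method <- "Spearman (t approximation)"
  }
  new_corr_result(rho, n, p, method)
}

#' Steiger's Z-test for two dependent correlations sharing one variable
#'
#' Compares r12 and r13 measured on the same n subjects, where variable 1
#' is shared (e.g. freezing vs AI plaque burden and freezing vs RSC plaque
#' burden) and r23 is the correlation of the two non-shared variables.
#' Default variant is Steiger's Z1* with the pooled estimate
#' `rbar = (r12 + r13)/2` in the covariance term:
#' \deqn{Z = (z12 - z13) \sqrt{(n-3) / (2 - 2 s)}}
#' with `z = atanh(r)`, `s = psi / (1 - rbar^2)^2` and
#' `psi = r23 (1 - 2 rbar^2) - 0.5 rbar^2 (1 - 2 rbar^2 - r23^2)`.
#' `method = "williams"` gives Williams' T2 (t on n - 3 df) instead.
#' The same machinery is conventionally applied to Spearman coefficients;
#' the normal approximation is then an approximation on ranks.
#'
#' @param r12,r13 The two dependent correlations being compared.
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @param method `"steiger"` (Z1*, default) or `"williams"` (T2).
#' @return Object of class `steiger_result`: `statistic`, `p.value`,
#'   `method`, and the inputs.
#' @export
steiger_z <- function(r12, r13, r23, n, method = c("steiger", "williams")) {
  method <- match.arg(method)
  stopifnot(n >= 4)
  if (any(abs(c(r12, r13, r23)) >= 1))
    stop("correlations must lie strictly within (-1, 1)")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0)
    stop("correlation triple is not positive definite")
  if (method == "steiger") {
    rbar <- (r12 + r13) / 2
    psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
    s <- psi / (1 - rbar^2)^2
    z <- atanh(r12) - atanh(r13)
    stat <- z * sqrt((n - 3) / (2 - 2 * s))
    p <- 2 * stats::pnorm(-abs(stat))
    lab <- "Steiger Z1* (pooled r)"
  } else {
    rbar <- (r12 + r13) / 2
    stat <- (r12 - r13) *
      sqrt((n - 1) * (1 + r23) /
           (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3))
    p <- 2 * stats::pt(-abs(stat), df = n - 3)
    lab <- "Williams T2"
  }
  structure(list(statistic = stat, p.value = p, method = lab,
                 r12 = r12, r13 = r13, r23 = r23, n = n),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g  (r12 = %.3f, r13 = %.3f, r23 = %.3f, n = %d)\n",
              x$method, x$statistic, x$p.value, x$r12, x$r13, x$r23, x$n))
  invisible(x)
}

#' Ordinary least-squares linear trend
#'
#' Closed-form simple regression of `y` on `x` (default index 0..n-1,
#' so the intercept is the trend value at the first point).
#'
#' @param y Numeric response, length >= 2.
#' @param x Numeric predictor, same length, non-constant.
#' @return List with `slope` and `intercept`.
#' @export
linear_trend <- function(y, x = seq_along(y) - 1) {
  stopifnot(length(y) >= 2, length(x) == length(y))
  if (stats::sd(x) == 0) stop("predictor is constant")
  slope <- stats::cov(x, y) / stats::var(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}
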