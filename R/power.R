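## Monte-Carlo power calculations: empirical power of the paired Wilcoxon
## signed-rank test under Normal paired differences, and a simulation-based
## sample-size finder for the Spearman correlation test.

## Two-sided signed-rank p-value for continuous differences (no zeros/ties
## expected under a continuous model; falls back to the normal approximation
## when ties occur or n > 50). Matches wilcox.test's exact two-sided rule.
signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 50 && !anyDuplicated(abs(d))) {
    p <- if (v > n * (n + 1) / 4) {
      2 * stats::psignrank(v - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(v, n)
    }
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

#' Monte-Carlo power of the paired Wilcoxon signed-rank test
#'
#' Simulates `reps` datasets of `n` paired differences from
#' Normal(`effect_mean`, `effect_sd`), applies the exact two-sided
#' signed-rank test at level `alpha`, and reports the rejection fraction.
#' With `effect_mean = 0` this recovers the test's type-I error (which for
#' the exact test sits at the largest achievable level below `alpha`).
#'
#' @param n Number of paired subjects (>= 5).
#' @param effect_mean,effect_sd Mean and SD of the paired differences
#'   (relative-abundance units in the microbiome use case).
#' @param alpha Two-sided significance level, in (0, 1).
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed Integer seed.
#' @return List of class `"power_result"`: `n, effect_mean, effect_sd,
#'   alpha, reps, power_hat, mc_se`.
#' @export
wilcoxon_power <- function(n, effect_mean, effect_sd, alpha = 0.05,
                           reps = 10000, seed = 1) {
  assert_that(n >= 5, "n must be >= 5")
  assert_that(reps >= 1000, "reps must be >= 1000")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  set.seed(seed)
  rejections <- 0L
  for (i in seq_len(reps)) {
    d <- stats::rnorm(n, effect_mean, effect_sd)
    if (signed_rank_p(d) <= alpha) rejections <- rejections + 1L
  }
  power_hat <- rejections / reps
  structure(list(n = n, effect_mean = effect_mean, effect_sd = effect_sd,
                 alpha = alpha, reps = reps, power_hat = power_hat,
                 mc_se = sqrt(power_hat * (1 - power_hat) / reps)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank power: n = %d, effect %.4g +/- %.4g, alpha = %.3g\n",
    x$n, x$effect_mean, x$effect_sd, x$alpha))
  cat(sprintf("  power_hat = %.3f (MC SE %.4f, %d reps)\n",
              x$power_hat, x$mc_se, x$reps))
  invisible(x)
}

## Simulated power of the Spearman correlation test at sample size n.
spearman_power <- function(n, rho_s, alpha, reps) {
  ## Pearson rho inducing the requested Spearman rho under bivariate normal:
  ## rho_s = (6/pi) asin(rho_p / 2)  =>  rho_p = 2 sin(pi rho_s / 6)
  rho_p <- 2 * sin(pi * rho_s / 6)
  hits <- 0L
  for (i in seq_len(reps)) {
    x <- stats::rnorm(n)
    y <- rho_p * x + sqrt(1 - rho_p^2) * stats::rnorm(n)
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
    if (p <= alpha) hits <- hits + 1L
  }
  hits / reps
}

#' Smallest sample size reaching target power for a Spearman correlation
#'
#' Simulation-based finder: data are bivariate Gaussian with the Pearson
#' correlation chosen to induce the requested population Spearman `rho`
#' (rho_s = (6/pi) asin(rho_p/2)); power at each candidate n is the fraction
#' of replicates with a two-sided Spearman test p <= `alpha`. A coarse
#' doubling search brackets the answer, then a bisection refines it
#' (power is monotone in n).
#'
#' @param rho Target population Spearman correlation, |rho| < 1 and != 0.
#' @param alpha Significance level.
#' @param target_power Desired power, in (0, 1).
#' @param reps Replicates per candidate n.
#' @param seed Integer seed.
#' @param n_max Give up (error) beyond this n.
#' @return Smallest n (integer) with estimated power >= `target_power`.
#' @export
spearman_sample_size <- function(rho, alpha = 0.05, target_power = 0.8,
                                 reps = 400, seed = 1, n_max = 10000) {
  assert_that(abs(rho) < 1, "rho must satisfy |rho| < 1")
  assert_that(target_power > 0 && target_power < 1,
              "target_power must lie in (0, 1)")
  if (rho == 0) stop_arg("power never exceeds alpha at rho = 0")
  set.seed(seed)
  lo <- 4L
  hi <- 8L
  while (spearman_power(hi, rho, alpha, reps) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) stop_arg("target power unreachable within n <= ", n_max)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (spearman_power(mid, rho, alpha, reps) >= target_power) hi <- mid else lo <- mid
  }
  hi
}
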