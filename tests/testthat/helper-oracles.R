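# Independent oracles, coded against first principles rather than the
# package's implementation paths.

# ANCOVA with subject factor and common slope, solved directly through the
# normal equations on the dummy-coded design (no lm / anova).
rmcorr_oracle <- function(x, y, subjects) {
  subj <- factor(subjects)
  Z <- stats::model.matrix(~ subj)        # intercept + k-1 dummies
  X <- cbind(Z, x = x)
  beta_full <- solve(crossprod(X), crossprod(X, y))
  rss_full <- sum((y - X %*% beta_full)^2)
  beta_red <- solve(crossprod(Z), crossprod(Z, y))
  rss_red <- sum((y - Z %*% beta_red)^2)
  ss_x <- rss_red - rss_full
  df <- length(y) - nlevels(subj) - 1
  slope <- unname(beta_full["x", 1])
  r <- sign(slope) * sqrt(ss_x / (ss_x + rss_full))
  f_stat <- ss_x / (rss_full / df)
  list(r = r, df = df, p = stats::pf(f_stat, 1, df, lower.tail = FALSE))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments (zeros dropped beforehand; assumes no ties in |d|).
signrank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs >= mu) {
    2 * mean(v_all >= v_obs)
  } else {
    2 * mean(v_all <= v_obs)
  }
  min(1, p)
}

# Small wide-format food-record table with specified per-record values.
make_records <- function(values_by_phase, subjects = c("A", "B"),
                         category = "prebiotics") {
  rows <- list()
  day <- 1L
  for (ph in names(values_by_phase)) {
    vals <- values_by_phase[[ph]]
    for (i in seq_along(vals)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects[((i - 1) %% length(subjects)) + 1],
        day = day, week = if (ph == "baseline") 1L + (i %% 6L) else 7L + (i %% 8L),
        phase = ph, stringsAsFactors = FALSE)
      day <- day + 1L
    }
  }
  out <- do.call(rbind, rows)
  for (cc in diet_categories()) out[[cc]] <- 0
  v <- unlist(values_by_phase, use.names = FALSE)
  out[[category]] <- v
  out
}

# Clustered regression data with a known random-intercept structure.
make_clustered <- function(n_clusters, n_per, intercept_sd, noise_sd, seed,
                           f = function(x) 2 * x[, 1]) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n_clusters * n_per * 3), ncol = 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  cl <- rep(seq_len(n_clusters), each = n_per)
  b <- stats::rnorm(n_clusters, 0, intercept_sd)
  y <- f(X) + b[cl] + stats::rnorm(length(cl), 0, noise_sd)
  list(X = as.data.frame(X), y = y, clusters = paste0("c", cl), b = b)
}
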