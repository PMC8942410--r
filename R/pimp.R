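## Permutation-importance (PIMP) significance. The observed per-feature
## importance is compared against a null built by refitting the whole model
## on permuted responses; the nonparametric p-value is
## (1 + #{null >= observed}) / (n_perm + 1), BH-adjusted across features.

#' Permutation-importance p-values by response-permutation refits
#'
#' @param fit_importance Function `(X, y, clusters, seed) -> named numeric`
#'   returning per-feature importances of a freshly fitted model (see
#'   [merf_importance_spec()]).
#' @param X,y,clusters Model inputs; passed through to `fit_importance`.
#' @param n_perm Number of permutations (>= 19, else p < 0.05 cannot be
#'   resolved).
#' @param seed Integer seed driving the permutations and the per-refit seeds.
#' @param scheme `"within-subject"` permutes the response within cluster
#'   blocks (the default: respects repeated-measures structure); `"free"`
#'   permutes across all samples.
#' @return Data.frame of class `"pimp_result"`: `feature,
#'   observed_importance, p_value, q_value`; the null importance matrix
#'   (n_perm x features) is in `attr(, "null_importances")`.
#' @export
pimp <- function(fit_importance, X, y, clusters, n_perm = 99, seed = 1,
                 scheme = c("within-subject", "free")) {
  scheme <- match.arg(scheme)
  assert_that(n_perm >= 19, "n_perm must be >= 19 to resolve p < 0.05")
  observed <- fit_importance(X, y, clusters, seed)
  features <- names(observed)
  set.seed(derive_seed(seed, 101L))
  perms <- replicate(n_perm, permute_response(y, clusters, scheme),
                     simplify = FALSE)
  null_imp <- matrix(NA_real_, n_perm, length(features),
                     dimnames = list(NULL, features))
  for (i in seq_len(n_perm)) {
    null_imp[i, ] <- fit_importance(X, perms[[i]], clusters,
                                    derive_seed(seed, 200L + i))[features]
  }
  p <- vapply(features, function(f) {
    (1 + sum(null_imp[, f] >= observed[[f]])) / (n_perm + 1)
  }, numeric(1))
  out <- data.frame(feature = features,
                    observed_importance = unname(observed),
                    p_value = unname(p),
                    q_value = adjust_bh(unname(p)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "null_importances") <- null_imp
  class(out) <- c("pimp_result", class(out))
  out
}

permute_response <- function(y, clusters, scheme) {
  if (scheme == "free") return(sample(y))
  idx <- seq_along(y)
  for (g in split(idx, clusters)) {
    if (length(g) > 1) idx[g] <- g[sample.int(length(g))]
  }
  y[idx]
}

#' Importance recipe for a MERF fit
#'
#' Wraps [fit_merf()] into the `(X, y, clusters, seed)` refitting interface
#' [pimp()] expects, returning the final forest's permutation importances.
#'
#' @param control [merf_control()] used for every refit (its seed is
#'   overridden per call).
#' @return A function suitable as `fit_importance` in [pimp()].
#' @export
merf_importance_spec <- function(control = merf_control()) {
  function(X, y, clusters, seed) {
    control$seed <- seed
    fit_merf(X, y, clusters, control)$importance
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment; monotone in rank order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
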