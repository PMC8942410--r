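## Community statistics: Shannon diversity, Bray-Curtis dissimilarity and
## PERMANOVA. Computation is delegated to vegan; this layer adds the
## pipeline's input validation and permutation bookkeeping.

#' Shannon diversity index (nats)
#'
#' `H = -sum p_i ln p_i` with `0 ln 0 = 0`; the vector is renormalized
#' internally so counts, percentages or proportions are all accepted.
#'
#' @param p Nonnegative abundance vector with positive sum.
#' @return Shannon index in nats.
#' @export
shannon <- function(p) {
  assert_that(all(p >= 0), "abundances must be nonnegative")
  assert_that(sum(p) > 0, "all-zero abundance vector")
  as.numeric(vegan::diversity(p, index = "shannon"))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `1 - 2 sum min(a_i, b_i) / (sum a + sum b)`; in \[0, 1\] for nonnegative
#' inputs.
#'
#' @param a,b Nonnegative abundance vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  assert_that(length(a) == length(b), "vectors must have equal length")
  assert_that(all(a >= 0) && all(b >= 0), "abundances must be nonnegative")
  assert_that(sum(a) > 0 || sum(b) > 0, "both vectors are all-zero")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Bray-Curtis distance matrix for a sample-by-species table
#'
#' @param abundance Samples x species matrix of nonnegative abundances.
#' @return A `dist` object.
#' @export
bray_curtis_matrix <- function(abundance) {
  vegan::vegdist(abundance, method = "bray")
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from among/within sums of squared distances with a permutation
#' p-value `(1 + #{F_perm >= F_obs}) / (n_perm + 1)`; permutations are
#' restricted to within-`strata` blocks when subject labels are supplied
#' (recommended for repeated samples).
#'
#' @param D A `dist` object or square symmetric matrix.
#' @param groups Group labels (>= 2 groups, each with >= 2 samples).
#' @param n_perm Number of permutations (>= 19).
#' @param strata Optional blocking labels (e.g. subject).
#' @param seed Integer seed.
#' @return List: `f` (pseudo-F), `p`, `r2`, `n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 999, strata = NULL, seed = 1) {
  if (!inherits(D, "dist")) D <- stats::as.dist(D)
  groups <- factor(groups)
  assert_that(nlevels(groups) >= 2, "need at least 2 groups")
  assert_that(all(table(groups) >= 2), "every group needs >= 2 samples")
  assert_that(n_perm >= 19, "n_perm must be >= 19")
  set.seed(seed)
  ctrl <- if (is.null(strata)) {
    permute::how(nperm = n_perm)
  } else {
    permute::how(nperm = n_perm, blocks = factor(strata))
  }
  fit <- vegan::adonis2(D ~ groups, permutations = ctrl)
  list(f = fit$F[1], p = fit$`Pr(>F)`[1], r2 = fit$R2[1], n_perm = n_perm)
}

#' Classical MDS (PCoA) coordinates of a distance matrix
#'
#' Supporting output for ordination plots.
#'
#' @param D A `dist` object or square matrix.
#' @param k Number of dimensions.
#' @return Samples x k coordinate matrix.
#' @export
pcoa_coordinates <- function(D, k = 2) {
  if (!inherits(D, "dist")) D <- stats::as.dist(D)
  stats::cmdscale(D, k = k)
}
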