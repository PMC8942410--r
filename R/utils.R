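#' @keywords internal
"_PACKAGE"

## Shared constants ----------------------------------------------------------

#' IBD-AID diet categories
#'
#' The five serving categories used throughout the pipeline: the four main
#' categories (prebiotics, probiotics, beneficial, adverse) plus alcohol,
#' which is scored separately.
#'
#' @return Character vector of category names.
#' @export
diet_categories <- function() {
  c("prebiotics", "probiotics", "beneficial", "adverse", "alcohol")
}

#' Cytokine panel analytes
#'
#' The 14 analytes of the high-sensitivity inflammation panel modelled by the
#' cytokine generator and association stage.
#'
#' @return Character vector of analyte names.
#' @export
cytokine_analytes <- function() {
  c("GM-CSF", "IFN-gamma", "IL-1beta", "IL-2", "IL-4", "IL-5", "IL-6",
    "IL-8", "IL-10", "IL-12p70", "IL-13", "IL-17A", "IL-23", "TNF-alpha")
}

## Small helpers --------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_arg(msg)
  invisible(TRUE)
}

## Rank-based AUC (Mann-Whitney statistic / n1*n0); ties get half weight.
#' Area under the ROC curve
#'
#' Rank-based AUC of a numeric score against binary labels, equivalent to the
#' normalized Mann-Whitney U statistic.
#'
#' @param labels Binary vector (0/1 or logical); 1 is the positive class.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Fisher-z confidence interval for a correlation with given effective df.
fisher_ci <- function(r, df, level = 0.95) {
  if (df <= 2 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(df - 1)
  halfwidth <- stats::qnorm(1 - (1 - level) / 2) * se
  tanh(c(z - halfwidth, z + halfwidth))
}

## deterministic sub-seed derivation (keeps results independent of call order)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}
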