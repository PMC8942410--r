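## Cytokine-food associations (simple linear regressions of analyte levels on
## mean category intakes) and pre/post matched-pairs Wilcoxon comparisons.

#' Simple linear regressions of cytokine levels on category intakes
#'
#' For every (analyte, category) pair, regresses the analyte concentration on
#' the subject's mean servings/day of the category. By default the
#' subject x period points are pooled across periods (baseline intake with
#' baseline level, intervention intake with the post level); `"per-period"`
#' fits each period separately.
#'
#' @param panel Long cytokine data.frame (`subject_id, timepoint, analyte,
#'   concentration`; timepoints "baseline"/"post").
#' @param intakes Data.frame of per-subject per-phase mean servings:
#'   `subject_id, phase`, one column per category (as produced by
#'   [phase_mean_intakes()]).
#' @param pooling `"pooled"` (default) or `"per-period"`.
#' @return Data.frame: `analyte, category, period, n, slope, intercept,
#'   se, p, ci_low, ci_high, r_squared`. Regressions with zero intake
#'   variance or fewer than 3 points are skipped with a message.
#' @export
cytokine_food_regression <- function(panel, intakes,
                                     pooling = c("pooled", "per-period")) {
  pooling <- match.arg(pooling)
  cats <- intersect(diet_categories(), names(intakes))
  panel$phase <- ifelse(panel$timepoint == "baseline", "baseline", "intervention")
  merged <- merge(panel, intakes, by = c("subject_id", "phase"))
  periods <- if (pooling == "pooled") list(pooled = unique(merged$phase)) else {
    stats::setNames(as.list(unique(merged$phase)), unique(merged$phase))
  }
  out <- list()
  for (an in unique(merged$analyte)) {
    for (cc in cats) {
      for (pn in names(periods)) {
        sub <- merged[merged$analyte == an & merged$phase %in% periods[[pn]], ]
        x <- sub[[cc]]; y <- sub$concentration
        if (length(x) < 3) {
          message("cytokine_food_regression: <3 points for ", an, " x ", cc,
                  " (", pn, "); skipped")
          next
        }
        if (stats::var(x) == 0) {
          message("cytokine_food_regression: zero intake variance for ", cc,
                  " (", pn, "); skipped")
          next
        }
        fit <- stats::lm(y ~ x)
        sm <- suppressWarnings(summary(fit))
        ## a (numerically) perfect or constant fit leaves no residual scale
        ## for t-based inference
        degenerate <- sm$sigma < 1e-10 * max(1, mean(abs(y))) ||
          is.na(sm$coefficients["x", "Std. Error"])
        ci <- if (degenerate) c(NA_real_, NA_real_) else stats::confint(fit)["x", ]
        slope <- unname(stats::coef(fit)["x"])
        if (degenerate && abs(slope) < 1e-10) slope <- 0
        out[[length(out) + 1L]] <- data.frame(
          analyte = an, category = cc, period = pn, n = length(x),
          slope = slope,
          intercept = unname(stats::coef(fit)["(Intercept)"]),
          se = if (degenerate) NA_real_ else sm$coefficients["x", "Std. Error"],
          p = if (degenerate) NA_real_ else sm$coefficients["x", "Pr(>|t|)"],
          ci_low = ci[1], ci_high = ci[2],
          r_squared = sm$r.squared, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-subject per-phase mean category intakes
#'
#' @param records Wide category records (generator `food_records` or
#'   [load_food_queries()] output).
#' @return Data.frame: `subject_id, phase`, one mean-servings column per
#'   category.
#' @export
phase_mean_intakes <- function(records) {
  cats <- intersect(diet_categories(), names(records))
  stats::aggregate(records[cats], by = records[c("subject_id", "phase")],
                   FUN = mean)
}

#' Pre/post cytokine comparison (Wilcoxon matched-pairs signed-rank)
#'
#' Pairs each subject's baseline and post concentrations per analyte; exact
#' two-sided p for n <= 25 pairs without ties (zero differences dropped,
#' Wilcoxon's original treatment), normal approximation otherwise. Analytes
#' with fewer than `min_pairs` complete pairs are skipped with a message.
#' `p <= 0.1` is labelled a trend (small-sample reporting convention), never
#' a rejection.
#'
#' @param panel Long cytokine data.frame.
#' @param min_pairs Minimum complete pairs per analyte.
#' @return Data.frame: `analyte, n_pairs, statistic, p, degenerate, trend`.
#' @export
pre_post_wilcoxon <- function(panel, min_pairs = 5) {
  out <- list()
  for (an in unique(panel$analyte)) {
    sub <- panel[panel$analyte == an, ]
    pre <- sub$concentration[sub$timepoint == "baseline"]
    names(pre) <- sub$subject_id[sub$timepoint == "baseline"]
    post <- sub$concentration[sub$timepoint == "post"]
    names(post) <- sub$subject_id[sub$timepoint == "post"]
    common <- intersect(names(pre), names(post))
    if (length(common) < min_pairs) {
      message("pre_post_wilcoxon: only ", length(common), " pairs for ", an,
              "; skipped")
      next
    }
    d <- post[common] - pre[common]
    if (all(d == 0)) {
      out[[length(out) + 1L]] <- data.frame(
        analyte = an, n_pairs = length(common), statistic = NA_real_, p = 1,
        degenerate = TRUE, trend = FALSE, stringsAsFactors = FALSE)
      next
    }
    nz <- d[d != 0]
    exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
    wt <- suppressWarnings(
      stats::wilcox.test(post[common], pre[common], paired = TRUE,
                         exact = exact, correct = !exact))
    out[[length(out) + 1L]] <- data.frame(
      analyte = an, n_pairs = length(common),
      statistic = unname(wt$statistic), p = wt$p.value,
      degenerate = FALSE, trend = wt$p.value <= 0.1, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
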