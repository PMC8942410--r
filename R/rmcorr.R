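## Repeated-measures correlation: the common within-subject linear
## association between two repeatedly measured variables, from an ANCOVA
## with subject as a factor and a common slope. r_rm is the signed square
## root of SS_measure / (SS_measure + SS_error) with df = N - k - 1.

#' Repeated-measures correlation
#'
#' Fits `y ~ subject + x` (subject a factor, x entered after the subject
#' factor) and returns the common within-subject correlation
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, its F-test p-value
#' on (1, N - k - 1) degrees of freedom, and a 95% Fisher-z confidence
#' interval using the rmcorr degrees of freedom. Incomplete pairs are
#' dropped pairwise; subjects left with fewer than two pairs are dropped
#' (with a message reporting the count).
#'
#' @param x,y Numeric vectors of paired repeated measures.
#' @param subjects Subject labels, one per pair.
#' @param conf_level Confidence level for the interval.
#' @return List of class `"rmcorr_result"`: `r_rm, df, p_value, ci_low,
#'   ci_high, n_obs, n_subjects, slope`.
#' @export
rmcorr <- function(x, y, subjects, conf_level = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]; subjects <- as.character(subjects)[keep]
  counts <- table(subjects)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    message("rmcorr: dropping ", length(singletons),
            " subject(s) with fewer than 2 complete pairs")
    keep <- !subjects %in% singletons
    x <- x[keep]; y <- y[keep]; subjects <- subjects[keep]
  }
  k <- length(unique(subjects))
  assert_that(k >= 2, "need at least 2 subjects with >= 2 complete pairs")
  subj <- factor(subjects)
  ## slope is undefined without within-subject variance in x
  wvar <- stats::ave(x, subj, FUN = function(v) stats::var(v))
  assert_that(any(wvar > 0), "zero within-subject variance in x")
  fit <- stats::lm(y ~ subj + x)
  ## suppress the "essentially perfect fit" warning: noiseless common-slope
  ## inputs are a legitimate boundary case (r_rm = +/-1) handled below
  an <- suppressWarnings(stats::anova(fit))  # sequential: subj, x, residuals
  ss_x <- an["x", "Sum Sq"]
  ss_e <- an["Residuals", "Sum Sq"]
  df <- an["Residuals", "Df"]        # N - k - 1
  slope <- stats::coef(fit)[["x"]]
  denom <- ss_x + ss_e
  r <- if (denom > 0) sign(slope) * sqrt(ss_x / denom) else 0
  f_stat <- an["x", "F value"]
  p <- stats::pf(f_stat, 1, df, lower.tail = FALSE)
  ci <- fisher_ci(r, df, conf_level)
  structure(list(r_rm = r, df = df, p_value = p,
                 ci_low = ci[1], ci_high = ci[2],
                 n_obs = length(x), n_subjects = k, slope = slope),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr: r = %.4f (df = %d), p = %.3g, 95%% CI [%.3f, %.3f]\n",
              x$r_rm, x$df, x$p_value, x$ci_low, x$ci_high))
  invisible(x)
}

#' Repeated-measures correlations of screened food-species pairs
#'
#' For each (species, food column) pair surviving the PIMP screen, runs
#' [rmcorr()] separately in CD and UC subjects on the species' relative
#' abundance against the sample-aligned food-category covariate (interaction
#' columns map back to their food category). Each species is annotated with
#' its enrichment phase (higher mean abundance at baseline or intervention).
#' Pairs lacking enough data in a stratum are skipped with a message.
#'
#' @param pairs Data.frame with columns `species` and `food_column`.
#' @param cohort A `"longitudinal_cohort"`.
#' @param diagnoses Strata to analyse (default both).
#' @return Data.frame: `species, food, diagnosis, r_rm, df, p, q,
#'   enrichment`; `q` is BH across all returned rows.
#' @export
food_species_rmcorr <- function(pairs, cohort, diagnoses = c("CD", "UC")) {
  empty <- data.frame(species = character(), food = character(),
                      diagnosis = character(), r_rm = numeric(),
                      df = integer(), p = numeric(), q = numeric(),
                      enrichment = character(), stringsAsFactors = FALSE)
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  foods <- sample_food_covariates(cohort)
  samples <- cohort$samples
  is_int <- samples$phase == "intervention"
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    sp <- pairs$species[i]
    food <- sub(":UC$", "", pairs$food_column[i])
    if (!food %in% colnames(foods)) next
    ab <- cohort$abundance[, sp]
    enr <- if (mean(ab[is_int]) >= mean(ab[!is_int])) "intervention" else "baseline"
    for (dx in diagnoses) {
      sel <- samples$diagnosis == dx
      res <- tryCatch(
        suppressMessages(rmcorr(foods[sel, food], ab[sel], samples$subject_id[sel])),
        error = function(e) NULL)
      if (is.null(res)) {
        message("food_species_rmcorr: skipping ", sp, " x ", food,
                " in ", dx, " (insufficient data)")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        species = sp, food = food, diagnosis = dx, r_rm = res$r_rm,
        df = res$df, p = res$p_value, q = NA_real_, enrichment = enr,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("species", "food", "diagnosis")]), ]
  res$q <- adjust_bh(res$p)
  rownames(res) <- NULL
  res
}

## Per-sample food covariates: the subject's weekly mean category servings in
## the sample's week, falling back to the subject's phase mean.
sample_food_covariates <- function(cohort) {
  cats <- diet_categories()
  samples <- cohort$samples
  wk <- cohort$weekly_intake
  phase_intake <- stats::aggregate(
    cohort$food_records[cats],
    by = cohort$food_records[c("subject_id", "phase")], FUN = mean)
  out <- matrix(NA_real_, nrow(samples), length(cats),
                dimnames = list(samples$sample_id, cats))
  for (i in seq_len(nrow(samples))) {
    hit <- wk$subject_id == samples$subject_id[i] & wk$week == samples$week[i]
    if (any(hit)) {
      out[i, ] <- as.numeric(wk[which(hit)[1], cats])
    } else {
      hit <- phase_intake$subject_id == samples$subject_id[i] &
        phase_intake$phase == samples$phase[i]
      if (any(hit)) {
        out[i, ] <- as.numeric(phase_intake[which(hit)[1], cats])
      } else {
        out[i, ] <- as.numeric(
          cohort$design$category_means[, samples$phase[i]])
      }
    }
  }
  out
}
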