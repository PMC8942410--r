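## Food-query scoring: item-level records -> per-record category servings/day,
## weekly/bi-weekly trajectories, the baseline-vs-intervention shift summary
## (phase means, SEM of the per-subject difference, fold changes) and
## per-category Mann-Whitney phase comparisons with two-stage adaptive FDR.

#' Score item-level food records into diet-category servings
#'
#' Maps each item to its IBD-AID category through the category map and sums
#' `servings x conversion` per record (one record = one subject-day query).
#'
#' @param records Item-level data.frame (`subject_id, day, week, phase, item,
#'   servings`) or a CSV path.
#' @param map Category map (data.frame from [read_category_map()] or path).
#' @param unmapped `"warn"` drops unknown items with a warning; `"error"`
#'   fails naming the first unknown item.
#' @return Wide data.frame: one row per record with `subject_id, day, week,
#'   phase` and one servings/day column per category (0 when absent).
#' @export
load_food_queries <- function(records, map = default_category_map(),
                              unmapped = c("warn", "error")) {
  unmapped <- match.arg(unmapped)
  if (is.character(records)) records <- read_food_records_csv(records)
  if (is.character(map)) map <- read_category_map(map)
  cats <- diet_categories()
  empty <- data.frame(subject_id = character(), day = integer(),
                      week = integer(), phase = character(),
                      stringsAsFactors = FALSE)
  for (cc in cats) empty[[cc]] <- numeric(0)
  if (nrow(records) == 0) return(empty)
  need <- c("subject_id", "day", "item", "servings")
  bad <- which(!stats::complete.cases(records[intersect(need, names(records))]))
  if (length(bad)) stop_arg("malformed food record at row ", bad[1])
  assert_that(all(need %in% names(records)),
              paste("food records must have columns:", paste(need, collapse = ", ")))
  unknown <- setdiff(unique(records$item), map$item)
  if (length(unknown)) {
    if (unmapped == "error") {
      stop_arg("unknown food item: ", unknown[1])
    }
    warning("dropping ", sum(records$item %in% unknown),
            " records with unmapped items: ", paste(unknown, collapse = ", "))
    records <- records[!records$item %in% unknown, , drop = FALSE]
    if (nrow(records) == 0) return(empty)
  }
  idx <- match(records$item, map$item)
  records$category <- map$category[idx]
  records$scored <- records$servings * map$conversion[idx]
  if (!"week" %in% names(records)) records$week <- ceiling(records$day / 7)
  if (!"phase" %in% names(records)) {
    records$phase <- ifelse(records$week <= 6, "baseline", "intervention")
  }
  key <- c("subject_id", "day", "week", "phase")
  agg <- stats::aggregate(records["scored"],
                          by = c(records[key], list(category = records$category)),
                          FUN = sum)
  wide <- stats::reshape(agg, idvar = key, timevar = "category",
                         direction = "wide")
  names(wide) <- sub("^scored\\.", "", names(wide))
  for (cc in cats) {
    if (!cc %in% names(wide)) wide[[cc]] <- 0
    wide[[cc]][is.na(wide[[cc]])] <- 0
  }
  wide <- wide[c(key, cats)]
  wide <- wide[order(wide$subject_id, wide$day), ]
  rownames(wide) <- NULL
  wide
}

#' Mean category intake per time bin
#'
#' Bins records by study week within each phase (bins are anchored at the
#' first week of the phase) and averages the per-record daily servings. Bins
#' with no records are absent from the output, not zero.
#'
#' @param records Wide category records from [load_food_queries()] (or the
#'   generator's `food_records`).
#' @param bin_weeks Bin width in weeks (>= 1); 2 gives the bi-weekly
#'   trajectory used for plotting.
#' @return Long data.frame: `phase, bin, week_start, week_end, category,
#'   mean, n_records`.
#' @export
weekly_category_means <- function(records, bin_weeks = 1) {
  assert_that(bin_weeks >= 1 && bin_weeks == round(bin_weeks),
              "bin_weeks must be a positive integer")
  cats <- intersect(diet_categories(), names(records))
  out <- list()
  for (ph in unique(records$phase)) {
    sub <- records[records$phase == ph, , drop = FALSE]
    if (nrow(sub) == 0) next
    w0 <- min(sub$week)
    sub$bin <- (sub$week - w0) %/% bin_weeks
    for (b in sort(unique(sub$bin))) {
      blk <- sub[sub$bin == b, , drop = FALSE]
      for (cc in cats) {
        out[[length(out) + 1L]] <- data.frame(
          phase = ph, bin = b,
          week_start = w0 + b * bin_weeks,
          week_end = w0 + (b + 1) * bin_weeks - 1,
          category = cc, mean = mean(blk[[cc]]), n_records = nrow(blk),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(phase = character(), bin = integer(),
                      week_start = integer(), week_end = integer(),
                      category = character(), mean = numeric(),
                      n_records = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Baseline-vs-intervention diet-shift summary
#'
#' Per category: phase means over per-record servings/day, the mean
#' difference (intervention minus baseline), its SEM computed over
#' per-subject (baseline mean, intervention mean) pairs, and the fold change
#' reported as larger/smaller with an increase/reduction direction label.
#'
#' @param records Wide category records (must contain both phases).
#' @return Data.frame: `category, mean_baseline, mean_intervention,
#'   difference, sem_difference, fold_change, direction`.
#' @export
diet_shift_summary <- function(records) {
  for (ph in c("baseline", "intervention")) {
    if (!any(records$phase == ph)) stop_arg("no records in phase: ", ph)
  }
  cats <- intersect(diet_categories(), names(records))
  out <- lapply(cats, function(cc) {
    b <- records[[cc]][records$phase == "baseline"]
    i <- records[[cc]][records$phase == "intervention"]
    mb <- mean(b); mi <- mean(i)
    ## subject-level paired differences for the SEM
    per_subj <- stats::aggregate(records[[cc]],
                                 by = records[c("subject_id", "phase")], FUN = mean)
    wide <- stats::reshape(per_subj, idvar = "subject_id", timevar = "phase",
                           direction = "wide")
    d <- wide$x.intervention - wide$x.baseline
    d <- d[!is.na(d)]
    sem <- if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_
    fc <- if (mb == mi) 1 else max(mb, mi) / min(mb, mi)
    data.frame(category = cc, mean_baseline = mb, mean_intervention = mi,
               difference = mi - mb, sem_difference = sem,
               fold_change = fc,
               direction = if (mi > mb) "increase" else if (mi < mb) "reduction" else "none",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Benjamini-Hochberg step-up rejection set at level q.
bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  thresh <- q * seq_len(m) / m
  passed <- which(p[o] <= thresh)
  reject <- rep(FALSE, m)
  if (length(passed)) reject[o[seq_len(max(passed))]] <- TRUE
  reject
}

#' Two-stage adaptive FDR (Benjamini-Krieger-Yekutieli)
#'
#' The two-stage linear step-up procedure: stage one applies BH at
#' q' = q/(1+q) to estimate the number of true nulls m0 = m - r1; stage two
#' applies BH at q' * m / m0. Rejections of stage two are the decisions.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param q Target FDR level.
#' @return List: `reject` (logical), `r1` (stage-one rejections), `m0_hat`,
#'   `stage2_level`.
#' @export
adjust_bky <- function(p, q = 0.05) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(bh_reject(p, q1))
  if (r1 == 0) {
    return(list(reject = rep(FALSE, m), r1 = 0L, m0_hat = m, stage2_level = q1))
  }
  if (r1 == m) {
    return(list(reject = rep(TRUE, m), r1 = as.integer(m), m0_hat = 0L,
                stage2_level = NA_real_))
  }
  m0 <- m - r1
  q2 <- q1 * m / m0
  list(reject = bh_reject(p, q2), r1 = as.integer(r1), m0_hat = as.integer(m0),
       stage2_level = q2)
}

#' Compare phase intakes per category (Mann-Whitney with adaptive FDR)
#'
#' Two-sided Mann-Whitney U test of baseline vs intervention per-record
#' servings for each category (ranks computed per comparison), exact when
#' both phase counts are <= 8 and there are no ties, otherwise the normal
#' approximation with tie correction. Decisions across categories by the
#' two-stage BKY procedure at level `q`.
#'
#' @param records Wide category records.
#' @param categories Categories to test (default the five main ones present).
#' @param q FDR level for the BKY decisions.
#' @return Data.frame: `category, n_baseline, n_intervention, U, p,
#'   degenerate, reject`.
#' @export
compare_phases <- function(records, categories = NULL, q = 0.05) {
  cats <- categories %||% intersect(diet_categories(), names(records))
  rows <- lapply(cats, function(cc) {
    b <- records[[cc]][records$phase == "baseline"]
    i <- records[[cc]][records$phase == "intervention"]
    assert_that(length(b) >= 1 && length(i) >= 1,
                paste0("category ", cc, " needs observations in both phases"))
    degenerate <- length(unique(c(b, i))) == 1
    if (degenerate) {
      return(data.frame(category = cc, n_baseline = length(b),
                        n_intervention = length(i), U = NA_real_, p = 1,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    ties <- anyDuplicated(c(b, i)) > 0
    exact <- length(b) <= 8 && length(i) <= 8 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(b, i, exact = exact, correct = !exact))
    data.frame(category = cc, n_baseline = length(b),
               n_intervention = length(i), U = unname(wt$statistic),
               p = wt$p.value, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$reject <- adjust_bky(res$p, q = q)$reject
  rownames(res) <- NULL
  res
}
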