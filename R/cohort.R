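## Synthetic longitudinal cohort generator.
##
## Emulates the structure of a single-arm pre/post diet-intervention study in
## IBD: repeated stool sampling per subject over a 6-week baseline and 8-week
## intervention, 24-hour food queries roughly three times a week, species
## relative abundances driven by diet-category intakes through a latent linear
## model with per-subject random intercepts, and a pre/post cytokine panel
## linear in mean category intakes. Ground-truth effects are explicit so every
## downstream stage can be validated against what was planted.

## Demographic targets for the two diagnosis groups (means and SDs).
.cohort_demographics <- list(
  CD = list(age = c(41.7, 13.3), bmi = c(29.3, 5.4), p_female = 11 / 15),
  UC = list(age = c(37.8, 11.5), bmi = c(25.4, 6.7), p_female = 2 / 7)
)

## positive-truncated normal draw (rejection; tails here are far from 0)
rtnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= 0
  }
  x
}

#' Generate a synthetic IBD cohort
#'
#' Draws subject profiles for Crohn's disease (CD) and ulcerative colitis
#' (UC) participants with age, sex and BMI distributions matching the study
#' demographics (CD: age 41.7 +/- 13.3, BMI 29.3 +/- 5.4, 73% female;
#' UC: age 37.8 +/- 11.5, BMI 25.4 +/- 6.7, 29% female).
#'
#' @param n_cd Number of CD subjects (>= 0).
#' @param n_uc Number of UC subjects (>= 0).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A data.frame with columns `subject_id`, `diagnosis` ("CD"/"UC"),
#'   `age`, `sex` ("F"/"M"), `bmi`.
#' @examples
#' generate_cohort(15, 7, seed = 1)
#' @export
generate_cohort <- function(n_cd, n_uc, seed) {
  assert_that(length(n_cd) == 1 && n_cd >= 0 && n_cd == round(n_cd),
              "n_cd must be a nonnegative integer")
  assert_that(length(n_uc) == 1 && n_uc >= 0 && n_uc == round(n_uc),
              "n_uc must be a nonnegative integer")
  set.seed(seed)
  one_group <- function(n, dx) {
    par <- .cohort_demographics[[dx]]
    data.frame(
      diagnosis = rep(dx, n),
      age = rtnorm_pos(n, par$age[1], par$age[2]),
      sex = ifelse(stats::runif(n) < par$p_female, "F", "M"),
      bmi = rtnorm_pos(n, par$bmi[1], par$bmi[2]),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_group(n_cd, "CD"), one_group(n_uc, "UC"))
  out <- cbind(subject_id = sprintf("S%02d", seq_len(nrow(out))), out)
  if (nrow(out) == 0) {
    out <- data.frame(subject_id = character(), diagnosis = character(),
                      age = numeric(), sex = character(), bmi = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Default sampling design
#'
#' Study-schedule parameters of the simulated trial: a 6-week baseline
#' (weeks 1-6) followed by an 8-week intervention (weeks 7-14); per-subject
#' stool-sample counts drawn from rounded Normal(6.5, 2.1) at baseline and
#' Normal(10.3, 5.1) at intervention (clipped to >= 1); food queries answered
#' on each day with probability 3/7; and per-phase mean servings/day for each
#' diet category (baseline -> intervention): prebiotics 4.08 -> 7.51,
#' probiotics 1.09 -> 1.59, beneficial 3.88 -> 6.13, adverse 12.64 -> 3.42,
#' alcohol 0.3 -> 0.2. Daily category servings are drawn from a Gamma
#' distribution with the configured mean and shape `serving_shape` (so
#' generated phase means converge to the configured values).
#'
#' @param baseline_weeks,intervention_weeks Integer vectors of study weeks.
#' @param stool_baseline,stool_intervention Mean/SD pairs for per-subject
#'   stool-sample counts in each phase.
#' @param food_query_prob Daily probability of completing a food query.
#' @param category_means 5 x 2 matrix of per-phase category serving means
#'   (rows = categories, columns = baseline, intervention).
#' @param serving_shape Gamma shape for daily servings (controls dispersion).
#' @return A list of design parameters, class `"sampling_design"`.
#' @export
default_design <- function(baseline_weeks = 1:6,
                           intervention_weeks = 7:14,
                           stool_baseline = c(mean = 6.5, sd = 2.1),
                           stool_intervention = c(mean = 10.3, sd = 5.1),
                           food_query_prob = 3 / 7,
                           category_means = NULL,
                           serving_shape = 4) {
  if (is.null(category_means)) {
    category_means <- rbind(
      prebiotics = c(4.08, 7.51),
      probiotics = c(1.09, 1.59),
      beneficial = c(3.88, 6.13),
      adverse    = c(12.64, 3.42),
      alcohol    = c(0.30, 0.20)
    )
    colnames(category_means) <- c("baseline", "intervention")
  }
  assert_that(all(rownames(category_means) == diet_categories()),
              "category_means rows must be the five diet categories")
  structure(list(
    baseline_weeks = baseline_weeks,
    intervention_weeks = intervention_weeks,
    stool_baseline = stool_baseline,
    stool_intervention = stool_intervention,
    food_query_prob = food_query_prob,
    category_means = category_means,
    serving_shape = serving_shape
  ), class = "sampling_design")
}

#' Construct a ground-truth effect configuration
#'
#' Defines the latent generative model of the simulator: each species' latent
#' abundance is `baseline + sum_c effect[s, c] * servings_c +
#' sum_c interaction[s, c] * servings_c * 1[UC] + subject intercept + noise`,
#' truncated at zero and renormalized per sample to a composition. Cytokines
#' are linear in per-phase mean category servings.
#'
#' @param n_species Number of species in the panel.
#' @param species_effects `n_species x 5` matrix of per-serving latent
#'   effects (columns in `diet_categories()` order); defaults to all zero.
#' @param interaction_effects Same shape; UC-specific additional effects.
#' @param subject_intercept_sd Latent-scale SD of per-subject-per-species
#'   random intercepts (>= 0).
#' @param noise_sd Latent-scale residual SD (>= 0).
#' @param species_baseline Latent baseline means (length `n_species`);
#'   drawn Uniform(0.5, 3) from `seed` when NULL.
#' @param cytokine_slopes `14 x 5` matrix of pg/mL-per-serving slopes.
#' @param cytokine_intercepts Length-14 baseline concentrations (pg/mL).
#' @param cytokine_noise_sd Residual SD of cytokine levels (pg/mL).
#' @param seed Seed used only to draw `species_baseline` when unspecified.
#' @return A list of class `"ground_truth"`.
#' @export
make_truth <- function(n_species = 40,
                       species_effects = NULL,
                       interaction_effects = NULL,
                       subject_intercept_sd = 1,
                       noise_sd = 0.5,
                       species_baseline = NULL,
                       cytokine_slopes = NULL,
                       cytokine_intercepts = NULL,
                       cytokine_noise_sd = 5,
                       seed = 1) {
  cats <- diet_categories()
  analytes <- cytokine_analytes()
  zmat <- function(nr, rown, coln) {
    matrix(0, nr, length(coln), dimnames = list(rown, coln))
  }
  species <- sprintf("s__Synthetic_species_%02d", seq_len(n_species))
  if (is.null(species_effects)) species_effects <- zmat(n_species, species, cats)
  if (is.null(interaction_effects)) interaction_effects <- zmat(n_species, species, cats)
  if (is.null(cytokine_slopes)) cytokine_slopes <- zmat(length(analytes), analytes, cats)
  if (is.null(cytokine_intercepts)) {
    cytokine_intercepts <- stats::setNames(rep(30, length(analytes)), analytes)
  }
  if (is.null(species_baseline)) {
    set.seed(derive_seed(seed, 7L))
    species_baseline <- stats::setNames(stats::runif(n_species, 0.5, 3), species)
  }
  assert_that(subject_intercept_sd >= 0 && noise_sd >= 0 && cytokine_noise_sd >= 0,
              "standard deviations must be >= 0")
  assert_that(nrow(species_effects) == n_species &&
                ncol(species_effects) == length(cats),
              "species_effects must be n_species x 5")
  assert_that(all(dim(interaction_effects) == dim(species_effects)),
              "interaction_effects must match species_effects dimensions")
  assert_that(nrow(cytokine_slopes) == length(analytes),
              "cytokine_slopes must have 14 rows")
  dimnames(species_effects) <- list(species, cats)
  dimnames(interaction_effects) <- list(species, cats)
  dimnames(cytokine_slopes) <- list(analytes, cats)
  structure(list(
    species = species,
    species_baseline = species_baseline,
    species_effects = species_effects,
    interaction_effects = interaction_effects,
    subject_intercept_sd = subject_intercept_sd,
    noise_sd = noise_sd,
    cytokine_slopes = cytokine_slopes,
    cytokine_intercepts = cytokine_intercepts,
    cytokine_noise_sd = cytokine_noise_sd
  ), class = "ground_truth")
}

#' Default ground truth: ten SCFA-producer analogs respond to prebiotics
#'
#' Forty synthetic species of which the first ten ("SCFA-producer" analogs)
#' carry a positive latent prebiotic effect of 0.5 per serving/day, and IL-6
#' carries a negative slope on prebiotic intake (-1.5 pg/mL per serving/day).
#'
#' @inheritParams make_truth
#' @return A `"ground_truth"` list; SCFA-analog species are in
#'   `attr(, "scfa_species")`.
#' @export
default_truth <- function(seed = 1) {
  truth <- make_truth(n_species = 40, seed = seed)
  truth$species_effects[1:10, "prebiotics"] <- 0.5
  truth$cytokine_slopes["IL-6", "prebiotics"] <- -1.5
  attr(truth, "scfa_species") <- truth$species[1:10]
  truth
}

#' Planted diet-responsive species scenario
#'
#' The demonstration ground truth for end-to-end recovery runs: `n_planted`
#' species respond to the intervention's two largest intake shifts, with a
#' positive latent effect of prebiotic servings and a negative latent effect
#' of adverse-food servings (the diet's SCFA-producer narrative: fed by
#' fermentable fiber, suppressed by adverse foods). Between phases the
#' planted species' latent mean shifts by about +3 units against a residual
#' SD of 0.5 and subject-intercept SD of 1 - a strong, unambiguous effect.
#'
#' @param n_planted Number of diet-responsive species.
#' @param prebiotic_effect Latent effect per prebiotic serving/day.
#' @param adverse_effect Latent effect per adverse serving/day.
#' @inheritParams make_truth
#' @return A `"ground_truth"` list; planted species in
#'   `attr(, "planted_species")`.
#' @export
planted_truth <- function(n_planted = 5, prebiotic_effect = 0.5,
                          adverse_effect = -0.15, seed = 1) {
  truth <- make_truth(n_species = 40, seed = seed)
  truth$species_effects[seq_len(n_planted), "prebiotics"] <- prebiotic_effect
  truth$species_effects[seq_len(n_planted), "adverse"] <- adverse_effect
  attr(truth, "planted_species") <- truth$species[seq_len(n_planted)]
  truth
}

#' Null ground truth (no diet effects)
#'
#' All food-category and interaction effects are zero; subject intercepts and
#' residual noise remain so the null data are still clustered.
#'
#' @inheritParams make_truth
#' @return A `"ground_truth"` list.
#' @export
null_truth <- function(subject_intercept_sd = 1, noise_sd = 0.5, seed = 1) {
  make_truth(n_species = 40, subject_intercept_sd = subject_intercept_sd,
             noise_sd = noise_sd, seed = seed)
}

phase_of_week <- function(week, design) {
  ifelse(week %in% design$baseline_weeks, "baseline",
         ifelse(week %in% design$intervention_weeks, "intervention",
                NA_character_))
}

## Daily category servings: Gamma with the phase mean (exact in expectation).
draw_servings <- function(n, mean, shape) {
  if (mean <= 0) return(rep(0, n))
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Generate longitudinal diet, microbiome and metadata for a cohort
#'
#' Simulates food-query records and stool samples over the study schedule,
#' then generates species relative abundances from the ground-truth latent
#' model. Species respond to the subject's weekly mean category servings in
#' the week of the sample (falling back to the subject's phase mean when the
#' week has no query).
#'
#' @param cohort Data.frame from [generate_cohort()].
#' @param truth A `"ground_truth"` list from [make_truth()].
#' @param design A `"sampling_design"` list from [default_design()].
#' @param seed Integer seed.
#' @return A list of class `"longitudinal_cohort"` with elements `subjects`,
#'   `samples` (per-sample metadata), `abundance` (samples x species matrix of
#'   proportions summing to 1 per row), `food_items` (item-level records),
#'   `food_records` (per-record category servings/day), `weekly_intake`
#'   (subject x week category means), `truth`, `design`.
#' @export
generate_longitudinal_data <- function(cohort, truth, design = default_design(),
                                       seed = 1) {
  assert_that(nrow(cohort) > 0, "cohort must contain at least one subject")
  assert_that(inherits(truth, "ground_truth"), "truth must come from make_truth()")
  cats <- diet_categories()
  set.seed(derive_seed(seed, 1L))
  weeks <- c(design$baseline_weeks, design$intervention_weeks)
  days <- seq_len(7 * length(weeks))
  day_week <- ceiling(days / 7)
  day_phase <- phase_of_week(day_week, design)
  cmap <- default_category_map()

  ## --- food queries -------------------------------------------------------
  rec_list <- list()
  item_list <- list()
  for (s in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[s]
    answered <- days[stats::runif(length(days)) < design$food_query_prob]
    if (length(answered) == 0) next
    for (d in answered) {
      ph <- day_phase[d]
      mu <- design$category_means[, if (ph == "baseline") "baseline" else "intervention"]
      serv <- vapply(cats, function(cc)
        draw_servings(1, mu[[cc]], design$serving_shape), numeric(1))
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        subject_id = sid, day = d, week = day_week[d], phase = ph,
        t(serv), stringsAsFactors = FALSE)
      ## split category totals across that category's items (random weights)
      for (cc in cats) {
        if (serv[[cc]] <= 0) next
        items <- cmap$item[cmap$category == cc]
        w <- stats::runif(length(items))
        w <- w / sum(w)
        keep <- w > 0.05          # a few items per query, as on a real form
        if (!any(keep)) keep[which.max(w)] <- TRUE
        w <- w[keep] / sum(w[keep])
        item_list[[length(item_list) + 1L]] <- data.frame(
          subject_id = sid, day = d, week = day_week[d], phase = ph,
          item = items[keep], servings = serv[[cc]] * w,
          stringsAsFactors = FALSE)
      }
    }
  }
  food_records <- do.call(rbind, rec_list)
  food_items <- do.call(rbind, item_list)
  rownames(food_records) <- rownames(food_items) <- NULL

  ## weekly per-subject category means, with phase-mean fallback
  weekly_intake <- stats::aggregate(
    food_records[cats], by = food_records[c("subject_id", "week")], FUN = mean)
  phase_intake <- stats::aggregate(
    food_records[cats], by = food_records[c("subject_id", "phase")], FUN = mean)

  lookup_intake <- function(sid, wk) {
    hit <- weekly_intake$subject_id == sid & weekly_intake$week == wk
    if (any(hit)) return(as.numeric(weekly_intake[which(hit)[1], cats]))
    ph <- phase_of_week(wk, design)
    hit <- phase_intake$subject_id == sid & phase_intake$phase == ph
    if (any(hit)) return(as.numeric(phase_intake[which(hit)[1], cats]))
    as.numeric(design$category_means[, if (ph == "baseline") "baseline" else "intervention"])
  }

  ## --- stool samples ------------------------------------------------------
  set.seed(derive_seed(seed, 2L))
  samp_list <- list()
  for (s in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[s]
    for (ph in c("baseline", "intervention")) {
      par <- if (ph == "baseline") design$stool_baseline else design$stool_intervention
      phw <- if (ph == "baseline") design$baseline_weeks else design$intervention_weeks
      n_s <- max(1L, as.integer(round(stats::rnorm(1, par[["mean"]], par[["sd"]]))))
      phase_days <- days[day_phase == ph]
      n_s <- min(n_s, length(phase_days))
      sdays <- sort(sample(phase_days, n_s))
      samp_list[[length(samp_list) + 1L]] <- data.frame(
        subject_id = sid, day = sdays, week = day_week[sdays], phase = ph,
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, samp_list)
  samples <- cbind(sample_id = sprintf("%s_d%03d", samples$subject_id, samples$day),
                   samples)
  samples <- merge(samples, cohort, by = "subject_id", sort = FALSE)
  samples <- samples[order(samples$subject_id, samples$day), ]
  rownames(samples) <- NULL

  ## --- latent abundances --------------------------------------------------
  set.seed(derive_seed(seed, 3L))
  n_sp <- length(truth$species)
  u <- matrix(stats::rnorm(nrow(cohort) * n_sp, 0, truth$subject_intercept_sd),
              nrow(cohort), n_sp, dimnames = list(cohort$subject_id, truth$species))
  abund <- matrix(0, nrow(samples), n_sp,
                  dimnames = list(samples$sample_id, truth$species))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$subject_id[i]
    x <- lookup_intake(sid, samples$week[i])
    is_uc <- samples$diagnosis[i] == "UC"
    latent <- truth$species_baseline +
      as.numeric(truth$species_effects %*% x) +
      (if (is_uc) as.numeric(truth$interaction_effects %*% x) else 0) +
      u[sid, ] +
      stats::rnorm(n_sp, 0, truth$noise_sd)
    latent <- pmax(latent, 0)
    if (sum(latent) == 0) latent <- rep(1, n_sp)   # degenerate all-truncated sample
    abund[i, ] <- latent / sum(latent)
  }

  structure(list(
    subjects = cohort, samples = samples, abundance = abund,
    food_items = food_items, food_records = food_records,
    weekly_intake = weekly_intake, truth = truth, design = design
  ), class = "longitudinal_cohort")
}

#' Generate a pre/post cytokine panel
#'
#' Each analyte level is `intercept + sum_c slope[a, c] * mean servings_c +
#' Normal(0, noise)` where the category means are the subject's per-phase
#' averages from the food records; baseline records feed the "baseline"
#' timepoint and intervention records the "post" timepoint. Subjects with no
#' food records in a phase are omitted from that timepoint (with a message).
#'
#' @param cohort A `"longitudinal_cohort"` from [generate_longitudinal_data()].
#' @param truth A `"ground_truth"` list (cytokine slopes/intercepts used).
#' @param seed Integer seed.
#' @return Long data.frame: `subject_id`, `timepoint` ("baseline"/"post"),
#'   `analyte`, `concentration` (pg/mL, truncated at 0).
#' @export
generate_cytokines <- function(cohort, truth, seed = 1) {
  assert_that(inherits(cohort, "longitudinal_cohort"),
              "cohort must come from generate_longitudinal_data()")
  cats <- diet_categories()
  analytes <- cytokine_analytes()
  set.seed(derive_seed(seed, 4L))
  phase_intake <- stats::aggregate(
    cohort$food_records[cats],
    by = cohort$food_records[c("subject_id", "phase")], FUN = mean)
  out <- list()
  for (s in cohort$subjects$subject_id) {
    for (ph in c("baseline", "intervention")) {
      hit <- phase_intake$subject_id == s & phase_intake$phase == ph
      if (!any(hit)) {
        message("generate_cytokines: no food records for ", s, " in ", ph,
                "; subject omitted at that timepoint")
        next
      }
      x <- as.numeric(phase_intake[which(hit)[1], cats])
      mu <- truth$cytokine_intercepts + as.numeric(truth$cytokine_slopes %*% x)
      lev <- pmax(mu + stats::rnorm(length(analytes), 0, truth$cytokine_noise_sd), 0)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = s,
        timepoint = if (ph == "baseline") "baseline" else "post",
        analyte = analytes, concentration = lev, stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  panel
}

#' Simulate a complete study cohort
#'
#' Convenience wrapper: subjects, longitudinal data and cytokines in one call
#' under a single seed.
#'
#' @param n_cd,n_uc Subject counts per diagnosis.
#' @param truth Ground truth (default [default_truth()]).
#' @param design Sampling design (default [default_design()]).
#' @param seed Integer seed.
#' @return A `"longitudinal_cohort"` with an added `cytokines` element.
#' @export
simulate_study <- function(n_cd = 15, n_uc = 7, truth = default_truth(),
                           design = default_design(), seed = 1) {
  subjects <- generate_cohort(n_cd, n_uc, seed = derive_seed(seed, 11L))
  cohort <- generate_longitudinal_data(subjects, truth, design,
                                       seed = derive_seed(seed, 12L))
  cohort$cytokines <- generate_cytokines(cohort, truth,
                                         seed = derive_seed(seed, 13L))
  cohort
}
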