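## End-to-end orchestration: simulate or load a cohort, then run diet
## summaries, period classification, per-species food association
## (MERF -> PIMP screen -> rmcorr), diversity, cytokine associations and the
## power calculation, writing figure-analog tables plus a run manifest.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `simulation` or `inputs` must be supplied.
#'
#' @param simulation List with `n_cd`, `n_uc`, optional `truth`
#'   ([make_truth()]) and `design` ([default_design()]).
#' @param inputs List of paths: `abundance` (MetaPhlAn2-style TSV),
#'   `metadata` (CSV), `food` (item-level CSV), optional `map` (category-map
#'   CSV) and `cytokines` (CSV).
#' @param seed Integer seed for every stochastic stage.
#' @param fdr FDR level for screening/decisions.
#' @param n_perm PIMP permutations per species model.
#' @param perm_scheme PIMP permutation scheme (see [pimp()]).
#' @param merf [merf_control()] for the per-species association models; kept
#'   light because PIMP refits it `n_perm + 1` times per species.
#' @param merf_class [merf_control()] for the single period-classification
#'   fits (heavier; fitted once per stratum).
#' @param diversity_strata Permute PERMANOVA within subjects (TRUE) or
#'   freely (FALSE, the published analysis' choice).
#' @param power List `n, effect_mean, effect_sd, alpha, reps` for the power
#'   stage; NULL skips it.
#' @return Validated list, class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL, seed = 1,
                            fdr = 0.05, n_perm = 99,
                            perm_scheme = "within-subject",
                            merf = merf_control(num_trees = 50, max_iter = 3,
                                                tol = 1e-3),
                            merf_class = merf_control(num_trees = 300,
                                                      max_iter = 10),
                            diversity_strata = FALSE,
                            power = list(n = 10, effect_mean = 0.005,
                                         effect_sd = 0.005, alpha = 0.05,
                                         reps = 1000)) {
  assert_that(xor(is.null(simulation), is.null(inputs)),
              "exactly one of simulation/inputs must be given")
  structure(list(simulation = simulation, inputs = inputs, seed = seed,
                 fdr = fdr, n_perm = n_perm, perm_scheme = perm_scheme,
                 merf = merf, merf_class = merf_class,
                 diversity_strata = diversity_strata, power = power),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the [pipeline_config()] fields (`truth` and
#'   `design` given as argument lists for [make_truth()]/[default_design()]).
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  assert_that(!is.null(raw$seed), "config must set an explicit seed")
  if (!is.null(raw$simulation)) {
    if (!is.null(raw$simulation$truth)) {
      raw$simulation$truth <- do.call(make_truth, raw$simulation$truth)
    }
    if (!is.null(raw$simulation$design)) {
      raw$simulation$design <- do.call(default_design, raw$simulation$design)
    }
  }
  merf <- if (is.null(raw$merf)) merf_control(num_trees = 50, max_iter = 3,
                                              tol = 1e-3)
          else do.call(merf_control, raw$merf)
  merf_class <- if (is.null(raw$merf_class)) merf_control(num_trees = 300,
                                                          max_iter = 10)
                else do.call(merf_control, raw$merf_class)
  pipeline_config(simulation = raw$simulation, inputs = raw$inputs,
                  seed = raw$seed, fdr = raw$fdr %||% 0.05,
                  n_perm = raw$n_perm %||% 99,
                  perm_scheme = raw$perm_scheme %||% "within-subject",
                  merf = merf, merf_class = merf_class,
                  diversity_strata = isTRUE(raw$diversity_strata),
                  power = raw$power %||% list(n = 10, effect_mean = 0.005,
                                              effect_sd = 0.005, alpha = 0.05,
                                              reps = 1000))
}

load_cohort_from_inputs <- function(inputs) {
  abundance <- read_abundance_tsv(inputs$abundance)
  samples <- read_metadata_csv(inputs$metadata)
  map <- if (is.null(inputs$map)) default_category_map() else read_category_map(inputs$map)
  food_items <- read_food_records_csv(inputs$food)
  food_records <- load_food_queries(food_items, map)
  samples <- samples[match(rownames(abundance), samples$sample_id), ]
  assert_that(!anyNA(samples$sample_id),
              "every abundance sample needs a metadata row")
  cats <- diet_categories()
  weekly_intake <- stats::aggregate(
    food_records[cats], by = food_records[c("subject_id", "week")], FUN = mean)
  cyt <- if (!is.null(inputs$cytokines)) read_cytokines_csv(inputs$cytokines)
  structure(list(
    subjects = unique(samples[c("subject_id", "diagnosis", "age", "sex", "bmi")]),
    samples = samples, abundance = abundance, food_items = food_items,
    food_records = food_records, weekly_intake = weekly_intake,
    cytokines = cyt, truth = NULL, design = default_design()
  ), class = "longitudinal_cohort")
}

#' Food-species association stage (MERF -> PIMP -> rmcorr)
#'
#' Fits one MERF per species on the food/covariate/interaction design, runs
#' the PIMP screen, keeps food and interaction columns with PIMP p below
#' `screen_p`, and follows up the screened pairs with repeated-measures
#' correlation per diagnosis.
#'
#' @param cohort A `"longitudinal_cohort"`.
#' @param config A `"pipeline_config"`.
#' @param screen_p PIMP screening threshold (default the config FDR level).
#' To keep the false-discovery rate interpretable despite the screen and the
#' correlation being computed on the same data, the BH adjustment of the
#' rmcorr p-values is taken across the complete
#' (species x category x diagnosis) family - not only across the screened
#' subset, which would inherit the screen's selection bias.
#'
#' @return List: `pimp` (per-species PIMP tables, food/interaction columns),
#'   `pairs` (screened pairs), `rmcorr_all` (full-family correlation table
#'   with BH `q` across that family), `rmcorr_screened` (rows of the full
#'   table matching screened pairs), `rmcorr` (the figure-analog table:
#'   screened rows with `q` below the FDR level).
#' @export
associate_foods <- function(cohort, config = pipeline_config(simulation = list()),
                            screen_p = NULL) {
  screen_p <- screen_p %||% config$fdr
  foods <- sample_food_covariates(cohort)
  samples <- cohort$samples
  covars <- samples[c("age", "sex", "bmi")]
  X <- build_design_matrix(as.data.frame(foods), samples$diagnosis, covars)
  prov <- attr(X, "provenance")
  food_cols <- names(prov)[prov %in% c("food", "interaction")]
  spec <- merf_importance_spec(config$merf)
  pimp_tabs <- list()
  pairs <- list()
  for (sp in colnames(cohort$abundance)) {
    y <- cohort$abundance[, sp]
    res <- pimp(spec, X, y, samples$subject_id, n_perm = config$n_perm,
                seed = derive_seed(config$seed, match(sp, colnames(cohort$abundance))),
                scheme = config$perm_scheme)
    res <- res[res$feature %in% food_cols, ]
    res$species <- sp
    pimp_tabs[[sp]] <- res
    hits <- res$feature[res$p_value < screen_p]
    if (length(hits)) {
      pairs[[sp]] <- data.frame(species = sp, food_column = hits,
                                stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(species = character(), food_column = character())
  ## rmcorr over the complete family (valid BH despite the screen)
  all_pairs <- expand.grid(species = colnames(cohort$abundance),
                           food_column = setdiff(diet_categories(), character()),
                           stringsAsFactors = FALSE)
  rmc <- food_species_rmcorr(all_pairs, cohort)
  key <- function(df, sp, fo) paste(df[[sp]], df[[fo]])
  screened_keys <- unique(paste(pairs$species, sub(":UC$", "", pairs$food_column)))
  screened <- rmc[key(rmc, "species", "food") %in% screened_keys, , drop = FALSE]
  list(pimp = do.call(rbind, pimp_tabs),
       pairs = pairs,
       rmcorr_all = rmc,
       rmcorr_screened = screened,
       rmcorr = screened[!is.na(screened$q) & screened$q < config$fdr, ,
                         drop = FALSE])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort and emits: diet-shift summary JSON with
#' phase-comparison tests, bi-weekly intake trajectory TSV, signed species
#' importance rankings for period classification (whole cohort and per
#' diagnosis), the PIMP-screened food-species rmcorr table, cytokine
#' association tables, diversity statistics, the Wilcoxon power result and a
#' run manifest. All stages are deterministic given the config seed.
#'
#' @param config A `"pipeline_config"` or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of all stage results (also written to `out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_that(inherits(config, "pipeline_config"), "invalid config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  ## 1. cohort
  cohort <- if (!is.null(config$simulation)) {
    sim <- config$simulation
    simulate_study(n_cd = sim$n_cd %||% 15, n_uc = sim$n_uc %||% 7,
                   truth = sim$truth %||% default_truth(),
                   design = sim$design %||% default_design(),
                   seed = config$seed)
  } else {
    load_cohort_from_inputs(config$inputs)
  }
  results$cohort <- cohort

  ## 2. diet scoring: Table-2 analog + trajectories + phase tests
  shift <- diet_shift_summary(cohort$food_records)
  tests <- compare_phases(cohort$food_records, q = config$fdr)
  jsonlite::write_json(
    list(shift = shift, tests = tests),
    file.path(out_dir, "diet_summary.json"),
    dataframe = "rows", digits = 10, pretty = TRUE)
  traj <- weekly_category_means(cohort$food_records, bin_weeks = 2)
  write_tsv(traj, file.path(out_dir, "intake_trajectory.tsv"))
  results$diet <- list(shift = shift, tests = tests, trajectory = traj)

  ## 3. period classification (whole cohort, then per diagnosis)
  ctrl <- config$merf_class
  ctrl$mtry <- NULL
  ctrl$seed <- derive_seed(config$seed, 31L)
  cls <- list()
  strata <- list(all = rep(TRUE, nrow(cohort$samples)),
                 CD = cohort$samples$diagnosis == "CD",
                 UC = cohort$samples$diagnosis == "UC")
  for (nm in names(strata)) {
    sel <- strata[[nm]]
    if (!any(sel)) next
    cls[[nm]] <- classify_period(cohort$abundance[sel, , drop = FALSE],
                                 cohort$samples$phase[sel],
                                 cohort$samples$subject_id[sel], ctrl)
    rk <- cls[[nm]]$ranking
    rk$stratum <- nm
    write_tsv(rk, file.path(out_dir, paste0("classification_ranking_", nm, ".tsv")))
  }
  results$classification <- cls

  ## 4. food-species association
  assoc <- associate_foods(cohort, config)
  write_tsv(assoc$rmcorr_all, file.path(out_dir, "food_species_rmcorr_all.tsv"))
  write_tsv(assoc$rmcorr, file.path(out_dir, "food_species_rmcorr.tsv"))
  results$association <- assoc

  ## 5. diversity
  alpha <- data.frame(sample_id = rownames(cohort$abundance),
                      shannon = apply(cohort$abundance, 1, shannon),
                      phase = cohort$samples$phase, stringsAsFactors = FALSE)
  D <- bray_curtis_matrix(cohort$abundance)
  pmv <- permanova(D, cohort$samples$phase, n_perm = 999,
                   strata = if (config$diversity_strata) cohort$samples$subject_id,
                   seed = derive_seed(config$seed, 41L))
  write_tsv(alpha, file.path(out_dir, "shannon.tsv"))
  jsonlite::write_json(pmv, file.path(out_dir, "permanova.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  results$diversity <- list(shannon = alpha, permanova = pmv)

  ## 6. cytokines
  if (!is.null(cohort$cytokines)) {
    intakes <- phase_mean_intakes(cohort$food_records)
    reg <- cytokine_food_regression(cohort$cytokines, intakes)
    wil <- pre_post_wilcoxon(cohort$cytokines)
    write_tsv(reg, file.path(out_dir, "cytokine_food_regression.tsv"))
    write_tsv(wil, file.path(out_dir, "cytokine_pre_post.tsv"))
    results$cytokines <- list(regression = reg, pre_post = wil)
  }

  ## 7. power
  if (!is.null(config$power)) {
    pw <- config$power
    pow <- wilcoxon_power(pw$n, pw$effect_mean, pw$effect_sd, pw$alpha,
                          reps = pw$reps, seed = derive_seed(config$seed, 51L))
    jsonlite::write_json(unclass(pow), file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    results$power <- pow
  }

  ## 8. manifest (deliberately timestamp-free so reruns are byte-identical)
  manifest <- list(
    package = "dietshift",
    version = as.character(utils::packageVersion("dietshift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, fdr = config$fdr, n_perm = config$n_perm,
    perm_scheme = config$perm_scheme,
    merf = config$merf[c("num_trees", "max_iter", "tol", "min_node_size")],
    n_samples = nrow(cohort$samples), n_species = ncol(cohort$abundance),
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
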