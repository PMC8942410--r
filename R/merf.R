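## Mixed-effect random forest (MERF).
##
## Model: Y_ij = f(X_ij) + b_j Z + eps, with f an ensemble of trees, b_j a
## per-cluster (here per-patient) random intercept with variance D, and eps
## iid Normal(0, sigma2_e). Fitted by alternating (EM-style) optimization:
## (E) given the current b_j, fit the forest to y - Z b_j; (M) given forest
## predictions, update b_j, sigma2_e and D with the standard linear
## mixed-model closed forms using V_j = Z D Z' + sigma2_e I. Convergence is
## monitored through the generalized log-likelihood (GLL)
##   GLL = sum_j [ ||y_j - f_j - Z b_j||^2 / sigma2_e + b_j' D^-1 b_j
##                 + log|D| + n_j log sigma2_e ].
## The random-effect design is intercept-only (Z = 1), so D is a scalar and
## every update has a closed form.

#' MERF fitting settings
#'
#' @param num_trees Trees per forest fit.
#' @param mtry Features tried per split; NULL lets the caller-facing wrappers
#'   pick sqrt(p) (classification use) or p/3 (regression use).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative GLL change declaring convergence.
#' @param min_iter Iterations before convergence may be declared.
#' @param min_node_size Minimum terminal node size of the forest.
#' @param seed Integer seed; forest fits are seeded per iteration from it.
#' @param learner `"ranger"` (default) or `"constant"` (f is the mean of the
#'   working response; used for closed-form cross-checks against one-way
#'   mixed-model BLUPs).
#' @return A list of settings, class `"merf_control"`.
#' @export
merf_control <- function(num_trees = 300, mtry = NULL, max_iter = 50,
                         tol = 1e-4, min_iter = 2, min_node_size = 5,
                         seed = 1, learner = c("ranger", "constant")) {
  learner <- match.arg(learner)
  structure(list(num_trees = num_trees, mtry = mtry, max_iter = max_iter,
                 tol = tol, min_iter = min_iter,
                 min_node_size = min_node_size, seed = seed,
                 learner = learner),
            class = "merf_control")
}

#' Fit a mixed-effect random forest
#'
#' @param X Design matrix or data.frame of fixed-effect features.
#' @param y Numeric response.
#' @param clusters Cluster (patient) labels, one per row of `X`.
#' @param control Settings from [merf_control()].
#' @return An object of class `"merf"`: `forest` (final ranger fit with
#'   permutation importance), `b` (named per-cluster random intercepts),
#'   `sigma2_e`, `D`, `gll_trace`, `converged`, `iterations`,
#'   `feature_names`, `oob_fixed` (out-of-bag fixed-part predictions of the
#'   final forest), `fitted` (in-sample combined predictions), `control`.
#' @export
fit_merf <- function(X, y, clusters, control = merf_control()) {
  X <- as.data.frame(X)
  n <- nrow(X)
  assert_that(length(y) == n && length(clusters) == n,
              "X, y and clusters must have matching lengths")
  clusters <- factor(clusters)
  K <- nlevels(clusters)
  assert_that(K >= 2, "need at least 2 clusters")
  p <- ncol(X)
  mtry <- control$mtry %||% max(1L, floor(p / 3))
  nj <- as.numeric(table(clusters))
  names(nj) <- levels(clusters)
  cl_idx <- as.integer(clusters)

  b <- stats::setNames(rep(0, K), levels(clusters))
  s2 <- max(stats::var(y), 1e-12)
  d <- 1
  gll_trace <- numeric(0)
  converged <- FALSE
  forest <- NULL
  fhat <- NULL
  iter <- 0L

  ## one forest seed for every EM iteration: as b stabilizes the working
  ## response stabilizes, so the refit forest (and hence the GLL) settles
  ## instead of jittering with fresh tree randomness each pass
  fit_fixed <- function(ystar, importance = "none") {
    if (control$learner == "constant") {
      mu <- mean(ystar)
      return(list(model = mu, pred = rep(mu, n), oob = rep(mu, n),
                  importance = stats::setNames(rep(0, p), names(X))))
    }
    rf <- ranger::ranger(
      x = X, y = ystar, num.trees = control$num_trees, mtry = min(mtry, p),
      min.node.size = control$min_node_size, importance = importance,
      seed = control$seed, num.threads = 1,
      respect.unordered.factors = "order")
    list(model = rf,
         pred = stats::predict(rf, X, num.threads = 1)$predictions,
         oob = rf$predictions,
         importance = if (importance == "none") NULL else rf$variable.importance)
  }

  for (iter in seq_len(control$max_iter)) {
    ystar <- y - b[cl_idx]
    fx <- fit_fixed(ystar)
    ## out-of-bag predictions for the mixed-model updates: in-sample forest
    ## predictions memorize the training response, which collapses the
    ## residual variance and biases both sigma2_e and D downward
    fhat <- fx$oob
    fhat[is.na(fhat)] <- fx$pred[is.na(fhat)]   # rows never out of bag
    r <- y - fhat
    sum_r <- as.numeric(tapply(r, clusters, sum))
    ## BLUP update of the random intercepts given (s2, d)
    b_new <- d * sum_r / (s2 + nj * d)
    e <- r - b_new[cl_idx]
    sse_j <- as.numeric(tapply(e^2, clusters, sum))
    tr_vinv <- nj / s2 - nj * d / (s2 * (s2 + nj * d))
    s2_new <- sum(sse_j + s2 * (nj - s2 * tr_vinv)) / n
    d_new <- mean(b_new^2 + d - d^2 * nj / (s2 + nj * d))
    b <- stats::setNames(b_new, levels(clusters))
    s2 <- max(s2_new, 1e-12)
    if (d_new < 1e-10) {
      d <- 1e-10   # ridge floor: keeps V_j invertible when variance collapses
    } else {
      d <- d_new
    }
    ## marginal negative log-likelihood (up to the n log 2pi constant) of
    ## r = y - f under V_j = d J + s2 I; this is the quantity the EM pass
    ## improves, so its trace is the convergence monitor
    sse_r <- as.numeric(tapply(r^2, clusters, sum))
    gll <- sum((sse_r - d / (s2 + nj * d) * sum_r^2) / s2 +
                 (nj - 1) * log(s2) + log(s2 + nj * d))
    gll_trace <- c(gll_trace, gll)
    if (iter >= control$min_iter && length(gll_trace) >= 2) {
      prev <- gll_trace[length(gll_trace) - 1]
      if (abs(gll - prev) / max(abs(prev), 1e-12) < control$tol) {
        converged <- TRUE
        break
      }
    }
  }

  ## final forest refit (same working response) with permutation importance
  final <- fit_fixed(y - b[cl_idx], importance = "permutation")
  structure(list(
    forest = final$model,
    learner = control$learner,
    b = b, sigma2_e = s2, D = d,
    gll_trace = gll_trace, converged = converged, iterations = iter,
    feature_names = names(X),
    oob_fixed = final$oob,
    fitted = final$pred + b[cl_idx],
    importance = final$importance,
    cluster_levels = levels(clusters),
    control = control
  ), class = "merf")
}

#' @export
print.merf <- function(x, ...) {
  cat("Mixed-effect random forest\n")
  cat(sprintf("  features: %d   clusters: %d   iterations: %d (%s)\n",
              length(x$feature_names), length(x$b), x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  sigma2_e = %.4g   D = %.4g\n", x$sigma2_e, x$D))
  invisible(x)
}

#' Predict from a fitted MERF
#'
#' Known clusters get `f(X) + b_j`; unseen clusters (or `clusters = NULL`)
#' get the population prediction `f(X)`.
#'
#' @param model A `"merf"` object.
#' @param X New data with the training feature columns.
#' @param clusters Optional cluster labels.
#' @return Numeric predictions.
#' @export
predict_merf <- function(model, X, clusters = NULL) {
  X <- as.data.frame(X)
  missing <- setdiff(model$feature_names, names(X))
  if (length(missing)) {
    stop_arg("missing feature columns: ", paste(missing, collapse = ", "))
  }
  X <- X[model$feature_names]
  f <- if (model$learner == "constant") {
    rep(model$forest, nrow(X))
  } else {
    stats::predict(model$forest, X, num.threads = 1)$predictions
  }
  if (is.null(clusters)) return(f)
  badd <- ifelse(as.character(clusters) %in% names(model$b),
                 model$b[as.character(clusters)], 0)
  f + unname(badd)
}

#' Build the fixed-effect design matrix for food-microbiome models
#'
#' Columns ordered (food categories, covariates, food x diagnosis
#' interactions). Diagnosis is encoded 0/1 (CD = 0, UC = 1), sex 0/1
#' (F = 0, M = 1); each interaction column is exactly the food column times
#' the UC indicator. Column provenance ("food", "covariate", "interaction")
#' is kept in `attr(, "provenance")`; constant columns are flagged in
#' `attr(, "constant")`.
#'
#' @param foods Data.frame of per-sample category servings.
#' @param diagnosis Character vector of "CD"/"UC" per sample.
#' @param covariates Data.frame with `age`, `sex`, `bmi` per sample (optional).
#' @return Numeric data.frame with attributes `provenance` and `constant`.
#' @export
build_design_matrix <- function(foods, diagnosis, covariates = NULL) {
  foods <- as.data.frame(foods)
  n <- nrow(foods)
  assert_that(length(diagnosis) == n, "diagnosis length must match foods rows")
  assert_that(all(diagnosis %in% c("CD", "UC")),
              "unknown diagnosis label (expected CD or UC)")
  uc <- as.numeric(diagnosis == "UC")
  X <- foods
  prov <- rep("food", ncol(foods))
  X$diagnosisUC <- uc
  prov <- c(prov, "covariate")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    assert_that(nrow(covariates) == n, "covariates rows must match foods rows")
    if ("sex" %in% names(covariates) && !is.numeric(covariates$sex)) {
      covariates$sex <- as.numeric(covariates$sex == "M")
    }
    X <- cbind(X, covariates)
    prov <- c(prov, rep("covariate", ncol(covariates)))
  }
  for (cc in names(foods)) {
    X[[paste0(cc, ":UC")]] <- foods[[cc]] * uc
    prov <- c(prov, "interaction")
  }
  names(prov) <- names(X)
  is_const <- vapply(X, function(v) length(unique(v)) == 1, logical(1))
  attr(X, "provenance") <- prov
  attr(X, "constant") <- names(X)[is_const]
  X
}

#' Classify study period from species abundances
#'
#' Fits a MERF regression on the 0/1 period label (intervention = 1) with the
#' patient as random intercept, scores samples by out-of-bag fixed-part
#' predictions plus the fitted subject intercept, and ranks species by the
#' forest's out-of-bag permutation importance signed by enrichment direction
#' (mean abundance at intervention vs baseline).
#'
#' @param abundance Samples x species matrix of proportions.
#' @param period Per-sample labels ("baseline"/"intervention" or 0/1).
#' @param subjects Per-sample subject labels.
#' @param control [merf_control()]; `mtry` defaults to sqrt(p) here.
#' @return List: `model`, `ranking` (data.frame `feature, importance,
#'   direction, signed_importance`), `scores`, `predicted` (0/1), `auc`.
#' @export
classify_period <- function(abundance, period, subjects,
                            control = merf_control()) {
  if (!is.numeric(period)) period <- as.numeric(period == "intervention")
  assert_that(all(period %in% c(0, 1)), "period must be binary")
  assert_that(length(unique(period)) == 2, "both classes must be present")
  if (is.null(control$mtry)) {
    control$mtry <- max(1L, floor(sqrt(ncol(abundance))))
  }
  model <- fit_merf(as.data.frame(abundance), period, subjects, control)
  ## scores use the population (fixed) part only, out of bag: adding the
  ## fitted subject intercept would leak each subject's average label into
  ## its own samples' scores and inflate apparent accuracy under the null
  scores <- pmin(pmax(model$oob_fixed, 0), 1)
  imp <- model$importance
  mi <- colMeans(abundance[period == 1, , drop = FALSE])
  mb <- colMeans(abundance[period == 0, , drop = FALSE])
  dir <- ifelse(mi >= mb, 1, -1)
  ranking <- data.frame(
    feature = names(imp),
    importance = unname(imp),
    direction = ifelse(dir[names(imp)] > 0, "enriched_intervention",
                       "enriched_baseline"),
    signed_importance = unname(imp) * dir[names(imp)],
    stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$importance), ]
  rownames(ranking) <- NULL
  list(model = model, ranking = ranking, scores = scores,
       predicted = as.integer(scores >= 0.5),
       auc = auc_score(period, scores))
}

#' MERF regression of one species on food categories
#'
#' Builds the design matrix (foods, diagnosis, clinical covariates,
#' food x diagnosis interactions) and fits a MERF with the patient as random
#' intercept; `mtry` defaults to p/3 for this regression use.
#'
#' @param abundance Numeric vector of one species' proportions per sample.
#' @param foods Per-sample category servings data.frame.
#' @param diagnosis Per-sample "CD"/"UC".
#' @param covariates Per-sample `age`, `sex`, `bmi` data.frame.
#' @param subjects Per-sample subject labels.
#' @param control [merf_control()].
#' @return A `"merf"` object; the design matrix is in `attr(, "design")`.
#' @export
regress_species_on_foods <- function(abundance, foods, diagnosis, covariates,
                                     subjects, control = merf_control()) {
  X <- build_design_matrix(foods, diagnosis, covariates)
  model <- fit_merf(X, abundance, subjects, control)
  attr(model, "design") <- X
  model
}
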