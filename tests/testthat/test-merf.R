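test_that("design matrix encodes foods, covariates and interactions exactly", {
  foods <- data.frame(prebiotics = c(1, 2, 3), adverse = c(4, 0, 1))
  dx <- c("CD", "UC", "UC")
  cov <- data.frame(age = c(30, 40, 50), sex = c("F", "M", "F"),
                    bmi = c(22, 28, 31))
  X <- build_design_matrix(foods, dx, cov)
  prov <- attr(X, "provenance")
  expect_equal(sum(prov == "interaction"), 2)   # one per food column
  expect_equal(X$`prebiotics:UC`, c(0, 2, 3))   # food x UC indicator, exactly
  expect_equal(X$`adverse:UC`, c(0, 0, 1))
  expect_equal(X$diagnosisUC, c(0, 1, 1))
  expect_equal(X$sex, c(0, 1, 0))
  expect_error(build_design_matrix(foods, c("CD", "XX", "UC"), cov), "diagnosis")

  ## CD-only cohort: interaction columns constant zero and flagged
  Xcd <- build_design_matrix(foods, rep("CD", 3), cov)
  expect_true(all(Xcd$`prebiotics:UC` == 0))
  expect_true(all(c("prebiotics:UC", "adverse:UC", "diagnosisUC")
                  %in% attr(Xcd, "constant")))
})

test_that("MERF recovers random intercepts and degenerate variances", {
  ## planted intercepts: sd 2 against noise sd 0.5
  dat <- make_clustered(30, 10, intercept_sd = 2, noise_sd = 0.5, seed = 14)
  fit <- fit_merf(dat$X, dat$y, dat$clusters,
                  merf_control(num_trees = 150, max_iter = 25, seed = 3))
  expect_gt(cor(fit$b[paste0("c", 1:30)], dat$b), 0.9)

  ## no between-cluster variance: D estimate collapses toward zero
  dat0 <- make_clustered(50, 20, intercept_sd = 0, noise_sd = 1, seed = 15)
  fit0 <- fit_merf(dat0$X, dat0$y, dat0$clusters,
                   merf_control(num_trees = 100, max_iter = 25, seed = 3))
  expect_lt(fit0$D, 0.05 * fit0$sigma2_e)

  ## constant response: everything degenerates to the constant
  ycst <- rep(2.5, 40)
  cl <- rep(letters[1:4], each = 10)
  Xc <- data.frame(x1 = rnorm(40))
  fitc <- fit_merf(Xc, ycst, cl, merf_control(num_trees = 50, max_iter = 10))
  expect_lt(max(abs(fitc$b)), 1e-6)
  expect_lt(fitc$sigma2_e, 1e-6)
  expect_equal(unname(predict_merf(fitc, Xc)), rep(2.5, 40), tolerance = 1e-6)
})

test_that("GLL descends and stabilizes across EM iterations", {
  dat <- make_clustered(20, 8, intercept_sd = 1.5, noise_sd = 0.7, seed = 8)
  ## constant learner is exact EM: strictly non-increasing to within 1e-8
  fitc <- fit_merf(dat$X, dat$y, dat$clusters,
                   merf_control(max_iter = 40, tol = 0, learner = "constant"))
  expect_true(all(diff(fitc$gll_trace[-1]) <= 1e-8))
  ## forest learner: steep initial descent, then a stabilized tail whose
  ## refit-to-refit fluctuation stays small against the total descent
  fit <- fit_merf(dat$X, dat$y, dat$clusters,
                  merf_control(num_trees = 100, max_iter = 20, tol = 0, seed = 2))
  tr <- fit$gll_trace
  descent <- tr[1] - min(tr)
  expect_gt(descent, 0)
  expect_true(all(diff(tr[-(1:2)]) <= 0.1 * descent))
})

test_that("MERF predictions honour the cluster contract", {
  dat <- make_clustered(10, 12, intercept_sd = 2, noise_sd = 0.5, seed = 5)
  fit <- fit_merf(dat$X, dat$y, dat$clusters,
                  merf_control(num_trees = 100, max_iter = 15, seed = 7))
  newX <- dat$X[1:4, ]
  ## unseen cluster -> population prediction, exactly f(X)
  expect_equal(predict_merf(fit, newX, clusters = rep("zz", 4)),
               predict_merf(fit, newX))
  ## two clusters differing only in b: prediction gap is b1 - b2
  p1 <- predict_merf(fit, newX, clusters = rep("c1", 4))
  p2 <- predict_merf(fit, newX, clusters = rep("c2", 4))
  expect_equal(unique(round(p1 - p2, 10)),
               round(fit$b[["c1"]] - fit$b[["c2"]], 10))
  ## in-sample residuals cannot exceed the response variance
  expect_lte(var(dat$y - fit$fitted), var(dat$y))
  expect_error(predict_merf(fit, dat$X[, 1:2]), "missing feature")
})

test_that("with a constant learner the intercepts equal closed-form BLUPs", {
  dat <- make_clustered(12, 6, intercept_sd = 1, noise_sd = 1, seed = 9,
                        f = function(x) 0 * x[, 1])
  fit <- fit_merf(dat$X, dat$y, dat$clusters,
                  merf_control(max_iter = 200, tol = 1e-12, learner = "constant"))
  ## BLUP of a one-way random-intercept model at the fitted variance
  ## components: b_j = D * sum_j(resid) / (sigma2 + n_j D)
  mu <- mean(dat$y - fit$b[as.character(factor(dat$clusters))])
  r <- dat$y - mu
  nj <- table(dat$clusters)
  blup <- vapply(names(fit$b), function(j) {
    fit$D * sum(r[dat$clusters == j]) / (fit$sigma2_e + nj[[j]] * fit$D)
  }, numeric(1))
  expect_equal(unname(fit$b), unname(blup), tolerance = 1e-6)
})

test_that("period classification recovers planted shifts and is null-calibrated", {
  truth <- planted_truth()
  co <- simulate_study(truth = truth, seed = 31)
  ctrl <- merf_control(num_trees = 200, max_iter = 8)
  cls <- classify_period(co$abundance, co$samples$phase,
                         co$samples$subject_id, ctrl)
  planted <- attr(truth, "planted_species")
  expect_setequal(head(cls$ranking$feature, 5), planted)
  expect_gt(cls$auc, 0.9)
  ## planted species are enriched at intervention and signed accordingly
  expect_true(all(cls$ranking$direction[cls$ranking$feature %in% planted]
                  == "enriched_intervention"))

  ## permuted labels: no discrimination left (averaged over three
  ## permutations; single-replicate OOB AUC is noisier and slightly
  ## pessimistic under the null)
  null_auc <- vapply(77:79, function(s) {
    set.seed(s)
    perm <- sample(co$samples$phase)
    classify_period(co$abundance, perm, co$samples$subject_id, ctrl)$auc
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.1)
  expect_error(classify_period(co$abundance, rep(1, nrow(co$abundance)),
                               co$samples$subject_id, ctrl), "both classes")
})
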