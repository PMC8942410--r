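test_that("noiseless common slopes give r_rm of exactly +/- 1", {
  x <- rep(1:4, 3)
  subj <- rep(c("a", "b", "c"), each = 4)
  offs <- rep(c(0, 5, -3), each = 4)
  up <- rmcorr(x, x + offs, subj)
  expect_equal(up$r_rm, 1)
  expect_lt(up$p_value, 1e-12)
  down <- rmcorr(x, -x + offs, subj)
  expect_equal(down$r_rm, -1)
})

test_that("rmcorr agrees with the normal-equations ANCOVA oracle", {
  ## fixed 2-subject x 3-point numeric fixture
  x <- c(1, 2, 3, 2, 4, 6)
  y <- c(1.2, 2.1, 2.8, 5.4, 6.9, 8.8)
  subj <- c("a", "a", "a", "b", "b", "b")
  got <- rmcorr(x, y, subj)
  want <- rmcorr_oracle(x, y, subj)
  expect_equal(got$r_rm, want$r, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  ## 100 random small datasets
  set.seed(19)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    n_per <- sample(2:5, 1)
    subj <- rep(paste0("s", 1:k), each = n_per)
    x <- rnorm(k * n_per)
    y <- 0.6 * x + rep(rnorm(k, 0, 2), each = n_per) + rnorm(k * n_per)
    got <- rmcorr(x, y, subj)
    want <- rmcorr_oracle(x, y, subj)
    expect_lt(abs(got$r_rm - want$r), 1e-10)
    expect_lt(abs(got$p_value - want$p), 1e-10)
    expect_equal(got$df, length(x) - k - 1)
  }
})

test_that("r_rm is invariant to per-subject additive shifts", {
  set.seed(23)
  subj <- rep(paste0("s", 1:5), each = 6)
  x <- rnorm(30)
  y <- 0.8 * x + rnorm(30, 0, 0.5)
  base <- rmcorr(x, y, subj)$r_rm
  for (i in 1:10) {
    sx <- rep(rnorm(5, 0, 10), each = 6)
    sy <- rep(rnorm(5, 0, 10), each = 6)
    expect_equal(rmcorr(x + sx, y + sy, subj)$r_rm, base, tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected and singletons dropped", {
  expect_error(suppressMessages(rmcorr(1:4, 1:4, c("a", "b", "c", "d"))),
               "2 subjects")
  expect_error(rmcorr(rep(1, 8), rnorm(8), rep(c("a", "b"), each = 4)),
               "within-subject variance")
  expect_message(rmcorr(c(1, 2, 3, 2, 4, 1), c(1, 2, 2, 3, 5, 9),
                        c("a", "a", "a", "b", "b", "c")), "dropping 1")
  ## incomplete pairs are dropped pairwise
  res <- rmcorr(c(1, 2, 3, NA, 2, 4, 6), c(1, 2, 3, 4, 5, 7, 9),
                rep(c("a", "b"), c(4, 3)))
  expect_equal(res$n_obs, 6)
})

test_that("screened pairs feed stratified correlations with enrichment labels", {
  truth <- planted_truth(n_planted = 2)
  co <- simulate_study(truth = truth, seed = 41)
  pairs <- data.frame(species = truth$species[1:2],
                      food_column = c("prebiotics", "adverse"))
  tab <- food_species_rmcorr(pairs, co)
  expect_setequal(unique(tab$diagnosis), c("CD", "UC"))
  expect_true(all(tab$r_rm[tab$food == "prebiotics"] > 0))
  expect_true(all(tab$r_rm[tab$food == "adverse"] < 0))
  expect_true(all(tab$enrichment == "intervention"))
  expect_true(all(tab$q >= tab$p))
  ## no pairs in -> empty table
  expect_equal(nrow(food_species_rmcorr(pairs[0, ], co)), 0)
})

test_that("a planted UC-only interaction appears in UC but not CD", {
  truth <- make_truth(n_species = 40, seed = 2)
  truth$interaction_effects[3, "beneficial"] <- -0.8   # UC-only suppression
  co <- simulate_study(n_cd = 15, n_uc = 7, truth = truth, seed = 43)
  foods <- dietshift:::sample_food_covariates(co)
  sel_uc <- co$samples$diagnosis == "UC"
  uc <- rmcorr(foods[sel_uc, "beneficial"], co$abundance[sel_uc, 3],
               co$samples$subject_id[sel_uc])
  cd <- rmcorr(foods[!sel_uc, "beneficial"], co$abundance[!sel_uc, 3],
               co$samples$subject_id[!sel_uc])
  expect_lt(uc$r_rm, 0)
  expect_lt(uc$p_value, 0.05)
  expect_gt(cd$p_value, 0.05)
})
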