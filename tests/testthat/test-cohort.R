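test_that("cohort generation is deterministic and respects counts", {
  expect_equal(nrow(generate_cohort(0, 0, seed = 3)), 0)
  a <- generate_cohort(15, 7, seed = 11)
  b <- generate_cohort(15, 7, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 22)
  expect_equal(sum(a$diagnosis == "CD"), 15)
  expect_true(all(a$age > 0) && all(a$bmi > 0))
  expect_error(generate_cohort(-1, 2, seed = 1), "nonnegative")
})

test_that("demographics converge to configured group means", {
  big <- generate_cohort(1000, 1000, seed = 5)
  expect_lt(abs(mean(big$age[big$diagnosis == "CD"]) - 41.7), 1.5)
  expect_lt(abs(mean(big$age[big$diagnosis == "UC"]) - 37.8), 1.5)
  expect_lt(abs(mean(big$bmi[big$diagnosis == "CD"]) - 29.3), 1)
  expect_lt(abs(mean(big$bmi[big$diagnosis == "UC"]) - 25.4), 1)
})

test_that("abundances are compositional and the module is seed-deterministic", {
  subjects <- generate_cohort(4, 2, seed = 2)
  co1 <- generate_longitudinal_data(subjects, default_truth(), seed = 9)
  co2 <- generate_longitudinal_data(subjects, default_truth(), seed = 9)
  expect_identical(co1$abundance, co2$abundance)
  expect_identical(co1$food_records, co2$food_records)
  expect_true(all(abs(rowSums(co1$abundance) - 1) < 1e-9))
  expect_true(all(co1$abundance >= 0 & co1$abundance <= 1))
  expect_true(all(co1$samples$phase %in% c("baseline", "intervention")))
  expect_true(all((co1$samples$week <= 6) == (co1$samples$phase == "baseline")))
  expect_true(all(co1$food_records$subject_id %in% subjects$subject_id))
  cats <- diet_categories()
  expect_true(all(as.matrix(co1$food_records[cats]) >= 0))
})

test_that("generated phase intake means converge to the configured targets", {
  subjects <- generate_cohort(60, 30, seed = 4)
  co <- generate_longitudinal_data(subjects, null_truth(), seed = 4)
  rec <- co$food_records
  m <- function(cat, ph) mean(rec[[cat]][rec$phase == ph])
  expect_lt(abs(m("prebiotics", "baseline") - 4.08), 0.25)
  expect_lt(abs(m("prebiotics", "intervention") - 7.51), 0.35)
  expect_lt(abs(m("adverse", "baseline") - 12.64), 0.6)
  expect_lt(abs(m("adverse", "intervention") - 3.42), 0.25)
})

test_that("a strong planted prebiotic effect yields a significant positive rmcorr", {
  truth <- planted_truth(n_planted = 1)
  co <- simulate_study(n_cd = 15, n_uc = 7, truth = truth, seed = 21)
  foods <- dietshift:::sample_food_covariates(co)
  res <- rmcorr(foods[, "prebiotics"], co$abundance[, 1],
                co$samples$subject_id)
  expect_gt(res$r_rm, 0)
  expect_lt(res$p_value, 0.001)
})

test_that("cytokine generation recovers planted slopes and nulls", {
  truth <- default_truth()           # IL-6 slope on prebiotics is -1.5
  subjects <- generate_cohort(30, 20, seed = 6)
  co <- generate_longitudinal_data(subjects, truth, seed = 6)
  p1 <- generate_cytokines(co, truth, seed = 8)
  p2 <- generate_cytokines(co, truth, seed = 8)
  expect_identical(p1, p2)
  expect_true(all(p1$concentration >= 0))
  expect_equal(length(unique(p1$analyte)), 14)
  intakes <- phase_mean_intakes(co$food_records)
  reg <- cytokine_food_regression(p1, intakes)
  il6 <- reg[reg$analyte == "IL-6" & reg$category == "prebiotics", ]
  expect_lt(il6$slope, 0)
  expect_lt(il6$p, 0.05)
  ## a null analyte/category pair stays centred near zero
  null_row <- reg[reg$analyte == "IL-4" & reg$category == "probiotics", ]
  expect_gt(null_row$p, 0.001)
})
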