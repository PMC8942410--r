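test_that("item records map onto category totals", {
  map <- default_category_map()
  expect_equal(nrow(load_food_queries(
    data.frame(subject_id = character(), day = integer(),
               item = character(), servings = numeric()), map)), 0)

  rec <- data.frame(subject_id = "A", day = 1,
                    item = c("yogurt", "oats"), servings = c(2, 1))
  out <- load_food_queries(rec, map)
  expect_equal(nrow(out), 1)
  expect_equal(out$probiotics, 2)
  expect_equal(out$prebiotics, 1)
  expect_equal(out$beneficial + out$adverse + out$alcohol, 0)

  ## 6 records x 3 items, totals hand-computed
  rec6 <- data.frame(
    subject_id = rep(c("A", "B"), each = 9),
    day = rep(1:6, each = 3),
    item = rep(c("oats", "salmon", "soda"), 6),
    servings = rep(c(1.5, 1, 2), 6))
  out6 <- load_food_queries(rec6, map)
  expect_equal(nrow(out6), 6)
  expect_equal(out6$prebiotics, rep(1.5, 6))
  expect_equal(out6$beneficial, rep(1, 6))
  expect_equal(out6$adverse, rep(2, 6))

  ## record-order invariance of totals
  shuf <- load_food_queries(rec6[sample(nrow(rec6)), ], map)
  expect_equal(shuf[order(shuf$subject_id, shuf$day), ],
               out6[order(out6$subject_id, out6$day), ],
               ignore_attr = TRUE)

  ## unmapped item handling
  bad <- rbind(rec, data.frame(subject_id = "A", day = 2,
                               item = "unobtainium", servings = 1))
  expect_error(load_food_queries(bad, map, unmapped = "error"), "unobtainium")
  expect_warning(res <- load_food_queries(bad, map, unmapped = "warn"),
                 "unobtainium")
  expect_equal(nrow(res), 1)
})

test_that("weekly bin means match hand computation and omit empty bins", {
  rec <- make_records(list(baseline = rep(3, 6), intervention = rep(3, 8)))
  wm <- weekly_category_means(rec, bin_weeks = 1)
  expect_true(all(wm$mean[wm$category == "prebiotics"] == 3))

  rec2 <- make_records(list(baseline = c(1, 2, 3, 4)))
  rec2$week <- c(1L, 1L, 2L, 2L)   # two known bins of two records
  wm2 <- weekly_category_means(rec2, bin_weeks = 2)
  expect_equal(wm2$mean[wm2$category == "prebiotics"], mean(c(1, 2, 3, 4)))
  rec2$week <- c(1L, 1L, 3L, 3L)
  wm3 <- weekly_category_means(rec2, bin_weeks = 2)
  expect_equal(wm3$mean[wm3$category == "prebiotics"], c(1.5, 3.5))

  ## baseline-only records: no intervention series at all
  expect_false("intervention" %in% wm3$phase)
})

test_that("diet shift summary reproduces fold changes and pairs reciprocally", {
  rec <- make_records(list(baseline = rep(4.08, 6), intervention = rep(7.51, 8)))
  s <- diet_shift_summary(rec)
  pre <- s[s$category == "prebiotics", ]
  expect_equal(round(pre$fold_change, 1), 1.8)
  expect_equal(pre$direction, "increase")

  rec_adv <- make_records(list(baseline = rep(12.64, 6), intervention = rep(3.42, 8)),
                          category = "adverse")
  adv <- diet_shift_summary(rec_adv)
  adv <- adv[adv$category == "adverse", ]
  expect_equal(round(adv$fold_change, 1), 3.7)
  expect_equal(adv$direction, "reduction")

  ## reversing the phases inverts the direction but keeps the ratio
  rec_rev <- make_records(list(baseline = rep(7.51, 6), intervention = rep(4.08, 8)))
  rev <- diet_shift_summary(rec_rev)[1, ]
  expect_equal(pre$fold_change * (1 / rev$fold_change), 1, tolerance = 1e-12)

  ## identical phases: no shift
  same <- diet_shift_summary(make_records(list(baseline = rep(2, 4),
                                               intervention = rep(2, 4))))
  expect_equal(same$difference[1], 0)
  expect_equal(same$fold_change[1], 1)

  expect_error(diet_shift_summary(make_records(list(baseline = rep(1, 3)))),
               "intervention")
})

test_that("phase comparison uses the exact Mann-Whitney rule", {
  rec <- make_records(list(baseline = c(1, 2, 3), intervention = c(4, 5, 6)))
  res <- compare_phases(rec, categories = "prebiotics")
  expect_equal(res$p, 0.1)   # exact enumeration over choose(6,3) = 20 rank splits

  same <- make_records(list(baseline = c(5, 6, 7, 8), intervention = c(7, 5, 8, 6)))
  res2 <- compare_phases(same, categories = "prebiotics")
  expect_gt(res2$p, 0.99)

  const <- make_records(list(baseline = rep(2, 4), intervention = rep(2, 4)))
  res3 <- compare_phases(const, categories = "prebiotics")
  expect_true(res3$degenerate)
  expect_equal(res3$p, 1)
})

test_that("BKY two-stage decisions follow the hand-executed algorithm", {
  ## q = 0.05, m = 3: stage 1 at 0.05/1.05 rejects only 0.001; m0 = 2;
  ## stage 2 level = (0.05/1.05) * 3/2 = 0.0714 -> still only the first.
  res <- adjust_bky(c(0.001, 0.2, 0.9), q = 0.05)
  expect_equal(res$reject, c(TRUE, FALSE, FALSE))
  expect_equal(res$r1, 1L)
  expect_equal(res$m0_hat, 2L)
  expect_equal(res$stage2_level, 0.05 / 1.05 * 3 / 2)
  expect_equal(adjust_bky(rep(1, 5))$reject, rep(FALSE, 5))
  expect_equal(adjust_bky(rep(1e-6, 5))$reject, rep(TRUE, 5))
  expect_error(adjust_bky(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BKY rejections contain BH rejections on randomized p-vectors", {
  set.seed(42)
  for (i in 1:50) {
    m <- sample(5:200, 1)
    n_sig <- rbinom(1, m, 0.2)
    p <- c(rbeta(n_sig, 0.2, 5), runif(m - n_sig))
    bky <- adjust_bky(p, q = 0.05)$reject
    bh <- adjust_bh(p) <= 0.05
    expect_true(all(bky[bh]), info = paste("replicate", i))
  }
})
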