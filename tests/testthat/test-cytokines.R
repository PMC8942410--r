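make_panel <- function(levels_by_subject, analyte = "IL-6") {
  do.call(rbind, lapply(names(levels_by_subject), function(s) {
    v <- levels_by_subject[[s]]
    data.frame(subject_id = s, timepoint = c("baseline", "post"),
               analyte = analyte, concentration = v, stringsAsFactors = FALSE)
  }))
}

test_that("an exact linear relation is fitted exactly", {
  subs <- paste0("s", 1:5)
  intakes <- data.frame(subject_id = rep(subs, 2),
                        phase = rep(c("baseline", "intervention"), each = 5),
                        prebiotics = c(1:5, 6:10))
  panel <- data.frame(subject_id = rep(subs, 2),
                      timepoint = rep(c("baseline", "post"), each = 5),
                      analyte = "IL-8",
                      concentration = 2 * c(1:5, 6:10) + 1)
  res <- cytokine_food_regression(panel, intakes)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$r_squared, 1)
  expect_equal(res$n, 10)

  ## constant cytokine: zero slope, degenerate inference flagged as NA p
  panel$concentration <- 7
  res0 <- cytokine_food_regression(panel, intakes)
  expect_equal(res0$slope, 0)
  expect_true(is.na(res0$p))

  ## constant intake: regression skipped
  intakes$prebiotics <- 3
  expect_message(resz <- cytokine_food_regression(panel, intakes),
                 "zero intake variance")
  expect_null(resz)
})

test_that("a planted negative slope is recovered at generator noise", {
  set.seed(51)
  n <- 50
  x <- runif(n, 1, 8)
  y <- pmax(30 - 1.5 * x + rnorm(n, 0, 5), 0)
  intakes <- data.frame(subject_id = paste0("s", 1:n), phase = "baseline",
                        prebiotics = x)
  panel <- data.frame(subject_id = paste0("s", 1:n), timepoint = "baseline",
                      analyte = "IL-6", concentration = y)
  res <- cytokine_food_regression(panel, intakes)
  expect_lt(res$slope, 0)
  expect_lt(res$p, 0.05)
})

test_that("matched-pairs Wilcoxon is exact and order invariant", {
  pre <- c(10, 11, 12, 13, 14, 15)
  post <- pre + 1:6            # six same-signed differences
  panel <- make_panel(stats::setNames(
    lapply(1:6, function(i) c(pre[i], post[i])), paste0("s", 1:6)))
  res <- pre_post_wilcoxon(panel)
  expect_equal(res$p, 0.03125)   # 2 * 1/2^6 * 2 = 2/64... enumeration check below
  expect_equal(res$p, signrank_enum_p(post - pre))
  expect_false(res$degenerate)
  expect_true(res$trend)

  ## shuffled pair order: identical result
  shuffled <- panel[sample(nrow(panel)), ]
  expect_equal(pre_post_wilcoxon(shuffled)$p, res$p)

  ## identical pre/post: degenerate, p = 1
  same <- make_panel(stats::setNames(
    lapply(1:6, function(i) c(pre[i], pre[i])), paste0("s", 1:6)))
  res0 <- pre_post_wilcoxon(same)
  expect_true(res0$degenerate)
  expect_equal(res0$p, 1)

  ## fewer than 5 pairs: skipped
  small <- make_panel(list(s1 = c(1, 2), s2 = c(2, 3), s3 = c(3, 5)))
  expect_message(out <- pre_post_wilcoxon(small), "only 3 pairs")
  expect_null(out)
})

test_that("exact Wilcoxon p matches the sign-enumeration oracle", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n, 0.3, 1), 6)
    pre <- runif(n, 10, 20)
    panel <- make_panel(stats::setNames(
      lapply(seq_len(n), function(j) c(pre[j], pre[j] + d[j])),
      paste0("s", seq_len(n))))
    res <- pre_post_wilcoxon(panel)
    expect_equal(res$p, signrank_enum_p(d), tolerance = 1e-12,
                 info = paste("replicate", i))
  }
})
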