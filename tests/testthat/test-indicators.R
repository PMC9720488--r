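test_that("weekly aggregation assigns records to age-weeks and drops partial weeks", {
  # week 26 covers days 175..181; three collections summing to 7
  wc <- weekly_counts(day = c(175, 178, 181), eggs = c(3, 3, 1))
  expect_equal(wc, data.frame(week = 26L, eggs = 7L))
  # a record in the next week is dropped while that week is uncovered
  wc2 <- weekly_counts(day = c(175, 178, 181, 183), eggs = c(3, 3, 1, 2))
  expect_equal(wc2$week, 26L)
  # death at day 200 (week 29): no weeks after the week containing 200
  wc3 <- weekly_counts(day = c(189, 195, 196, 200), eggs = c(7, 6, 1, 3))
  expect_true(all(wc3$week <= 29L))
  # empty log
  expect_equal(nrow(weekly_counts(integer(0), integer(0))), 0L)
  expect_error(weekly_counts(c(10, 10), c(1, 1)), "strictly increasing")
})

test_that("batch-wide weekly production matches the per-hen rule", {
  cfg <- sim_config(n_hens = 40)
  ped <- simulate_pedigree(cfg, seed = 1)
  eggs <- simulate_egg_production(ped, NULL, NULL, cfg, seed = 1)
  wk <- weekly_production(eggs$log)
  for (h in sample(unique(eggs$log$hen), 5)) {
    one <- eggs$log[eggs$log$hen == h, ]
    ref <- weekly_counts(one$day, one$eggs)
    got <- wk[wk$hen == h, c("week", "eggs")]
    rownames(got) <- NULL
    expect_equal(got, ref)
  }
})

test_that("batch mean curve averages observed hens per week", {
  weekly <- data.frame(hen = c("a", "b", "a"), week = c(30L, 30L, 31L),
                       eggs = c(6L, 8L, 5L))
  bm <- batch_mean(weekly)
  expect_equal(bm$mean_eggs[bm$week == 30], 7)
  expect_equal(bm$n_hens[bm$week == 31], 1L)
  # a single hen's curve is her own series
  one <- weekly[weekly$hen == "a", ]
  expect_equal(batch_mean(one)$mean_eggs, one$eggs)
})

test_that("deviations subtract the curve elementwise and reject missing weeks", {
  weekly <- data.frame(hen = "a", week = 30:32, eggs = c(5L, 7L, 6L))
  curve <- data.frame(week = 30:32, mean_eggs = c(6.5, 7, 6))
  d <- deviations(weekly, curve)
  expect_equal(d$deviation, c(-1.5, 0, 0))
  expect_error(deviations(data.frame(hen = "a", week = 40L, eggs = 1L),
                          curve), "absent")
})

test_that("indicator formulas reproduce hand-computed values", {
  expect_equal(ln_variance(c(1, -1, 1, -1)), log(4 / 3), tolerance = 1e-12)
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 1.1547005, tolerance = 1e-6)
  # linear trend over 64 weeks, closed-form serial estimator
  expect_equal(lag1_autocorrelation(1:64), 0.953125, tolerance = 1e-12)
  # long alternating series approaches -1: r1 = -(n-1)/n
  x <- rep(c(1, -1), 200)
  expect_equal(lag1_autocorrelation(x), -(length(x) - 1) / length(x),
               tolerance = 1e-12)
})

test_that("indicators match independent oracles on random series", {
  skip_if_not_installed("e1071")
  set.seed(10)
  for (r in 1:20) {
    x <- rnorm(sample(10:80, 1), sd = runif(1, 0.5, 3))
    expect_equal(ln_variance(x), log(stats::var(x)), tolerance = 1e-10)
    expect_equal(skewness(x), e1071::skewness(x, type = 1),
                 tolerance = 1e-10)
    expect_equal(lag1_autocorrelation(x),
                 drop(stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]),
                 tolerance = 1e-10)
  }
})

test_that("indicators respect location/scale symmetries and bounds", {
  set.seed(11)
  for (r in 1:10) {
    x <- rnorm(40)
    c0 <- runif(1, -5, 5)
    expect_equal(skewness(x + c0), skewness(x), tolerance = 1e-10)
    expect_equal(lag1_autocorrelation(x + c0), lag1_autocorrelation(x),
                 tolerance = 1e-10)
    expect_equal(ln_variance(3 * x) - ln_variance(x), 2 * log(3),
                 tolerance = 1e-10)
    expect_equal(skewness(-x), -skewness(x), tolerance = 1e-10)
    r1 <- lag1_autocorrelation(x)
    expect_gte(r1, -1)
    expect_lte(r1, 1)
  }
})

test_that("degenerate series yield missing indicators", {
  expect_true(is.na(ln_variance(c(2, 2, 2))))
  expect_true(is.na(ln_variance(1)))
  expect_true(is.na(skewness(c(3, 3, 3, 3))))
  expect_true(is.na(lag1_autocorrelation(c(1, 2))))
  expect_true(is.na(lag1_autocorrelation(c(5, 5, 5, 5))))
})

test_that("gap weeks drop Rauto pairs but keep variance and skewness data", {
  x <- c(1, 2, 3, 4, 5, 6)
  wks <- c(30, 31, 32, 40, 41, 42)      # one gap between weeks 32 and 40
  full <- lag1_autocorrelation(x)
  gapped <- lag1_autocorrelation(x, weeks = wks)
  expect_false(isTRUE(all.equal(full, gapped)))
  xc <- x - mean(x)
  num <- sum(xc[c(1, 2, 4, 5)] * xc[c(2, 3, 5, 6)])
  expect_equal(gapped, num / sum(xc^2), tolerance = 1e-12)
  expect_equal(ln_variance(x), log(var(x)), tolerance = 1e-12)
})

test_that("the 20-egg filter and period windows behave at the boundary", {
  # 58 weeks (25..82) with a constant batch curve of 1; hen A lays 19
  # eggs in the first period, hen B exactly 20, hen C dies at week 80
  mk <- function(hen, weeks, eggs) data.frame(hen = hen, week = weeks,
                                              eggs = eggs)
  wA <- mk("A", 25:82, c(rep(1L, 19), rep(0L, 39)))
  wB <- mk("B", 25:82, c(rep(1L, 20), rep(0L, 38)))
  wC <- mk("C", 25:79, rep(1L, 55))
  weekly <- rbind(wA, wB, wC)
  curve <- data.frame(week = 25:82, mean_eggs = 0.5)
  res <- resilience_indicators(weekly, curve, min_eggs = 20)
  a1 <- res[res$hen == "A" & res$period == "25-83", ]
  b1 <- res[res$hen == "B" & res$period == "25-83", ]
  c2 <- res[res$hen == "C" & res$period == "83-end", ]
  expect_true(is.na(a1$ln_var) && is.na(a1$skew) && is.na(a1$r_auto))
  expect_false(is.na(b1$ln_var))
  expect_true(all(is.na(c2[c("ln_var", "skew", "r_auto")])))
  expect_equal(c2$n_weeks, 0L)
  fc <- attr(res, "filter_counts")
  expect_equal(unname(fc["25-83"]), 1L)
})

test_that("a constant producer shows rising deviations against a declining curve", {
  wks <- 29:92
  curve <- data.frame(week = wks,
                      mean_eggs = 6.8 + (4.9 - 6.8) * (wks - 29) / (92 - 29))
  weekly <- data.frame(hen = "star", week = wks, eggs = 7L)
  d <- deviations(weekly, curve)
  expect_true(all(diff(d$deviation) > 0))
})
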