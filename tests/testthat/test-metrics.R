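test_that("Dice similarity matches hand counts and its boundary conventions", {
  a <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), c(6, 1, 1))
  b <- array(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), c(6, 1, 1))
  expect_equal(dsc(a, b), 2 * 2 / 6)        # |A|=4, |B|=2, |A^B|=2
  expect_equal(dsc(a, a), 1.0)
  disj <- array(c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE), c(6, 1, 1))
  expect_equal(dsc(a, disj), 0.0)
  none <- array(FALSE, c(6, 1, 1))
  expect_equal(dsc(none, none), 1.0)        # both-empty: perfect agreement
})

test_that("Dice is symmetric and bounded on random masks", {
  set.seed(31)
  for (i in 1:20) {
    a <- array(runif(60) < runif(1), c(60, 1, 1))
    b <- array(runif(60) < runif(1), c(60, 1, 1))
    d1 <- dsc(a, b)
    expect_identical(d1, dsc(b, a))
    expect_gte(d1, 0)
    expect_lte(d1, 1)
  }
})

test_that("concordance penalizes location shift and matches the frozen oracle value", {
  x <- c(3, 8, 1, 9, 4)
  expect_equal(concordance(x, x), 1.0)
  shifted <- concordance(x, x + 5)
  expect_lt(shifted, 1)
  expect_equal(cor(x, x + 5), 1)

  # oracle: population-moment evaluation for x=(1,2,3), y=(1,2,4) gives 6/7
  expect_equal(concordance(c(1, 2, 3), c(1, 2, 4)), 6 / 7, tolerance = 1e-12)

  expect_error(concordance(c(2, 2, 2), c(5, 5, 5)), "constant")
  expect_error(concordance(1, 1), "at least 2")
})

test_that("concordance never exceeds Pearson correlation in magnitude", {
  set.seed(17)
  for (i in 1:25) {
    x <- rnorm(30, 100, 20)
    y <- 0.5 * x + rnorm(30, sample(c(-30, 0, 30), 1), 10)
    expect_lte(abs(concordance(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("RMSE and percent error match hand evaluations", {
  expect_equal(rmse(c(100, 200), c(110, 190)), 10)
  expect_equal(rmse(c(5, 5), c(5, 5)), 0)
  expect_equal(meanPercentError(200, 210), 5)
  expect_equal(meanPercentError(c(100, 200), c(100, 200)), 0)
  expect_error(meanPercentError(c(0, 10), c(1, 10)), "zero")

  # rmse = 0 iff identical; percent error is scale-invariant
  set.seed(4)
  x <- runif(10, 100, 1000)
  y <- x * (1 + runif(10, -0.1, 0.1))
  expect_gt(rmse(x, y), 0)
  expect_equal(meanPercentError(x, y), meanPercentError(10 * x, 10 * y))
})

test_that("zero-error counting uses whole-mL rounding", {
  expect_identical(zeroErrorCount(rep(42.2, 7), rep(42.2, 7)), 7L)
  expect_identical(zeroErrorCount(608.4, 608.2), 1L)  # both round to 608
  expect_identical(zeroErrorCount(608.4, 609.6), 0L)  # 608 vs 610
  expect_identical(zeroErrorCount(c(608.4, 100), c(608.2, 103)), 1L)
})

test_that("Bland-Altman bias, limits and coverage behave as designed", {
  x <- c(100, 220, 540)
  ba0 <- blandAltman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$upper - ba0$lower, 0)

  ba_off <- blandAltman(x, x * 1.1)
  expect_gt(ba_off$bias, 0)

  # ~95% of simulated differences fall inside the limits at n = 500
  set.seed(99)
  xt <- runif(500, 200, 2000)
  yt <- xt * (1 + rnorm(500, 0, 0.05))
  ba <- blandAltman(xt, yt)
  cover <- mean(ba$differences >= ba$lower & ba$differences <= ba$upper)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("interobserver SD averages per-case sample SDs", {
  expect_equal(interobserverSD(matrix(c(100, 110, 120), 1)), 10)
  expect_equal(interobserverSD(matrix(rep(7, 9), 3)), 0)
  m <- rbind(c(100, 110, 120), c(200, 200, 200))
  expect_equal(interobserverSD(m), 5)
  expect_error(interobserverSD(matrix(1:3, 3, 1)), "2 observers")
})

test_that("boundary-noise scale drives the interobserver SD monotonically", {
  truth <- noiseFreePhantom()@truth
  sd_at <- function(noise_mm) {
    meas <- t(sapply(1:4, function(case)
      sapply(1:3, function(obs)
        organVolume(simulateObserver(truth, noise_mm,
                                     seed = case * 100 + obs), "liver"))))
    interobserverSD(meas)
  }
  expect_gt(sd_at(6), sd_at(1))
})

test_that("ICC(2,1) matches an aov mean-squares oracle and recovers parameters", {
  # hand-computable 3x3 table vs. variance components from aov()
  m <- rbind(c(9, 2, 5), c(6, 1, 3), c(8, 4, 6))
  df <- data.frame(y = as.vector(m),
                   case = factor(rep(1:3, 3)),
                   rater = factor(rep(1:3, each = 3)))
  ms <- anova(stats::aov(y ~ case + rater, data = df))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 3; k <- 3
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc(m), oracle, tolerance = 1e-12)

  # identical observers over heterogeneous cases: perfect reliability
  ident <- matrix(rep(c(100, 450, 900, 1800), 3), ncol = 3)
  expect_equal(icc(ident), 1.0)

  # observer values independent of case: near-zero reliability
  set.seed(23)
  noise <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(icc(noise)), 0.2)

  expect_error(icc(matrix(1:3, 1, 3)), "at least 2")
  expect_error(icc(matrix(1:3, 3, 1)), "at least 2")
})

test_that("the ICC estimator recovers a simulated intraclass correlation", {
  set.seed(55)
  n <- 200; k <- 3
  sigma_case <- 200; sigma_err <- 100
  target <- sigma_case^2 / (sigma_case^2 + sigma_err^2)  # 0.8
  cases <- rnorm(n, 1200, sigma_case)
  m <- matrix(rep(cases, k), n, k) + matrix(rnorm(n * k, 0, sigma_err), n, k)
  expect_lt(abs(icc(m) - target), 0.05)
})

test_that("organ volumes are voxel count times voxel volume", {
  d <- array(0L, c(20, 20, 10))
  d[seq_len(2000)] <- 1L
  map <- LabelMap(d, spacing = c(1.25, 1.25, 5))
  expect_equal(organVolume(map, "right_kidney"), 15.625)  # 2000 x 7.8125 mm^3
  expect_equal(organVolume(map, "spleen"), 0)

  vr <- volumeReport(map, height_m = 1.6)
  expect_equal(vr$TKV_mL, vr$right_kidney + vr$left_kidney)
  expect_equal(vr$htTKV_mL_per_m, vr$TKV_mL / 1.6)
})

test_that("evaluateRun assembles the per-organ agreement table", {
  cohort <- generateCohort(4, base_spec = phantomSpec(noise_sd = 0), seed = 6)
  truth <- lapply(cohort, function(s) s@truth)

  # predictions identical to truth: perfect agreement everywhere
  rep0 <- evaluateRun(truth, truth)
  tab <- as.data.frame(rep0)
  expect_setequal(tab$organ,
                  c("right_kidney", "left_kidney", "liver", "spleen"))
  expect_true(all(tab$dsc == 1))
  expect_true(all(tab$rmse_mL == 0))
  expect_true(all(tab$mean_pct_error == 0))
  expect_true(all(tab$zero_error_n == 4))
  expect_true(all(tab$ba_bias_pct == 0))

  # simulated observer predictions: metrics populated and in range
  pred <- lapply(seq_along(truth), function(i)
    simulateObserver(truth[[i]], 2, seed = i))
  rep1 <- evaluateRun(truth, pred)
  t1 <- as.data.frame(rep1)
  expect_true(all(t1$dsc >= 0 & t1$dsc <= 1))
  expect_true(all(abs(t1$concordance) <= 1, na.rm = TRUE))
  expect_true(all(t1$rmse_mL >= 0))

  # single case: concordance undefined, the rest computed
  rep2 <- evaluateRun(truth[1], pred[1])
  t2 <- as.data.frame(rep2)
  expect_true(all(is.na(t2$concordance)))
  expect_true(all(is.finite(t2$dsc)))

  f <- tempfile(fileext = ".csv")
  exportReport(rep1, f)
  expect_identical(nrow(read.csv(f)), 4L)
})

test_that("observer agreement summarises SD and ICC per organ", {
  truth <- noiseFreePhantom()@truth
  meas <- lapply(stats::setNames(c("right_kidney", "left_kidney"),
                                 c("right_kidney", "left_kidney")),
                 function(org) {
    t(sapply(1:4, function(case) {
      sapply(1:3, function(obs)
        organVolume(simulateObserver(truth, 1.5, seed = case * 10 + obs), org))
    }))
  })
  oa <- observerAgreement(meas)
  expect_identical(nrow(oa), 2L)
  expect_true(all(oa$mean_sd_mL >= 0))
  expect_true(all(oa$icc >= -1 & oa$icc <= 1))
})
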