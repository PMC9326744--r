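test_that("kidney labels merge into one class and binary targets select organs", {
  d <- array(0L, c(10, 10, 4))
  d[1:5, 1:4, 1] <- 1L   # 20 RK voxels
  d[8:10, 8:10, 4] <- 3L
  set.seed(1)
  lk_idx <- sample(which(d == 0L), 80)
  d[lk_idx] <- 2L
  map <- LabelMap(d)
  mk <- mergeKidneyLabels(map)
  expect_identical(sum(mk), 100L)  # 20 + 80
  expect_identical(binaryTarget(map, "kidney"), mk)
  expect_identical(sum(binaryTarget(map, "spleen")), 9L)
  expect_identical(sum(binaryTarget(map, "liver")), 0L)

  empty <- LabelMap(array(0L, c(4, 4, 2)))
  expect_false(any(mergeKidneyLabels(empty)))
  liver_only <- LabelMap(array(4L, c(4, 4, 2)))
  expect_false(any(mergeKidneyLabels(liver_only)))
})

test_that("the network has five decoder upsampling stages and a sigmoid codomain", {
  m <- buildOrganModel("kidney", preset = "default")
  expect_identical(nUpsamplingStages(m), 5L)
  tiny <- buildOrganModel("spleen", preset = "tiny")
  expect_identical(nUpsamplingStages(tiny), 5L)

  set.seed(3)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  p <- abdoseg:::.netForward(tiny$params, x)$prob
  expect_identical(dim(p), c(64L, 64L, 1L, 1L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the default preset maps a 512x512 slice to a 512x512 probability map", {
  m <- buildOrganModel("liver", preset = "default", seed = 2)
  set.seed(2)
  x <- array(runif(512 * 512), c(512, 512, 1, 1))
  p <- abdoseg:::.netForward(m$params, x)$prob
  expect_identical(dim(p), c(512L, 512L, 1L, 1L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("combined loss matches hand-evaluated soft dice and cross-entropy", {
  # identical binary prediction: both terms vanish (up to the CE clamp)
  g <- array(c(1, 0, 0, 1), c(2, 2))
  expect_lt(combinedLoss(g, g, eps = 1e-12), 1e-5)

  # pred 0.5 on 4 pixels, 2 positive targets, eps -> 0: dice = 1 - 2*1/4 = 0.5
  p <- array(0.5, c(2, 2))
  dice_only <- combinedLoss(p, g, w_dice = 1, w_ce = 0, eps = 1e-12)
  expect_equal(dice_only, 0.5, tolerance = 1e-9)

  # disjoint one-hots: dice -> 1
  a <- array(0, c(2, 2)); a[1] <- 1
  b <- array(0, c(2, 2)); b[4] <- 1
  expect_equal(combinedLoss(a, b, w_ce = 0, eps = 1e-12), 1, tolerance = 1e-9)

  expect_error(combinedLoss(array(1.5, c(2, 2)), g), "\\[0, 1\\]")
})

test_that("soft dice equals 1 - DSC for binary predictions as eps -> 0", {
  set.seed(8)
  for (i in 1:5) {
    a <- array(runif(200) < 0.3, c(10, 20))
    b <- array(runif(200) < 0.3, c(10, 20))
    if (sum(a) + sum(b) == 0) next
    dice_term <- combinedLoss(a * 1, b * 1, w_dice = 1, w_ce = 0, eps = 1e-12)
    expect_equal(dice_term, 1 - dsc(a, b), tolerance = 1e-8)
  }
})

test_that("backpropagation matches finite differences", {
  m <- buildOrganModel("kidney", preset = "tiny", seed = 13)
  set.seed(13)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  y <- array(rbinom(64 * 64, 1, 0.25), c(64, 64, 1, 1))
  fw <- abdoseg:::.netForward(m$params, x, keep = TRUE)
  lg <- abdoseg:::.lossGrad(fw$prob, y)
  gr <- abdoseg:::.netBackward(m$params, fw$cache, lg$dz)
  lossAt <- function(params)
    abdoseg:::.lossGrad(abdoseg:::.netForward(params, x)$prob, y)$loss
  for (key in c("enc2.w", "dec4.w", "head.b")) {
    p2 <- m$params
    i <- 1L
    eps <- 1e-5
    p2[[key]][i] <- p2[[key]][i] + eps
    lp <- lossAt(p2)
    p2[[key]][i] <- p2[[key]][i] - 2 * eps
    lm <- lossAt(p2)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - gr[[key]][i]) / max(abs(num), abs(gr[[key]][i]), 1e-10),
              1e-3, label = key)
  }
})

test_that("stratified splits keep subjects atomic and near the requested fraction", {
  cohort <- generateCohort(20, base_spec = phantomSpec(noise_sd = 0), seed = 7)
  man <- cohortManifest(cohort)
  # a subject scanned twice must stay in one partition
  man2 <- rbind(man, man[3, ])
  sp <- stratifiedSplit(man2, 0.7, seed = 1)
  expect_identical(sum(sp$assignments$subject_id == man$subject_id[3]), 1L)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_true(abs(length(sp$train) - 14) <= 2)
  expect_identical(sort(c(sp$train, sp$validation)), sort(man$subject_id))

  # degenerate single-stratum cohort still splits
  man_deg <- data.frame(subject_id = paste0("s", 1:6), TKV_truth_mL = 100,
                        sequence_name = "ssfse_t2")
  sp_deg <- stratifiedSplit(man_deg, 0.5, seed = 2)
  expect_gt(length(sp_deg$train), 0)
  expect_gt(length(sp_deg$validation), 0)

  expect_error(stratifiedSplit(man, 1.2), "fraction")
  expect_error(stratifiedSplit(man, 0), "fraction")
})

test_that("subject atomicity holds across random manifests", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    ids <- paste0("s", seq_len(n))
    man <- data.frame(
      subject_id = sample(ids, n * 2, replace = TRUE),
      TKV_truth_mL = NA_real_,
      sequence_name = sample(c("a", "b"), n * 2, replace = TRUE))
    man$TKV_truth_mL <- stats::ave(runif(nrow(man), 200, 3000),
                                   man$subject_id, FUN = function(v) v[1])
    man$sequence_name <- stats::ave(man$sequence_name, man$subject_id,
                                    FUN = function(v) v[1])
    sp <- stratifiedSplit(man, 0.7, seed = rep)
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_setequal(c(sp$train, sp$validation), unique(man$subject_id))
  }
})

test_that("short training runs log per-epoch metrics and checkpoints reload exactly", {
  cohort <- generateCohort(3, base_spec = phantomSpec(noise_sd = 0), seed = 2)
  man <- cohortManifest(cohort)
  split <- stratifiedSplit(man, 0.67, seed = 1)
  cfg <- trainConfig("kidney", max_epochs = 2, seed = 1)
  ck <- trainOrgan(cohort, split, cfg)
  expect_identical(nrow(ck@log), 2L)
  expect_equal(ck@bestDSC, max(ck@log$val_dsc))
  expect_identical(ck@bestEpoch,
                   ck@log$epoch[which.max(ck@log$val_dsc)])

  f <- tempfile(fileext = ".rds")
  saveCheckpoint(ck, f)
  ck2 <- loadCheckpoint(f)
  img <- cohort[[1]]@image
  p1 <- inferOrgan(img, ck)
  p2 <- inferOrgan(img, ck2)
  expect_identical(voxelData(p1), voxelData(p2))

  expect_error(trainOrgan(cohort, list(train = man$subject_id,
                                       validation = character(0)), cfg),
               "non-empty")
})
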