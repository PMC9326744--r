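test_that("kidney voxel count matches a brute-force point-in-ellipsoid scan", {
  spec <- singleKidneySpec()
  subj <- generatePhantom(spec)
  got <- sum(voxelData(subj@truth) == 1L)

  # independent oracle: explicit loop over every lattice point
  gs <- spec$grid_shape; sp <- spec$spacing_mm
  ctr <- spec$organ_params$right_kidney$center
  ax <- spec$organ_params$right_kidney$semiaxes
  count <- 0L
  for (i in seq_len(gs[1])) {
    x <- (i - (gs[1] + 1) / 2) * sp[1]
    for (j in seq_len(gs[2])) {
      y <- (j - (gs[2] + 1) / 2) * sp[2]
      for (k in seq_len(gs[3])) {
        z <- (k - (gs[3] + 1) / 2) * sp[3]
        q <- ((x - ctr[1]) / ax[1])^2 + ((y - ctr[2]) / ax[2])^2 +
          ((z - ctr[3]) / ax[3])^2
        if (q < 1) count <- count + 1L
      }
    }
  }
  expect_identical(got, count)
})

test_that("noise-free truth is seed-independent and generation is reproducible", {
  a <- generatePhantom(phantomSpec(noise_sd = 0, seed = 1))
  b <- generatePhantom(phantomSpec(noise_sd = 0, seed = 42))
  expect_identical(voxelData(a@truth), voxelData(b@truth))

  # with noise, the full image is bit-reproducible under a fixed seed
  c1 <- generatePhantom(phantomSpec(seed = 5))
  c2 <- generatePhantom(phantomSpec(seed = 5))
  expect_identical(voxelData(c1@image), voxelData(c2@image))
})

test_that("default phantom contains exactly the standard label values", {
  subj <- noiseFreePhantom()
  expect_setequal(unique(as.vector(voxelData(subj@truth))), 0:4)
  expect_true(validateLabels(subj@truth)$valid)
})

test_that("overlapping organ ellipsoids are rejected naming the pair", {
  op <- defaultOrganParams()
  op$liver$center <- op$right_kidney$center + c(10, 0, 0)  # collide with RK
  spec <- phantomSpec(organ_params = op, noise_sd = 0)
  expect_error(generatePhantom(spec), "right_kidney.*liver|liver.*right_kidney")
})

test_that("noise-free organ volumes match analytic ellipsoid volumes within a surface shell", {
  subj <- noiseFreePhantom()
  op <- defaultOrganParams()
  sp <- voxelSpacing(subj@truth)
  voxvol <- prod(sp) / 1000
  for (org in names(op)) {
    analytic <- 4 / 3 * pi * prod(op[[org]]$semiaxes) / 1000
    measured <- organVolume(subj@truth, org)
    m <- voxelData(subj@truth) == organLabels()[[org]]
    shell <- sum(m & !abdoseg:::.erode1(m)) * voxvol
    expect_lt(abs(measured - analytic), shell,
              label = sprintf("%s |%.1f - %.1f| mL", org, measured, analytic))
  }
})

test_that("cysts are hyperintense in the image but invisible in the truth", {
  spec <- phantomSpec(noise_sd = 0)
  with_cysts <- generatePhantom(spec)
  spec0 <- spec
  spec0$cyst_params <- lapply(spec0$cyst_params, function(p) {
    p$count <- 0L
    p
  })
  without <- generatePhantom(spec0)
  expect_identical(voxelData(with_cysts@truth), voxelData(without@truth))
  diff_vox <- voxelData(with_cysts@image) != voxelData(without@image)
  expect_gt(sum(diff_vox), 0)
  # every altered voxel lies inside an organ and is brighter than before
  expect_true(all(voxelData(with_cysts@truth)[diff_vox] > 0))
  expect_true(all(voxelData(with_cysts@image)[diff_vox] >
                    voxelData(without@image)[diff_vox]))
})

test_that("cohorts are reproducible and degenerate jitter collapses them", {
  c1 <- generateCohort(8, base_spec = phantomSpec(noise_sd = 0), seed = 3)
  c2 <- generateCohort(8, base_spec = phantomSpec(noise_sd = 0), seed = 3)
  expect_identical(lapply(c1, function(s) voxelData(s@image)),
                   lapply(c2, function(s) voxelData(s@image)))
  expect_identical(length(unique(vapply(c1, function(s) s@subject_id,
                                        character(1)))), 8L)

  c0 <- generateCohort(8, base_spec = phantomSpec(noise_sd = 0),
                       scale_jitter = 0, position_jitter_mm = 0,
                       tkv_spread = 0, seed = 3)
  truths <- lapply(c0, function(s) voxelData(s@truth))
  for (i in 2:8) expect_identical(truths[[i]], truths[[1]])
})

test_that("default jitter spreads TKV over several quartile bins", {
  cohort <- generateCohort(20, base_spec = phantomSpec(noise_sd = 0), seed = 11)
  tkv <- cohortManifest(cohort)$TKV_truth_mL
  brk <- unique(quantile(tkv, 0:4 / 4))
  bins <- cut(tkv, breaks = brk, include.lowest = TRUE, labels = FALSE)
  expect_gte(length(unique(bins)), 3)
})

test_that("simulated observers perturb boundaries but respect identities", {
  truth <- noiseFreePhantom()@truth
  expect_identical(simulateObserver(truth, 0), truth)
  expect_error(simulateObserver(truth, -1), "non-negative")

  vols <- sapply(1:3, function(s) {
    obs <- simulateObserver(truth, 2, seed = s)
    vapply(names(organLabels())[-1], function(o) organVolume(obs, o),
           numeric(1))
  })
  expect_true(all(apply(vols, 1, sd) > 0))
  # labels remain within the standard convention
  obs <- simulateObserver(truth, 2, seed = 1)
  expect_true(all(unique(as.vector(voxelData(obs))) %in% 0:4))
})

test_that("extreme boundary noise may erase an organ but volumes stay non-negative", {
  spec <- singleKidneySpec(semiaxes = c(4, 4, 4), grid = c(24L, 24L, 24L))
  truth <- generatePhantom(spec)@truth
  vols <- vapply(1:5, function(s)
    organVolume(simulateObserver(truth, 40, seed = s), "right_kidney"),
    numeric(1))
  expect_true(all(vols >= 0))
})
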