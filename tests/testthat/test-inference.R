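test_that("thresholding is strict at the cutoff", {
  d <- array(0, c(4, 4, 2))
  d[1, 1, 1] <- 0.5
  d[2, 1, 1] <- 0.51
  claims <- list(kidney = ProbabilityMap(d), spleen = ProbabilityMap(d * 0),
                 liver = ProbabilityMap(d * 0))
  masks <- thresholdClaims(claims)
  expect_false(masks$kidney[1, 1, 1])   # exactly 0.5 is negative
  expect_true(masks$kidney[2, 1, 1])
  expect_false(any(masks$spleen))
  expect_false(any(masks$liver))
})

test_that("priority adjudication matches a brute-force per-voxel oracle on all claim combinations", {
  # all 8 kidney/spleen/liver claim combinations appear in one small volume
  combos <- expand.grid(k = c(FALSE, TRUE), s = c(FALSE, TRUE),
                        l = c(FALSE, TRUE))
  d <- c(2L, 2L, 2L)
  masks <- list(kidney = array(combos$k, d), spleen = array(combos$s, d),
                liver = array(combos$l, d))
  adj <- adjudicatePriority(masks)

  oracle <- integer(8)
  priority <- c(kidney = 1L, spleen = 3L, liver = 4L)
  for (v in 1:8) {
    lab <- 0L
    for (org in c("kidney", "spleen", "liver")) {
      if (masks[[org]][v]) { lab <- priority[[org]]; break }
    }
    oracle[v] <- lab
  }
  expect_identical(as.vector(voxelData(adj)), oracle)

  # and on random volumes
  set.seed(6)
  for (rep in 1:5) {
    rm <- lapply(c(kidney = .4, spleen = .3, liver = .5), function(p)
      array(runif(4 * 4 * 3) < p, c(4, 4, 3)))
    got <- voxelData(adjudicatePriority(rm))
    want <- array(0L, c(4, 4, 3))
    for (v in seq_along(want)) {
      for (org in c("kidney", "spleen", "liver")) {
        if (rm[[org]][v]) { want[v] <- priority[[org]]; break }
      }
    }
    expect_identical(got, want)
    # voxel conservation: priority never discards a claimed voxel
    expect_identical(sum(got > 0), sum(rm$kidney | rm$spleen | rm$liver))
  }
})

test_that("kidney/liver overlaps default to kidney, spleen/liver to spleen", {
  d <- c(3L, 1L, 1L)
  masks <- list(kidney = array(c(TRUE, FALSE, FALSE), d),
                spleen = array(c(FALSE, TRUE, FALSE), d),
                liver = array(c(TRUE, TRUE, FALSE), d))
  adj <- voxelData(adjudicatePriority(masks))
  expect_identical(adj[1, 1, 1], 1L)  # kidney beats liver
  expect_identical(adj[2, 1, 1], 3L)  # spleen beats liver
  expect_identical(adj[3, 1, 1], 0L)  # unclaimed is background
})

test_that("adjudication is idempotent on its own output", {
  set.seed(11)
  masks <- lapply(c(kidney = .4, spleen = .3, liver = .5), function(p)
    array(runif(5 * 5 * 4) < p, c(5, 5, 4)))
  adj <- adjudicatePriority(masks)
  again <- adjudicatePriority(list(kidney = voxelData(adj) == 1L,
                                   spleen = voxelData(adj) == 3L,
                                   liver = voxelData(adj) == 4L))
  expect_identical(voxelData(again), voxelData(adj))
})

test_that("the legacy sum encoding reproduces the historical overlap codes", {
  d <- c(3L, 1L, 1L)
  rk <- array(c(TRUE, FALSE, FALSE), d)
  lv <- array(c(TRUE, TRUE, FALSE), d)
  enc <- encodeOverlapsSum(list(right_kidney = rk, liver = lv))
  expect_identical(voxelData(enc)[1, 1, 1], 5L)  # RK 1 + liver 4 = pink 5
  expect_identical(voxelData(enc)[2, 1, 1], 4L)
  expect_identical(voxelData(enc)[3, 1, 1], 0L)
  expect_identical(labelConvention(enc), "legacy-sum")

  # without overlaps the encoding is the standard one
  masks <- list(kidney = array(c(TRUE, FALSE, FALSE), d),
                spleen = array(c(FALSE, TRUE, FALSE), d),
                liver = array(FALSE, d))
  enc2 <- encodeOverlapsSum(masks)
  adj2 <- adjudicatePriority(masks)
  expect_identical(voxelData(enc2), voxelData(adj2))
})

test_that("the sum-code audit flags the 2+3 = 1+4 ambiguity", {
  lk <- array(c(TRUE, FALSE), c(2L, 1L, 1L))
  sp <- array(c(TRUE, FALSE), c(2L, 1L, 1L))
  enc <- encodeOverlapsSum(list(left_kidney = lk, spleen = sp))
  expect_identical(voxelData(enc)[1, 1, 1], 5L)  # collides with RK+liver pink

  audit <- sumOverlapAudit(list(right_kidney = array(TRUE, c(1, 1, 1)),
                                left_kidney = lk, spleen = sp,
                                liver = array(TRUE, c(1, 1, 1))))
  row5 <- audit[audit$code == 5, ]
  expect_true(row5$ambiguous)
  expect_match(row5$combinations, "right_kidney\\+liver")
  expect_match(row5$combinations, "left_kidney\\+spleen")
})

test_that("the midline split assigns sides and partitions the kidney class", {
  # phantom truth: merging then splitting recovers the original sides
  truth <- noiseFreePhantom()@truth
  merged <- voxelData(truth)
  merged[merged == 2L] <- 1L
  split <- splitKidneysMidline(LabelMap(merged, voxelSpacing(truth)))
  expect_identical(voxelData(split), voxelData(truth))

  # all-right kidney: no left label appears
  d <- array(0L, c(8, 4, 2))
  d[1:3, , ] <- 1L
  sp <- splitKidneysMidline(LabelMap(d))
  expect_identical(sum(voxelData(sp) == 2L), 0L)

  # a single voxel exactly on the midline plane of an odd grid stays right
  odd <- array(0L, c(5, 3, 1))
  odd[3, 2, 1] <- 1L
  expect_identical(voxelData(splitKidneysMidline(LabelMap(odd)))[3, 2, 1], 1L)

  # partition: |RK| + |LK| equals the provisional kidney count
  set.seed(3)
  rnd <- array(sample(c(0L, 1L, 3L, 4L), 6 * 6 * 4, TRUE), c(6, 6, 4))
  out <- voxelData(splitKidneysMidline(LabelMap(rnd)))
  expect_identical(sum(out %in% 1:2), sum(rnd == 1L))
  expect_identical(out[rnd == 3L], rnd[rnd == 3L])
  expect_identical(out[rnd == 4L], rnd[rnd == 4L])
})

test_that("organ inference returns native-grid probabilities deterministically", {
  ck <- untrainedCheckpoint("kidney")
  img <- VolumeImage(array(0, c(64, 64, 3)), spacing = c(6, 6, 9))
  p1 <- inferOrgan(img, ck)
  expect_s4_class(p1, "ProbabilityMap")
  expect_identical(dim(voxelData(p1)), c(64L, 64L, 3L))
  expect_true(all(voxelData(p1) >= 0 & voxelData(p1) <= 1))
  p2 <- inferOrgan(img, ck)
  expect_identical(voxelData(p1), voxelData(p2))

  # non-square native grids run through the crop-free resize path
  img2 <- VolumeImage(array(runif(48 * 40 * 2), c(48, 40, 2)),
                      spacing = c(8, 9, 9))
  pr <- inferOrgan(img2, ck)
  expect_identical(dim(voxelData(pr)), c(48L, 40L, 2L))
})

test_that("ensemble output is a standard single-label-per-voxel map", {
  cks <- list(kidney = untrainedCheckpoint("kidney", seed = 1),
              spleen = untrainedCheckpoint("spleen", seed = 2),
              liver = untrainedCheckpoint("liver", seed = 3))
  subj <- noiseFreePhantom()
  out <- runEnsemble(subj@image, cks)
  expect_s4_class(out, "LabelMap")
  expect_identical(labelConvention(out), "standard")
  expect_true(all(unique(as.vector(voxelData(out))) %in% 0:4))
  expect_identical(dim(voxelData(out)), dim(voxelData(subj@image)))
})
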