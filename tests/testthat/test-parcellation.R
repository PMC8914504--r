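test_that("parcellation handles empty masks and exact region support", {
  atlas <- fixtureAtlas()
  empty <- array(0L, c(16, 16, 9))
  row <- parcellateLesion(empty, atlas)
  expect_true(all(row == 0L))
  expect_equal(attr(row, "volume"), 0)

  support <- regionMask(atlas, 7) + 0L
  row <- parcellateLesion(support, atlas)
  expect_equal(unname(row[7]), sum(support))
  expect_true(all(row[setdiff(1:94, 7)] == 0L))
})

test_that("parcellation agrees with the voxel triple-loop oracle", {
  atlas <- fixtureAtlas()
  mask <- randomMask(c(16, 16, 9), 200L, seed = 31L)
  fast <- parcellateLesion(mask, atlas)
  expect_equal(unname(as.integer(fast)), oracleParcellate(mask, atlas))

  over <- fixtureOverlapAtlas()
  fastOver <- parcellateLesion(mask, over)
  expect_equal(unname(as.integer(fastOver)), oracleParcellate(mask, over))
})

test_that("overlapping cortical and tract labels are counted in both layers", {
  over <- fixtureOverlapAtlas()
  layers <- atlasLayers(over)
  both <- which(layers$cortical > 0 & layers$tract > 0)
  expect_gt(length(both), 0)
  mask <- array(0L, dim(layers$cortical))
  mask[both[1]] <- 1L
  row <- parcellateLesion(mask, over)
  expect_equal(sum(row), 2L) # one voxel, two layers
})

test_that("parcellation is additive over disjoint masks", {
  atlas <- fixtureAtlas()
  a <- randomMask(c(16, 16, 9), 150L, seed = 41L)
  b <- randomMask(c(16, 16, 9), 150L, seed = 42L)
  b[a == 1L] <- 0L
  un <- pmax(a, b)
  expect_equal(
    as.integer(parcellateLesion(un, atlas)),
    as.integer(parcellateLesion(a, atlas)) + as.integer(parcellateLesion(b, atlas))
  )
})

test_that("grid, affine and binarity violations are refused", {
  atlas <- fixtureAtlas()
  expect_error(parcellateLesion(array(0L, c(8, 8, 4)), atlas), "does not match")
  bad <- array(0L, c(16, 16, 9))
  bad[1] <- 2L
  expect_error(parcellateLesion(bad, atlas), "not binary")
  img <- RNifti::asNifti(array(0, c(16, 16, 9)))
  shifted <- diag(4)
  shifted[1, 4] <- 5
  RNifti::qform(img) <- structure(shifted, code = 2L)
  expect_error(parcellateLesion(img, atlas), "affine")
})

test_that("matrix assembly is order-invariant and rejects duplicate ids", {
  atlas <- fixtureAtlas()
  rows <- lapply(c(a = 51, b = 52, c = 53), function(s) {
    parcellateLesion(randomMask(c(16, 16, 9), 80L, seed = s), atlas)
  })
  m1 <- assembleLesionMatrix(rows, atlas)
  m2 <- assembleLesionMatrix(rev(rows), atlas)
  expect_identical(lesionCounts(m1), lesionCounts(m2))
  expect_identical(patientIds(m1), c("a", "b", "c"))
  expect_error(assembleLesionMatrix(rows[c(1, 1)], atlas), "duplicate")

  emptyM <- assembleLesionMatrix(list(), atlas)
  expect_equal(dim(lesionCounts(emptyM)), c(0L, 129L))

  # row sums match per-mask voxel counts (disjoint layers: each voxel once)
  expect_equal(unname(rowSums(lesionCounts(m1))), rep(80, 3))
})

test_that("atlas label permutation permutes parcellation columns identically", {
  atlas <- fixtureAtlas()
  mask <- randomMask(c(16, 16, 9), 120L, seed = 61L)
  base <- as.integer(parcellateLesion(mask, atlas))

  perm <- StrokeSexPatterns:::withSeed(7L, sample(94L))
  layers <- atlasLayers(atlas)
  ctx <- layers$cortical
  ctx[ctx > 0] <- perm[ctx[ctx > 0]]
  atlas2 <- new("AtlasSpec",
    layers = list(cortical = ctx, subcortical = layers$subcortical, tract = layers$tract),
    regions = atlasRegions(atlas), voxelVolume = 1, affine = diag(4) # nolint
  )
  atlas2@affine <- atlas@affine
  permuted <- as.integer(parcellateLesion(mask, atlas2))
  # region r of the old atlas is region perm[r] of the new one
  for (r in 1:94) expect_equal(permuted[perm[r]], base[r])
  expect_equal(permuted[95:129], base[95:129])
})

test_that("probabilistic atlas layers discretize by max probability with a floor", {
  prob <- array(0, c(2, 2, 1, 3))
  prob[1, 1, 1, ] <- c(0.6, 0.3, 0.1) # clear winner
  prob[2, 1, 1, ] <- c(0.2, 0.24, 0.1) # below the 25% floor
  prob[1, 2, 1, ] <- c(0.3, 0.5, 0.2) # winner is region 2
  prob[2, 2, 1, ] <- c(0.25, 0.25, 0.5)
  lab <- discretizeProbAtlas(prob)
  expect_equal(as.vector(lab), c(1L, 0L, 2L, 3L))
  # percent-scaled input gives the same labels
  expect_equal(discretizeProbAtlas(prob * 100), lab)
})

test_that("lesion matrices survive a CSV round trip", {
  sim <- fixtureNullCohort()
  path <- tempfile(fileext = ".csv")
  writeLesionMatrix(sim$lesions, path)
  back <- readLesionMatrix(path)
  expect_identical(lesionCounts(back), lesionCounts(sim$lesions))
  expect_equal(unname(lesionVolume(back)), unname(lesionVolume(sim$lesions)))
})

test_that("sex comparison of lesion anatomy is null-calibrated under permutation", {
  sim <- fixtureNullCohort()
  n <- nrow(lesionCounts(sim$lesions))
  rejections <- 0L
  for (s in 1:3) {
    sex <- StrokeSexPatterns:::withSeed(s, sample(rep(c("male", "female"), length.out = n)))
    res <- compareLesionAnatomy(sim$lesions, sex)
    rejections <- rejections +
      sum(res$regions$p_t_bonf < 0.05, na.rm = TRUE) +
      sum(res$regions$p_fisher_bonf < 0.05, na.rm = TRUE)
  }
  expect_equal(rejections, 0L)
})

test_that("the Fisher test on a fully sex-separated region matches enumeration", {
  counts <- matrix(0L, 40, 129,
    dimnames = list(sprintf("p%02d", 1:40), defaultColnames())
  )
  sex <- rep(c("female", "male"), each = 20)
  counts[sex == "female", 5] <- 3L # affected in all women, no men
  rl <- new("RegionLesionMatrix",
    counts = counts, volume = rowSums(counts) / 1000,
    voxelVolume = 1
  )
  res <- compareLesionAnatomy(rl, sex)
  # two-sided hypergeometric enumeration: sum over all tables with fixed
  # margins whose probability does not exceed the observed one
  probs <- sapply(0:20, function(k) {
    choose(20, k) * choose(20, 20 - k) / choose(40, 20)
  })
  pObs <- probs[21] # all 20 affected patients are women
  pEnum <- sum(probs[probs <= pObs + 1e-15])
  expect_equal(res$regions$p_fisher[5], pEnum, tolerance = 1e-12)
})

test_that("identical groups give t = 0 and p = 1", {
  counts <- matrix(2L, 8, 129, dimnames = list(sprintf("p%d", 1:8), defaultColnames()))
  rl <- new("RegionLesionMatrix",
    counts = counts, volume = rowSums(counts) / 1000,
    voxelVolume = 1
  )
  res <- compareLesionAnatomy(rl, rep(c("male", "female"), 4))
  expect_true(all(res$regions$t == 0))
  expect_true(all(res$regions$p_t == 1))
  expect_error(compareLesionAnatomy(rl, rep("male", 8)), "each sex")
})
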