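test_that("variant sampling covers the affiliated set with the expected inclusion rate", {
  one <- sampleVariants(c(42L), nVariants = 20L, seed = 1L)
  expect_true(all(vapply(one, identical, TRUE, 42L)))

  aff <- c(3L, 8L, 15L, 22L, 31L)
  many <- sampleVariants(aff, nVariants = 10000L, seed = 2L)
  # inclusion probability per region: (1/5) sum_m m/5 = 0.6
  incl <- rowMeans(sapply(many, function(v) aff %in% v))
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_true(all(abs(incl - 0.6) < 3 * se))

  expect_identical(sampleVariants(aff, 50L, seed = 9L), sampleVariants(aff, 50L, seed = 9L))
  expect_error(sampleVariants(integer(0)), "empty")
})

test_that("a connectome equal to the seed plus tiny noise gives a uniformly positive t map", {
  dims <- c(5L, 4L, 3L)
  seedMask <- array(FALSE, dims)
  seedMask[1:2, 1, 1] <- TRUE
  base <- StrokeSexPatterns:::withSeed(3L, rnorm(30))
  subjects <- lapply(1:4, function(s) {
    x <- StrokeSexPatterns:::withSeed(
      s + 10L,
      rep(base, each = prod(dims)) + rnorm(prod(dims) * 30, sd = 1e-3)
    )
    array(x, c(dims, 30))
  })
  tmap <- lesionConnectivity(seedMask, subjects, gsr = FALSE)
  expect_true(all(tmap > 0))
  expect_equal(attr(tmap, "nSubjects"), 4L)
})

test_that("constant voxels follow the r = 0 convention and stay finite", {
  dims <- c(4L, 3L, 2L)
  subjects <- lapply(1:3, function(s) {
    a <- array(StrokeSexPatterns:::withSeed(s, rnorm(prod(dims) * 20)), c(dims, 20))
    a[1, 1, 1, ] <- 7 # constant time series
    a
  })
  seedMask <- array(FALSE, dims)
  seedMask[4, 3, 2] <- TRUE
  tmap <- lesionConnectivity(seedMask, subjects, gsr = FALSE)
  expect_equal(tmap[1, 1, 1], 0)
  expect_true(all(is.finite(tmap)))

  flat <- lapply(1:3, function(s) array(5, c(dims, 20)))
  expect_error(
    lesionConnectivity(seedMask, flat, gsr = FALSE, label = "variant 9"),
    "zero-variance seed.*variant 9"
  )
})

test_that("the connectivity t map matches a per-voxel brute-force oracle", {
  dims <- c(6L, 1L, 1L)
  nt <- 20L
  subjects <- lapply(1:4, function(s) {
    array(StrokeSexPatterns:::withSeed(s + 50L, rnorm(6 * nt)), c(dims, nt))
  })
  seedMask <- array(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), dims)

  # oracle: explicit regression, correlation, atanh and t per voxel
  zmaps <- sapply(1:4, function(s) {
    V <- matrix(subjects[[s]], 6, nt)
    gs <- colMeans(V)
    Vr <- t(apply(V, 1, function(v) residuals(lm(v ~ gs))))
    seed <- colMeans(Vr[1:2, ])
    sapply(1:6, function(vox) {
      r <- cor(Vr[vox, ], seed)
      atanh(min(max(r, -0.999999), 0.999999))
    })
  })
  oracle <- apply(zmaps, 1, function(z) mean(z) / (sd(z) / sqrt(4)))
  tmap <- lesionConnectivity(seedMask, subjects, gsr = TRUE)
  expect_equal(as.vector(tmap), oracle, tolerance = 1e-8)

  # permutation of subjects leaves the map unchanged
  tmap2 <- lesionConnectivity(seedMask, subjects[c(3, 1, 4, 2)], gsr = TRUE)
  expect_equal(as.vector(tmap2), as.vector(tmap), tolerance = 1e-12)
})

test_that("network intensities are signed sums matching a voxel-loop oracle", {
  dims <- c(14L, 4L, 4L)
  networks <- networkLabelImage(dims)
  zero <- array(0, dims)
  ni <- networkIntensity(zero, networks)
  expect_true(all(ni$positive == 0) && all(ni$negative == 0))

  t3 <- array(0, dims)
  t3[networks == 3L] <- 1
  ni3 <- networkIntensity(t3, networks)
  expect_equal(ni3$positive[3], sum(networks == 3L))
  expect_true(all(ni3$positive[-3] == 0))

  rnd <- array(StrokeSexPatterns:::withSeed(4L, rnorm(prod(dims))), dims)
  ni <- networkIntensity(rnd, networks)
  for (nw in 1:14) {
    vals <- rnd[networks == nw]
    expect_equal(ni$positive[nw], sum(vals[vals > 0]))
    expect_equal(ni$negative[nw], sum(vals[vals < 0]))
  }
  expect_true(all(ni$positive >= 0) && all(ni$negative <= 0))

  badNet <- networks
  badNet[badNet == 5L] <- 4L
  expect_error(networkIntensity(rnd, badNet), "zero voxels")
})

test_that("the sex contrast flags planted shifts and matches hand step-up BH", {
  grid <- expand.grid(variant = 1:100, sex = c("male", "female"), network = 1:14)
  grid$pattern <- 1L
  noise <- StrokeSexPatterns:::withSeed(6L, rnorm(nrow(grid)))
  grid$positive <- abs(noise)
  grid$negative <- -abs(noise)
  # plant a +10 shift in network 4 of the female maps
  sel <- grid$sex == "female" & grid$network == 4L
  grid$positive[sel] <- grid$positive[sel] + 10
  res <- sexContrast(grid)
  expect_true(res$significant[res$network == 4 & res$sign == "positive"])
  expect_lt(mean(res$significant[!(res$network == 4 & res$sign == "positive")]), 0.1)

  # identical groups (same value per variant x network in both sexes): no flags
  grid$positive <- abs(noise[grid$variant + 100L * (grid$network - 1L)])
  grid$negative <- 0
  resNull <- sexContrast(grid)
  expect_true(all(resNull$p[resNull$sign == "positive"] == 1))
  expect_false(any(resNull$significant))

  # BH adjusted values equal the hand step-up formula
  p <- c(0.001, seq(0.01, 0.14, by = 0.01))
  m <- length(p)
  stepup <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(p.adjust(p, "BH"), pmin(1, stepup))
})

test_that("the batched LNM path equals the single-variant reference operation", {
  atlas <- simulateAtlas(c(14L, 14L, 8L))
  cfg <- connectomeConfig(
    nSubjectsPerSex = 3L, dims = c(14L, 14L, 8L),
    nTimepoints = 12L, seed = 7L
  )
  conn <- simulateConnectomes(cfg)
  aff <- list(c(5L, 9L, 20L, 100L, 111L))
  res <- lnmAnalysis(aff, atlas, conn, conn$networks, nVariants = 6L, seed = 11L)
  variants <- sampleVariants(aff[[1]], 6L, StrokeSexPatterns:::deriveSeeds(11L, 1L))
  for (v in c(1L, 4L)) {
    tmap <- lesionConnectivity(regionMask(atlas, variants[[v]]), conn$male)
    ni <- networkIntensity(tmap, conn$networks)
    got <- res$intensities[
      res$intensities$variant == v & res$intensities$sex == "male",
    ]
    expect_equal(got$positive, ni$positive, tolerance = 1e-8)
    expect_equal(got$negative, ni$negative, tolerance = 1e-8)
  }
})

test_that("the smallest admissible connectome runs through the LNM stage", {
  atlas <- simulateAtlas(c(14L, 14L, 8L))
  cfg <- connectomeConfig(
    nSubjectsPerSex = 2L, dims = c(14L, 14L, 8L),
    nTimepoints = 10L, seed = 2L
  )
  conn <- simulateConnectomes(cfg)
  res <- lnmAnalysis(list(c(1L, 2L), c(60L, 70L)), atlas, conn, conn$networks,
    nVariants = 4L, seed = 3L
  )
  expect_equal(nrow(res$contrasts), 2 * 2 * 14)
  expect_true(all(is.finite(res$intensities$positive)))
})
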