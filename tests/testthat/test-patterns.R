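test_that("an exact low-rank non-negative product is recovered", {
  k <- 10L
  H0 <- territoryBasis(k, 129L)
  W0 <- StrokeSexPatterns:::withSeed(3L, matrix(rgamma(200 * k, 0.3, rate = 0.1), 200, k))
  X <- W0 %*% H0
  rownames(X) <- sprintf("p%03d", seq_len(nrow(X)))
  fit <- fitNMF(X, k = k, seed = 5L)
  relErr <- sqrt(sum((X - patternExpression(fit) %*% patternBasis(fit))^2)) /
    sqrt(sum(X^2))
  expect_lt(relErr, 1e-3)
  m <- matchPatterns(patternBasis(fit), H0)
  expect_equal(nrow(m), k)
  expect_true(all(m$cosine > 0.95))
})

test_that("a rank-one matrix yields a basis proportional to the generating vector", {
  v <- c(rep(0, 50), seq(0.1, 1, length.out = 79))
  X <- outer(seq(0.5, 5, length.out = 30), v)
  rownames(X) <- sprintf("p%02d", 1:30)
  fit <- fitNMF(X, k = 1L, seed = 2L)
  cosine <- sum(patternBasis(fit) * v) /
    sqrt(sum(patternBasis(fit)^2) * sum(v^2))
  expect_gt(cosine, 0.999)
})

test_that("the factorization is deterministic given the seed and validates inputs", {
  sim <- fixtureNullCohort()
  a <- fitNMF(sim$lesions, k = 6L, seed = 9L, maxIter = 200L)
  b <- fitNMF(sim$lesions, k = 6L, seed = 9L, maxIter = 200L)
  expect_identical(patternBasis(a), patternBasis(b))
  expect_identical(patternExpression(a), patternExpression(b))
  X <- matrix(c(-1, 2, 3, 4), 2)
  expect_error(fitNMF(X, k = 1), "non-negative")
  expect_error(fitNMF(matrix(1, 5, 129), k = 6), "rank bound")
})

test_that("the multiplicative-update objective never increases", {
  sim <- fixtureNullCohort()
  fit <- fitNMF(sim$lesions, k = 8L, seed = 4L)
  expect_true(all(diff(fit@objective) <= 1e-8 * (1 + fit@objective[-length(fit@objective)])))
  expect_true(all(apply(patternBasis(fit), 1, max) == 1))
})

test_that("fitting is scale-invariant up to pattern matching", {
  sim <- fixtureNullCohort()
  X <- lesionCounts(sim$lesions)[1:120, ]
  f1 <- fitNMF(X, k = 5L, seed = 7L)
  f2 <- fitNMF(X * 4.5, k = 5L, seed = 7L)
  m <- matchPatterns(patternBasis(f2), patternBasis(f1))
  expect_true(all(m$cosine > 0.99))
})

test_that("scoring against a fixed basis inverts known expressions", {
  H0 <- territoryBasis(10L, 129L)
  fit <- structure(
    new("LesionPatternFit",
      basis = H0, expression = matrix(0, 0, 10), scales = rep(1, 10),
      objective = 1, iterations = 1L, converged = TRUE, seed = 1L
    )
  )
  X <- rbind(5 * H0[4, ], rep(0, 129))
  W <- nmfTransform(X, fit)
  expect_equal(W[1, 4], 5, tolerance = 1e-8)
  expect_true(all(abs(W[1, -4]) < 1e-6))
  expect_true(all(W[2, ] == 0))
  expect_error(nmfTransform(matrix(1, 2, 5), fit), "columns")
})

test_that("the NNLS projection matches a projected-gradient oracle", {
  H0 <- territoryBasis(6L, 40L)
  x <- StrokeSexPatterns:::withSeed(8L, rgamma(40, 1, rate = 0.5))
  w <- nmfTransform(matrix(x, 1), H0)[1, ]
  objective <- function(w) sum((x - as.vector(w %*% H0))^2)
  # independent oracle: projected gradient descent with small steps
  wo <- rep(0, 6)
  G <- H0 %*% t(H0)
  step <- 1 / (2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values))
  for (i in 1:20000) {
    grad <- 2 * (as.vector(G %*% wo) - as.vector(H0 %*% x))
    wo <- pmax(0, wo - step * grad)
  }
  expect_lt(abs(objective(w) - objective(wo)), 1e-4)
  expect_true(all(w >= 0))
})

test_that("pattern affiliation thresholds normalized loadings", {
  basis <- rbind(
    c(1.0, 0.04, 0.5, rep(0, 126)),
    c(rep(0, 3), 1, rep(0.2, 4), rep(0, 121))
  )
  fit <- new("LesionPatternFit",
    basis = basis, expression = matrix(0, 0, 2), scales = c(1, 1),
    objective = 1, iterations = 1L, converged = TRUE, seed = 1L
  )
  expect_equal(unname(affiliatedRegions(fit, 1)), c(1L, 3L)) # descending order
  expect_equal(unname(affiliatedRegions(fit, 1, threshold = 0)[1:3]), c(1L, 3L, 2L))
  expect_length(affiliatedRegions(fit, 2, threshold = 0), 5L)
  expect_error(affiliatedRegions(fit, 1, threshold = 2), "lower the threshold")
  expect_error(affiliatedRegions(fit, 3), "pattern must be")
})

test_that("patterns fit on territory-structured data recover their territories", {
  cfg <- cohortConfig(nPatients = 400L, seed = 77L)
  sim <- simulateCohort(cfg)
  fit <- fitNMF(sim$lesions, k = 10L, seed = 1L)
  m <- matchPatterns(patternBasis(fit), cfg$trueBasis)
  # perfect matching with high cosines on well-separated territories
  expect_equal(sort(m$reference), 1:10)
  expect_true(all(m$cosine > 0.9))
  # affiliated regions coincide with the generating territory's support
  for (row in seq_len(10)) {
    j <- m$fitted[row]
    territory <- which(cfg$trueBasis[m$reference[row], ] > 0.05)
    expect_setequal(unname(affiliatedRegions(fit, j)), territory)
  }
})

test_that("pattern hemispheres are read off the loading mass", {
  atlas <- fixtureAtlas()
  regions <- atlasRegions(atlas)
  basis <- matrix(1e-6, 3, 129)
  basis[1, which(regions$hemisphere == "L")[1:5]] <- 1
  basis[2, which(regions$hemisphere == "R")[1:5]] <- 1
  basis[3, c(which(regions$hemisphere == "L")[1:3], which(regions$hemisphere == "R")[1:3])] <- 1
  fit <- new("LesionPatternFit",
    basis = basis, expression = matrix(0, 0, 3), scales = rep(1, 3),
    objective = 1, iterations = 1L, converged = TRUE, seed = 1L
  )
  expect_equal(patternHemisphere(fit, regions), c("L", "R", "B"))
})
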