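makeCohort <- function(n = 60L, seed = 1L) {
  simulateCohort(cohortConfig(nPatients = n, seed = seed))
}

test_that("the design derives the outcome from mRS > 2 and standardizes columns", {
  sim <- makeCohort(200L, seed = 5L)
  sim$cohort$mRS <- rep(0:6, length.out = 200)
  design <- buildDesign(sim$cohort, sim$expression, lesionVolume(sim$lesions))
  expect_identical(design@outcome, as.integer(sim$cohort$mRS > 2))
  expect_false(any(design@outcome[sim$cohort$mRS == 2]) == 1L)
  Z <- cbind(design@patterns, design@covariates[, c("age", "age2", "volume")])
  expect_true(all(abs(colMeans(Z)) < 1e-8))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-8))
})

test_that("degenerate covariates and misaligned inputs are refused", {
  sim <- makeCohort(50L)
  cohort <- sim$cohort
  cohort$age <- 60
  expect_error(
    buildDesign(cohort, sim$expression, lesionVolume(sim$lesions)),
    "'age' has zero variance"
  )
  cohort2 <- sim$cohort
  cohort2$sex[1] <- "other"
  expect_error(
    buildDesign(cohort2, sim$expression, lesionVolume(sim$lesions)),
    "binary coding"
  )
  cohort3 <- sim$cohort
  cohort3$mRS[1] <- 9L
  expect_error(
    buildDesign(cohort3, sim$expression, lesionVolume(sim$lesions)),
    "0..6"
  )
})

test_that("incomplete rows are dropped with a message", {
  sim <- makeCohort(80L, seed = 6L)
  cohort <- sim$cohort
  cohort$age[c(3, 9)] <- NA
  expect_message(
    design <- buildDesign(cohort, sim$expression, lesionVolume(sim$lesions)),
    "2 row"
  )
  expect_equal(nrow(design@patterns), 78L)
  expect_equal(design@dropped, 2L)
})

test_that("standardization parameters transfer between cohorts and invert exactly", {
  a <- makeCohort(150L, seed = 7L)
  b <- makeCohort(150L, seed = 8L)
  dA <- buildDesign(a$cohort, a$expression, lesionVolume(a$lesions))
  zB <- applyScaling(dA, "age", b$cohort$age)
  expect_equal(invertScaling(dA, "age", zB), b$cohort$age, tolerance = 1e-10)
  expect_error(applyScaling(dA, "nope", 1), "no scaling")
})

test_that("the HPD interval is the shortest mass window with lower-tie preference", {
  expect_equal(unname(hpdi(rep(3.5, 20))[1:2]), c(3.5, 3.5))
  expect_equal(unname(hpdi(1:10, mass = 0.5)[1:2]), c(1, 5))

  z <- StrokeSexPatterns:::withSeed(9L, rnorm(1e5))
  h <- hpdi(z, 0.90)
  expect_lt(abs(h[["lower"]] + 1.645), 0.03)
  expect_lt(abs(h[["upper"]] - 1.645), 0.03)

  # exhaustive window-search oracle on irregular samples
  for (s in 1:5) {
    x <- StrokeSexPatterns:::withSeed(s, rgamma(83, 0.7))
    m <- ceiling(0.9 * length(x))
    xs <- sort(x)
    widths <- sapply(seq_len(length(x) - m + 1), function(i) xs[i + m - 1] - xs[i])
    i <- which.min(widths)
    expect_equal(unname(hpdi(x)[1:2]), c(xs[i], xs[i + m - 1]))
  }
  expect_error(hpdi(1:5), "at least 10")
  expect_error(hpdi(c(1:10, NA)), "finite")
})

test_that("the substantial-effect rule is HPDI-excludes-zero", {
  expect_true(substantialEffect(runif(100, 0.1, 0.9)))
  expect_false(substantialEffect(StrokeSexPatterns:::withSeed(2L, rnorm(1000))))
  expect_true(substantialEffect(runif(100, -0.9, -0.1)))
})

test_that("the Mann-Whitney AUC matches all-pairs counting with half ties", {
  y <- c(1, 1, 0, 0, 1, 0)
  s <- c(0.9, 0.7, 0.7, 0.2, 0.4, 0.4)
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1, ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  expect_equal(aucMannWhitney(s, y), oracle)
  expect_equal(aucMannWhitney(y, y), 1)
  expect_equal(aucMannWhitney(rep(0.3, 6), y), 0.5)
  # invariance under strictly monotone transforms
  expect_equal(aucMannWhitney(qlogis(pmin(pmax(s, 0.01), 0.99)), y), oracle)
})

test_that("baseline comparisons use Welch t and Fisher tests as appropriate", {
  sim <- makeCohort(200L, seed = 10L)
  tab <- compareBaseline(sim$cohort, volume = lesionVolume(sim$lesions))
  expect_true(all(c("age", "volume_ml", "unfavourable", "smoking") %in% tab$variable))
  expect_equal(tab$test[tab$variable == "age"], "t")
  expect_equal(tab$test[tab$variable == "smoking"], "fisher")

  # Fisher p equals direct hypergeometric enumeration for a 3,7 / 7,3 table
  cohort <- data.frame(
    patient_id = sprintf("p%02d", 1:20),
    age = rnorm(20, 65), sex = rep(c("male", "female"), each = 10),
    hypertension = c(rep(1, 3), rep(0, 7), rep(1, 7), rep(0, 3)),
    afib = 0L, diabetes = 0L, chd = 0L, prior_stroke = 0L, smoking = 0L,
    mRS = rep(2:3, 10)
  )
  res <- compareBaseline(cohort)
  # enumerate all 2x2 tables with margins (10, 10) x (10, 10)
  pTable <- function(a) choose(10, a) * choose(10, 10 - a) / choose(20, 10)
  probs <- sapply(0:10, pTable)
  pObs <- pTable(3)
  pEnum <- sum(probs[probs <= pObs + 1e-12])
  expect_equal(res$p[res$variable == "hypertension"], pEnum, tolerance = 1e-12)

  # identical groups: p = 1; zero-variance continuous flagged with p = 1
  cohort$hypertension <- rep(c(1, 0), 10)
  cohort$age <- 65
  res2 <- compareBaseline(cohort)
  expect_equal(res2$p[res2$variable == "hypertension"], 1)
  expect_equal(res2$p[res2$variable == "age"], 1)
  expect_true(res2$degenerate[res2$variable == "age"])
})

test_that("the sampler is reproducible and guards its preconditions", {
  sim <- makeCohort(250L, seed = 20L)
  design <- buildDesign(sim$cohort, sim$expression, lesionVolume(sim$lesions))
  a <- fitOutcomeModel(design,
    draws = 150L, chains = 2L, warmup = 150L, seed = 3L,
    rhatAction = "warn"
  )
  b <- fitOutcomeModel(design,
    draws = 150L, chains = 2L, warmup = 150L, seed = 3L,
    rhatAction = "warn"
  )
  expect_identical(posteriorDraws(a), posteriorDraws(b))
  expect_true(all(parameterSamples(a, "tau_1") > 0))
  expect_equal(dim(posteriorDraws(a)), c(150L, 2L, 51L))

  maleOnly <- sim$cohort
  maleOnly$sex <- "male"
  dm <- buildDesign(maleOnly, sim$expression, lesionVolume(sim$lesions))
  expect_error(fitOutcomeModel(dm, draws = 10, chains = 1, warmup = 10), "both sexes")
  oneClass <- sim$cohort
  oneClass$mRS <- 1L
  d1 <- buildDesign(oneClass, sim$expression, lesionVolume(sim$lesions))
  expect_error(fitOutcomeModel(d1, draws = 10, chains = 1, warmup = 10), "outcome classes")
})

test_that("tightening the between-sex scale prior pools the sex coefficients", {
  sim <- simulateCohort(cohortConfig(
    nPatients = 500L, seed = 30L,
    coefFemale = c(0.8, rep(0, 9)), coefMale = rep(0, 10)
  ))
  design <- buildDesign(sim$cohort, sim$expression, lesionVolume(sim$lesions))
  pooled <- fitOutcomeModel(design,
    draws = 300L, chains = 2L, warmup = 300L, seed = 4L,
    priorScales = list(tau = 0.01), rhatAction = "warn"
  )
  for (j in 1:10) {
    gap <- abs(
      mean(parameterSamples(pooled, sprintf("b_male_%d", j))) -
        mean(parameterSamples(pooled, sprintf("b_female_%d", j)))
    )
    expect_lt(gap, 0.05)
  }
})

test_that("sex differences use the men-minus-women convention", {
  vals <- setNames(numeric(51), c(
    "alpha", paste0("g_", c(
      "age", "age2", "sex", "hypertension", "afib",
      "diabetes", "chd", "prior_stroke", "smoking", "volume"
    )),
    sprintf("mu_%d", 1:10), sprintf("tau_%d", 1:10),
    sprintf("b_male_%d", 1:10), sprintf("b_female_%d", 1:10)
  ))
  vals["tau_1"] <- vals["tau_2"] <- 0.5
  vals[sprintf("tau_%d", 3:10)] <- 0.5
  vals["b_male_2"] <- 0.4
  vals["b_female_2"] <- 0.1
  post <- constantPosterior(vals)
  d <- sexDifference(post, 2)
  expect_equal(d$mean, 0.3)
  expect_true(d$substantial)
  dNull <- sexDifference(post, 1)
  expect_equal(dNull$mean, 0)
  expect_false(dNull$substantial)
})

test_that("posterior-predictive AUC separates informative from null fits", {
  sim <- simulateCohort(cohortConfig(
    nPatients = 600L, seed = 31L,
    coefFemale = rep(0.8, 10), coefMale = rep(0.8, 10),
    covariateEffects = c(age = 0.8, volume = 0.8)
  ))
  design <- buildDesign(sim$cohort, sim$expression, lesionVolume(sim$lesions))
  fit <- fitOutcomeModel(design,
    draws = 250L, chains = 2L, warmup = 250L, seed = 5L,
    rhatAction = "warn"
  )
  auc <- posteriorPredictiveAUC(fit, design)
  expect_gt(auc, 0.7)
  expect_lte(auc, 1)
  # per-draw averaging is close to the posterior-mean-score variant
  expect_lt(abs(posteriorPredictiveAUC(fit, design, perDraw = TRUE) - auc), 0.05)
})
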