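#' Build the standardized design for the outcome model
#'
#' Joins the cohort table with the pattern expressions by patient id, derives
#' the binary unfavourable-outcome label (mRS > 2), z-scores the pattern
#' expressions and the continuous covariates (age; age-squared computed from
#' centred age before scaling; lesion volume) and drops incomplete rows with
#' a message. Standardization parameters are stored so the same scaling can
#' be applied to another cohort ([applyScaling()]) or inverted
#' ([invertScaling()]).
#'
#' @param cohort data.frame with columns `patient_id`, `age`, `sex`
#'   (`"male"`/`"female"`), `hypertension`, `afib`, `diabetes`, `chd`,
#'   `prior_stroke`, `smoking`, `mRS`.
#' @param expression patients x k non-negative pattern expression matrix with
#'   patient ids as rownames.
#' @param volume per-patient lesion volume in ml (named or aligned with
#'   `cohort`); taken from `attr(expression, "volume")` if missing.
#' @return an [OutcomeDesign].
#' @export
buildDesign <- function(cohort, expression, volume) {
  stopifnot(is.data.frame(cohort), !is.null(rownames(expression)))
  need <- c(
    "patient_id", "age", "sex", "hypertension", "afib", "diabetes",
    "chd", "prior_stroke", "smoking", "mRS"
  )
  missingCols <- setdiff(need, colnames(cohort))
  if (length(missingCols)) {
    stop("cohort is missing column(s): ", paste(missingCols, collapse = ", "))
  }
  ids <- as.character(cohort$patient_id)
  if (!all(ids %in% rownames(expression))) {
    stop("cohort and expression matrix are not aligned by patient id")
  }
  W <- expression[ids, , drop = FALSE]
  if (!is.null(names(volume))) volume <- volume[ids]
  if (length(volume) != nrow(cohort)) {
    stop("volume must align with the cohort")
  }
  if (any(!cohort$mRS %in% 0:6)) stop("mRS values must be in 0..6")
  female <- normalizeSexVector(cohort$sex, nrow(cohort))

  raw <- data.frame(
    cohort[need], volume = as.numeric(volume), female = female, W,
    check.names = FALSE
  )
  keep <- complete.cases(raw)
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped as incomplete (complete-case analysis)")
  }
  raw <- raw[keep, , drop = FALSE]
  W <- W[keep, , drop = FALSE]
  female <- female[keep]

  zscore <- function(x, what) {
    s <- sd(x)
    if (s < 1e-12) {
      stop("covariate '", what, "' has zero variance on the fitting cohort")
    }
    list(z = (x - mean(x)) / s, center = mean(x), scale = s)
  }

  ageC <- raw$age - mean(raw$age)
  cols <- list(
    age = zscore(raw$age, "age"),
    age2 = zscore(ageC^2, "age2"),
    volume = zscore(raw$volume, "volume")
  )
  patz <- vector("list", ncol(W))
  for (j in seq_len(ncol(W))) {
    patz[[j]] <- zscore(W[, j], colnames(W)[j])
  }
  patterns <- do.call(cbind, lapply(patz, `[[`, "z"))
  dimnames(patterns) <- list(raw$patient_id, colnames(W))

  covariates <- cbind(
    age = cols$age$z, age2 = cols$age2$z, sex = female,
    hypertension = raw$hypertension, afib = raw$afib, diabetes = raw$diabetes,
    chd = raw$chd, prior_stroke = raw$prior_stroke, smoking = raw$smoking,
    volume = cols$volume$z
  )[, COVARIATE_NAMES]
  rownames(covariates) <- raw$patient_id

  scaling <- data.frame(
    column = c(names(cols), colnames(W)),
    center = c(vapply(cols, `[[`, 0, "center"), vapply(patz, `[[`, 0, "center")),
    scale = c(vapply(cols, `[[`, 0, "scale"), vapply(patz, `[[`, 0, "scale")),
    stringsAsFactors = FALSE
  )
  attr(scaling, "ageCenter") <- mean(raw$age)

  new("OutcomeDesign",
    patterns = patterns, covariates = covariates,
    outcome = as.integer(raw$mRS > 2), female = as.integer(female),
    scaling = scaling, dropped = sum(!keep)
  )
}

#' Apply or invert stored standardization parameters
#'
#' `applyScaling` standardizes raw values of a column with another design's
#' stored center/scale; `invertScaling` maps standardized values back to the
#' raw scale (exact inverse pair).
#'
#' @param design an [OutcomeDesign].
#' @param column a column name present in the design's scaling table.
#' @param x numeric values.
#' @return numeric vector.
#' @export
applyScaling <- function(design, column, x) {
  s <- scalingRow(design, column)
  (x - s$center) / s$scale
}

#' @rdname applyScaling
#' @export
invertScaling <- function(design, column, x) {
  s <- scalingRow(design, column)
  x * s$scale + s$center
}

scalingRow <- function(design, column) {
  stopifnot(is(design, "OutcomeDesign"))
  i <- match(column, design@scaling$column)
  if (is.na(i)) stop("no scaling stored for column '", column, "'")
  design@scaling[i, ]
}

#' Fit the Bayesian hierarchical logistic outcome model
#'
#' Samples the posterior of the sex-hierarchical logistic regression with the
#' package's built-in No-U-Turn Sampler: each lesion pattern j has a
#' hypermean `mu_j ~ Normal(0, 1)`, a between-sex scale
#' `tau_j ~ HalfNormal(1)` and sex-specific coefficients
#' `b_{j,s} ~ Normal(mu_j, tau_j)`; the intercept has a `Normal(0, 2.5)`
#' prior and covariate coefficients `Normal(0, 1)` (all scales
#' configurable via `priorScales`). Chains run sequentially with seeds
#' derived from `seed`; the fit errors if any parameter's split-Rhat exceeds
#' 1.05 (set `rhatAction = "warn"` to downgrade) and warns if more than 5%
#' of post-warmup transitions diverge.
#'
#' @param design an [OutcomeDesign].
#' @param draws post-warmup draws per chain (default 5000).
#' @param chains number of chains (default 4).
#' @param warmup warmup iterations per chain (default 1000), excluded from
#'   the draws.
#' @param seed integer master seed.
#' @param targetAccept NUTS target acceptance statistic (default 0.9).
#' @param priorScales named list overriding `alpha`, `gamma`, `mu`, `tau`.
#' @param rhatAction `"error"` (default) or `"warn"` on split-Rhat > 1.05.
#' @return an [OutcomePosterior].
#' @export
fitOutcomeModel <- function(design, draws = 5000L, chains = 4L,
                            warmup = 1000L, seed = 1L, targetAccept = 0.9,
                            priorScales = list(), rhatAction = c("error", "warn")) {
  stopifnot(is(design, "OutcomeDesign"))
  rhatAction <- match.arg(rhatAction)
  if (length(unique(design@female)) < 2L) {
    stop("both sexes must be present in the design")
  }
  if (length(unique(design@outcome)) < 2L) {
    stop("both outcome classes must be present in the design")
  }
  ps <- list(alpha = 2.5, gamma = 1, mu = 1, tau = 1)
  ps[names(priorScales)] <- priorScales
  k <- ncol(design@patterns)
  q <- ncol(design@covariates)

  chainSeeds <- deriveSeeds(seed, chains)
  raw <- vector("list", chains)
  div <- integer(chains)
  for (ch in seq_len(chains)) {
    res <- withSeed(chainSeeds[ch], .nutsChain(
      design@patterns, design@covariates, design@outcome, design@female,
      as.integer(warmup), as.integer(draws), targetAccept, 10L,
      ps$alpha, ps$gamma, ps$mu, ps$tau
    ))
    raw[[ch]] <- res$draws
    div[ch] <- res$divergences
  }

  pnames <- c(
    "alpha", paste0("g_", colnames(design@covariates)),
    sprintf("mu_%d", seq_len(k)), sprintf("tau_%d", seq_len(k)),
    sprintf("b_male_%d", seq_len(k)), sprintf("b_female_%d", seq_len(k))
  )
  arr <- array(NA_real_, c(draws, chains, length(pnames)),
    dimnames = list(NULL, NULL, pnames)
  )
  iMu <- 1 + q + seq_len(k)
  iLt <- 1 + q + k + seq_len(k)
  iZm <- 1 + q + 2 * k + seq_len(k)
  iZf <- 1 + q + 3 * k + seq_len(k)
  for (ch in seq_len(chains)) {
    m <- raw[[ch]]
    tau <- exp(m[, iLt, drop = FALSE])
    arr[, ch, ] <- cbind(
      m[, 1], m[, 1 + seq_len(q), drop = FALSE],
      m[, iMu, drop = FALSE], tau,
      m[, iMu, drop = FALSE] + tau * m[, iZm, drop = FALSE],
      m[, iMu, drop = FALSE] + tau * m[, iZf, drop = FALSE]
    )
  }

  diag <- data.frame(
    parameter = pnames,
    rhat = vapply(pnames, function(p) splitRhat(arr[, , p, drop = FALSE]), 0),
    ess = vapply(pnames, function(p) splitEss(arr[, , p, drop = FALSE]), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  bad <- diag$parameter[diag$rhat > 1.05]
  if (length(bad)) {
    msg <- sprintf(
      "split-Rhat > 1.05 for %d parameter(s): %s (max %.3f); chains have not mixed",
      length(bad), paste(head(bad, 5), collapse = ", "), max(diag$rhat)
    )
    if (rhatAction == "error") stop(msg) else warning(msg)
  }
  divRate <- sum(div) / (draws * chains)
  if (divRate > 0.05) {
    warning(sprintf("%.1f%% of post-warmup transitions diverged", 100 * divRate))
  }

  new("OutcomePosterior",
    draws = arr, diagnostics = diag, divergences = div,
    seed = as.integer(seed),
    meta = list(
      draws = draws, warmup = warmup, chains = chains,
      targetAccept = targetAccept, priorScales = ps,
      divergenceRate = divRate, chainSeeds = chainSeeds
    )
  )
}

# split-half Rhat (potential scale reduction) of a draws x chains slice
splitRhat <- function(x) {
  x <- x[, , 1]
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- n %/% 2
  sp <- cbind(x[seq_len(half), , drop = FALSE], x[half + seq_len(half), , drop = FALSE])
  m <- ncol(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# bulk effective sample size via Geyer's initial monotone sequence on the
# split chains
splitEss <- function(x) {
  x <- x[, , 1]
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- n %/% 2
  sp <- cbind(x[seq_len(half), , drop = FALSE], x[half + seq_len(half), , drop = FALSE])
  m <- ncol(sp)
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  B <- half * var(colMeans(sp))
  varPlus <- (half - 1) / half * W + B / half
  if (varPlus < 1e-300) return(m * half)
  maxLag <- min(half - 1, 200)
  rho <- numeric(maxLag)
  centred <- sweep(sp, 2, colMeans(sp))
  for (t in seq_len(maxLag)) {
    acov <- mean(vapply(seq_len(m), function(ch) {
      mean(centred[seq_len(half - t), ch] * centred[t + seq_len(half - t), ch])
    }, 0))
    rho[t] <- 1 - (W - acov) / varPlus
  }
  # Geyer: sum consecutive pairs while positive
  s <- 0
  t <- 1
  while (t + 1 <= maxLag) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, m * half / (1 + 2 * s))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval over the sorted samples containing at
#' least `mass` of them: with `m = ceiling(mass * n)`, the window
#' `[x_(i), x_(i+m-1)]` of minimal width; ties broken toward the lower
#' window.
#'
#' @param samples numeric vector of at least 10 finite draws.
#' @param mass interval mass (default 0.90).
#' @return named numeric vector `c(lower, upper, mass)`.
#' @examples
#' hpdi(rnorm(10000))
#' @export
hpdi <- function(samples, mass = 0.90) {
  if (length(samples) < 10L) stop("need at least 10 samples")
  if (any(!is.finite(samples))) stop("samples must be finite")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m > n) stop("fewer samples than the requested window")
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths) # which.min takes the first (lowest) on ties
  c(lower = x[i], upper = x[i + m - 1L], mass = mass)
}

#' Substantial-effect decision rule
#'
#' An effect is flagged substantial when the 90% highest-posterior-density
#' interval of its posterior (or posterior-difference) samples excludes zero.
#'
#' @param samples posterior draws.
#' @param mass HPDI mass (default 0.90).
#' @return logical flag.
#' @export
substantialEffect <- function(samples, mass = 0.90) {
  h <- hpdi(samples, mass)
  h[["lower"]] > 0 || h[["upper"]] < 0
}

#' Sex difference of a pattern effect
#'
#' Per-draw difference of the male and female coefficients of one lesion
#' pattern, `b_male - b_female` (sign convention: men minus women), with its
#' posterior mean, 90% HPDI and substantial-effect flag.
#'
#' @param posterior an [OutcomePosterior].
#' @param pattern pattern index in 1..k.
#' @return list with `samples`, `mean`, `hpdi`, `substantial`.
#' @export
sexDifference <- function(posterior, pattern) {
  stopifnot(is(posterior, "OutcomePosterior"))
  dm <- parameterSamples(posterior, sprintf("b_male_%d", pattern))
  df <- parameterSamples(posterior, sprintf("b_female_%d", pattern))
  d <- dm - df
  list(
    samples = d, mean = mean(d), hpdi = hpdi(d),
    substantial = substantialEffect(d)
  )
}

#' Posterior-predictive AUC on the fitting cohort
#'
#' Scores each patient by the posterior mean of the inverse-logit linear
#' predictor across all draws (using the patient's own sex's pattern
#' coefficients) and computes the area under the ROC curve as the
#' Mann-Whitney statistic, ties counting one half.
#'
#' @param posterior an [OutcomePosterior].
#' @param design the [OutcomeDesign] that was fit.
#' @param perDraw if `TRUE`, instead average the per-draw AUCs (alternative
#'   summary; default `FALSE` uses posterior-mean scores).
#' @return AUC in `[0, 1]`.
#' @export
posteriorPredictiveAUC <- function(posterior, design, perDraw = FALSE) {
  stopifnot(is(posterior, "OutcomePosterior"), is(design, "OutcomeDesign"))
  if (length(unique(design@outcome)) < 2L) {
    stop("both outcome classes must be present")
  }
  k <- ncol(design@patterns)
  pn <- dimnames(posterior@draws)[[3]]
  flat <- matrix(posterior@draws, ncol = dim(posterior@draws)[3],
    dimnames = list(NULL, pn)
  )
  covNames <- paste0("g_", colnames(design@covariates))
  etaBase <- tcrossprod(
    cbind(1, design@covariates),
    flat[, c("alpha", covNames), drop = FALSE]
  )
  bm <- flat[, sprintf("b_male_%d", seq_len(k)), drop = FALSE]
  bf <- flat[, sprintf("b_female_%d", seq_len(k)), drop = FALSE]
  fem <- design@female == 1L
  eta <- etaBase
  eta[fem, ] <- eta[fem, ] + design@patterns[fem, , drop = FALSE] %*% t(bf)
  eta[!fem, ] <- eta[!fem, ] + design@patterns[!fem, , drop = FALSE] %*% t(bm)
  if (perDraw) {
    return(mean(apply(plogis(eta), 2, aucMannWhitney, y = design@outcome)))
  }
  aucMannWhitney(rowMeans(plogis(eta)), design@outcome)
}

#' Mann-Whitney AUC of scores against binary labels
#'
#' @param scores numeric scores.
#' @param y 0/1 labels.
#' @return AUC with ties counting one half.
#' @export
aucMannWhitney <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Baseline-characteristics table with sex comparison
#'
#' Per-variable comparison of male and female patients: Welch two-sample
#' t-tests for continuous variables, two-sided Fisher's exact tests on the
#' 2x2 count tables for binary ones. A zero-variance continuous variable is
#' reported with p = 1 and a `degenerate` flag.
#'
#' @param cohort cohort data.frame as in [buildDesign()].
#' @param volume optional per-patient lesion volume (ml), compared as a
#'   continuous variable.
#' @return data.frame with per-variable summaries (mean or percentage per
#'   sex), the test used and the p-value.
#' @export
compareBaseline <- function(cohort, volume = NULL) {
  female <- normalizeSexVector(cohort$sex, nrow(cohort)) == 1L
  if (!any(female) || all(female)) stop("both sexes must be present")
  rows <- list()
  addCont <- function(name, x) {
    degen <- var(x[female]) + var(x[!female]) < .Machine$double.eps
    res <- safeWelch(x[female], x[!female])
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = name, type = "continuous",
      male = mean(x[!female]), female = mean(x[female]),
      test = "t", p = res[2], degenerate = degen, stringsAsFactors = FALSE
    )
  }
  addBin <- function(name, x) {
    x <- as.integer(x)
    tab <- matrix(
      c(sum(x[!female]), sum(!x[!female]), sum(x[female]), sum(!x[female])), 2
    )
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = name, type = "binary",
      male = mean(x[!female]) * 100, female = mean(x[female]) * 100,
      test = "fisher", p = fisher.test(tab)$p.value, degenerate = FALSE,
      stringsAsFactors = FALSE
    )
  }
  addCont("age", cohort$age)
  if (!is.null(volume)) addCont("volume_ml", as.numeric(volume))
  if ("mRS" %in% colnames(cohort)) addBin("unfavourable", cohort$mRS > 2)
  for (v in c("hypertension", "afib", "diabetes", "chd", "prior_stroke", "smoking")) {
    if (v %in% colnames(cohort)) addBin(v, cohort[[v]])
  }
  do.call(rbind, rows)
}
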