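#' Configuration for the synthetic stroke cohort generator
#'
#' Defines the generative model the synthetic cohort is drawn from. Lesion
#' pattern expressions are sparse gamma draws (shape < 1, so most patients
#' load mainly on one or two patterns, mimicking single-territory strokes);
#' region counts are Poisson around `expression %*% basis`; the binary
#' 3-month outcome (mRS > 2) is Bernoulli with a logistic linear predictor
#' using the sex-appropriate pattern coefficients. Coefficients act on the
#' in-cohort standardized expressions and continuous covariates, matching the
#' scale on which the outcome model is fit, so fitted coefficients are
#' directly comparable with the truth.
#'
#' The default cohort shape follows the study this emulates: n = 822, 39.2%
#' women, age 63.9 (14.2) for men and 65.8 (16.2) for women, sex-specific
#' cardiovascular risk-factor prevalences (hypertension 63.0/65.9%, diabetes
#' 23.0/19.9%, atrial fibrillation 14.6/20.2%, coronary artery disease
#' 21.8/13.0%, smoking 61.0/45.7%, prior stroke 9.4/10.2%), and an intercept
#' targeting roughly 28% unfavourable outcomes.
#'
#' @param nPatients cohort size.
#' @param nPatterns number of true lesion patterns (default 10).
#' @param nRegions number of atlas regions (default 129).
#' @param trueBasis nPatterns x nRegions non-negative matrix; default: block
#'   territories built by [territoryBasis()].
#' @param coefFemale,coefMale length-nPatterns log-odds effects of the
#'   standardized pattern expressions, per sex (default all 0).
#' @param covariateEffects named log-odds coefficients for
#'   `age, age2, sex, hypertension, afib, diabetes, chd, prior_stroke,
#'   smoking, volume` (default all 0).
#' @param intercept log-odds intercept (default `qlogis(0.28)`).
#' @param sexRatio fraction female, in (0, 1) (default 0.392).
#' @param expressionShape,expressionScale gamma parameters of the sparse
#'   expression draws (shape < 1 keeps them territory-dominant).
#' @param seed integer RNG seed; all generator randomness flows through it.
#' @return a `cohortConfig` list.
#' @export
cohortConfig <- function(nPatients = 822L,
                         nPatterns = 10L,
                         nRegions = 129L,
                         trueBasis = NULL,
                         coefFemale = numeric(nPatterns),
                         coefMale = numeric(nPatterns),
                         covariateEffects = NULL,
                         intercept = qlogis(0.28),
                         sexRatio = 0.392,
                         expressionShape = 0.2,
                         expressionScale = 12,
                         seed = 1L) {
  if (is.null(trueBasis)) trueBasis <- territoryBasis(nPatterns, nRegions)
  stopifnot(
    nrow(trueBasis) == nPatterns, ncol(trueBasis) == nRegions,
    all(trueBasis >= 0)
  )
  if (any(rowSums(trueBasis > 0) < 1L)) {
    stop("every pattern row of trueBasis needs at least one positive entry")
  }
  if (sexRatio <= 0 || sexRatio >= 1) stop("sexRatio must be in (0, 1)")
  covDefault <- setNames(numeric(length(COVARIATE_NAMES)), COVARIATE_NAMES)
  if (!is.null(covariateEffects)) {
    bad <- setdiff(names(covariateEffects), COVARIATE_NAMES)
    if (length(bad)) stop("unknown covariate effect(s): ", paste(bad, collapse = ", "))
    covDefault[names(covariateEffects)] <- covariateEffects
  }
  stopifnot(length(coefFemale) == nPatterns, length(coefMale) == nPatterns)
  structure(
    list(
      nPatients = as.integer(nPatients), nPatterns = as.integer(nPatterns),
      nRegions = as.integer(nRegions), trueBasis = trueBasis,
      coefFemale = coefFemale, coefMale = coefMale,
      covariateEffects = covDefault, intercept = intercept,
      sexRatio = sexRatio, expressionShape = expressionShape,
      expressionScale = expressionScale, seed = as.integer(seed)
    ),
    class = "cohortConfig"
  )
}

COVARIATE_NAMES <- c(
  "age", "age2", "sex", "hypertension", "afib", "diabetes",
  "chd", "prior_stroke", "smoking", "volume"
)

# sex-specific marginals of the emulated cohort (female, male)
COHORT_MARGINALS <- list(
  ageMean = c(female = 65.8, male = 63.9),
  ageSD = c(female = 16.2, male = 14.2),
  hypertension = c(female = 0.659, male = 0.630),
  diabetes = c(female = 0.199, male = 0.230),
  afib = c(female = 0.202, male = 0.146),
  chd = c(female = 0.130, male = 0.218),
  smoking = c(female = 0.457, male = 0.610),
  prior_stroke = c(female = 0.102, male = 0.094)
)

#' Disjoint block-territory pattern basis
#'
#' A simple ground-truth basis in which each pattern loads on its own
#' contiguous block of regions (vascular-territory-like structure): pattern j
#' covers `nRegions / nPatterns` consecutive regions with loadings decaying
#' linearly from 1 at the block centre.
#'
#' @param nPatterns,nRegions dimensions.
#' @return nPatterns x nRegions non-negative matrix, rows max-normalized.
#' @export
territoryBasis <- function(nPatterns = 10L, nRegions = 129L) {
  B <- matrix(0, nPatterns, nRegions)
  bounds <- floor(seq(0, nRegions, length.out = nPatterns + 1))
  for (j in seq_len(nPatterns)) {
    idx <- (bounds[j] + 1L):bounds[j + 1L]
    centre <- mean(idx)
    w <- 1 - abs(idx - centre) / (length(idx) / 2 + 1)
    B[j, idx] <- pmax(w, 0.1)
  }
  B / apply(B, 1, max)
}

#' Generate a synthetic stroke cohort with known ground truth
#'
#' Draws pattern expressions, region lesion counts, covariates and outcomes
#' from the generative model in a [cohortConfig()]. Deterministic given the
#' config's seed.
#'
#' @param config a [cohortConfig()].
#' @return list with `lesions` (a [RegionLesionMatrix]), `expression` (the
#'   true patients x nPatterns expression matrix), `cohort` (data.frame:
#'   patient_id, age, sex, the six risk factors, mRS, plus the true linear
#'   predictor) and `config`.
#' @examples
#' cohort <- simulateCohort(cohortConfig(nPatients = 50, seed = 7))
#' table(cohort$cohort$sex)
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- config$nPatients
  k <- config$nPatterns
  withSeed(config$seed, {
    female <- rbinom(n, 1L, config$sexRatio)
    sexKey <- ifelse(female == 1L, "female", "male")
    age <- rnorm(n, COHORT_MARGINALS$ageMean[sexKey], COHORT_MARGINALS$ageSD[sexKey])
    rf <- sapply(c("hypertension", "afib", "diabetes", "chd", "prior_stroke", "smoking"),
      function(v) rbinom(n, 1L, COHORT_MARGINALS[[v]][sexKey])
    )
    # sparse gamma expressions: shape < 1 concentrates mass on few patterns
    W <- matrix(
      rgamma(n * k, shape = config$expressionShape, scale = config$expressionScale),
      n, k
    )
    lambda <- W %*% config$trueBasis
    counts <- matrix(rpois(length(lambda), lambda), n, config$nRegions)
    volume <- rowSums(counts) / 1000 # 1 mm^3 voxels -> ml

    zs <- function(x) {
      s <- sd(x)
      if (s < 1e-12) stop("degenerate covariate with zero variance in generator")
      (x - mean(x)) / s
    }
    Wz <- apply(W, 2, zs)
    ageC <- age - mean(age)
    covz <- cbind(
      age = zs(age), age2 = zs(ageC^2), sex = female,
      rf[, c("hypertension", "afib", "diabetes", "chd", "prior_stroke", "smoking")],
      volume = zs(volume)
    )[, COVARIATE_NAMES]
    beta <- ifelse(female == 1L, 1, 0) %*% t(config$coefFemale) +
      ifelse(female == 1L, 0, 1) %*% t(config$coefMale)
    eta <- config$intercept + rowSums(Wz * beta) +
      as.vector(covz %*% config$covariateEffects)
    if (any(!is.finite(eta))) {
      stop(
        "non-finite linear predictor; check the scale of trueBasis / ",
        "coefFemale / coefMale / covariateEffects"
      )
    }
    unfav <- rbinom(n, 1L, plogis(eta))

    ids <- sprintf("pt%05d", seq_len(n))
    cn <- defaultRegionNames(config$nRegions)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(ids, cn)
    lesions <- if (config$nRegions == N_REGIONS) {
      new("RegionLesionMatrix", counts = counts, volume = volume, voxelVolume = 1)
    } else {
      # non-standard region count: plain matrix with a volume attribute
      structure(counts, volume = volume)
    }
    dimnames(W) <- list(ids, sprintf("pattern%02d", seq_len(k)))
    cohort <- data.frame(
      patient_id = ids,
      age = age,
      sex = sexKey,
      hypertension = rf[, "hypertension"], afib = rf[, "afib"],
      diabetes = rf[, "diabetes"], chd = rf[, "chd"],
      prior_stroke = rf[, "prior_stroke"], smoking = rf[, "smoking"],
      # mRS consistent with the binary label: favourable -> 0..2, unfav -> 3..6
      mRS = ifelse(unfav == 1L, 3L + (seq_len(n) %% 4L), seq_len(n) %% 3L),
      linpred = eta,
      stringsAsFactors = FALSE
    )
    list(lesions = lesions, expression = W, cohort = cohort, config = config)
  })
}

defaultRegionNames <- function(nRegions) {
  if (nRegions == N_REGIONS) {
    rep(LAYER_NAMES, LAYER_SIZES)
    sprintf(
      "%s_%d_%s",
      rep(LAYER_NAMES, LAYER_SIZES),
      c(seq_len(94L), seq_len(15L), seq_len(20L)),
      c(sprintf("ctx%02d", 1:94), sprintf("sub%02d", 1:15), sprintf("wm%02d", 1:20))
    )
  } else {
    sprintf("region_%03d", seq_len(nRegions))
  }
}

# evaluate expr with a local, restored RNG state seeded at seed
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# derive a stream of sub-seeds below 2^31 from a master seed
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Write lesion masks realizing a RegionLesionMatrix
#'
#' For each patient, builds a binary mask whose per-region lesioned-voxel
#' counts equal the requested counts exactly: the first `count` voxels of each
#' region's deterministically sorted voxel list are set to 1. Requires an
#' atlas whose three layers are disjoint (otherwise exact per-layer counts
#' cannot be guaranteed simultaneously).
#'
#' @param lesions a [RegionLesionMatrix].
#' @param atlas an [AtlasSpec] with disjoint layers.
#' @param dir output directory for `<patient_id>.nii.gz` masks; `NULL`
#'   (default) returns masks as arrays instead of writing.
#' @return named list of 3D 0/1 arrays, or (with `dir`) the file paths,
#'   invisibly.
#' @export
simulateLesionMasks <- function(lesions, atlas, dir = NULL) {
  stopifnot(is(lesions, "RegionLesionMatrix"), is(atlas, "AtlasSpec"))
  overlap <- (atlas@layers$cortical > 0) +
    (atlas@layers$subcortical > 0) + (atlas@layers$tract > 0)
  if (any(overlap > 1)) {
    stop("atlas layers overlap; exact count realization needs disjoint layers")
  }
  sizes <- regionSizes(atlas)
  X <- lesions@counts
  over <- which(t(X) > sizes, arr.ind = TRUE)
  if (nrow(over)) {
    stop(
      "requested count exceeds region size for region(s): ",
      paste(unique(names(sizes)[over[, 1]]), collapse = ", ")
    )
  }
  # per-region sorted voxel index lists (column-major linear indices)
  tab <- atlas@regions
  voxlists <- vector("list", N_REGIONS)
  for (r in seq_len(N_REGIONS)) {
    voxlists[[r]] <- sort(which(atlas@layers[[tab$layer[r]]] == tab$label[r]))
  }
  dims <- dim(atlas@layers[[1]])
  masks <- vector("list", nrow(X))
  names(masks) <- rownames(X)
  for (i in seq_len(nrow(X))) {
    m <- array(0L, dims)
    for (r in seq_len(N_REGIONS)) {
      cnt <- X[i, r]
      if (cnt > 0) m[voxlists[[r]][seq_len(cnt)]] <- 1L
    }
    masks[[i]] <- m
  }
  if (is.null(dir)) {
    return(masks)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(masks))
  for (i in seq_along(masks)) {
    img <- RNifti::asNifti(masks[[i]] + 0)
    RNifti::qform(img) <- structure(atlas@affine, code = 2L)
    paths[i] <- file.path(dir, paste0(names(masks)[i], ".nii.gz"))
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}
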