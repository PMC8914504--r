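#' @import methods
#' @importFrom stats rnorm runif rbinom rgamma rpois sd var quantile
#'   plogis qlogis fisher.test t.test p.adjust pt setNames complete.cases
#'   cor
#' @importFrom utils head
NULL

LAYER_NAMES <- c("cortical", "subcortical", "tract")
LAYER_SIZES <- c(cortical = 94L, subcortical = 15L, tract = 20L)
N_REGIONS <- 129L
N_NETWORKS <- 14L

#' Three-layer brain atlas on a common voxel grid
#'
#' Holds discrete label images for the three atlas layers used to parcellate
#' lesion masks: 94 cortical regions, 15 subcortical regions and 20
#' white-matter tracts (129 regions in total), together with a region lookup
#' table, the voxel volume and the grid affine. All three label images must
#' share grid shape and affine. Label value 0 means background; within each
#' layer the non-zero labels are `1..n_layer`.
#'
#' @slot layers named list of three integer 3D arrays (`cortical`,
#'   `subcortical`, `tract`) of identical dimension.
#' @slot regions `data.frame` with one row per region in fixed column order
#'   (cortical, then subcortical, then tract): `region` (global index
#'   1..129), `layer`, `label` (value in that layer's image), `name`,
#'   `hemisphere` (`"L"`, `"R"` or `"B"`).
#' @slot voxelVolume voxel volume in mm^3.
#' @slot affine 4x4 voxel-to-world affine.
#' @name AtlasSpec-class
#' @aliases AtlasSpec
#' @exportClass AtlasSpec
setClass("AtlasSpec",
  representation(
    layers = "list",
    regions = "data.frame",
    voxelVolume = "numeric",
    affine = "matrix"
  )
)

setValidity("AtlasSpec", function(object) {
  msg <- character()
  if (!identical(sort(names(object@layers)), sort(LAYER_NAMES))) {
    msg <- c(msg, "layers must be named cortical, subcortical, tract")
  } else {
    d <- lapply(object@layers, dim)
    if (!all(vapply(d, length, 1L) == 3L)) {
      msg <- c(msg, "each layer must be a 3D array")
    } else if (!all(vapply(d, identical, TRUE, d[[1]]))) {
      msg <- c(msg, "all layers must share grid dimensions")
    }
    for (ly in LAYER_NAMES) {
      labs <- sort(unique(as.integer(object@layers[[ly]])))
      labs <- labs[labs != 0L]
      n <- LAYER_SIZES[[ly]]
      if (!identical(labs, seq_len(n))) {
        msg <- c(msg, sprintf("layer '%s' must contain labels 1..%d exactly", ly, n))
      }
    }
  }
  if (nrow(object@regions) != N_REGIONS) {
    msg <- c(msg, sprintf("regions table must have %d rows", N_REGIONS))
  }
  if (length(object@voxelVolume) != 1L || object@voxelVolume <= 0) {
    msg <- c(msg, "voxelVolume must be a positive scalar")
  }
  if (!identical(dim(object@affine), c(4L, 4L))) {
    msg <- c(msg, "affine must be 4x4")
  }
  if (length(msg)) msg else TRUE
})

#' Patients-by-region lesion-load matrix
#'
#' The lesion representation used throughout: for each patient, the number of
#' lesioned voxels falling in each of the 129 atlas regions (columns ordered
#' cortical, subcortical, tract), plus the total lesion volume in ml.
#'
#' @slot counts non-negative integer matrix, patients x 129, with patient ids
#'   as rownames and `<layer>_<label>_<name>` column names.
#' @slot volume total lesion volume per patient in ml (total lesioned voxels
#'   x voxel volume / 1000).
#' @slot voxelVolume voxel volume in mm^3 the volumes were computed with.
#' @name RegionLesionMatrix-class
#' @aliases RegionLesionMatrix
#' @exportClass RegionLesionMatrix
setClass("RegionLesionMatrix",
  representation(
    counts = "matrix",
    volume = "numeric",
    voxelVolume = "numeric"
  )
)

setValidity("RegionLesionMatrix", function(object) {
  msg <- character()
  if (ncol(object@counts) != N_REGIONS) {
    msg <- c(msg, sprintf("counts must have %d columns", N_REGIONS))
  }
  if (nrow(object@counts) > 0 && any(object@counts < 0)) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (length(object@volume) != nrow(object@counts)) {
    msg <- c(msg, "volume must have one entry per patient")
  }
  if (is.null(rownames(object@counts)) && nrow(object@counts) > 0) {
    msg <- c(msg, "counts must carry patient ids as rownames")
  }
  if (anyDuplicated(rownames(object@counts))) {
    msg <- c(msg, "duplicate patient ids")
  }
  if (length(msg)) msg else TRUE
})

#' Non-negative lesion-pattern factorization
#'
#' Result of factorizing a [RegionLesionMatrix] into `k` non-negative lesion
#' patterns: `counts ~ expression %*% basis`. Basis rows are rescaled so each
#' pattern's maximum loading is 1, with the inverse scale absorbed into the
#' expression matrix, so a loading is interpretable as a fraction of the
#' pattern's peak region.
#'
#' @slot basis k x 129 non-negative loading matrix, rows max-normalized.
#' @slot expression patients x k non-negative expression matrix.
#' @slot scales the per-pattern factors the raw basis rows were divided by.
#' @slot objective Frobenius objective value per multiplicative-update
#'   iteration (non-increasing).
#' @slot iterations,converged fit metadata.
#' @slot seed RNG seed used for initialization tie-breaking.
#' @name LesionPatternFit-class
#' @aliases LesionPatternFit
#' @exportClass LesionPatternFit
setClass("LesionPatternFit",
  representation(
    basis = "matrix",
    expression = "matrix",
    scales = "numeric",
    objective = "numeric",
    iterations = "integer",
    converged = "logical",
    seed = "integer"
  )
)

setValidity("LesionPatternFit", function(object) {
  msg <- character()
  if (any(object@basis < 0) || any(object@expression < 0)) {
    msg <- c(msg, "basis and expression must be non-negative")
  }
  if (nrow(object@basis) != ncol(object@expression)) {
    msg <- c(msg, "basis rows must match expression columns")
  }
  rowmax <- apply(object@basis, 1L, max)
  if (any(rowmax <= 0)) {
    msg <- c(msg, "every pattern row must have a positive loading")
  } else if (any(abs(rowmax - 1) > 1e-8)) {
    msg <- c(msg, "basis rows must be max-normalized to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Standardized design matrix for the outcome model
#'
#' Complete-case design for the hierarchical logistic regression: standardized
#' pattern expressions, standardized continuous covariates (age, age-squared
#' computed from centred age, lesion volume), binary covariates, the sex
#' grouping vector and the binary unfavourable-outcome label (mRS > 2).
#' Standardization parameters are stored so the same scaling can be applied
#' to, or inverted on, other cohorts.
#'
#' @slot patterns patients x k standardized pattern-expression matrix.
#' @slot covariates patients x 10 covariate matrix (age, age2, sex,
#'   hypertension, afib, diabetes, chd, prior_stroke, smoking, volume).
#' @slot outcome integer 0/1 vector, 1 = unfavourable (mRS > 2).
#' @slot female integer 0/1 vector, 1 = female.
#' @slot scaling data.frame of (column, center, scale) for each standardized
#'   column, plus the age centre used before squaring.
#' @slot dropped number of rows removed as incomplete.
#' @name OutcomeDesign-class
#' @aliases OutcomeDesign
#' @exportClass OutcomeDesign
setClass("OutcomeDesign",
  representation(
    patterns = "matrix",
    covariates = "matrix",
    outcome = "integer",
    female = "integer",
    scaling = "data.frame",
    dropped = "integer"
  )
)

setValidity("OutcomeDesign", function(object) {
  msg <- character()
  n <- nrow(object@patterns)
  if (nrow(object@covariates) != n || length(object@outcome) != n ||
      length(object@female) != n) {
    msg <- c(msg, "patterns, covariates, outcome and female must align")
  }
  if (n > 0 && !all(object@outcome %in% c(0L, 1L))) {
    msg <- c(msg, "outcome must be 0/1")
  }
  if (n > 0 && !all(object@female %in% c(0L, 1L))) {
    msg <- c(msg, "female must be 0/1")
  }
  if (anyNA(object@patterns) || anyNA(object@covariates)) {
    msg <- c(msg, "design must be complete-case (no missing values)")
  }
  if (length(msg)) msg else TRUE
})

#' Posterior draws from the hierarchical outcome model
#'
#' NUTS draws for the Bayesian hierarchical logistic regression. Parameters:
#' intercept `alpha`; covariate coefficients `g_<name>`; per-pattern
#' hypermeans `mu_j`; between-sex scales `tau_j` (positive in every draw);
#' sex-specific pattern coefficients `b_male_j` and `b_female_j`.
#'
#' @slot draws array draw x chain x parameter with parameter dimnames.
#' @slot diagnostics data.frame with split-Rhat and bulk effective sample
#'   size per parameter.
#' @slot divergences divergent-transition count per chain.
#' @slot seed,meta sampler configuration (draws, warmup, chains, prior
#'   scales, target acceptance).
#' @name OutcomePosterior-class
#' @aliases OutcomePosterior
#' @exportClass OutcomePosterior
setClass("OutcomePosterior",
  representation(
    draws = "array",
    diagnostics = "data.frame",
    divergences = "integer",
    seed = "integer",
    meta = "list"
  )
)

setValidity("OutcomePosterior", function(object) {
  msg <- character()
  if (length(dim(object@draws)) != 3L) {
    msg <- c(msg, "draws must be a draw x chain x parameter array")
  } else {
    pn <- dimnames(object@draws)[[3]]
    if (is.null(pn)) msg <- c(msg, "draws must carry parameter names")
    taus <- grep("^tau_", pn)
    if (length(taus) && any(object@draws[, , taus, drop = FALSE] <= 0)) {
      msg <- c(msg, "tau draws must be positive")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AtlasSpec", function(object) {
  d <- dim(object@layers[[1]])
  cat(sprintf(
    "AtlasSpec: %d x %d x %d grid, %d regions (%d cortical / %d subcortical / %d tracts), voxel %.3g mm^3\n",
    d[1], d[2], d[3], nrow(object@regions),
    sum(object@regions$layer == "cortical"),
    sum(object@regions$layer == "subcortical"),
    sum(object@regions$layer == "tract"),
    object@voxelVolume
  ))
})

setMethod("show", "RegionLesionMatrix", function(object) {
  cat(sprintf(
    "RegionLesionMatrix: %d patients x %d regions; volume %.2f-%.2f ml\n",
    nrow(object@counts), ncol(object@counts),
    if (length(object@volume)) min(object@volume) else NA_real_,
    if (length(object@volume)) max(object@volume) else NA_real_
  ))
})

setMethod("show", "LesionPatternFit", function(object) {
  cat(sprintf(
    "LesionPatternFit: %d patterns x %d regions, %d patients; %d iterations (%s), final objective %.4g\n",
    nrow(object@basis), ncol(object@basis), nrow(object@expression),
    object@iterations, if (object@converged) "converged" else "max iterations",
    object@objective[length(object@objective)]
  ))
})

setMethod("show", "OutcomeDesign", function(object) {
  cat(sprintf(
    "OutcomeDesign: %d patients (%d female), %d patterns, %d covariates; %d unfavourable; %d rows dropped\n",
    nrow(object@patterns), sum(object@female), ncol(object@patterns),
    ncol(object@covariates), sum(object@outcome), object@dropped
  ))
})

setMethod("show", "OutcomePosterior", function(object) {
  d <- dim(object@draws)
  cat(sprintf(
    "OutcomePosterior: %d draws x %d chains x %d parameters; max split-Rhat %.3f; %d divergences\n",
    d[1], d[2], d[3], max(object@diagnostics$rhat), sum(object@divergences)
  ))
})

#' Accessors
#'
#' Small accessor functions for the package's S4 containers.
#'
#' @param x an object of the matching class.
#' @return The slot contents; see each description.
#' @name accessors
NULL

#' @describeIn accessors integer count matrix (patients x 129) of a
#'   [RegionLesionMatrix].
#' @export
lesionCounts <- function(x) {
  stopifnot(is(x, "RegionLesionMatrix"))
  x@counts
}

#' @describeIn accessors per-patient lesion volume in ml.
#' @export
lesionVolume <- function(x) {
  stopifnot(is(x, "RegionLesionMatrix"))
  setNames(x@volume, rownames(x@counts))
}

#' @describeIn accessors patient identifiers.
#' @export
patientIds <- function(x) {
  stopifnot(is(x, "RegionLesionMatrix"))
  rownames(x@counts)
}

#' @describeIn accessors region lookup table of an [AtlasSpec].
#' @export
atlasRegions <- function(x) {
  stopifnot(is(x, "AtlasSpec"))
  x@regions
}

#' @describeIn accessors named list of the three label arrays of an
#'   [AtlasSpec].
#' @export
atlasLayers <- function(x) {
  stopifnot(is(x, "AtlasSpec"))
  x@layers
}

#' @describeIn accessors k x 129 max-normalized pattern basis.
#' @export
patternBasis <- function(x) {
  stopifnot(is(x, "LesionPatternFit"))
  x@basis
}

#' @describeIn accessors patients x k pattern expression matrix.
#' @export
patternExpression <- function(x) {
  stopifnot(is(x, "LesionPatternFit"))
  x@expression
}

#' @describeIn accessors draw x chain x parameter array of an
#'   [OutcomePosterior].
#' @export
posteriorDraws <- function(x) {
  stopifnot(is(x, "OutcomePosterior"))
  x@draws
}

#' @describeIn accessors per-parameter convergence diagnostics.
#' @export
posteriorDiagnostics <- function(x) {
  stopifnot(is(x, "OutcomePosterior"))
  x@diagnostics
}

#' Extract all draws of one parameter, pooled across chains
#'
#' @param x an [OutcomePosterior].
#' @param parameter parameter name, e.g. `"b_female_3"`.
#' @return numeric vector of length draws x chains.
#' @export
parameterSamples <- function(x, parameter) {
  stopifnot(is(x, "OutcomePosterior"))
  pn <- dimnames(x@draws)[[3]]
  if (!parameter %in% pn) {
    stop("unknown parameter '", parameter, "'")
  }
  as.vector(x@draws[, , parameter])
}

# region column names in the fixed (cortical, subcortical, tract) order
regionColumnNames <- function(regions) {
  sprintf("%s_%d_%s", regions$layer, regions$label, regions$name)
}
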