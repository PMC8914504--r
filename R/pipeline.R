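#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. Inputs can
#' be given either as in-memory objects (from the simulators) or as paths
#' (mask directory + atlas directory, cohort CSV, connectome directories).
#' The seed is mandatory; every stage derives its own sub-seed from it.
#'
#' @param lesions a [RegionLesionMatrix], or `masks` + `atlas` to parcellate.
#' @param masks optional character vector of NIfTI mask paths or named list
#'   of arrays.
#' @param atlas an [AtlasSpec] (required with `masks` or for the LNM stage).
#' @param cohort cohort data.frame (see [buildDesign()]) or CSV path.
#' @param connectomes optional list with `male`/`female` subject lists (or
#'   `NULL` to skip the LNM stage).
#' @param networks optional 14-network label array (required with
#'   connectomes).
#' @param k number of lesion patterns (default 10).
#' @param draws,chains,warmup sampler settings.
#' @param sensitivityReps downsampling repetitions (default 20; 0 skips the
#'   stage).
#' @param lnmVariants LNM variants per pattern (default 100).
#' @param rhatAction `"error"` (default) or `"warn"` when a fit's split-Rhat
#'   exceeds 1.05; `"warn"` is intended for deliberately short desk-scale
#'   runs.
#' @param seed mandatory integer master seed.
#' @return a validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(lesions = NULL, masks = NULL, atlas = NULL,
                           cohort, connectomes = NULL, networks = NULL,
                           k = 10L, draws = 5000L, chains = 4L,
                           warmup = 1000L, sensitivityReps = 20L,
                           lnmVariants = 100L, rhatAction = c("error", "warn"),
                           seed) {
  rhatAction <- match.arg(rhatAction)
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(lesions) && is.null(masks)) {
    stop("either lesions or masks must be provided")
  }
  if (!is.null(masks) && is.null(atlas)) {
    stop("masks require an atlas")
  }
  if (is.character(masks) && !all(file.exists(masks))) {
    stop("missing mask file(s): ",
         paste(head(masks[!file.exists(masks)]), collapse = ", "))
  }
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop("cohort file does not exist: ", cohort)
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  }
  if (!is.null(connectomes)) {
    if (!all(c("male", "female") %in% names(connectomes))) {
      stop("connectomes must have male and female sets")
    }
    if (is.null(networks)) stop("connectomes require a networks label image")
    if (is.null(atlas)) stop("the LNM stage requires an atlas")
  }
  structure(
    list(
      lesions = lesions, masks = masks, atlas = atlas, cohort = cohort,
      connectomes = connectomes, networks = networks, k = as.integer(k),
      draws = as.integer(draws), chains = as.integer(chains),
      warmup = as.integer(warmup),
      sensitivityReps = as.integer(sensitivityReps),
      lnmVariants = as.integer(lnmVariants), rhatAction = rhatAction,
      seed = as.integer(seed)
    ),
    class = "pipelineConfig"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads scalar settings (k, draws, chains, warmup, sensitivityReps,
#' lnmVariants, seed) and paths (`cohort` CSV, `matrix` CSV or `masks` +
#' `atlas` directories, `connectomes` directory with `male/`/`female/`
#' subdirectories and a `networks` NIfTI) from a YAML file and resolves them
#' into a [pipelineConfig()].
#'
#' @param path YAML file.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  atlas <- if (!is.null(y$atlas)) readAtlas(resolve(y$atlas)) else NULL
  lesions <- if (!is.null(y$matrix)) readLesionMatrix(resolve(y$matrix)) else NULL
  masks <- if (!is.null(y$masks)) {
    list.files(resolve(y$masks), pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  } else {
    NULL
  }
  connectomes <- NULL
  networks <- NULL
  if (!is.null(y$connectomes)) {
    cdir <- resolve(y$connectomes)
    readSet <- function(sub) {
      files <- list.files(file.path(cdir, sub),
        pattern = "\\.nii(\\.gz)?$", full.names = TRUE
      )
      lapply(setNames(files, sub("\\.nii(\\.gz)?$", "", basename(files))),
        function(f) as.array(RNifti::readNifti(f))
      )
    }
    connectomes <- list(male = readSet("male"), female = readSet("female"))
    nimg <- RNifti::readNifti(resolve(y$networks))
    networks <- array(as.integer(round(as.array(nimg))), dim(nimg))
  }
  args <- list(
    lesions = lesions, masks = masks, atlas = atlas, cohort = resolve(y$cohort),
    connectomes = connectomes, networks = networks, seed = y$seed
  )
  for (nm in c("k", "draws", "chains", "warmup", "sensitivityReps",
               "lnmVariants", "rhatAction")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(pipelineConfig, args)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — parcellation (if masks are given),
#' pattern factorization, baseline table, outcome model, downsampling
#' sensitivity, lesion network mapping — skipping stages whose inputs are
#' absent (no connectomes: LNM is marked "skipped"; `sensitivityReps = 0`:
#' sensitivity is skipped). Returns a result bundle whose manifest records a
#' content hash per stage output, the config snapshot (scalars and seed) and
#' the package version, so a re-run with the same config and inputs can be
#' checked for bit-compatibility on deterministic stages.
#'
#' @param config a [pipelineConfig()].
#' @return a `resultBundle` list: `stages` (per-stage status + hash),
#'   `lesions`, `patterns`, `baseline`, `design`, `posterior`, `effects`
#'   (the [renderEffectsTable()] output), `sensitivity`, `lnm`, `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  stageSeeds <- deriveSeeds(config$seed, 4L)
  stages <- list()
  runStage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
    stages[[name]] <<- list(status = "done", hash = rlang::hash(out))
    out
  }

  lesions <- if (!is.null(config$lesions)) {
    stages$parcellation <- list(status = "skipped (matrix supplied)", hash = NA)
    config$lesions
  } else {
    runStage("parcellation", function() {
      parcellateCohort(config$masks, config$atlas)
    })
  }

  patterns <- runStage("patterns", function() {
    fitNMF(lesions, k = config$k, seed = stageSeeds[1])
  })
  baseline <- runStage("baseline", function() {
    compareBaseline(config$cohort, volume = lesionVolume(lesions))
  })
  model <- runStage("model", function() {
    design <- buildDesign(
      config$cohort, patternExpression(patterns), lesionVolume(lesions)
    )
    posterior <- fitOutcomeModel(design,
      draws = config$draws, chains = config$chains,
      warmup = config$warmup, seed = stageSeeds[2],
      rhatAction = config$rhatAction
    )
    list(design = design, posterior = posterior,
         auc = posteriorPredictiveAUC(posterior, design))
  })

  sensitivity <- if (config$sensitivityReps > 0L) {
    runStage("sensitivity", function() {
      downsampleAndRefit(
        config$cohort, patternExpression(patterns), lesionVolume(lesions),
        nReps = config$sensitivityReps, seed = stageSeeds[3],
        draws = config$draws, chains = config$chains, warmup = config$warmup,
        rhatAction = config$rhatAction
      )
    })
  } else {
    stages$sensitivity <- list(status = "skipped", hash = NA)
    NULL
  }

  lnm <- if (!is.null(config$connectomes)) {
    runStage("lnm", function() {
      lnmAnalysis(
        patterns, config$atlas, config$connectomes, config$networks,
        nVariants = config$lnmVariants, seed = stageSeeds[4]
      )
    })
  } else {
    message("no connectomes configured; skipping the LNM stage")
    stages$lnm <- list(status = "skipped", hash = NA)
    NULL
  }

  effects <- renderEffectsTable(model$posterior)
  manifest <- list(
    package = "StrokeSexPatterns",
    version = as.character(utils::packageVersion("StrokeSexPatterns")),
    seed = config$seed,
    settings = config[c(
      "k", "draws", "chains", "warmup", "sensitivityReps", "lnmVariants"
    )],
    stages = stages
  )
  structure(
    list(
      stages = stages, lesions = lesions, patterns = patterns,
      baseline = baseline, design = model$design,
      posterior = model$posterior, auc = model$auc, effects = effects,
      sensitivity = sensitivity, lnm = lnm, manifest = manifest
    ),
    class = "resultBundle"
  )
}

#' Headline effects table
#'
#' Per pattern and sex: posterior mean, 90% HPDI and substantial-effect
#' flag, plus a difference row (men minus women) per pattern — the reporting
#' format of the study this package implements.
#'
#' @param posterior an [OutcomePosterior].
#' @param mass HPDI mass (default 0.90).
#' @return data.frame with columns `pattern`, `quantity` (`male`, `female`,
#'   `difference`), `mean`, `hpdi_lower`, `hpdi_upper`, `substantial`.
#' @export
renderEffectsTable <- function(posterior, mass = 0.90) {
  stopifnot(is(posterior, "OutcomePosterior"))
  pn <- dimnames(posterior@draws)[[3]]
  k <- sum(grepl("^mu_", pn))
  rows <- list()
  for (j in seq_len(k)) {
    for (q in c("male", "female", "difference")) {
      s <- if (q == "difference") {
        sexDifference(posterior, j)$samples
      } else {
        parameterSamples(posterior, sprintf("b_%s_%d", q, j))
      }
      h <- hpdi(s, mass)
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = j, quantity = q, mean = mean(s),
        hpdi_lower = h[["lower"]], hpdi_upper = h[["upper"]],
        substantial = substantialEffect(s, mass), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.resultBundle <- function(x, ...) {
  cat("StrokeSexPatterns result bundle\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-13s %s\n", nm, x$stages[[nm]]$status))
  }
  cat(sprintf("  posterior-predictive AUC: %.3f\n", x$auc))
  sub <- x$effects[x$effects$substantial & x$effects$quantity == "difference", ]
  if (nrow(sub)) {
    cat("  substantial sex differences (men - women): pattern",
        paste(sub$pattern, collapse = ", "), "\n")
  } else {
    cat("  no substantial sex differences\n")
  }
  invisible(x)
}
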