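#' Majority-class downsampling sensitivity analysis
#'
#' Rebalances favourable outcomes between the sexes and refits the outcome
#' model repeatedly: in each repetition the larger sex's favourable-outcome
#' patients are sampled without replacement down to the smaller sex's
#' favourable count, while all unfavourable patients and the whole minority
#' sex are kept. The design is rebuilt (and restandardized) on each
#' subsample and the model refit with an independent sampler seed derived
#' from the master seed and the repetition index. The pattern expressions
#' are fixed from the full-cohort factorization and subset, not refit.
#'
#' @param cohort cohort data.frame as in [buildDesign()].
#' @param expression full-cohort pattern expression matrix (patient ids as
#'   rownames).
#' @param volume per-patient lesion volume in ml, named by patient id.
#' @param nReps repetitions (default 20).
#' @param seed master seed.
#' @param draws,chains,warmup sampler settings per refit (defaults mirror
#'   the main analysis).
#' @param ... further arguments to [fitOutcomeModel()].
#' @return list with `repetitions` (per repetition: selected ids and
#'   per-pattern flags) and `summary` (per pattern: count and fraction of
#'   repetitions whose sex-difference HPDI excludes zero, and per-sex
#'   substantial-effect counts).
#' @export
downsampleAndRefit <- function(cohort, expression, volume, nReps = 20L,
                               seed = 1L, draws = 5000L, chains = 4L,
                               warmup = 1000L, ...) {
  female <- normalizeSexVector(cohort$sex, nrow(cohort))
  unfav <- cohort$mRS > 2
  favBySex <- table(factor(female[!unfav], levels = 0:1))
  majority <- if (favBySex[["0"]] >= favBySex[["1"]]) 0L else 1L
  nMinor <- min(favBySex)
  nMajor <- max(favBySex)
  if (nMinor >= nMajor) {
    warning("favourable outcomes already balanced; nothing to downsample")
  }
  majorFavIds <- cohort$patient_id[!unfav & female == majority]
  keepAlways <- cohort$patient_id[unfav | female != majority]

  repSeeds <- deriveSeeds(seed, 2L * nReps)
  k <- ncol(expression)
  reps <- vector("list", nReps)
  diffFlags <- matrix(FALSE, nReps, k)
  maleFlags <- matrix(FALSE, nReps, k)
  femaleFlags <- matrix(FALSE, nReps, k)
  for (r in seq_len(nReps)) {
    chosen <- withSeed(
      repSeeds[r],
      sample(majorFavIds, nMinor, replace = FALSE)
    )
    ids <- c(keepAlways, chosen)
    sub <- cohort[cohort$patient_id %in% ids, , drop = FALSE]
    design <- buildDesign(sub, expression, volume)
    fit <- fitOutcomeModel(design,
      draws = draws, chains = chains, warmup = warmup,
      seed = repSeeds[nReps + r], ...
    )
    for (j in seq_len(k)) {
      d <- sexDifference(fit, j)
      diffFlags[r, j] <- d$substantial
      maleFlags[r, j] <- substantialEffect(
        parameterSamples(fit, sprintf("b_male_%d", j))
      )
      femaleFlags[r, j] <- substantialEffect(
        parameterSamples(fit, sprintf("b_female_%d", j))
      )
    }
    reps[[r]] <- list(
      repetition = r, selected = sort(chosen), n = nrow(sub),
      diff = diffFlags[r, ], male = maleFlags[r, ], female = femaleFlags[r, ]
    )
  }
  list(
    repetitions = reps,
    summary = data.frame(
      pattern = seq_len(k),
      diff_count = colSums(diffFlags),
      diff_fraction = colMeans(diffFlags),
      male_count = colSums(maleFlags),
      female_count = colSums(femaleFlags)
    ),
    majoritySex = if (majority == 0L) "male" else "female",
    nMinorityFavourable = as.integer(nMinor),
    seed = as.integer(seed)
  )
}
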