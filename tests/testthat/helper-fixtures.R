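# shared fixtures, built once per test run

fixtureAtlas <- function() {
  if (is.null(.fixtures$atlas)) .fixtures$atlas <- simulateAtlas(c(16L, 16L, 9L))
  .fixtures$atlas
}

fixtureOverlapAtlas <- function() {
  if (is.null(.fixtures$overlap)) {
    .fixtures$overlap <- simulateAtlas(c(16L, 16L, 9L), overlap = TRUE)
  }
  .fixtures$overlap
}

# a small cohort with no planted effects
fixtureNullCohort <- function() {
  if (is.null(.fixtures$nullCohort)) {
    .fixtures$nullCohort <- simulateCohort(cohortConfig(nPatients = 300L, seed = 404L))
  }
  .fixtures$nullCohort
}

.fixtures <- new.env(parent = emptyenv())

defaultColnames <- function() {
  colnames(lesionCounts(fixtureNullCohort()$lesions))
}

# triple-loop reference parcellation (the oracle the fast path is tested
# against): walks every voxel of every layer explicitly
oracleParcellate <- function(mask, atlas) {
  layers <- atlasLayers(atlas)
  tab <- atlasRegions(atlas)
  d <- dim(mask)
  counts <- integer(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    lay <- layers[[tab$layer[r]]]
    lab <- tab$label[r]
    cnt <- 0L
    for (x in seq_len(d[1])) {
      for (y in seq_len(d[2])) {
        for (z in seq_len(d[3])) {
          if (mask[x, y, z] == 1 && lay[x, y, z] == lab) cnt <- cnt + 1L
        }
      }
    }
    counts[r] <- cnt
  }
  counts
}

# random binary mask with a fixed number of lesioned voxels
randomMask <- function(dims, nVoxels, seed) {
  m <- array(0L, dims)
  idx <- StrokeSexPatterns:::withSeed(seed, sample.int(prod(dims), nVoxels))
  m[idx] <- 1L
  m
}

# build an OutcomePosterior filled with given per-parameter constant draws
constantPosterior <- function(values, nDraws = 50L, nChains = 2L) {
  pn <- names(values)
  arr <- array(rep(values, each = nDraws * nChains),
    c(nDraws, nChains, length(values)),
    dimnames = list(NULL, NULL, pn)
  )
  new("OutcomePosterior",
    draws = arr,
    diagnostics = data.frame(parameter = pn, rhat = 1, ess = nDraws),
    divergences = integer(nChains), seed = 1L, meta = list()
  )
}
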