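#' Sample region-subset variants of a lesion pattern
#'
#' Generates variants of a lesion pattern for group-level lesion network
#' mapping: for each variant, a size `m` is drawn uniformly from
#' `{1, ..., |affiliated|}` and then `m` affiliated regions are drawn
#' uniformly without replacement. Deterministic given the seed.
#'
#' @param affiliated integer vector of affiliated region ids
#'   (see [affiliatedRegions()]).
#' @param nVariants number of variants (default 100).
#' @param seed integer seed.
#' @return list of integer vectors of region ids (sorted within variant).
#' @export
sampleVariants <- function(affiliated, nVariants = 100L, seed = 1L) {
  affiliated <- as.integer(affiliated)
  if (!length(affiliated)) stop("affiliated region set is empty")
  withSeed(seed, {
    lapply(seq_len(nVariants), function(v) {
      m <- sample.int(length(affiliated), 1L)
      sort(affiliated[sample.int(length(affiliated), m)])
    })
  })
}

#' Seed-based lesion connectivity t-map
#'
#' Whole-brain functional connectivity of a seed mask against a normative
#' connectome: per subject, the global (whole-brain mean) signal is
#' regressed out of every voxel time series (if `gsr`), the seed time series
#' is the mean over mask voxels, every voxel is Pearson-correlated with the
#' seed, correlations are clipped to +/- 0.999999 and Fisher
#' z-transformed (`atanh`); a voxel with a constant time series gets r = 0.
#' The group map is the one-sample t statistic across subjects of the z
#' maps. Voxels with zero between-subject variance get t = 0 when the mean
#' z is also 0, otherwise a clipped t of +/- 1e6, so the map is finite
#' everywhere.
#'
#' @param seedMask logical/0-1 3D array on the connectome grid.
#' @param connectome list of 4D arrays (x, y, z, time), one per subject.
#' @param gsr apply global signal regression (default `TRUE`).
#' @param label identifier used in error messages (e.g. the variant).
#' @return 3D array of group t values, with attribute `nSubjects`.
#' @export
lesionConnectivity <- function(seedMask, connectome, gsr = TRUE, label = "seed") {
  if (length(connectome) < 2L) stop("need at least 2 subjects")
  d <- dim(connectome[[1]])[1:3]
  if (!identical(dim(seedMask)[1:3], d)) stop("seed mask grid does not match connectome")
  seedIdx <- which(seedMask != 0)
  if (!length(seedIdx)) stop("empty seed mask for ", label)
  zsum <- 0
  zsumsq <- 0
  for (s in seq_along(connectome)) {
    V <- matrix(connectome[[s]], prod(d)) # voxels x time
    z <- subjectSeedZ(V, seedIdx, gsr, label)
    zsum <- zsum + z
    zsumsq <- zsumsq + z^2
  }
  n <- length(connectome)
  tmap <- groupT(zsum, zsumsq, n)
  structure(array(tmap, d), nSubjects = n)
}

# per-subject Fisher-z seed connectivity over a voxels x time matrix
subjectSeedZ <- function(V, seedIdx, gsr, label) {
  nt <- ncol(V)
  if (gsr) {
    gs <- colMeans(V)
    gsc <- gs - mean(gs)
    denom <- sum(gsc^2)
    if (denom > 0) {
      # per-voxel simple least-squares removal of the global signal
      beta <- (V %*% gsc) / denom
      V <- V - tcrossprod(beta, gsc)
    }
  }
  seed <- colMeans(V[seedIdx, , drop = FALSE])
  seedC <- seed - mean(seed)
  seedSS <- sum(seedC^2)
  if (seedSS < 1e-24) stop("zero-variance seed time series for ", label)
  Vc <- V - rowMeans(V)
  vss <- rowSums(Vc^2)
  r <- as.vector(Vc %*% seedC) / sqrt(pmax(vss * seedSS, 1e-300))
  r[vss < 1e-24] <- 0 # constant voxel convention
  atanh(pmin(pmax(r, -0.999999), 0.999999))
}

# one-sample t from accumulated sums; finite by convention
groupT <- function(zsum, zsumsq, n) {
  zmean <- zsum / n
  zvar <- pmax((zsumsq - n * zmean^2) / (n - 1), 0)
  se <- sqrt(zvar / n)
  t <- ifelse(se > 1e-12, zmean / pmax(se, 1e-300),
    ifelse(abs(zmean) < 1e-12, 0, sign(zmean) * 1e6)
  )
  pmin(pmax(t, -1e6), 1e6)
}

#' Network intensity of a connectivity t-map
#'
#' Sums the positive and the negative t values separately within each of the
#' 14 hemisphere-specific cortical networks: the "intensity" of lesion
#' connectivity per network and sign.
#'
#' @param tmap 3D t-statistic array.
#' @param networks integer 3D label array (values 1..14) on the same grid.
#' @return data.frame with `network`, `positive` (sum of t > 0, >= 0) and
#'   `negative` (sum of t < 0, <= 0).
#' @export
networkIntensity <- function(tmap, networks) {
  if (!identical(dim(tmap), dim(networks))) stop("grids do not match")
  lab <- as.vector(networks)
  t <- as.vector(tmap)
  present <- tabulate(lab, nbins = N_NETWORKS)
  if (any(present == 0L)) {
    stop("network(s) with zero voxels: ", paste(which(present == 0L), collapse = ", "))
  }
  pos <- vapply(seq_len(N_NETWORKS), function(nw) sum(t[lab == nw & t > 0]), 0)
  neg <- vapply(seq_len(N_NETWORKS), function(nw) sum(t[lab == nw & t < 0]), 0)
  data.frame(network = seq_len(N_NETWORKS), positive = pos, negative = neg)
}

#' Sex contrast of network intensities
#'
#' For every (pattern, network, sign) cell, a two-sided two-sample t-test of
#' the male-connectome-based against the female-connectome-based intensity
#' values across variants, followed by Benjamini-Hochberg FDR correction
#' within each sign's family of 14 networks x number of patterns; flags at
#' adjusted p < 0.05. Cells where both groups are constant and equal get
#' p = 1.
#'
#' @param intensities data.frame with columns `pattern`, `variant`, `sex`,
#'   `network`, `positive`, `negative` (one row per pattern x variant x
#'   sex), as produced by [lnmAnalysis()].
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame keyed by (pattern, network, sign) with the t
#'   statistic, raw and BH-adjusted p, and significance flag.
#' @export
sexContrast <- function(intensities, alpha = 0.05) {
  need <- c("pattern", "variant", "sex", "network", "positive", "negative")
  stopifnot(all(need %in% colnames(intensities)))
  cells <- unique(intensities[, c("pattern", "network")])
  out <- list()
  for (sign in c("positive", "negative")) {
    res <- data.frame(
      pattern = cells$pattern, network = cells$network, sign = sign,
      t = NA_real_, p = NA_real_, stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(cells))) {
      sel <- intensities$pattern == cells$pattern[i] &
        intensities$network == cells$network[i]
      male <- intensities[sel & intensities$sex == "male", sign]
      female <- intensities[sel & intensities$sex == "female", sign]
      if (length(male) != length(female)) {
        stop("unequal variant counts between sexes for pattern ",
             cells$pattern[i], ", network ", cells$network[i])
      }
      res[i, c("t", "p")] <- safeWelch(male, female)
      if (!is.finite(res$t[i])) res$p[i] <- 0
    }
    res$p_adj <- p.adjust(res$p, method = "BH")
    res$significant <- res$p_adj < alpha
    out[[sign]] <- res
  }
  rbind(out$positive, out$negative)
}

#' Variant-based lesion network mapping of all patterns
#'
#' Full LNM stage: for each lesion pattern, samples region-subset variants
#' ([sampleVariants()]), computes each variant's seed-connectivity group
#' t-map against the male and the female normative connectome
#' ([lesionConnectivity()], vectorized across variants), summarizes network
#' intensities ([networkIntensity()]) and runs the sex contrast
#' ([sexContrast()]).
#'
#' @param patterns a [LesionPatternFit] (or a list of affiliated-region id
#'   vectors, one per pattern).
#' @param atlas the [AtlasSpec] providing region voxel support on the
#'   connectome grid.
#' @param connectomes list with elements `male` and `female`, each a list of
#'   4D subject arrays (as from [simulateConnectomes()]).
#' @param networks integer 14-network label array on the connectome grid.
#' @param nVariants variants per pattern (default 100).
#' @param seed master seed; per-pattern variant seeds are derived from it.
#' @param threshold affiliation threshold when `patterns` is a fit.
#' @param gsr apply global signal regression (default `TRUE`).
#' @return list with `intensities` (pattern x variant x sex x network table)
#'   and `contrasts` (the [sexContrast()] table).
#' @export
lnmAnalysis <- function(patterns, atlas, connectomes, networks,
                        nVariants = 100L, seed = 1L, threshold = 0.05,
                        gsr = TRUE) {
  stopifnot(is(atlas, "AtlasSpec"), all(c("male", "female") %in% names(connectomes)))
  affiliated <- if (is(patterns, "LesionPatternFit")) {
    lapply(seq_len(nrow(patterns@basis)), function(j) {
      affiliatedRegions(patterns, j, threshold)
    })
  } else {
    patterns
  }
  nPat <- length(affiliated)
  patSeeds <- deriveSeeds(seed, nPat)
  d <- dim(networks)
  lab <- as.vector(networks)

  # voxel membership masks per variant, stacked as a voxels x variants matrix
  variantMasks <- function(variants) {
    M <- matrix(FALSE, prod(d), length(variants))
    for (v in seq_along(variants)) {
      M[, v] <- as.vector(regionMask(atlas, variants[[v]]))
    }
    if (any(colSums(M) == 0)) stop("variant with empty seed mask")
    M
  }

  rows <- list()
  for (j in seq_len(nPat)) {
    variants <- sampleVariants(affiliated[[j]], nVariants, patSeeds[j])
    M <- variantMasks(variants)
    Mw <- sweep(M * 1, 2, colSums(M), `/`) # mask-mean weights
    for (sex in c("male", "female")) {
      subs <- connectomes[[sex]]
      n <- length(subs)
      zsum <- 0
      zsumsq <- 0
      for (s in seq_len(n)) {
        V <- matrix(subs[[s]], prod(d))
        z <- subjectSeedZMulti(V, Mw, gsr)
        zsum <- zsum + z
        zsumsq <- zsumsq + z^2
      }
      tmat <- groupT(zsum, zsumsq, n) # voxels x variants
      for (v in seq_len(nVariants)) {
        tv <- tmat[, v]
        rows[[length(rows) + 1L]] <- data.frame(
          pattern = j, variant = v, sex = sex, network = seq_len(N_NETWORKS),
          positive = vapply(seq_len(N_NETWORKS),
            function(nw) sum(tv[lab == nw & tv > 0]), 0
          ),
          negative = vapply(seq_len(N_NETWORKS),
            function(nw) sum(tv[lab == nw & tv < 0]), 0
          ),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  intensities <- do.call(rbind, rows)
  list(intensities = intensities, contrasts = sexContrast(intensities))
}

# Fisher-z seed connectivity of one subject against many seed-weight columns
# at once: V voxels x time, Mw voxels x variants column-normalized weights.
# Matches subjectSeedZ() column by column.
subjectSeedZMulti <- function(V, Mw, gsr) {
  nt <- ncol(V)
  if (gsr) {
    gs <- colMeans(V)
    gsc <- gs - mean(gs)
    denom <- sum(gsc^2)
    if (denom > 0) {
      beta <- (V %*% gsc) / denom
      V <- V - tcrossprod(beta, gsc)
    }
  }
  seeds <- crossprod(Mw, V) # variants x time
  seedsC <- seeds - rowMeans(seeds)
  seedSS <- rowSums(seedsC^2)
  if (any(seedSS < 1e-24)) {
    stop("zero-variance seed time series for variant ",
         paste(which(seedSS < 1e-24), collapse = ", "))
  }
  Vc <- V - rowMeans(V)
  vss <- rowSums(Vc^2)
  num <- Vc %*% t(seedsC) # voxels x variants
  r <- num / sqrt(pmax(outer(vss, seedSS), 1e-300))
  r[vss < 1e-24, ] <- 0
  atanh(pmin(pmax(r, -0.999999), 0.999999))
}
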