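#' Configuration for sex-specific normative connectome fixtures
#'
#' Describes small synthetic resting-state 4D datasets for lesion network
#' mapping: the grid is partitioned into 14 cortical networks (7 per
#' hemisphere: low-x half = left networks 1-7, high-x half = right networks
#' 8-14). Each network has a latent time series; every voxel's signal is its
#' network latent plus white noise. For female subjects, the latent amplitude
#' in network `n` is multiplied by `sexEffect[n]`, so `sexEffect = 2` in one
#' network raises its within-network correlation in the female set only.
#' The full-scale normative cohorts this emulates have 346 subjects per sex
#' (`FULLSCALE_SUBJECTS_PER_SEX`); the default is a desk-scale 20.
#'
#' @param nSubjectsPerSex subjects per sex (default 20).
#' @param dims 3D grid (default `c(20, 20, 10)`); must be large enough to
#'   hold all 14 networks.
#' @param nTimepoints time series length, >= 10 (default 60).
#' @param sexEffect length-14 per-network amplitude multiplier for female
#'   subjects (default all 1 = no sex difference).
#' @param latentSD,noiseSD amplitudes of the shared network signal and the
#'   voxel noise.
#' @param seed integer RNG seed.
#' @return a `connectomeConfig` list, including the `networks` label array.
#' @export
connectomeConfig <- function(nSubjectsPerSex = 20L,
                             dims = c(20L, 20L, 10L),
                             nTimepoints = 60L,
                             sexEffect = rep(1, N_NETWORKS),
                             latentSD = 1,
                             noiseSD = 1,
                             seed = 1L) {
  dims <- as.integer(dims)
  if (nTimepoints < 10L) stop("nTimepoints must be at least 10")
  stopifnot(length(sexEffect) == N_NETWORKS, all(is.finite(sexEffect)))
  networks <- networkLabelImage(dims)
  structure(
    list(
      nSubjectsPerSex = as.integer(nSubjectsPerSex), dims = dims,
      nTimepoints = as.integer(nTimepoints), sexEffect = sexEffect,
      latentSD = latentSD, noiseSD = noiseSD, seed = as.integer(seed),
      networks = networks
    ),
    class = "connectomeConfig"
  )
}

#' @rdname connectomeConfig
#' @export
FULLSCALE_SUBJECTS_PER_SEX <- 346L

#' 14-network hemisphere-specific label image
#'
#' Partitions a grid into 7 networks per hemisphere (left = networks 1-7 on
#' the low-x half, right = 8-14), by contiguous blocks in scan order.
#'
#' @param dims 3D grid dimensions.
#' @return integer 3D array with values 1..14.
#' @export
networkLabelImage <- function(dims) {
  dims <- as.integer(dims)
  if (prod(dims) < 10L * N_NETWORKS || dims[1] < 2L) {
    stop("grid too small to contain all 14 networks")
  }
  lab <- array(0L, dims)
  half <- dims[1] %/% 2L
  hemi <- list(seq_len(half), seq(half + 1L, dims[1]))
  for (h in 1:2) {
    vox <- which(slice.index(lab, 1) %in% hemi[[h]])
    grp <- cut(seq_along(vox), 7L, labels = FALSE)
    lab[vox] <- (h - 1L) * 7L + grp
  }
  lab
}

#' Generate sex-specific normative connectome fixtures
#'
#' Draws the synthetic 4D resting-state data described in
#' [connectomeConfig()] for a male and a female set of subjects.
#' Deterministic given the config seed.
#'
#' @param config a [connectomeConfig()].
#' @param dir if non-NULL, write 4D NIfTI files under `dir/male/` and
#'   `dir/female/` and return paths instead of arrays.
#' @return list with `male` and `female` (each a list of 4D arrays, voxel x
#'   time), `networks` (the label image) and `config`.
#' @export
simulateConnectomes <- function(config, dir = NULL) {
  stopifnot(inherits(config, "connectomeConfig"))
  d <- config$dims
  nt <- config$nTimepoints
  nets <- config$networks
  netIdx <- as.vector(nets)
  withSeed(config$seed, {
    sets <- list(male = NULL, female = NULL)
    for (sex in names(sets)) {
      amp <- if (sex == "female") config$sexEffect else rep(1, N_NETWORKS)
      subjects <- vector("list", config$nSubjectsPerSex)
      for (s in seq_len(config$nSubjectsPerSex)) {
        latents <- matrix(rnorm(N_NETWORKS * nt, sd = config$latentSD), N_NETWORKS, nt)
        latents <- latents * amp
        x <- latents[netIdx, , drop = FALSE] +
          matrix(rnorm(prod(d) * nt, sd = config$noiseSD), prod(d), nt)
        subjects[[s]] <- array(x, c(d, nt))
      }
      names(subjects) <- sprintf("%s%03d", substr(sex, 1, 1), seq_along(subjects))
      sets[[sex]] <- subjects
    }
    if (!is.null(dir)) {
      for (sex in names(sets)) {
        sub <- file.path(dir, sex)
        dir.create(sub, showWarnings = FALSE, recursive = TRUE)
        for (nm in names(sets[[sex]])) {
          RNifti::writeNifti(
            RNifti::asNifti(sets[[sex]][[nm]]),
            file.path(sub, paste0(nm, ".nii.gz"))
          )
        }
      }
    }
    list(male = sets$male, female = sets$female, networks = nets, config = config)
  })
}
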