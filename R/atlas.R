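#' Build a synthetic three-layer atlas on a small grid
#'
#' Constructs a synthetic [AtlasSpec] for testing and simulation: the grid is
#' split into a left (low x) and right (high x) hemisphere and, within each
#' hemisphere, into contiguous blocks of voxels forming 47 cortical regions,
#' 7 or 8 subcortical regions and 10 tracts (94 + 15 + 20 = 129 in total).
#' With `overlap = FALSE` (default) the three layers partition disjoint
#' z-slabs, so a voxel belongs to at most one region across all layers and
#' the lesion-mask round trip is exact. With `overlap = TRUE` the tract layer
#' is additionally painted over part of the cortical slab, producing voxels
#' labelled in two layers (as in real structural atlases, where a cortical
#' region and a white-matter tract can occupy the same normalized voxel).
#'
#' @param dims integer grid dimensions, default `c(22, 22, 12)`.
#' @param voxelVolume voxel volume in mm^3 (default 1, so volume in ml is
#'   voxel count / 1000).
#' @param overlap paint tracts over part of the cortical slab (see above).
#' @return an [AtlasSpec].
#' @examples
#' atlas <- simulateAtlas(c(16, 16, 9))
#' atlas
#' @export
simulateAtlas <- function(dims = c(22L, 22L, 12L), voxelVolume = 1,
                          overlap = FALSE) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= c(8L, 2L, 6L)))
  nz <- dims[3]
  # z-slabs: cortical on top, subcortical in the middle, tracts at the bottom
  zc <- seq_len(max(3L, round(nz * 0.5)))
  zs <- seq(max(zc) + 1L, max(zc) + max(1L, round(nz * 0.2)))
  zt <- seq(max(zs) + 1L, nz)
  if (length(zt) < 1L) stop("grid too small for three atlas layers")

  empty <- array(0L, dims)
  half <- dims[1] %/% 2L
  hemi <- list(L = seq_len(half), R = seq(half + 1L, dims[1]))

  fillLayer <- function(zslab, nPerHemi) {
    lay <- empty
    lab <- 0L
    for (h in names(hemi)) {
      vox <- as.matrix(expand.grid(x = hemi[[h]], y = seq_len(dims[2]), z = zslab))
      # stable voxel order, then contiguous chunks
      vox <- vox[order(vox[, "z"], vox[, "y"], vox[, "x"]), , drop = FALSE]
      n <- nPerHemi[[h]]
      sizes <- rep(nrow(vox) %/% n, n)
      extra <- nrow(vox) - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      idx <- 0L
      for (i in seq_len(n)) {
        lab <- lab + 1L
        take <- vox[idx + seq_len(sizes[i]), , drop = FALSE]
        lay[cbind(take[, "x"], take[, "y"], take[, "z"])] <- lab
        idx <- idx + sizes[i]
      }
    }
    lay
  }

  cortical <- fillLayer(zc, list(L = 47L, R = 47L))
  subcortical <- fillLayer(zs, list(L = 7L, R = 8L))
  tract <- fillLayer(zt, list(L = 10L, R = 10L))
  if (overlap) {
    # re-paint the tracts across both the tract slab and the lower cortical
    # slab so tract voxels coincide with cortical ones
    tract <- fillLayer(c(max(zc), zt), list(L = 10L, R = 10L))
  }

  hemiOf <- function(n, nLeft) ifelse(seq_len(n) <= nLeft, "L", "R")
  regions <- data.frame(
    region = seq_len(N_REGIONS),
    layer = rep(LAYER_NAMES, LAYER_SIZES),
    label = c(seq_len(94L), seq_len(15L), seq_len(20L)),
    name = c(
      sprintf("ctx%02d", seq_len(94L)),
      sprintf("sub%02d", seq_len(15L)),
      sprintf("wm%02d", seq_len(20L))
    ),
    hemisphere = c(hemiOf(94L, 47L), hemiOf(15L, 7L), hemiOf(20L, 10L)),
    stringsAsFactors = FALSE
  )

  affine <- diag(4)
  affine[1:3, 4] <- -dims / 2
  new("AtlasSpec",
    layers = list(cortical = cortical, subcortical = subcortical, tract = tract),
    regions = regions, voxelVolume = voxelVolume, affine = affine
  )
}

#' Discretize a probabilistic atlas layer
#'
#' Standard distributions of cortical/subcortical atlases are probabilistic
#' (one probability map per region). Voxel counting needs discrete labels:
#' each voxel is assigned the region with maximum probability, provided that
#' probability reaches `floor` (default 25%); voxels below the floor become
#' background (0).
#'
#' @param prob 4D array, x-y-z-region, of probabilities in `[0, 1]`
#'   (percent scales 0-100 are detected and rescaled).
#' @param floor minimum winning probability, default 0.25.
#' @return integer 3D label array.
#' @export
discretizeProbAtlas <- function(prob, floor = 0.25) {
  stopifnot(length(dim(prob)) == 4L)
  if (max(prob) > 1.5) prob <- prob / 100
  d <- dim(prob)
  flat <- matrix(prob, prod(d[1:3]), d[4])
  win <- max.col(flat, ties.method = "first")
  pmax_ <- flat[cbind(seq_len(nrow(flat)), win)]
  win[pmax_ < floor] <- 0L
  array(as.integer(win), d[1:3])
}

#' Voxel support of a set of regions
#'
#' Logical 3D mask of all voxels belonging to any of the given global region
#' ids (1..129) in their respective layers.
#'
#' @param atlas an [AtlasSpec].
#' @param regionIds global region ids.
#' @return logical 3D array.
#' @export
regionMask <- function(atlas, regionIds) {
  stopifnot(is(atlas, "AtlasSpec"))
  tab <- atlas@regions
  if (!all(regionIds %in% tab$region)) stop("unknown region id(s)")
  mask <- array(FALSE, dim(atlas@layers[[1]]))
  for (id in regionIds) {
    row <- tab[tab$region == id, ]
    mask <- mask | (atlas@layers[[row$layer]] == row$label)
  }
  mask
}

#' Number of voxels per region
#'
#' @param atlas an [AtlasSpec].
#' @return integer vector of length 129, named by region column name.
#' @export
regionSizes <- function(atlas) {
  stopifnot(is(atlas, "AtlasSpec"))
  tab <- atlas@regions
  sizes <- integer(nrow(tab))
  for (ly in LAYER_NAMES) {
    sel <- tab$layer == ly
    cnt <- tabulate(atlas@layers[[ly]], nbins = LAYER_SIZES[[ly]])
    sizes[sel] <- cnt[tab$label[sel]]
  }
  setNames(sizes, regionColumnNames(tab))
}

#' Write / read an atlas as NIfTI label images plus a JSON region table
#'
#' `writeAtlas` writes `cortical.nii.gz`, `subcortical.nii.gz`,
#' `tract.nii.gz` and `regions.json` into `dir`; `readAtlas` reads them back.
#'
#' @param atlas an [AtlasSpec].
#' @param dir directory.
#' @return `writeAtlas` the directory, invisibly; `readAtlas` an
#'   [AtlasSpec].
#' @export
writeAtlas <- function(atlas, dir) {
  stopifnot(is(atlas, "AtlasSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ly in LAYER_NAMES) {
    img <- RNifti::asNifti(atlas@layers[[ly]] + 0)
    RNifti::qform(img) <- structure(atlas@affine, code = 2L)
    RNifti::writeNifti(img, file.path(dir, paste0(ly, ".nii.gz")))
  }
  jsonlite::write_json(
    list(
      regions = atlas@regions, voxelVolume = atlas@voxelVolume,
      affine = as.vector(atlas@affine)
    ),
    file.path(dir, "regions.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "regions.json"), simplifyVector = TRUE)
  layers <- lapply(setNames(LAYER_NAMES, LAYER_NAMES), function(ly) {
    img <- RNifti::readNifti(file.path(dir, paste0(ly, ".nii.gz")))
    array(as.integer(round(as.array(img))), dim(img))
  })
  new("AtlasSpec",
    layers = layers,
    regions = as.data.frame(meta$regions, stringsAsFactors = FALSE),
    voxelVolume = meta$voxelVolume,
    affine = matrix(unlist(meta$affine), 4, 4)
  )
}
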