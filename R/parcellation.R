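#' Parcellate a binary lesion mask against the three-layer atlas
#'
#' Counts, for every atlas region, the number of voxels that are lesioned
#' (mask value 1) and carry that region's label. The three layers are counted
#' independently, so a voxel labelled both in the cortical and in the tract
#' layer contributes to both regions. No resampling is performed: the mask
#' grid and affine must match the atlas exactly (affine elementwise within
#' 1e-4).
#'
#' @param mask binary 3D array or NIfTI image (values 0/1).
#' @param atlas an [AtlasSpec].
#' @return named integer vector of length 129 (columns ordered cortical,
#'   subcortical, tract) with attribute `volume`, the lesion volume in ml.
#' @examples
#' atlas <- simulateAtlas(c(16, 16, 9))
#' mask <- regionMask(atlas, 7)
#' parcellateLesion(mask, atlas)[7]
#' @export
parcellateLesion <- function(mask, atlas) {
  stopifnot(is(atlas, "AtlasSpec"))
  maskAffine <- NULL
  if (inherits(mask, "niftiImage")) {
    maskAffine <- structure(RNifti::xform(mask), dimnames = NULL)
    mask <- as.array(mask)
  }
  if (is.logical(mask)) mask <- mask + 0L
  if (!identical(dim(mask), dim(atlas@layers[[1]]))) {
    stop(sprintf(
      "mask grid %s does not match atlas grid %s",
      paste(dim(mask), collapse = "x"),
      paste(dim(atlas@layers[[1]]), collapse = "x")
    ))
  }
  if (!is.null(maskAffine) &&
      any(abs(maskAffine - atlas@affine) > 1e-4)) {
    stop(
      "mask affine does not match atlas affine:\nmask:\n",
      paste(capture.output(print(maskAffine)), collapse = "\n"),
      "\natlas:\n",
      paste(capture.output(print(atlas@affine)), collapse = "\n")
    )
  }
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) {
    stop("mask is not binary: values ", paste(head(setdiff(vals, 0:1)), collapse = ", "))
  }
  lesioned <- mask == 1
  tab <- atlas@regions
  counts <- integer(N_REGIONS)
  for (ly in LAYER_NAMES) {
    sel <- tab$layer == ly
    cnt <- tabulate(atlas@layers[[ly]][lesioned], nbins = LAYER_SIZES[[ly]])
    counts[sel] <- cnt[tab$label[sel]]
  }
  names(counts) <- regionColumnNames(tab)
  attr(counts, "volume") <- sum(lesioned) * atlas@voxelVolume / 1000
  counts
}

#' Assemble per-patient parcellation rows into a RegionLesionMatrix
#'
#' @param rows named list (names = patient ids) of vectors as returned by
#'   [parcellateLesion()], all from the same atlas.
#' @param atlas the [AtlasSpec] the rows were computed with.
#' @return a [RegionLesionMatrix]; patients ordered by id.
#' @export
assembleLesionMatrix <- function(rows, atlas) {
  stopifnot(is(atlas, "AtlasSpec"))
  ids <- names(rows)
  if (length(rows) && (is.null(ids) || any(!nzchar(ids)))) {
    stop("rows must be named by patient id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate patient id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cn <- regionColumnNames(atlas@regions)
  counts <- matrix(0L, length(rows), N_REGIONS, dimnames = list(ids, cn))
  volume <- numeric(length(rows))
  ord <- if (length(rows)) order(ids) else integer(0)
  for (i in seq_along(rows)) {
    counts[i, ] <- as.integer(rows[[i]])
    v <- attr(rows[[i]], "volume")
    volume[i] <- if (is.null(v)) NA_real_ else v
  }
  counts <- counts[ord, , drop = FALSE]
  volume <- volume[ord]
  new("RegionLesionMatrix",
    counts = counts, volume = volume,
    voxelVolume = atlas@voxelVolume
  )
}

#' Parcellate a directory (or list) of lesion masks
#'
#' @param masks either a character vector of NIfTI paths (patient id = file
#'   name without extension) or a named list of 3D arrays.
#' @param atlas an [AtlasSpec].
#' @return a [RegionLesionMatrix].
#' @export
parcellateCohort <- function(masks, atlas) {
  if (is.character(masks)) {
    paths <- masks
    ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
    masks <- lapply(paths, RNifti::readNifti)
    names(masks) <- ids
  }
  rows <- lapply(masks, parcellateLesion, atlas = atlas)
  assembleLesionMatrix(rows, atlas)
}

#' Sex comparison of lesion anatomy
#'
#' Region-wise comparison of lesion load between men and women: per region a
#' Welch two-sample t-test on lesioned-voxel counts and a two-sided Fisher's
#' exact test on the affected / not-affected dichotomy, each Bonferroni
#' corrected over the family of 129 regions; plus a whole-brain total lesion
#' volume t-test. Regions with identical counts in both groups (zero
#' between-group variance) get t = 0, p = 1.
#'
#' @param lesions a [RegionLesionMatrix].
#' @param sex character vector (`"male"` / `"female"`) or 0/1 female
#'   indicator aligned with the patients.
#' @return list with `regions` (data.frame: region, t, p_t, p_t_bonf,
#'   fisher odds table counts, p_fisher, p_fisher_bonf) and `volume`
#'   (volume t-test summary).
#' @export
compareLesionAnatomy <- function(lesions, sex) {
  stopifnot(is(lesions, "RegionLesionMatrix"))
  female <- normalizeSexVector(sex, nrow(lesions@counts))
  if (sum(female == 1L) < 2L || sum(female == 0L) < 2L) {
    stop("need at least two patients of each sex")
  }
  X <- lesions@counts
  res <- data.frame(
    region = colnames(X), t = NA_real_, p_t = NA_real_,
    affected_female = NA_integer_, affected_male = NA_integer_,
    p_fisher = NA_real_, stringsAsFactors = FALSE
  )
  f <- female == 1L
  for (j in seq_len(ncol(X))) {
    res[j, c("t", "p_t")] <- safeWelch(X[f, j], X[!f, j])
    aff <- X[, j] > 0
    tab <- matrix(c(sum(aff[f]), sum(!aff[f]), sum(aff[!f]), sum(!aff[!f])), 2)
    res$affected_female[j] <- tab[1, 1]
    res$affected_male[j] <- tab[1, 2]
    res$p_fisher[j] <- fisher.test(tab)$p.value
  }
  res$p_t_bonf <- pmin(1, res$p_t * ncol(X))
  res$p_fisher_bonf <- pmin(1, res$p_fisher * ncol(X))
  vol <- safeWelch(lesions@volume[f], lesions@volume[!f])
  list(
    regions = res,
    volume = data.frame(
      mean_female = mean(lesions@volume[f]), mean_male = mean(lesions@volume[!f]),
      t = vol[1], p = vol[2]
    )
  )
}

# Welch t-test that tolerates degenerate (zero-variance) inputs:
# equal constant groups -> t = 0, p = 1
safeWelch <- function(a, b) {
  if (var(a) + var(b) < .Machine$double.eps) {
    if (abs(mean(a) - mean(b)) < .Machine$double.eps) {
      return(c(0, 1))
    }
    return(c(sign(mean(a) - mean(b)) * Inf, 0))
  }
  tt <- t.test(a, b)
  c(unname(tt$statistic), tt$p.value)
}

normalizeSexVector <- function(sex, n) {
  if (length(sex) != n) stop("sex vector length does not match patients")
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    bad <- setdiff(unique(sex), c("male", "female"))
    if (length(bad)) {
      stop("sex labels outside the binary coding 'male'/'female': ",
           paste(bad, collapse = ", "))
    }
    return(as.integer(sex == "female"))
  }
  if (!all(sex %in% c(0, 1))) stop("numeric sex must be a 0/1 female indicator")
  as.integer(sex)
}

#' Write / read a RegionLesionMatrix as CSV
#'
#' The CSV has a `patient_id` column, one column per region named
#' `<layer>_<label>_<name>`, and a final `volume_ml` column.
#'
#' @param lesions a [RegionLesionMatrix].
#' @param path CSV path.
#' @param voxelVolume voxel volume in mm^3 assumed when reading.
#' @return `readLesionMatrix` a [RegionLesionMatrix].
#' @export
writeLesionMatrix <- function(lesions, path) {
  stopifnot(is(lesions, "RegionLesionMatrix"))
  df <- data.frame(
    patient_id = rownames(lesions@counts),
    lesions@counts,
    volume_ml = lesions@volume,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLesionMatrix
#' @export
readLesionMatrix <- function(path, voxelVolume = 1) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(colnames(df), c("patient_id", "volume_ml")), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- as.character(df$patient_id)
  new("RegionLesionMatrix",
    counts = counts, volume = df$volume_ml,
    voxelVolume = voxelVolume
  )
}
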