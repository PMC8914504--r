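#' Fit the non-negative lesion-pattern factorization
#'
#' Factorizes the patients x regions lesion-count matrix `X` into `k`
#' non-negative lesion patterns, `X ~ W H`, minimizing the Frobenius
#' reconstruction error by multiplicative updates (Lee-Seung). The objective
#' is checked to be non-increasing at every iteration; iteration stops when
#' the relative improvement falls below `tol` (default 1e-6) or after
#' `maxIter` (default 2000) iterations. Initialization is non-negative double
#' SVD (NNDSVD) with zeros replaced by small seeded uniform noise, so the fit
#' is deterministic given the seed. After fitting, each basis row is divided
#' by its maximum loading and the inverse scale is absorbed into `W`.
#'
#' Raw voxel counts are used unscaled: standardizing regions would destroy
#' the non-negativity and volume semantics the factorization relies on.
#'
#' @param X a [RegionLesionMatrix] or a non-negative numeric matrix
#'   (patients x regions).
#' @param k number of patterns (default 10).
#' @param seed integer seed for initialization noise.
#' @param tol,maxIter stopping rule.
#' @return a [LesionPatternFit].
#' @examples
#' sim <- simulateCohort(cohortConfig(nPatients = 120, seed = 3))
#' fit <- fitNMF(sim$lesions, k = 10, seed = 1)
#' fit
#' @export
fitNMF <- function(X, k = 10L, seed = 1L, tol = 1e-6, maxIter = 2000L) {
  if (is(X, "RegionLesionMatrix")) X <- X@counts
  X <- as.matrix(X) * 1
  if (any(X < 0)) stop("X must be non-negative")
  if (k > min(dim(X))) {
    stop(sprintf("k = %d exceeds the rank bound min(%d, %d)", k, nrow(X), ncol(X)))
  }
  ids <- rownames(X)
  init <- withSeed(seed, nndsvdInit(X, k))
  W <- init$W
  H <- init$H
  eps <- 1e-12
  obj <- numeric(0)
  lastErr <- Inf
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    # Lee-Seung multiplicative updates for Frobenius loss
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    err <- sqrt(sum((X - W %*% H)^2))
    if (length(obj) && err > obj[length(obj)] + 1e-8 * (1 + obj[length(obj)])) {
      stop("multiplicative-update objective increased; this should not happen")
    }
    obj <- c(obj, err)
    if (is.finite(lastErr) && (lastErr - err) < tol * max(lastErr, eps)) {
      converged <- TRUE
      break
    }
    lastErr <- err
  }
  # max-normalize basis rows, absorb scale into W
  scales <- apply(H, 1, max)
  if (any(scales <= 0)) {
    # degenerate empty pattern: keep a tiny uniform row so validity holds
    for (j in which(scales <= 0)) H[j, ] <- 1e-8
    scales <- apply(H, 1, max)
  }
  H <- H / scales
  W <- sweep(W, 2, scales, `*`)
  dimnames(H) <- list(sprintf("pattern%02d", seq_len(k)), colnames(X))
  dimnames(W) <- list(ids, rownames(H))
  new("LesionPatternFit",
    basis = H, expression = W, scales = unname(scales),
    objective = obj, iterations = it, converged = converged,
    seed = as.integer(seed)
  )
}

# Non-negative double SVD initialization (Boutsidis & Gallopoulos 2008),
# variant "ar": zero entries replaced with small uniform noise (uses the
# caller's seeded RNG state)
nndsvdInit <- function(X, k) {
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k)
  H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]
      v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        W[, j] <- sqrt(s$d[j] * npos) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(s$d[j] * npos) * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        W[, j] <- sqrt(s$d[j] * nneg) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(s$d[j] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  m <- mean(X)
  zw <- W <= 0
  zh <- H <= 0
  W[zw] <- runif(sum(zw), 0, m / 100 + 1e-9)
  H[zh] <- runif(sum(zh), 0, m / 100 + 1e-9)
  list(W = W, H = H)
}

#' Score lesion data against a fixed pattern basis
#'
#' Projects new patients onto an existing basis by per-patient non-negative
#' least squares: for each row `x`, minimizes `||x - w H||^2` over `w >= 0`
#' (cyclic coordinate descent on the normal equations, run to a 1e-12
#' coordinate-change tolerance).
#'
#' @param X new data: [RegionLesionMatrix] or non-negative matrix with the
#'   same number of columns as the basis.
#' @param fit a [LesionPatternFit] (or a bare k x regions basis matrix).
#' @return patients x k non-negative expression matrix.
#' @export
nmfTransform <- function(X, fit) {
  H <- if (is(fit, "LesionPatternFit")) fit@basis else as.matrix(fit)
  if (is(X, "RegionLesionMatrix")) X <- X@counts
  X <- as.matrix(X) * 1
  if (any(X < 0)) stop("X must be non-negative")
  if (ncol(X) != ncol(H)) {
    stop(sprintf("X has %d columns but the basis has %d", ncol(X), ncol(H)))
  }
  G <- H %*% t(H)
  W <- matrix(0, nrow(X), nrow(H))
  for (i in seq_len(nrow(X))) {
    W[i, ] <- nnlsCoordinate(G, as.vector(H %*% X[i, ]))
  }
  dimnames(W) <- list(rownames(X), rownames(H))
  W
}

# solve min_{w>=0} 1/2 w'Gw - b'w by cyclic coordinate descent
nnlsCoordinate <- function(G, b, maxSweeps = 1000L, tol = 1e-12) {
  k <- length(b)
  w <- rep(0, k)
  g <- -b # gradient = Gw - b
  for (sweep in seq_len(maxSweeps)) {
    delta <- 0
    for (j in seq_len(k)) {
      if (G[j, j] <= 0) next
      wj <- max(0, w[j] - g[j] / G[j, j])
      d <- wj - w[j]
      if (d != 0) {
        g <- g + G[, j] * d
        w[j] <- wj
        delta <- max(delta, abs(d))
      }
    }
    if (delta < tol) break
  }
  w
}

#' Regions affiliated with a lesion pattern
#'
#' A region is affiliated with a pattern if its max-normalized loading
#' exceeds `threshold` (default 0.05, i.e. at least 5% of the pattern's peak
#' loading). Returned in descending loading order.
#'
#' @param fit a [LesionPatternFit].
#' @param pattern pattern index in 1..k.
#' @param threshold loading threshold (default 0.05).
#' @return integer vector of global region ids (column indices), named by
#'   region, in descending loading order.
#' @export
affiliatedRegions <- function(fit, pattern, threshold = 0.05) {
  stopifnot(is(fit, "LesionPatternFit"))
  if (pattern < 1 || pattern > nrow(fit@basis)) {
    stop("pattern must be in 1..", nrow(fit@basis))
  }
  load <- fit@basis[pattern, ]
  sel <- which(load > threshold)
  if (!length(sel)) {
    stop(sprintf(
      "no region exceeds the affiliation threshold %g for pattern %d; lower the threshold",
      threshold, pattern
    ))
  }
  sel[order(load[sel], decreasing = TRUE)]
}

#' Hemisphere attribution of each pattern
#'
#' Attributes each pattern to the hemisphere carrying the larger summed
#' loading over that hemisphere's regions; near-ties (within `tieband` of
#' equality) are labelled bilateral.
#'
#' @param fit a [LesionPatternFit].
#' @param regions region table of the matching [AtlasSpec] (column
#'   `hemisphere` with `"L"`/`"R"`).
#' @param tieband relative band treated as bilateral (default 0.1).
#' @return character vector (`"L"`, `"R"` or `"B"`) per pattern.
#' @export
patternHemisphere <- function(fit, regions, tieband = 0.1) {
  stopifnot(is(fit, "LesionPatternFit"), nrow(regions) == ncol(fit@basis))
  left <- rowSums(fit@basis[, regions$hemisphere == "L", drop = FALSE])
  right <- rowSums(fit@basis[, regions$hemisphere == "R", drop = FALSE])
  tot <- left + right
  out <- ifelse(left > right, "L", "R")
  out[abs(left - right) <= tieband * tot] <- "B"
  out
}

#' Greedy cosine matching of fitted patterns to reference patterns
#'
#' Utility for recovery checks: greedily pairs fitted basis rows with
#' reference rows by descending cosine similarity.
#'
#' @param basis,reference matrices with equal numbers of columns.
#' @return data.frame with `fitted`, `reference`, `cosine`.
#' @export
matchPatterns <- function(basis, reference) {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  k <- nrow(basis)
  sim <- matrix(0, k, nrow(reference))
  for (i in seq_len(k)) {
    for (j in seq_len(nrow(reference))) sim[i, j] <- cosine(basis[i, ], reference[j, ])
  }
  out <- data.frame(fitted = integer(0), reference = integer(0), cosine = numeric(0))
  for (step in seq_len(min(k, nrow(reference)))) {
    ij <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(
      fitted = ij[1], reference = ij[2], cosine = sim[ij[1], ij[2]]
    ))
    sim[ij[1], ] <- -Inf
    sim[, ij[2]] <- -Inf
  }
  out[order(out$fitted), ]
}
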