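# Internal numeric helpers shared across modules.

# Deterministic per-patient seed derived from a master seed and a patient id;
# independent of cohort ordering. Kept within 32-bit integer range.
patientSeed <- function(masterSeed, patientId, offset = 0L) {
    h <- sum(utf8ToInt(as.character(patientId)) * seq_along(utf8ToInt(as.character(patientId))))
    as.integer((as.numeric(masterSeed) + 1009 * h + 97 * offset) %% 2147483647)
}

#' 3D Euclidean distance transform
#'
#' Exact anisotropic Euclidean distance (mm) from every foreground voxel to
#' the nearest background voxel inside the volume; background voxels map to
#' 0. Computed with the separable lower-envelope algorithm.
#'
#' @param mask 3D binary array or [ImageVolume-class].
#' @param spacing voxel spacing (mm); taken from the volume if given one.
#' @return numeric 3D array of distances (mm).
#' @export
edt3d <- function(mask, spacing = c(1, 1, 1)) {
    if (is(mask, "ImageVolume")) {
        spacing <- mask@spacing
        mask <- mask@data
    }
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    d <- dim(mask)
    out <- .edt3d_cpp(as.integer(mask != 0), as.integer(d), as.numeric(spacing))
    array(out, d)
}

# Apply an n x n matrix along one axis of a 3D array (separable filtering).
sepApply <- function(arr, axis, M) {
    d <- dim(arr)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- M %*% matrix(a, nrow = da[1])
    a <- array(a, da)
    aperm(a, order(perm))
}

# Truncated, renormalized 1D Gaussian kernel matrix (n x n) for smoothing
# along an axis with voxel step `h` (mm) and sd `sigma` (mm).
gaussKernelMatrix <- function(n, h, sigma) {
    if (sigma <= 0) return(diag(n))
    x <- (seq_len(n) - 1) * h
    K <- exp(-outer(x, x, "-")^2 / (2 * sigma^2))
    K / rowSums(K)
}

# Smooth a 3D array with an isotropic (in mm) Gaussian.
gaussSmooth3d <- function(arr, spacing, sigmaMm) {
    d <- dim(arr)
    for (ax in 1:3)
        arr <- sepApply(arr, ax, gaussKernelMatrix(d[ax], spacing[ax], sigmaMm))
    arr
}

# Moving box sum of half-width r along every axis, zero-padded at the volume
# boundary. Used by the binary median (majority) filter.
boxSum3d <- function(arr, r) {
    bandMatrix <- function(n) {
        M <- matrix(0, n, n)
        for (o in -r:r) {
            i <- seq_len(n)
            j <- i + o
            ok <- j >= 1 & j <= n
            M[cbind(i[ok], j[ok])] <- 1
        }
        M
    }
    d <- dim(arr)
    for (ax in 1:3) arr <- sepApply(arr, ax, bandMatrix(d[ax]))
    arr
}

# Smooth unit-variance random field on a grid: Gaussian-filtered white noise,
# rescaled to sd 1. Draws dim-many normals from the current RNG stream.
smoothNoiseField <- function(dm, spacing, sigmaMm) {
    f <- array(stats::rnorm(prod(dm)), dm)
    f <- gaussSmooth3d(f, spacing, sigmaMm)
    s <- stats::sd(f)
    if (s < .Machine$double.eps) f else f / s
}

# 0-based voxel index triples for every voxel of a grid, x fastest (matches
# R array linear order).
gridVoxelIndices <- function(dm) {
    cbind(
        rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
        rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
        rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2]))
}

# Row-wise ascending sort of a numeric matrix (vectorised).
rowSortMatrix <- function(m) {
    matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
}
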