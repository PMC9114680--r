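# Geometry and sampling for ImageVolume objects.

#' @describeIn imageVolume voxel spacing (mm).
#' @param x an `ImageVolume`.
#' @export
spacing <- function(x) x@spacing

#' @describeIn imageVolume world coordinate (mm) of the first voxel centre.
#' @export
origin <- function(x) x@origin

#' @describeIn imageVolume the voxel data array.
#' @export
voxelData <- function(x) x@data

setMethod("dim", "ImageVolume", function(x) dim(x@data))

# World extent of the grid (voxel edges, not centres): the field of view.
fovExtent <- function(vol) {
    lo <- vol@origin - vol@spacing / 2
    hi <- vol@origin + (dim(vol@data) - 1) * vol@spacing + vol@spacing / 2
    rbind(lower = lo, upper = hi)
}

# World coordinates (mm) of 0-based voxel indices (n x 3 matrix).
voxelToWorld <- function(vol, idx0) {
    sweep(sweep(idx0, 2, vol@spacing, "*"), 2, vol@origin, "+")
}

# Continuous 0-based voxel coordinates of world points.
worldToVoxel <- function(vol, pts) {
    sweep(sweep(pts, 2, vol@origin, "-"), 2, vol@spacing, "/")
}

# A grid whose FOV is centred on `center` with `dm` voxels at `spacing`.
centeredOrigin <- function(dm, spacing, center = c(0, 0, 0)) {
    center - (dm - 1) * spacing / 2
}

#' Rigid transform parameters
#'
#' A rigid transform is `T(x) = R (x - center) + center + translation` with
#' `R = Rz(rz) Ry(ry) Rx(rx)` built from rotation angles in degrees.
#'
#' @param translation length-3 translation (mm).
#' @param rotation length-3 rotation angles (deg) about x, y, z.
#' @param center rotation centre (mm).
#' @return list with class "rigidTransform".
#' @export
rigidTransform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
    structure(list(translation = as.numeric(translation),
                   rotation = as.numeric(rotation),
                   center = as.numeric(center)),
              class = "rigidTransform")
}

rotationMatrix <- function(rotDeg) {
    r <- rotDeg * pi / 180
    cx <- cos(r[1]); sx <- sin(r[1])
    cy <- cos(r[2]); sy <- sin(r[2])
    cz <- cos(r[3]); sz <- sin(r[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to world points
#' @param pts n x 3 matrix of world points (mm).
#' @param tf a [rigidTransform()].
#' @return transformed n x 3 matrix.
#' @export
transformPoints <- function(pts, tf) {
    R <- rotationMatrix(tf$rotation)
    sweep(sweep(pts, 2, tf$center, "-") %*% t(R), 2,
          tf$center + tf$translation, "+")
}

#' Invert a rigid transform
#' @param tf a [rigidTransform()].
#' @return the inverse transform (same rotation centre).
#' @export
invertRigid <- function(tf) {
    R <- rotationMatrix(tf$rotation)
    # inverse rotation matrix is t(R); recover its angles (ZYX convention)
    Ri <- t(R)
    ry <- asin(pmin(1, pmax(-1, -Ri[3, 1])))
    rx <- atan2(Ri[3, 2], Ri[3, 3])
    rz <- atan2(Ri[2, 1], Ri[1, 1])
    structure(list(translation = as.numeric(-(Ri %*% tf$translation)),
                   rotation = c(rx, ry, rz) * 180 / pi,
                   center = tf$center),
              class = "rigidTransform")
}

isIdentityTransform <- function(tf) {
    all(abs(tf$translation) < 1e-12) && all(abs(tf$rotation) < 1e-12)
}

# Precompute trilinear interpolation geometry (corner linear indices and
# weights) of world points on a volume's grid. Shared across all channels of
# a sequence so resampling pays the geometry cost once.
trilinearCoeffs <- function(vol, pts) {
    d <- dim(vol@data)
    u <- worldToVoxel(vol, pts)
    bad <- u[, 1] < 0 | u[, 1] > d[1] - 1 |
           u[, 2] < 0 | u[, 2] > d[2] - 1 |
           u[, 3] < 0 | u[, 3] > d[3] - 1
    for (a in 1:3) u[, a] <- pmin(pmax(u[, a], 0), d[a] - 1)
    f0 <- floor(u)
    w <- u - f0
    i0 <- f0 + 1  # 1-based lower corner
    i1x <- pmin(f0[, 1] + 2, d[1]); i1y <- pmin(f0[, 2] + 2, d[2])
    i1z <- pmin(f0[, 3] + 2, d[3])
    nxy <- d[1] * d[2]
    lin <- function(ix, iy, iz) (iz - 1) * nxy + (iy - 1) * d[1] + ix
    idx <- cbind(lin(i0[,1], i0[,2], i0[,3]), lin(i1x, i0[,2], i0[,3]),
                 lin(i0[,1], i1y,    i0[,3]), lin(i1x, i1y,    i0[,3]),
                 lin(i0[,1], i0[,2], i1z),    lin(i1x, i0[,2], i1z),
                 lin(i0[,1], i1y,    i1z),    lin(i1x, i1y,    i1z))
    wt <- cbind((1-w[,1])*(1-w[,2])*(1-w[,3]), w[,1]*(1-w[,2])*(1-w[,3]),
                (1-w[,1])*w[,2]*(1-w[,3]),     w[,1]*w[,2]*(1-w[,3]),
                (1-w[,1])*(1-w[,2])*w[,3],     w[,1]*(1-w[,2])*w[,3],
                (1-w[,1])*w[,2]*w[,3],         w[,1]*w[,2]*w[,3])
    list(idx = idx, wt = wt, bad = bad)
}

applyTrilinear <- function(coef, dat) {
    v <- numeric(nrow(coef$idx))
    for (k in 1:8) v <- v + coef$wt[, k] * dat[coef$idx[, k]]
    v
}

#' Sample a volume at world points by trilinear interpolation
#'
#' @param vol an [ImageVolume-class].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param outside "clamp" replicates the nearest edge voxel; "na" returns NA
#'   for points outside the grid.
#' @return numeric vector of interpolated values.
#' @export
sampleTrilinear <- function(vol, pts, outside = c("clamp", "na")) {
    outside <- match.arg(outside)
    coef <- trilinearCoeffs(vol, pts)
    v <- applyTrilinear(coef, vol@data)
    if (outside == "na") v[coef$bad] <- NA_real_
    v
}

# Nearest-neighbour sampling (for masks).
sampleNearest <- function(vol, pts, outside = 0) {
    d <- dim(vol@data)
    u <- round(worldToVoxel(vol, pts))
    bad <- u[, 1] < 0 | u[, 1] > d[1] - 1 |
           u[, 2] < 0 | u[, 2] > d[2] - 1 |
           u[, 3] < 0 | u[, 3] > d[3] - 1
    for (a in 1:3) u[, a] <- pmin(pmax(u[, a], 0), d[a] - 1)
    v <- vol@data[u[, 3] * d[1] * d[2] + u[, 2] * d[1] + u[, 1] + 1]
    v[bad] <- outside
    v
}

# The analysis grid implied by a RoiBox: dim, origin (voxel centres), spacing.
boxGrid <- function(box) {
    n <- box@indexUpper
    list(dim = n, spacing = rep(box@spacing, 3),
         origin = box@lowerMm + box@spacing / 2)
}

# Resample a volume onto the RoiBox analysis grid; `tf` maps analysis-grid
# world points to the moving volume's sampling positions. `coef` may carry
# precomputed trilinear coefficients (shared across a sequence's channels).
resampleToBox <- function(vol, box, tf = NULL,
                          interpolation = c("linear", "nearest"),
                          coef = NULL) {
    interpolation <- match.arg(interpolation)
    g <- boxGrid(box)
    v <- if (interpolation == "linear" && !is.null(coef)) {
        applyTrilinear(coef, vol@data)
    } else {
        pts <- voxelToWorld(imageVolume(array(0, g$dim), g$spacing, g$origin),
                            gridVoxelIndices(g$dim))
        if (!is.null(tf) && !isIdentityTransform(tf))
            pts <- transformPoints(pts, tf)
        if (interpolation == "linear") sampleTrilinear(vol, pts, "clamp")
        else sampleNearest(vol, pts)
    }
    imageVolume(array(v, g$dim), g$spacing, g$origin, vol@channel)
}

# Trilinear coefficients of the box grid points (optionally transformed)
# on a moving volume's grid.
boxCoeffs <- function(vol, box, tf = NULL) {
    g <- boxGrid(box)
    pts <- voxelToWorld(imageVolume(array(0, g$dim), g$spacing, g$origin),
                        gridVoxelIndices(g$dim))
    if (!is.null(tf) && !isIdentityTransform(tf)) pts <- transformPoints(pts, tf)
    trilinearCoeffs(vol, pts)
}

# Same grid (dim, spacing, origin) check for metric operations.
sameGrid <- function(a, b, tol = 1e-6) {
    identical(dim(a@data), dim(b@data)) &&
        all(abs(a@spacing - b@spacing) < tol) &&
        all(abs(a@origin - b@origin) < tol)
}
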