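# Evaluation measures: Dice overlap and mean symmetric surface distance.

asMaskVolume <- function(x) {
    if (is(x, "ImageVolume")) x
    else imageVolume((x != 0) * 1, c(1, 1, 1), c(0, 0, 0))
}

#' Sorensen-Dice similarity coefficient
#'
#' `DICE = 2 |P intersect G| / (|P| + |G|)`, 1 for perfect overlap.
#'
#' @param p,g binary masks ([ImageVolume-class] or 3D arrays) on the same
#'   grid; `g` (the ground truth) must be non-empty.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(p, g) {
    p <- asMaskVolume(p)
    g <- asMaskVolume(g)
    if (!sameGrid(p, g)) stop("masks must share a grid")
    np <- sum(p@data != 0)
    ng <- sum(g@data != 0)
    if (ng == 0) stop("ground-truth mask is empty")
    2 * sum(p@data != 0 & g@data != 0) / (np + ng)
}

#' Surface voxels of a mask
#'
#' Mask voxels with at least one face-adjacent (6-connectivity) background
#' neighbour; the volume boundary counts as background.
#'
#' @param mask non-empty binary mask ([ImageVolume-class] or 3D array).
#' @return A [SurfaceVoxelSet-class] (0-based indices and voxel-centre
#'   world coordinates in mm).
#' @export
surfaceVoxels <- function(mask) {
    mask <- asMaskVolume(mask)
    m <- mask@data != 0
    if (!any(m)) stop("mask is empty")
    d <- dim(m)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
    interior <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] &
                pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] &
                pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1), drop = FALSE] &
                pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1), drop = FALSE] &
                pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3], drop = FALSE] &
                pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2), drop = FALSE]
    surf <- m & !interior
    idx <- which(surf, arr.ind = TRUE) - 1L
    new("SurfaceVoxelSet", voxels = unname(idx),
        coordsMm = voxelToWorld(mask, idx), count = nrow(idx))
}

# Minimal distance from each row of a to the point set b (chunked; squared
# distances formed from explicit coordinate differences so coincident points
# give exactly zero).
minDistances <- function(a, b, chunk = 512L) {
    out <- numeric(nrow(a))
    for (s in seq(1L, nrow(a), by = chunk)) {
        e <- min(s + chunk - 1L, nrow(a))
        ach <- a[s:e, , drop = FALSE]
        d2 <- outer(ach[, 1], b[, 1], "-")^2 +
              outer(ach[, 2], b[, 2], "-")^2 +
              outer(ach[, 3], b[, 3], "-")^2
        out[s:e] <- sqrt(apply(d2, 1, min))
    }
    out
}

#' Mean symmetric surface distance
#'
#' `MSD = (sum_i d(i, G->P) + sum_i d(i, P->G)) / (N_G + N_P)`, where
#' `d(i, A->B)` is the minimal 3D Euclidean distance (mm) from surface voxel
#' `i` of A to the surface of B and `N` counts surface voxels. Distances are
#' measured between voxel centres in world coordinates, so anisotropic grids
#' are handled.
#'
#' @param p,g non-empty binary masks on the same grid.
#' @return MSD in mm. Empty masks raise an error of class
#'   `"mpMRIsegEmptyMask"` (the metric is undefined, not zero).
#' @export
msd <- function(p, g) {
    p <- asMaskVolume(p)
    g <- asMaskVolume(g)
    if (!sameGrid(p, g)) stop("masks must share a grid")
    if (!any(p@data != 0) || !any(g@data != 0))
        stop(structure(class = c("mpMRIsegEmptyMask", "error", "condition"),
                       list(message = "MSD undefined for an empty mask",
                            call = sys.call())))
    sp <- surfaceVoxels(p)
    sg <- surfaceVoxels(g)
    (sum(minDistances(sg@coordsMm, sp@coordsMm)) +
     sum(minDistances(sp@coordsMm, sg@coordsMm))) / (sg@count + sp@count)
}

#' One evaluation record
#'
#' @param patientId,algorithm,descriptor identifiers.
#' @param p predicted mask; `g` ground truth. An empty prediction yields
#'   Dice 0, MSD NA and the `emptyPrediction` flag.
#' @return one-row data.frame (patient, algorithm, descriptor, dice, msd,
#'   emptyPrediction).
#' @export
metricsRecord <- function(patientId, algorithm, descriptor, p, g) {
    empty <- !any(asMaskVolume(p)@data != 0)
    data.frame(patient = patientId, algorithm = algorithm,
        descriptor = paste(normalizeDescriptor(descriptor), collapse = "+"),
        dice = if (empty) 0 else dice(p, g),
        msd = if (empty) NA_real_ else msd(p, g),
        emptyPrediction = empty)
}

#' Interobserver agreement between two delineations
#'
#' @param a,b binary observer masks on the same grid.
#' @return one-row data.frame with Dice and MSD between the two observers.
#' @export
interobserver <- function(a, b) {
    data.frame(dice = dice(a, b), msd = msd(a, b))
}
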