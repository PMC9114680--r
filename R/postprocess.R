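# Semi-automatic post-processing: median smoothing, watershed region
# splitting on the Euclidean distance transform, simulated per-slice seeds
# and seed-based region selection.

#' Binary median filter
#'
#' 3D median filter with a (2r+1)^3 kernel applied to a binary mask: a voxel
#' is foreground when the majority of its kernel window is. The window is
#' zero-padded at the volume boundary.
#'
#' @param mask binary [ImageVolume-class] (or 3D array).
#' @param radius kernel half-width (default 1: 3x3x3).
#' @return the smoothed binary mask, same type as the input.
#' @export
medianSmooth <- function(mask, radius = 1L) {
    arr <- if (is(mask, "ImageVolume")) mask@data else mask
    k <- (2 * radius + 1)^3
    sm <- (boxSum3d((arr != 0) * 1, radius) > k / 2) * 1
    if (is(mask, "ImageVolume"))
        imageVolume(sm, mask@spacing, mask@origin, mask@channel)
    else sm
}

emptyLabelMap <- function(mask) {
    new("RegionLabelMap", labels = array(0L, dim(mask@data)), nRegions = 0L,
        counts = integer(), spacing = mask@spacing)
}

#' Watershed region splitting of a binary mask
#'
#' Computes the Euclidean distance transform inside the mask and applies a
#' watershed to the negated distance surface; markers are the regional
#' maxima of the distance transform after h-maxima suppression (minimum
#' basin depth `hMaxima`, mm). Touching regions are separated at the
#' watershed lines; every mask voxel receives a label (26-connectivity).
#'
#' @param mask binary [ImageVolume-class].
#' @param hMaxima h-maxima suppression depth (mm), default 1.
#' @return A [RegionLabelMap-class]; an empty mask yields an empty map.
#' @export
splitRegions <- function(mask, hMaxima = 1) {
    arr <- mask@data != 0
    if (!any(arr)) return(emptyLabelMap(mask))
    dm <- dim(arr)
    # the h-maxima merging of the watershed can join basins across
    # disconnected components, so each 26-connected component is
    # watershed-split independently on its padded bounding subarray
    comp <- array(.ccl3d_cpp(as.integer(arr), as.integer(dm)), dm)
    out <- array(0L, dm)
    offset <- 0L
    for (k in seq_len(max(comp))) {
        idx <- which(comp == k, arr.ind = TRUE)
        lo <- pmax(apply(idx, 2, min) - 1L, 1L)
        hi <- pmin(apply(idx, 2, max) + 1L, dm)
        sub <- (comp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == k)
        d <- edt3d(sub, mask@spacing)
        w <- array(as.integer(EBImage::watershed(d, tolerance = hMaxima,
                                                 ext = 1)), dim(sub))
        sel <- cbind(idx[, 1] - lo[1] + 1L, idx[, 2] - lo[2] + 1L,
                     idx[, 3] - lo[3] + 1L)
        out[idx] <- w[sel] + offset
        offset <- offset + max(w)
    }
    new("RegionLabelMap", labels = out, nRegions = offset,
        counts = tabulate(out[out > 0L], offset), spacing = mask@spacing)
}

#' Simulate per-slice seed selection
#'
#' Emulates a user clicking once per axial slice inside the tumor: for every
#' slice intersecting the ground-truth delineation, one voxel is sampled
#' uniformly from that slice's ground-truth voxels.
#'
#' @param gt non-empty binary [ImageVolume-class] (the union ground truth).
#' @param seed integer seed; deterministic given it.
#' @return A [SeedSet-class] with one seed per intersecting slice.
#' @export
simulateSeeds <- function(gt, seed) {
    idx <- which(gt@data != 0, arr.ind = TRUE)
    if (!nrow(idx)) stop("ground-truth mask is empty")
    voxels <- withr::with_seed(as.integer(seed), {
        do.call(rbind, lapply(sort(unique(idx[, 3])), function(z) {
            rows <- which(idx[, 3] == z)
            idx[rows[sample.int(length(rows), 1L)], , drop = FALSE]
        }))
    })
    new("SeedSet", voxels = unname(voxels) - 1L, seed = as.integer(seed))
}

#' Keep only the watershed regions containing seeds
#'
#' The final segmentation is the union of the regions holding at least one
#' seed. A seed falling on background is snapped to the nearest labelled
#' voxel within 1 mm (face neighbours on the 1 mm analysis grid) and ignored
#' if none exists.
#'
#' @param labels a [RegionLabelMap-class].
#' @param seeds a [SeedSet-class] on the same grid.
#' @return binary mask (3D array) of the kept regions; attribute
#'   `"keptRegions"` lists their labels.
#' @export
selectRegions <- function(labels, seeds) {
    lab <- labels@labels
    d <- dim(lab)
    kept <- integer(0)
    for (i in seq_len(nrow(seeds@voxels))) {
        v <- seeds@voxels[i, ] + 1L
        l <- lab[v[1], v[2], v[3]]
        if (l == 0L) {
            # snap within 1 mm: candidate offsets whose physical length <= 1
            offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
            dist <- sqrt(colSums((t(offs) * labels@spacing)^2))
            ok <- dist > 0 & dist <= 1 + 1e-9
            offs <- offs[ok, , drop = FALSE]
            dist <- dist[ok]
            o <- order(dist)
            for (k in o) {
                u <- v + offs[k, ]
                if (all(u >= 1L) && all(u <= d) && lab[u[1], u[2], u[3]] > 0L) {
                    l <- lab[u[1], u[2], u[3]]
                    break
                }
            }
        }
        if (l > 0L) kept <- union(kept, l)
    }
    out <- array((lab %in% kept & lab > 0L) * 1, d)
    attr(out, "keptRegions") <- sort(kept)
    out
}

#' Semi-automatic post-processing chain
#'
#' Median-smooths the raw voxelwise prediction, splits it into watershed
#' regions on the Euclidean distance transform, simulates one seed per axial
#' slice of the ground truth, and keeps only the seeded regions. All
#' intermediates are retained in the result.
#'
#' @param pred raw binary prediction ([ImageVolume-class]) on the ROI grid.
#' @param gt union ground-truth mask on the same grid (drives the simulated
#'   seeds).
#' @param seed integer seed for the seed sampling.
#' @param medianRadius median-filter half-width (voxels).
#' @param hMaxima watershed h-maxima suppression (mm).
#' @return A [SegmentationResult-class].
#' @export
postProcess <- function(pred, gt, seed, medianRadius = 1L, hMaxima = 1) {
    if (!sameGrid(pred, gt)) stop("prediction and ground truth must share a grid")
    smoothed <- medianSmooth(pred, medianRadius)
    labels <- splitRegions(smoothed, hMaxima)
    seeds <- simulateSeeds(gt, seed)
    finalArr <- selectRegions(labels, seeds)
    kept <- attr(finalArr, "keptRegions")
    attr(finalArr, "keptRegions") <- NULL
    final <- imageVolume(finalArr, pred@spacing, pred@origin,
                         list(sequence = "mask", role = "final"))
    new("SegmentationResult", patientId = "", raw = pred, smoothed = smoothed,
        labelMap = labels, seeds = seeds, final = final,
        meta = list(keptRegions = kept, seed = as.integer(seed),
                    medianRadius = medianRadius, hMaxima = hMaxima))
}
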