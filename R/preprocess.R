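# Preprocessing: dynamic time-point selection, bounding box, rigid
# registration and resampling onto the isotropic analysis grid.

#' Select the 14 dynamic time points
#'
#' From the full dynamic acquisition, selects the images most closely
#' matching a 4 s temporal resolution for the first eight images (starting at
#' contrast arrival) followed by six images at 80 s resolution, i.e. nominal
#' times `arrival + (0, 4, ..., 28, 108, 188, ..., 508) s`. Ties are broken
#' toward the earlier image; an image already selected for an earlier target
#' is skipped in favour of the nearest unused one.
#'
#' @param timestamps strictly increasing acquisition times (s).
#' @param arrival contrast-arrival time (s); must not lie after the last
#'   acquisition, and the acquisition must extend to `arrival + 508` s.
#' @return A [TimepointSelection-class] with 14 entries.
#' @export
selectDmeTimepoints <- function(timestamps, arrival) {
    if (any(diff(timestamps) <= 0))
        stop("timestamps must be strictly increasing")
    if (arrival > max(timestamps))
        stop("contrast arrival lies after the last acquired image")
    if (max(timestamps) < arrival + 508)
        stop("acquisition must extend to arrival + 508 s")
    targets <- arrival + c(4 * (0:7), 28 + 80 * (1:6))
    used <- logical(length(timestamps))
    idx <- integer(length(targets))
    for (k in seq_along(targets)) {
        cand <- which(!used)
        if (!length(cand)) stop("fewer than 14 distinct selectable images")
        d <- abs(timestamps[cand] - targets[k])
        # min() of candidates in time order breaks ties toward the earlier image
        pick <- cand[which.min(d)]
        idx[k] <- pick
        used[pick] <- TRUE
    }
    new("TimepointSelection", indices = idx, timestamps = timestamps[idx],
        arrival = as.numeric(arrival))
}

#' Common field of view of all sequences of a study
#'
#' @param study a [MultiSequenceStudy-class].
#' @param spacing analysis-grid spacing (mm).
#' @return A [RoiBox-class] covering the intersection of all sequence FOVs.
#' @export
commonFov <- function(study, spacing = 1) {
    vols <- c(list(study@t2w), study@t2star[1], study@dw[1], study@dme[1])
    lo <- rep(-Inf, 3)
    hi <- rep(Inf, 3)
    for (v in vols) {
        e <- fovExtent(v)
        lo <- pmax(lo, e["lower", ])
        hi <- pmin(hi, e["upper", ])
    }
    roiBox(lo, hi, spacing)
}

#' Bounding box around the union delineation
#'
#' Tight bounding box (over mask voxel centres) expanded by `marginMm` on all
#' six faces, then intersected with the common field of view.
#'
#' @param unionMask non-empty binary [ImageVolume-class].
#' @param marginMm margin (mm), default 20.
#' @param fov [RoiBox-class] of the common field of view (clipping region).
#' @param spacing analysis-grid spacing (mm).
#' @return A [RoiBox-class].
#' @export
computeBoundingBox <- function(unionMask, marginMm = 20, fov = NULL, spacing = 1) {
    idx <- which(unionMask@data != 0, arr.ind = TRUE)
    if (!nrow(idx)) stop("union mask is empty")
    pts <- voxelToWorld(unionMask, idx - 1)
    lo <- apply(pts, 2, min) - marginMm
    hi <- apply(pts, 2, max) + marginMm
    if (!is.null(fov)) {
        lo <- pmax(lo, fov@lowerMm)
        hi <- pmin(hi, fov@upperMm)
    }
    if (any(hi < lo)) stop("bounding box does not intersect the field of view")
    roiBox(lo, hi, spacing)
}

# Histogram mutual information of two integer bin vectors.
histMI <- function(fb, mb, bins) {
    counts <- tabulate((mb - 1L) * bins + fb, bins * bins)
    n <- sum(counts)
    p <- matrix(counts / n, bins, bins)
    px <- rowSums(p)
    py <- colSums(p)
    pos <- p > 0
    sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
}

binize <- function(v, lo, hi, bins) {
    b <- floor((v - lo) / (hi - lo) * bins) + 1L
    pmin(pmax(b, 1L), bins)
}

#' Rigid mutual-information registration
#'
#' Estimates the 6-DOF rigid transform that maps fixed-grid world points to
#' sampling positions in the moving volume, by maximizing histogram mutual
#' information over a multi-resolution (subsampled then full) point set with
#' Nelder-Mead. The rotation centre is the fixed-grid centre.
#'
#' @param fixed [ImageVolume-class] on the analysis grid (the T2w reference,
#'   restricted to the ROI box).
#' @param moving [ImageVolume-class] on its own acquisition grid.
#' @param bins joint-histogram bins per axis.
#' @param sampleCap maximum number of fixed-grid sample points per level.
#' @param maxit Nelder-Mead iteration cap per level.
#' @return A [rigidTransform()]; attribute `"mi"` holds the final mutual
#'   information.
#' @export
registerRigid <- function(fixed, moving, bins = 32L, sampleCap = 10000L,
                          maxit = 400L) {
    d <- dim(fixed@data)
    allIdx <- gridVoxelIndices(d)
    allPts <- voxelToWorld(fixed, allIdx)
    fvals <- as.numeric(fixed@data)
    frange <- range(fvals)
    mrange <- range(moving@data)
    if (diff(frange) == 0 || diff(mrange) == 0)
        stop("registration images are constant")
    center <- fixed@origin + (d - 1) * fixed@spacing / 2
    par <- rep(0, 6)
    conv <- 0L
    for (stride in c(2L, 1L)) {
        keep <- which(rowSums(allIdx %% stride) == 0L)
        if (length(keep) > sampleCap)
            keep <- keep[seq(1L, length(keep),
                             by = ceiling(length(keep) / sampleCap))]
        pts <- allPts[keep, , drop = FALSE]
        fb <- binize(fvals[keep], frange[1], frange[2], bins)
        obj <- function(p) {
            tf <- rigidTransform(p[1:3], p[4:6], center)
            v <- sampleTrilinear(moving, transformPoints(pts, tf), "na")
            ok <- !is.na(v)
            if (mean(ok) < 0.25) return(10)
            -histMI(fb[ok], binize(v[ok], mrange[1], mrange[2], bins), bins)
        }
        fit <- stats::optim(par, obj, method = "Nelder-Mead",
                            control = list(maxit = maxit, reltol = 1e-8,
                                           parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
        par <- fit$par
        conv <- fit$convergence
    }
    if (conv != 0L) stop("registration did not converge")
    tf <- rigidTransform(par[1:3], par[4:6], center)
    attr(tf, "mi") <- -fit$value
    tf
}

#' Register and resample a study onto the isotropic analysis grid
#'
#' Selects the 14 dynamic time points, estimates one rigid transform per
#' moving sequence (T2w is the fixed reference) with mutual information
#' restricted to the ROI box, and resamples every retained channel onto the
#' isotropic grid covering the box (linear interpolation for images,
#' nearest-neighbour for masks).
#'
#' @param study a raw [MultiSequenceStudy-class].
#' @param box the ROI [RoiBox-class] (see [computeBoundingBox()]).
#' @param register estimate rigid transforms (TRUE) or assume the sequences
#'   are aligned (identity transforms).
#' @return A preprocessed [MultiSequenceStudy-class] on the analysis grid;
#'   `meta` records the time-point selection, the ROI box and the estimated
#'   transforms.
#' @export
registerAndResample <- function(study, box, register = TRUE) {
    if (isTRUE(study@meta$preprocessed))
        stop("study is already preprocessed")
    selection <- selectDmeTimepoints(study@timestamps, study@arrival)
    fixed <- resampleToBox(study@t2w, box)
    idVol <- function(role) resampleToBox(slot(study, role), box, NULL, "nearest")

    repMoving <- list(
        T2sw = study@t2star[[1]],
        DW = study@dw[[1]],
        DME = study@dme[[(selection@indices[1] - 1L) * 3L + 1L]])
    transforms <- list(T2w = rigidTransform())
    for (s in names(repMoving)) {
        transforms[[s]] <- if (register) {
            tryCatch(registerRigid(fixed, repMoving[[s]]),
                     error = function(e) stop(sprintf(
                         "registration failed for sequence %s: %s",
                         s, conditionMessage(e)), call. = FALSE))
        } else rigidTransform()
    }

    coefT2sw <- boxCoeffs(study@t2star[[1]], box, transforms$T2sw)
    t2star <- lapply(study@t2star, resampleToBox, box = box, coef = coefT2sw)
    coefDw <- boxCoeffs(study@dw[[1]], box, transforms$DW)
    dw <- lapply(study@dw, resampleToBox, box = box, coef = coefDw)
    nEcho <- length(study@echoTimesDme)
    dmeIdx <- as.vector(vapply(selection@indices,
        function(t) (t - 1L) * nEcho + seq_len(nEcho), integer(nEcho)))
    coefDme <- boxCoeffs(study@dme[[1]], box, transforms$DME)
    dme <- lapply(study@dme[dmeIdx], resampleToBox, box = box, coef = coefDme)
    dmeInfo <- study@dmeInfo[dmeIdx, , drop = FALSE]
    rownames(dmeInfo) <- NULL

    new("MultiSequenceStudy", patientId = study@patientId, t2w = fixed,
        t2star = t2star, dw = dw, dme = dme, dmeInfo = dmeInfo,
        bValues = study@bValues, echoTimesT2star = study@echoTimesT2star,
        echoTimesDme = study@echoTimesDme,
        timestamps = study@timestamps, arrival = study@arrival,
        observerA = idVol("observerA"), observerB = idVol("observerB"),
        truth = idVol("truth"),
        meta = c(study@meta[setdiff(names(study@meta), "preprocessed")],
                 list(preprocessed = TRUE, selection = selection,
                      roiBox = box, transforms = transforms)))
}
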