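# Per-voxel feature construction, normalisation and class balancing.

FEATURE_COUNTS <- c(T2w = 9L, T2sw = 5L, DW = 7L, DME = 42L)

#' Number of features implied by a feature-set descriptor
#'
#' T2w contributes 9 (sorted in-plane neighbourhood), T2*w 5 (echoes), DW 7
#' (b-values) and DME 42 (14 selected time points x 3 echoes); counts are
#' additive over the descriptor.
#'
#' @param descriptor subset of `c("T2w","T2sw","DW","DME")`.
#' @return integer feature count.
#' @export
featureCount <- function(descriptor) {
    sum(FEATURE_COUNTS[normalizeDescriptor(descriptor)])
}

#' Canonical descriptor order
#'
#' Feature blocks are always concatenated in the fixed order T2w, T2*w, DW,
#' DME (restricted to the descriptor) so trained models are portable.
#'
#' @param descriptor subset of `c("T2w","T2sw","DW","DME")` in any order.
#' @return the descriptor in canonical order.
#' @export
normalizeDescriptor <- function(descriptor) {
    if (!length(descriptor) || !all(descriptor %in% SEQUENCE_NAMES))
        stop("descriptor must be a non-empty subset of T2w, T2sw, DW, DME")
    SEQUENCE_NAMES[SEQUENCE_NAMES %in% descriptor]
}

# Channel label of every feature column for a descriptor (the nine T2w
# neighbourhood features share the single "T2w" channel).
descriptorChannels <- function(study, descriptor) {
    out <- character(0)
    for (s in normalizeDescriptor(descriptor)) {
        out <- c(out, switch(s,
            T2w = rep("T2w", 9L),
            T2sw = paste0("T2sw.te", study@echoTimesT2star),
            DW = paste0("DW.b", study@bValues),
            DME = paste0("DME.t", study@dmeInfo$time, ".e", study@dmeInfo$echo)))
    }
    out
}

#' T2w neighbourhood features
#'
#' For each voxel, the intensities of the voxel and its eight in-plane
#' (axial-slice) neighbours, sorted ascending. Out-of-volume neighbours are
#' filled by edge replication.
#'
#' @param volume the T2w [ImageVolume-class].
#' @param voxel 0-based voxel index triple, or an n x 3 matrix of them.
#' @return numeric matrix (n x 9) of sorted neighbourhood intensities.
#' @export
t2wFeatures <- function(volume, voxel) {
    if (is.null(dim(voxel))) voxel <- matrix(voxel, ncol = 3)
    storage.mode(voxel) <- "integer"
    d <- dim(volume@data)
    if (any(voxel < 0) || any(sweep(voxel, 2, d - 1L, ">") ))
        stop("voxel index outside volume")
    offs <- expand.grid(dx = -1:1, dy = -1:1)
    cols <- lapply(seq_len(nrow(offs)), function(k) {
        ix <- pmin(pmax(voxel[, 1] + offs$dx[k], 0L), d[1] - 1L)
        iy <- pmin(pmax(voxel[, 2] + offs$dy[k], 0L), d[2] - 1L)
        volume@data[voxel[, 3] * d[1] * d[2] + iy * d[1] + ix + 1L]
    })
    rowSortMatrix(do.call(cbind, cols))
}

#' Per-voxel features for a feature-set descriptor
#'
#' Concatenates, in the fixed block order (T2w, T2*w, DW, DME restricted to
#' the descriptor): the 9 sorted T2w neighbourhood intensities, the 5 T2*w
#' echo intensities (ascending TE), the 7 DW intensities (ascending b) and
#' the 42 DME intensities (14 selected time points, time-major, 3 echoes).
#'
#' @param study a preprocessed [MultiSequenceStudy-class].
#' @param voxel 0-based voxel index triple or n x 3 matrix.
#' @param descriptor feature-set descriptor.
#' @return numeric matrix (n x [featureCount()]).
#' @export
sequenceFeatures <- function(study, voxel, descriptor) {
    descriptor <- normalizeDescriptor(descriptor)
    if (!isTRUE(study@meta$preprocessed))
        stop("study must be preprocessed (registered, resampled, time points selected)")
    if (is.null(dim(voxel))) voxel <- matrix(voxel, ncol = 3)
    storage.mode(voxel) <- "integer"
    d <- dim(study@t2w@data)
    lin <- voxel[, 3] * d[1] * d[2] + voxel[, 2] * d[1] + voxel[, 1] + 1L
    gather <- function(vols, what) {
        if (!length(vols)) stop(sprintf("missing channel: %s", what))
        do.call(cbind, lapply(vols, function(v) v@data[lin]))
    }
    blocks <- list()
    for (s in descriptor) {
        blocks[[s]] <- switch(s,
            T2w = t2wFeatures(study@t2w, voxel),
            T2sw = gather(study@t2star, "T2sw"),
            DW = gather(study@dw, "DW"),
            DME = {
                if (length(study@dme) != 42L)
                    stop("missing channel: DME (expected 14 selected time points x 3 echoes)")
                gather(study@dme, "DME")
            })
    }
    do.call(cbind, blocks)
}

#' Assemble the per-voxel feature matrix of one patient
#'
#' One row per voxel of the ROI analysis grid, with binary labels from the
#' union ground truth (voxelwise OR of the two observer delineations).
#'
#' @param study a preprocessed [MultiSequenceStudy-class].
#' @param descriptor feature-set descriptor.
#' @return An unnormalised [FeatureMatrix-class].
#' @export
assembleMatrix <- function(study, descriptor) {
    descriptor <- normalizeDescriptor(descriptor)
    d <- dim(study@t2w@data)
    voxel <- gridVoxelIndices(d)
    values <- sequenceFeatures(study, voxel, descriptor)
    gt <- groundTruthUnion(study@observerA, study@observerB)
    new("FeatureMatrix", values = values, voxelIndex = voxel,
        labels = as.integer(gt@data != 0), patientId = study@patientId,
        descriptor = descriptor,
        channels = descriptorChannels(study, descriptor),
        normStats = data.frame(channel = character(), mean = numeric(),
                               sd = numeric()))
}

#' Z-score normalisation within image channel and patient
#'
#' Each image channel's intensities are transformed to mean 0, sd 1 computed
#' over the patient's ROI voxels of that channel (the nine T2w neighbourhood
#' columns share the T2w channel and are pooled for the statistics). The
#' statistics are recorded in the returned matrix.
#'
#' @param matrix a [FeatureMatrix-class].
#' @return the normalised [FeatureMatrix-class].
#' @export
zscoreNormalize <- function(matrix) {
    v <- matrix@values
    ch <- matrix@channels
    stats <- data.frame(channel = unique(ch), mean = NA_real_, sd = NA_real_)
    for (i in seq_len(nrow(stats))) {
        cols <- which(ch == stats$channel[i])
        x <- v[, cols]
        m <- mean(x)
        s <- stats::sd(as.numeric(x))
        if (!is.finite(s) || s <= 0)
            stop(sprintf("zero variance channel: %s", stats$channel[i]))
        v[, cols] <- (x - m) / s
        stats$mean[i] <- m
        stats$sd[i] <- s
    }
    initialize(matrix, values = v, normStats = stats)
}

#' Balance classes by random undersampling
#'
#' Keeps every tumor row and samples non-tumor rows uniformly without
#' replacement down to the tumor count (per patient). If there are fewer
#' non-tumor than tumor rows, all non-tumor rows are kept with a warning.
#'
#' @param matrix a [FeatureMatrix-class] with at least one row per class.
#' @param seed integer seed; the selection is deterministic given it.
#' @return the balanced [FeatureMatrix-class].
#' @export
undersample <- function(matrix, seed) {
    tumor <- which(matrix@labels == 1L)
    normal <- which(matrix@labels == 0L)
    if (!length(tumor) || !length(normal))
        stop("matrix must contain both tumor and non-tumor voxels")
    keepNormal <- if (length(normal) < length(tumor)) {
        warning("fewer non-tumor than tumor voxels; keeping all non-tumor rows")
        normal
    } else {
        withr::with_seed(as.integer(seed), sample(normal, length(tumor)))
    }
    keep <- sort(c(tumor, keepNormal))
    initialize(matrix, values = matrix@values[keep, , drop = FALSE],
               voxelIndex = matrix@voxelIndex[keep, , drop = FALSE],
               labels = matrix@labels[keep])
}

#' Restrict a feature matrix to a smaller descriptor
#'
#' Selects the feature-block columns of `descriptor` from a matrix built for
#' a superset descriptor. Normalisation statistics, when present, are
#' restricted accordingly (z-scores are computed per channel, so the values
#' are unchanged by restriction).
#'
#' @param matrix a [FeatureMatrix-class].
#' @param descriptor subset of `matrix@descriptor`.
#' @return the restricted [FeatureMatrix-class].
#' @export
subsetFeatures <- function(matrix, descriptor) {
    descriptor <- normalizeDescriptor(descriptor)
    if (!all(descriptor %in% matrix@descriptor))
        stop("descriptor must be a subset of the matrix descriptor")
    blocks <- rep(matrix@descriptor, FEATURE_COUNTS[matrix@descriptor])
    cols <- which(blocks %in% descriptor)
    ns <- matrix@normStats
    if (nrow(ns)) ns <- ns[ns$channel %in% matrix@channels[cols], , drop = FALSE]
    rownames(ns) <- NULL
    initialize(matrix, values = matrix@values[, cols, drop = FALSE],
               descriptor = descriptor, channels = matrix@channels[cols],
               normStats = ns)
}
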