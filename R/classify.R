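# Training, whole-volume prediction and patient-level leave-one-out CV.

#' Train a voxel classifier on pooled balanced feature matrices
#'
#' Pools the rows of the supplied (balanced, normalised) per-patient feature
#' matrices — in sorted patient-id order, so the result is independent of the
#' order the matrices are passed in — and fits the requested classifier.
#'
#' @param kind a [ClassifierKind-class] (LDA, QDA, SVM or ADA).
#' @param matrices list of [FeatureMatrix-class] sharing one descriptor.
#' @param seed integer training seed (recorded; all four learners are
#'   deterministic given the data).
#' @return A [TrainedModel-class].
#' @export
trainClassifier <- function(kind, matrices, seed = 1L) {
    if (is.character(kind)) kind <- classifierKind(kind)
    descs <- unique(vapply(matrices, function(m) paste(m@descriptor, collapse = "+"), ""))
    if (length(descs) != 1L) stop("all matrices must share a descriptor")
    ids <- vapply(matrices, function(m) m@patientId, "")
    matrices <- matrices[order(ids)]
    x <- do.call(rbind, lapply(matrices, function(m) m@values))
    y <- unlist(lapply(matrices, function(m) m@labels))
    if (length(unique(y)) < 2L) stop("training data contain a single class")
    fit <- withr::with_seed(as.integer(seed), switch(kind@kind,
        LDA = MASS::lda(x, grouping = factor(y, levels = 0:1)),
        QDA = MASS::qda(x, grouping = factor(y, levels = 0:1)),
        SVM = e1071::svm(x, factor(y, levels = 0:1),
                         kernel = kind@hyper$kernel %||% "linear",
                         cost = kind@hyper$cost %||% 1, scale = FALSE),
        ADA = adaboostFit(x, y, rounds = kind@hyper$rounds %||% 100L,
                          learningRate = kind@hyper$learningRate %||% 1,
                          depth = kind@hyper$depth %||% 1L)))
    new("TrainedModel", kind = kind, descriptor = matrices[[1]]@descriptor,
        fit = fit, trainPatients = sort(ids), seed = as.integer(seed))
}

#' Predict 0/1 labels for feature rows
#'
#' Applies the classifier's native decision rule (0.5 posterior for LDA/QDA,
#' sign of the margin for SVM and AdaBoost); no threshold tuning.
#'
#' @param model a [TrainedModel-class].
#' @param x numeric feature matrix with `featureCount(model@descriptor)`
#'   columns.
#' @return integer vector of 0/1 labels.
#' @export
predictLabels <- function(model, x) {
    if (ncol(x) != featureCount(model@descriptor))
        stop(sprintf("descriptor mismatch: model expects %d features, got %d",
                     featureCount(model@descriptor), ncol(x)))
    switch(model@kind@kind,
        LDA = as.integer(predict(model@fit, x)$class == "1"),
        QDA = as.integer(predict(model@fit, x)$class == "1"),
        SVM = as.integer(predict(model@fit, x) == "1"),
        ADA = as.integer(adaboostScore(model@fit, x) > 0))
}

#' Predict a whole-ROI tumor mask for one patient
#'
#' Builds the full feature matrix of the patient's ROI (every voxel, not a
#' balanced subset), normalises it with the patient's own per-channel
#' statistics, and scores every voxel.
#'
#' @param model a [TrainedModel-class].
#' @param study a preprocessed [MultiSequenceStudy-class].
#' @param box optional [RoiBox-class] restricting the prediction; voxels
#'   outside it are 0.
#' @param matrix optional precomputed normalised [FeatureMatrix-class] for
#'   this patient (e.g. from [assembleMatrix()] + [zscoreNormalize()]);
#'   avoids recomputation in cross-validation loops.
#' @return binary [ImageVolume-class] on the analysis grid.
#' @export
predictVolume <- function(model, study, box = NULL, matrix = NULL) {
    if (is.null(matrix))
        matrix <- zscoreNormalize(assembleMatrix(study, model@descriptor))
    else if (!setequal(matrix@descriptor, model@descriptor))
        matrix <- subsetFeatures(matrix, model@descriptor)
    lab <- predictLabels(model, matrix@values)
    d <- dim(study@t2w@data)
    if (!is.null(box)) {
        g <- boxGrid(box)
        pts <- matrix@voxelIndex
        ctr <- voxelToWorld(study@t2w, pts)
        inBox <- ctr[, 1] >= box@lowerMm[1] & ctr[, 1] <= box@upperMm[1] &
                 ctr[, 2] >= box@lowerMm[2] & ctr[, 2] <= box@upperMm[2] &
                 ctr[, 3] >= box@lowerMm[3] & ctr[, 3] <= box@upperMm[3]
        lab[!inBox] <- 0L
    }
    arr <- array(0, d)
    arr[matrix@voxelIndex[, 3] * d[1] * d[2] +
        matrix@voxelIndex[, 2] * d[1] + matrix@voxelIndex[, 1] + 1L] <- lab
    imageVolume(arr, study@t2w@spacing, study@t2w@origin,
                list(sequence = "mask", role = "prediction"))
}

#' Patient-level leave-one-out cross-validation
#'
#' For each patient, trains on the balanced matrices of all other patients
#' and predicts the held-out patient's full ROI, optionally followed by the
#' semi-automatic post-processing chain. Per-patient undersampling and seed
#' streams derive deterministically from the master seed and the patient id,
#' so the per-patient results are independent of cohort ordering and there
#' is no train/test leakage (each patient is normalised with its own
#' statistics only).
#'
#' @param cohort list of preprocessed [MultiSequenceStudy-class] (>= 2).
#' @param kind a [ClassifierKind-class] or kind name.
#' @param descriptor feature-set descriptor. The per-patient seed streams
#'   mix in the descriptor, so different experiment arms draw independent
#'   balancing subsets and simulated seed clicks (as independent runs of the
#'   semi-automatic workflow would).
#' @param seed master seed.
#' @param postprocess apply [postProcess()] to each raw prediction.
#' @param medianRadius,hMaxima post-processing parameters.
#' @param fullMatrices optional named list (by patient id) of precomputed
#'   normalised full feature matrices (any superset descriptor).
#' @return named list of [SegmentationResult-class], one per patient.
#' @export
looCv <- function(cohort, kind, descriptor, seed, postprocess = TRUE,
                  medianRadius = 1L, hMaxima = 1, fullMatrices = NULL) {
    if (length(cohort) < 2L) stop("leave-one-out needs at least 2 patients")
    if (is.character(kind)) kind <- classifierKind(kind)
    descriptor <- normalizeDescriptor(descriptor)
    ids <- vapply(cohort, function(s) s@patientId, "")
    if (anyDuplicated(ids)) stop("patient ids must be unique")
    names(cohort) <- ids

    if (is.null(fullMatrices)) {
        fullMatrices <- lapply(cohort, function(s)
            zscoreNormalize(assembleMatrix(s, descriptor)))
    }
    full <- lapply(ids, function(id) {
        m <- fullMatrices[[id]]
        if (!setequal(m@descriptor, descriptor)) subsetFeatures(m, descriptor) else m
    })
    names(full) <- ids
    arm <- function(id) paste(id, paste(descriptor, collapse = "+"))
    balanced <- lapply(ids, function(id)
        undersample(full[[id]], patientSeed(seed, arm(id))))
    names(balanced) <- ids

    results <- lapply(ids, function(id) {
        model <- trainClassifier(kind, balanced[setdiff(ids, id)],
                                 seed = patientSeed(seed, arm(id), offset = 1L))
        raw <- predictVolume(model, cohort[[id]], matrix = full[[id]])
        gt <- groundTruthUnion(cohort[[id]]@observerA, cohort[[id]]@observerB)
        if (postprocess) {
            res <- postProcess(raw, gt, seed = patientSeed(seed, arm(id), offset = 2L),
                               medianRadius = medianRadius, hMaxima = hMaxima)
            res@patientId <- id
        } else {
            res <- new("SegmentationResult", patientId = id, raw = raw,
                smoothed = raw, labelMap = emptyLabelMap(raw),
                seeds = new("SeedSet", voxels = matrix(integer(), 0, 3),
                            seed = NA_integer_),
                final = raw, meta = list())
        }
        res@meta$kind <- kind@kind
        res@meta$hyper <- kind@hyper
        res@meta$descriptor <- descriptor
        res@meta$trainPatients <- setdiff(ids, id)
        res
    })
    names(results) <- ids
    results
}
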