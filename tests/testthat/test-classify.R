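# Classifier training, prediction, and leave-one-out cross-validation.

trainAccuracy <- function(kind, fm, ...) {
    model <- trainClassifier(kind, list(fm), ...)
    mean(predictLabels(model, fm@values) == fm@labels)
}

test_that("all four classifiers separate well-separated Gaussian blobs", {
    fm <- blobToy(n = 200, sep = 6)
    expect_gte(trainAccuracy(classifierKind("LDA"), fm), 0.99)
    expect_gte(trainAccuracy(classifierKind("QDA"), fm), 0.99)
    expect_gte(trainAccuracy(classifierKind("SVM"), fm), 0.99)
    expect_gte(trainAccuracy(classifierKind("ADA"), fm), 0.99)
})

test_that("boosted trees handle the XOR pattern that defeats linear discriminants", {
    fm <- xorToy()
    accLda <- trainAccuracy(classifierKind("LDA"), fm)
    expect_lt(accLda, 0.65)  # near chance: XOR is not linearly separable
    # depth-2 base trees capture the interaction (boosted stumps are
    # additive in single features and cannot express XOR)
    accAda <- trainAccuracy(classifierKind("ADA", depth = 2L, rounds = 50L), fm)
    expect_gte(accAda, 0.95)
})

test_that("training is deterministic and validates its inputs", {
    fm <- blobToy(n = 120, sep = 2, seed = 9)
    for (kind in c("LDA", "QDA", "SVM", "ADA")) {
        m1 <- trainClassifier(kind, list(fm), seed = 4)
        m2 <- trainClassifier(kind, list(fm), seed = 4)
        expect_identical(predictLabels(m1, fm@values),
                         predictLabels(m2, fm@values))
    }
    oneClass <- toyFeatureMatrix(matrix(rnorm(50), 10), rep(1, 10))
    expect_error(trainClassifier("LDA", list(oneClass)), "single class")
    # pooled matrices must agree on the descriptor
    other <- blobToy()
    other@descriptor <- "DW"
    other@values <- other@values[, 1:2]
    expect_error(suppressWarnings(trainClassifier("LDA", list(blobToy(), other))),
                 "descriptor")
})

test_that("prediction applies the native decision rule and checks the descriptor", {
    fm <- blobToy()
    model <- trainClassifier("ADA", list(fm))
    expect_error(predictLabels(model, fm@values[, 1:3]), "descriptor mismatch")
    # constant-feature degenerate input: a one-class answer, no crash
    const <- matrix(1, 20, 5)
    expect_length(unique(predictLabels(model, const)), 1)
})

test_that("pooling is invariant to the order the training matrices are given", {
    a <- blobToy(seed = 1)
    b <- blobToy(seed = 2)
    b@patientId <- "T02"
    m1 <- trainClassifier("ADA", list(a, b))
    m2 <- trainClassifier("ADA", list(b, a))
    probe <- blobToy(seed = 3)@values
    expect_identical(predictLabels(m1, probe), predictLabels(m2, probe))
})

easyCohort <- function(n = 3, seed0 = 100) {
    spec <- tinySpec(tumorSemiAxes = c(9, 8, 7), noise = 10,
                     observerAmplitudeMm = 1,
                     adc = c(tumor = 0.7e-3, normal = 1.8e-3),
                     t2wMeans = c(tumor = 800, normal = 400))
    cohort <- lapply(seq_len(n), function(i) {
        st <- generateStudy(spec, seed0 + i, patientId = sprintf("P%02d", i))
        gt <- groundTruthUnion(st@observerA, st@observerB)
        box <- computeBoundingBox(gt, 10, commonFov(st), 1)
        registerAndResample(st, box, register = FALSE)
    })
    names(cohort) <- vapply(cohort, function(s) s@patientId, "")
    cohort
}

test_that("a model trained on easy phantoms recovers the training tumor", {
    cohort <- easyCohort(2)
    fms <- lapply(cohort, function(s)
        zscoreNormalize(assembleMatrix(s, c("T2w", "DW"))))
    bal <- lapply(names(cohort), function(id) undersample(fms[[id]], 1))
    model <- trainClassifier(classifierKind("ADA", rounds = 40L), bal)
    pred <- predictVolume(model, cohort[[1]], matrix = fms[[1]])
    gt <- groundTruthUnion(cohort[[1]]@observerA, cohort[[1]]@observerB)
    expect_gte(dice(pred, gt), 0.9)
    # prediction restricted to a sub-box zeroes everything outside it
    box <- cohort[[1]]@meta$roiBox
    sub <- roiBox(box@lowerMm + 8, box@upperMm - 8, 1)
    predSub <- predictVolume(model, cohort[[1]], box = sub, matrix = fms[[1]])
    pts <- mpMRIseg:::voxelToWorld(predSub, which(predSub@data != 0, arr.ind = TRUE) - 1)
    expect_true(all(sweep(pts, 2, sub@lowerMm, ">=") & sweep(pts, 2, sub@upperMm, "<=")))
})

test_that("leave-one-out folds exclude the held-out patient and ignore cohort order", {
    cohort <- easyCohort(3)
    kind <- classifierKind("ADA", rounds = 30L)
    res <- looCv(cohort, kind, c("T2w", "DW"), seed = 7)
    expect_length(res, 3)
    expect_setequal(names(res), names(cohort))
    for (id in names(res)) {
        expect_false(id %in% res[[id]]@meta$trainPatients)
        expect_length(res[[id]]@meta$trainPatients, 2)
    }
    resPerm <- looCv(rev(cohort), kind, c("T2w", "DW"), seed = 7)
    for (id in names(res))
        expect_identical(res[[id]]@final@data, resPerm[[id]]@final@data)
    expect_error(looCv(cohort[1], kind, "T2w", 1), "at least 2")
})
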