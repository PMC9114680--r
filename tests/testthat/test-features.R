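# Feature construction, z-scoring and undersampling.

test_that("T2w neighbourhood features are the sorted in-plane 3x3 patch", {
    # constant image: nine copies of the constant
    vol <- imageVolume(array(7, c(5, 5, 3)))
    expect_equal(as.numeric(t2wFeatures(vol, c(2, 2, 1))), rep(7, 9))
    # known patch: {9,1,5,3,7,2,8,4,6} sorts to 1..9
    a <- array(0, c(3, 3, 2))
    a[, , 1] <- matrix(c(9, 1, 5, 3, 7, 2, 8, 4, 6), 3, 3)
    expect_equal(as.numeric(t2wFeatures(imageVolume(a), c(1, 1, 0))), 1:9)
    expect_error(t2wFeatures(imageVolume(a), c(3, 1, 0)), "outside")
})

test_that("corner voxels match an explicit edge-replication oracle", {
    withr::with_seed(4, {
        a <- array(runif(6 * 5 * 3), c(6, 5, 3))
        vol <- imageVolume(a)
        # oracle: pad the axial slice by replication, then sort the patch
        oracle <- function(ix, iy, iz) {
            sl <- a[, , iz + 1]
            pad <- rbind(sl[1, ], sl, sl[nrow(sl), ])
            pad <- cbind(pad[, 1], pad, pad[, ncol(pad)])
            sort(as.numeric(pad[(ix + 1):(ix + 3), (iy + 1):(iy + 3)]))
        }
        for (v in list(c(0, 0, 0), c(5, 0, 1), c(0, 4, 2), c(5, 4, 0), c(2, 2, 1)))
            expect_equal(as.numeric(t2wFeatures(vol, v)), oracle(v[1], v[2], v[3]))
    })
})

test_that("feature counts are additive over the descriptor blocks", {
    expect_equal(featureCount("DW"), 7)
    expect_equal(featureCount("DME"), 42)
    expect_equal(featureCount(c("T2w", "T2sw", "DW", "DME")), 63)
    expect_equal(featureCount(c("DME", "T2w")), 51)
    st <- tinyPreprocessed()
    vox <- rbind(c(3, 3, 3), c(4, 5, 6))
    expect_equal(ncol(sequenceFeatures(st, vox, "DW")), 7)
    expect_equal(ncol(sequenceFeatures(st, vox, "DME")), 42)
    expect_equal(ncol(sequenceFeatures(st, vox, c("T2w", "T2sw", "DW", "DME"))), 63)
    # descriptor order never matters: blocks are concatenated canonically
    expect_equal(sequenceFeatures(st, vox, c("DME", "T2w")),
                 sequenceFeatures(st, vox, c("T2w", "DME")))
})

test_that("z-scoring gives unit statistics per channel and is scale invariant", {
    st <- tinyPreprocessed()
    fm <- assembleMatrix(st, c("T2w", "DW"))
    nz <- zscoreNormalize(fm)
    for (ch in unique(nz@channels)) {
        vals <- nz@values[, nz@channels == ch]
        expect_lt(abs(mean(vals)), 1e-9)
        expect_lt(abs(stats::sd(as.numeric(vals)) - 1), 1e-9)
    }
    # global intensity scaling of the patient cancels out
    fm2 <- fm
    fm2@values <- fm@values * 3.7
    expect_equal(zscoreNormalize(fm2)@values, nz@values, tolerance = 1e-12)
    # degenerate constant channel is refused
    fm3 <- fm
    fm3@values[, 10] <- 5
    expect_error(zscoreNormalize(fm3), "zero variance")
})

test_that("per-channel z-scoring matches a hand-worked two-channel example", {
    # 4 voxels, 2 single-column channels with different scales
    x <- cbind(c(1, 2, 3, 4), c(10, 20, 30, 100))
    hand1 <- (x[, 1] - mean(x[, 1])) / sd(x[, 1])
    hand2 <- (x[, 2] - mean(x[, 2])) / sd(x[, 2])
    # pooled scoping would give a different answer on channel 2
    pooled <- (x - mean(x)) / sd(as.numeric(x))
    expect_false(isTRUE(all.equal(hand2, pooled[, 2])))
    x5 <- cbind(x, x[, 1], x[, 2], x[, 1])
    fm5 <- toyFeatureMatrix(x5, c(0, 0, 1, 1))
    fm5@channels <- c("c1", "c2", "c3", "c4", "c5")
    nz <- zscoreNormalize(fm5)
    expect_equal(nz@values[, 1], hand1)
    expect_equal(nz@values[, 2], hand2)
    expect_equal(nz@normStats$mean[1:2], c(2.5, 40))
    expect_equal(nz@normStats$sd[1:2], c(sd(x[, 1]), sd(x[, 2])))
})

test_that("assembled matrices cover the ROI with union-ground-truth labels", {
    st <- tinyPreprocessed()
    fm <- assembleMatrix(st, "T2w")
    d <- dim(st@t2w@data)
    expect_equal(nrow(fm@values), prod(d))
    gt <- groundTruthUnion(st@observerA, st@observerB)
    expect_equal(sum(fm@labels), sum(gt@data))
    # a known tumor voxel is labelled 1
    tumorIdx <- which(gt@data != 0, arr.ind = TRUE)[1, ] - 1L
    row <- which(fm@voxelIndex[, 1] == tumorIdx[1] &
                 fm@voxelIndex[, 2] == tumorIdx[2] &
                 fm@voxelIndex[, 3] == tumorIdx[3])
    expect_equal(fm@labels[row], 1L)
})

test_that("undersampling balances classes, keeps all tumor rows, and is seeded", {
    withr::with_seed(10, {
        x <- matrix(rnorm(1100 * 5), ncol = 5)
        y <- c(rep(1, 100), rep(0, 1000))
        fm <- toyFeatureMatrix(x, y)
    })
    bal <- undersample(fm, seed = 5)
    expect_equal(nrow(bal@values), 200)
    expect_equal(mean(bal@labels), 0.5)
    # all tumor rows retained
    expect_true(all(fm@values[fm@labels == 1L, 1] %in% bal@values[bal@labels == 1L, 1]))
    expect_identical(undersample(fm, 5)@values, bal@values)
    expect_false(identical(undersample(fm, 6)@values, bal@values))
    # fewer non-tumor than tumor: keep all with a warning
    fm2 <- toyFeatureMatrix(x[1:150, ], c(rep(1, 100), rep(0, 50)))
    expect_warning(bal2 <- undersample(fm2, 1), "fewer non-tumor")
    expect_equal(sum(bal2@labels == 0L), 50)
    expect_equal(sum(bal2@labels == 1L), 100)
    expect_error(undersample(toyFeatureMatrix(x[1:5, ], rep(1, 5)), 1), "both")
})

test_that("restricting a matrix to a sub-descriptor preserves values and stats", {
    st <- tinyPreprocessed()
    full <- zscoreNormalize(assembleMatrix(st, c("T2w", "DW", "DME")))
    sub <- subsetFeatures(full, c("T2w", "DME"))
    direct <- zscoreNormalize(assembleMatrix(st, c("T2w", "DME")))
    expect_equal(sub@values, direct@values, tolerance = 1e-12)
    expect_identical(sub@channels, direct@channels)
    expect_error(subsetFeatures(direct, "DW"), "subset")
})
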