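# Time-point selection, bounding box, registration and resampling.

test_that("time-point selection reproduces the two-phase 4 s / 80 s scheme", {
    sel <- selectDmeTimepoints(seq(0, 600, by = 4), arrival = 0)
    expect_length(sel@indices, 14)
    expect_equal(sel@timestamps,
                 c(0, 4, 8, 12, 16, 20, 24, 28, 108, 188, 268, 348, 428, 508))
    # denser grid: same 14 nominal targets hit exactly
    sel2 <- selectDmeTimepoints(seq(0, 600, by = 2), arrival = 0)
    expect_equal(sel2@timestamps, sel@timestamps)
    # non-zero arrival shifts the scheme
    sel3 <- selectDmeTimepoints(seq(0, 600, by = 4), arrival = 40)
    expect_equal(sel3@timestamps - 40, sel@timestamps)
})

test_that("selection under timestamp jitter matches a brute-force nearest search", {
    withr::with_seed(99, {
        for (rep in 1:5) {
            ts <- sort(seq(0, 620, by = 4) + runif(156, -1, 1))
            sel <- selectDmeTimepoints(ts, arrival = ts[1])
            targets <- ts[1] + c(4 * (0:7), 28 + 80 * (1:6))
            expect_true(all(abs(sel@timestamps - targets) <= 2))
            # greedy-in-order nearest-unused oracle
            used <- integer(0)
            for (k in seq_along(targets)) {
                cand <- setdiff(seq_along(ts), used)
                pick <- cand[which.min(abs(ts[cand] - targets[k]))]
                used <- c(used, pick)
            }
            expect_identical(sel@indices, used)
        }
    })
})

test_that("selection is idempotent and validates its inputs", {
    sel <- selectDmeTimepoints(seq(0, 600, by = 4), 0)
    resel <- selectDmeTimepoints(sel@timestamps, 0)
    expect_setequal(sel@timestamps, resel@timestamps)
    expect_error(selectDmeTimepoints(c(0, 4, 4, 8), 0), "increasing")
    expect_error(selectDmeTimepoints(seq(0, 600, 4), 700), "after the last")
    expect_error(selectDmeTimepoints(seq(0, 400, 4), 0), "508")
    expect_error(selectDmeTimepoints(seq(0, 600, 4), 100), "508")
})

test_that("ties in the nearest-image match go to the earlier image", {
    # targets at 4k: timestamps offset by 2 make every target equidistant
    ts <- c(seq(2, 118, by = 4), seq(120, 600, by = 16))
    sel <- selectDmeTimepoints(ts, arrival = 0)
    # first target 0: candidates 2 (dist 2) -> picked; target 4: 2 used,
    # candidates 6 at dist 2 ... earlier of the two equidistant wins
    expect_equal(sel@timestamps[1], 2)
    expect_equal(sel@timestamps[2], 6)
})

test_that("bounding box expands the tight box and clips to the field of view", {
    a <- array(0, c(101, 101, 101))
    a[51, 51, 51] <- 1  # 0-based (50,50,50) -> world 50 mm on a 1 mm grid
    m <- mkMask(a)
    box <- computeBoundingBox(m, 20)
    expect_equal(box@lowerMm, c(30, 30, 30))
    expect_equal(box@upperMm, c(70, 70, 70))
    box0 <- computeBoundingBox(m, 0)
    expect_equal(box0@lowerMm, c(50, 50, 50))
    fov <- roiBox(c(0, 0, 0), c(60, 60, 60))
    boxC <- computeBoundingBox(m, 20, fov)
    expect_equal(boxC@upperMm, c(60, 60, 60))
    expect_error(computeBoundingBox(mkMask(array(0, c(4, 4, 4)))), "empty")
    farFov <- roiBox(c(200, 200, 200), c(210, 210, 210))
    expect_error(computeBoundingBox(m, 2, farFov), "intersect")
})

test_that("registration recovers identity and a known 3 mm translation", {
    zero <- list(translation = c(0, 0, 0), rotation = c(0, 0, 0))
    shifted <- list(translation = c(3, 0, 0), rotation = c(0, 0, 0))
    spec <- tinySpec(gridScale = 2, noise = 0, aligned = FALSE,
        misalignment = list(T2w = zero, T2sw = zero, DW = shifted, DME = zero))
    st <- generateStudy(spec, 21)
    gt <- groundTruthUnion(st@observerA, st@observerB)
    box <- computeBoundingBox(gt, 15, commonFov(st), 1)
    pre <- registerAndResample(st, box, register = TRUE)
    tfs <- pre@meta$transforms
    # aligned noiseless sequences: estimated transform near identity
    expect_lt(max(abs(tfs$T2sw$translation)), 0.1)
    expect_lt(max(abs(tfs$T2sw$rotation)), 0.1)
    # DW was rendered with a +3 mm anatomy shift: the sampling transform is
    # its inverse, a -3 mm translation, recovered within 0.5 mm
    expect_lt(max(abs(tfs$DW$translation - c(-3, 0, 0))), 0.5)
    # contract: every output channel on the exact 1 mm isotropic grid
    for (v in c(list(pre@t2w), pre@t2star, pre@dw, pre@dme))
        expect_equal(spacing(v), c(1, 1, 1))
    expect_length(pre@dme, 42)
})

test_that("resampling preserves mask volume within the surface-voxel bound", {
    st <- tinyPreprocessed(seed = 7)
    raw <- generateStudy(tinySpec(), 7)
    vRaw <- sum(raw@truth@data) * prod(spacing(raw@truth))
    vRes <- sum(st@truth@data) * prod(spacing(st@truth))
    surf <- surfaceVoxels(st@truth)@count * prod(spacing(st@truth))
    expect_lte(abs(vRes - vRaw), surf)
})

test_that("interior features are invariant to the crop extent", {
    st <- generateStudy(tinySpec(), 13)
    gt <- groundTruthUnion(st@observerA, st@observerB)
    fov <- commonFov(st)
    boxBig <- computeBoundingBox(gt, 14, fov, 1)
    boxSmall <- roiBox(boxBig@lowerMm + 4, boxBig@upperMm - 4, 1)
    preBig <- registerAndResample(st, boxBig, register = FALSE)
    preSmall <- registerAndResample(st, boxSmall, register = FALSE)
    fmB <- assembleMatrix(preBig, c("T2w", "DW"))
    fmS <- assembleMatrix(preSmall, c("T2w", "DW"))
    keyB <- do.call(paste, as.data.frame(mpMRIseg:::voxelToWorld(preBig@t2w, fmB@voxelIndex)))
    keyS <- do.call(paste, as.data.frame(mpMRIseg:::voxelToWorld(preSmall@t2w, fmS@voxelIndex)))
    dS <- dim(preSmall@t2w@data)
    interiorS <- rowSums(fmS@voxelIndex >= 1L &
                         sweep(fmS@voxelIndex, 2, dS - 2L, "<=")) == 3L
    common <- intersect(keyB, keyS[interiorS])
    expect_gt(length(common), 1000)
    expect_equal(fmB@values[match(common, keyB), ],
                 fmS@values[match(common, keyS), ], tolerance = 1e-12)
})
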