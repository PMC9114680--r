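# Median smoothing, watershed splitting, seed simulation, region selection.

test_that("median filter follows kernel majority on canonical cases", {
    # solid 10^3 cube in a larger volume: interior unchanged, corners eroded
    cube <- cubeMask(10, 16)
    sm <- medianSmooth(cube, 1)
    inside <- edt3d(cube@data != 0, c(1, 1, 1)) > 1.8
    expect_true(all(sm@data[inside] == 1))
    # brute-force majority check on every voxel of a neighbourhood window
    brute <- function(a, i, j, k) {
        d <- dim(a)
        win <- a[max(1, i - 1):min(d[1], i + 1),
                 max(1, j - 1):min(d[2], j + 1),
                 max(1, k - 1):min(d[3], k + 1)]
        as.numeric(sum(win) > 27 / 2)  # zero padding: missing voxels count 0
    }
    corner <- which(cube@data != 0, arr.ind = TRUE)
    corner <- corner[which.min(rowSums(corner)), ]
    expect_equal(sm@data[corner[1], corner[2], corner[3]],
                 brute(cube@data, corner[1], corner[2], corner[3]))
    withr::with_seed(5, {
        a <- array(rbinom(12^3, 1, 0.4), c(12, 12, 12))
        sm2 <- medianSmooth(mkMask(a), 1)
        for (v in replicate(12, sample(1:12, 3), simplify = FALSE))
            expect_equal(sm2@data[v[1], v[2], v[3]], brute(a, v[1], v[2], v[3]))
    })
    # single isolated voxel is a minority in its 27-neighbourhood
    iso <- array(0, c(7, 7, 7)); iso[4, 4, 4] <- 1
    expect_equal(sum(medianSmooth(mkMask(iso), 1)@data), 0)
    expect_equal(sum(medianSmooth(mkMask(array(0, c(6, 6, 6))), 1)@data), 0)
})

test_that("watershed splitting separates blobs and labels every mask voxel", {
    # two disjoint spheres
    two <- array(0, c(30, 14, 14))
    for (ctr in c(7, 23))
        for (i in 1:30) for (j in 1:14) for (k in 1:14)
            if ((i - ctr)^2 + (j - 7)^2 + (k - 7)^2 <= 16) two[i, j, k] <- 1
    lm <- splitRegions(mkMask(two))
    expect_equal(lm@nRegions, 2)
    # dumbbell: two equal spheres joined by a thin neck split near the neck
    dumb <- array(0, c(30, 15, 15))
    for (i in 1:30) for (j in 1:15) for (k in 1:15)
        if ((i - 9)^2 + (j - 8)^2 + (k - 8)^2 <= 36 ||
            (i - 22)^2 + (j - 8)^2 + (k - 8)^2 <= 36) dumb[i, j, k] <- 1
    lmD <- splitRegions(mkMask(dumb))
    expect_equal(lmD@nRegions, 2)
    expect_true(lmD@labels[9, 8, 8] != lmD@labels[22, 8, 8])
    expect_true(all(lmD@labels[9, 8, 8] > 0, lmD@labels[22, 8, 8] > 0))
    # every mask voxel is labelled; counts add up
    expect_equal(sum(lmD@labels > 0), sum(dumb))
    expect_equal(sum(lmD@counts), sum(dumb))
    # a single convex blob stays whole at the default h
    expect_equal(splitRegions(sphereMask(24, 8))@nRegions, 1)
    expect_equal(splitRegions(cubeMask(9))@nRegions, 1)
    # empty mask: empty map, no error
    expect_equal(splitRegions(mkMask(array(0, c(5, 5, 5))))@nRegions, 0)
})

test_that("seed simulation draws one uniform seed per intersecting slice", {
    sph <- sphereMask(20, 7)
    zs <- sort(unique(which(sph@data != 0, arr.ind = TRUE)[, 3]))
    seeds <- simulateSeeds(sph, 9)
    expect_equal(nrow(seeds@voxels), length(zs))
    expect_setequal(seeds@voxels[, 3] + 1L, zs)
    # all seeds inside the mask
    expect_true(all(sph@data[seeds@voxels + 1L] != 0))
    expect_identical(simulateSeeds(sph, 9)@voxels, seeds@voxels)
    # single-voxel ground truth: that voxel is the seed
    one <- array(0, c(5, 5, 5)); one[2, 3, 4] <- 1
    expect_equal(simulateSeeds(mkMask(one), 1)@voxels,
                 matrix(c(1L, 2L, 3L), 1))
    expect_error(simulateSeeds(mkMask(array(0, c(4, 4, 4))), 1), "empty")
    # empirical uniformity over one slice (chi-squared on 2000 draws)
    slab <- array(0, c(9, 9, 1)); slab[3:5, 4:6, 1] <- 1
    slabM <- mkMask(slab)
    draws <- vapply(1:2000, function(s)
        paste(simulateSeeds(slabM, s)@voxels[1, 1:2], collapse = ","), "")
    counts <- table(draws)
    expect_equal(length(counts), 9)
    expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 1e-4)
})

test_that("region selection keeps exactly the seeded regions", {
    # three blobs along x
    a <- array(0, c(24, 8, 8))
    a[2:6, 3:6, 3:6] <- 1; a[10:14, 3:6, 3:6] <- 1; a[18:22, 3:6, 3:6] <- 1
    lm <- splitRegions(mkMask(a))
    expect_equal(lm@nRegions, 3)
    midLabel <- lm@labels[12, 4, 4]
    seeds <- new("SeedSet", voxels = rbind(c(11L, 3L, 3L), c(12L, 4L, 4L)),
                 seed = 1L)
    kept <- selectRegions(lm, seeds)
    expect_equal(sum(kept), sum(lm@labels == midLabel))
    expect_true(all(kept[lm@labels == midLabel] == 1))
    # seed on background far from any region selects nothing
    bgSeeds <- new("SeedSet", voxels = rbind(c(0L, 0L, 0L)), seed = 1L)
    expect_equal(sum(selectRegions(lm, bgSeeds)), 0)
    # seed adjacent to a region is snapped within 1 mm
    nearSeeds <- new("SeedSet", voxels = rbind(c(9L, 4L, 4L)), seed = 1L)
    expect_equal(sum(selectRegions(lm, nearSeeds)), sum(lm@labels == midLabel))
})

test_that("the post-processing chain removes unseeded false positives and never adds voxels", {
    sph <- sphereMask(26, 7)
    gt <- sph
    # prediction = truth plus a distant false-positive blob
    pred <- sph@data
    pred[21:24, 21:24, 21:24] <- 1
    predM <- mkMask(pred)
    res <- postProcess(predM, gt, seed = 3)
    # the blob is disconnected from every seeded region and must vanish
    expect_equal(sum(res@final@data[21:24, 21:24, 21:24]), 0)
    expect_gt(dice(res@final, gt), dice(predM, gt))
    # final is always a subset of the smoothed prediction
    expect_true(all(res@smoothed@data[res@final@data != 0] != 0))
    # perfect prediction: selection keeps the true region
    resP <- postProcess(gt, gt, seed = 4)
    expect_gte(dice(resP@final, gt), dice(medianSmooth(gt, 1), gt))
    # determinism given the seed
    res2 <- postProcess(predM, gt, seed = 3)
    expect_identical(res2@final@data, res@final@data)
})

test_that("post-processing improves noisy raw predictions in most seeds", {
    sph <- sphereMask(30, 8)
    withr::with_seed(31, {
        wins <- 0L
        for (rep in 1:12) {
            noisy <- sph@data
            # sprinkle isolated false positives away from the tumor
            bg <- which(edt3d(sph@data == 0, c(1, 1, 1)) > 4)
            noisy[sample(bg, 40)] <- 1
            res <- postProcess(mkMask(noisy), sph, seed = rep)
            if (dice(res@final, sph) >= dice(mkMask(noisy), sph)) wins <- wins + 1L
        }
    })
    expect_gte(wins, 11L)  # >= 95% of seeds at this sample size
})
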