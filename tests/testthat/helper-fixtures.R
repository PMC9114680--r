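# Shared fixtures and independent oracles for the test suite.

mkMask <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    imageVolume((arr != 0) * 1, spacing, origin, list(sequence = "mask"))
}

# Sphere of radius r (mm) voxelized on an n^3 grid (voxel centres).
sphereMask <- function(n = 24, r = 8, spacing = c(1, 1, 1)) {
    ctr <- (n - 1) / 2
    idx <- gridIdx3(c(n, n, n))
    d2 <- ((idx[, 1] - ctr) * spacing[1])^2 + ((idx[, 2] - ctr) * spacing[2])^2 +
          ((idx[, 3] - ctr) * spacing[3])^2
    mkMask(array(as.numeric(d2 <= r^2), c(n, n, n)), spacing)
}

cubeMask <- function(side, N = side + 4) {
    a <- array(0, c(N, N, N))
    lo <- floor((N - side) / 2) + 1
    a[lo:(lo + side - 1), lo:(lo + side - 1), lo:(lo + side - 1)] <- 1
    mkMask(a)
}

gridIdx3 <- function(dm) {
    cbind(rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
          rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
          rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2]))
}

# Independent MSD oracle: naive 6-neighbour surface extraction and exhaustive
# all-pairs distances, written without any package helpers.
oracleMsd <- function(p, g, spacing) {
    surf <- function(m) {
        d <- dim(m)
        out <- NULL
        for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
            if (m[i, j, k] == 0) next
            nb <- c(
                if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
                if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
                if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
            if (length(nb) < 6 || any(nb == 0))
                out <- rbind(out, (c(i, j, k) - 1) * spacing)
        }
        out
    }
    sp <- surf(p)
    sg <- surf(g)
    mind <- function(A, B) vapply(seq_len(nrow(A)), function(i)
        min(sqrt(colSums((t(B) - A[i, ])^2))), numeric(1))
    (sum(mind(sg, sp)) + sum(mind(sp, sg))) / (nrow(sg) + nrow(sp))
}

# Minimal valid FeatureMatrix around a plain 5-column toy (descriptor T2sw).
toyFeatureMatrix <- function(x, y, patientId = "T01") {
    stopifnot(ncol(x) == 5)
    new("FeatureMatrix", values = x,
        voxelIndex = cbind(seq_len(nrow(x)) - 1L, 0L, 0L),
        labels = as.integer(y), patientId = patientId,
        descriptor = "T2sw",
        channels = paste0("T2sw.te", c(4.6, 13.8, 23, 32.2, 41.4)),
        normStats = data.frame(channel = character(), mean = numeric(),
                               sd = numeric()))
}

# Two-blob linearly separable toy: informative features 1-2, noise 3-5.
blobToy <- function(n = 200, sep = 6, seed = 1) {
    withr::with_seed(seed, {
        y <- rep(0:1, each = n / 2)
        x <- cbind(rnorm(n) + sep * y, rnorm(n) + sep * y,
                   rnorm(n), rnorm(n), rnorm(n))
        toyFeatureMatrix(x, y)
    })
}

# Four-cluster XOR toy (not linearly separable, not additive).
xorToy <- function(nPerCluster = 60, sep = 6, seed = 2) {
    withr::with_seed(seed, {
        cl <- expand.grid(a = c(0, 1), b = c(0, 1))
        x12 <- do.call(rbind, lapply(seq_len(4), function(i)
            cbind(rnorm(nPerCluster, sep * cl$a[i]),
                  rnorm(nPerCluster, sep * cl$b[i]))))
        y <- rep(as.integer(xor(cl$a, cl$b)), each = nPerCluster)
        x <- cbind(x12, matrix(rnorm(3 * nrow(x12)), ncol = 3))
        toyFeatureMatrix(x, y)
    })
}

# Desk-scale phantom spec: coarsened grids, optional aligned sequences and
# free tissue-contrast knobs, for fast cohort tests.
tinySpec <- function(gridScale = 4, zFovMm = 66, tumorSemiAxes = c(10, 9, 8),
                     aligned = TRUE, noise = NULL, ...) {
    args <- list(gridScale = gridScale, zFovMm = zFovMm,
                 tumorSemiAxes = tumorSemiAxes, ...)
    if (aligned) {
        zero <- list(translation = c(0, 0, 0), rotation = c(0, 0, 0))
        args$misalignment <- list(T2w = zero, T2sw = zero, DW = zero, DME = zero)
    }
    if (!is.null(noise))
        args$noiseSd <- c(T2w = noise, T2sw = noise, DW = noise, DME = noise)
    do.call(phantomSpec, args)
}

# One preprocessed tiny study (cached per call signature via local memo).
tinyPreprocessed <- local({
    cache <- list()
    function(seed = 7, gridScale = 4, marginMm = 12, ...) {
        key <- paste(seed, gridScale, marginMm, ...)
        if (!is.null(cache[[key]])) return(cache[[key]])
        spec <- tinySpec(gridScale = gridScale, ...)
        st <- generateStudy(spec, seed, patientId = sprintf("P%02d", seed))
        gt <- groundTruthUnion(st@observerA, st@observerB)
        box <- computeBoundingBox(gt, marginMm, commonFov(st), 1)
        out <- registerAndResample(st, box, register = FALSE)
        cache[[key]] <<- out
        out
    }
})
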