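# Summaries, comparison statistics and experiment orchestration.

test_that("median/IQR summary uses linear-interpolation quantiles", {
    expect_equal(summarizeMetrics(1:5), c(MED = 3, IQR = 2))
    expect_equal(summarizeMetrics(rep(4.2, 10)), c(MED = 4.2, IQR = 0))
    withr::with_seed(3, {
        for (i in 1:10) {
            x <- rnorm(sample(5:40, 1))
            s <- sort(x)
            # order-statistic oracle: type-7 interpolation at p = .25/.5/.75
            q7 <- function(p) {
                h <- (length(s) - 1) * p
                s[floor(h) + 1] + (h - floor(h)) *
                    (s[pmin(floor(h) + 2, length(s))] - s[floor(h) + 1])
            }
            expect_equal(summarizeMetrics(x),
                         c(MED = q7(0.5), IQR = q7(0.75) - q7(0.25)))
        }
    })
    expect_error(summarizeMetrics(numeric()), "empty")
})

syntheticMetrics <- function(perGroup, seed = 1, sd = 0.03) {
    withr::with_seed(seed, {
        do.call(rbind, lapply(names(perGroup), function(g) {
            n <- length(perGroup[[g]]$dice)
            data.frame(patient = sprintf("P%02d", seq_len(n)), algorithm = g,
                descriptor = "T2w", dice = perGroup[[g]]$dice + rnorm(n, 0, sd),
                msd = perGroup[[g]]$msd + abs(rnorm(n, 0, sd)),
                emptyPrediction = FALSE, diceRaw = NA_real_, group = g)
        }))
    })
}

test_that("four algorithms yield six Bonferroni-corrected pairwise tests", {
    base <- list(dice = rep(0.7, 12), msd = rep(3, 12))
    worse <- list(dice = rep(0.35, 12), msd = rep(7, 12))
    met <- syntheticMetrics(list(LDA = base, QDA = base, SVM = worse, ADA = base))
    tab <- mpMRIseg:::buildComparison(met)
    expect_equal(tab@family, choose(4, 2))
    expect_lt(tab@friedman["dice"], 0.05)
    dicePairs <- tab@pairwise[tab@pairwise$metric == "dice", ]
    expect_equal(nrow(dicePairs), 6)
    expect_equal(dicePairs$pAdj, pmin(1, dicePairs$pRaw * 6))
    # the handicapped algorithm is significantly worse than every other
    svm <- dicePairs[dicePairs$a == "SVM" | dicePairs$b == "SVM", ]
    expect_true(all(svm$pAdj < 0.05))
    expect_true(all(dicePairs$pAdj[!(dicePairs$a == "SVM" | dicePairs$b == "SVM")] > 0.05))
})

test_that("identical metric vectors yield a non-significant omnibus and no post-hoc", {
    same <- list(dice = rep(0.7, 10), msd = rep(3, 10))
    met <- syntheticMetrics(list(LDA = same, QDA = same, SVM = same, ADA = same),
                            sd = 0)
    # perfectly tied blocks: Friedman is degenerate, never significant
    tab <- suppressWarnings(mpMRIseg:::buildComparison(met))
    expect_equal(nrow(tab@pairwise), 0)
    metNoise <- syntheticMetrics(list(LDA = same, QDA = same, SVM = same,
                                      ADA = same), sd = 0.05)
    tabN <- mpMRIseg:::buildComparison(metNoise)
    if (!is.na(tabN@friedman["dice"]) && tabN@friedman["dice"] >= 0.05)
        expect_equal(nrow(tabN@pairwise[tabN@pairwise$metric == "dice", ]), 0)
})

test_that("reference-based comparison adjusts over the number of comparisons", {
    ref <- list(dice = rep(0.6, 10), msd = rep(4, 10))
    good <- list(dice = rep(0.8, 10), msd = rep(2.5, 10))
    met <- syntheticMetrics(list(T2w = ref, `T2w+DME` = good, DW = ref))
    met$group <- met$algorithm
    tab <- mpMRIseg:::buildComparison(met, reference = "T2w")
    expect_equal(tab@family, 2L)
    expect_equal(tab@reference, "T2w")
    d <- tab@pairwise[tab@pairwise$metric == "dice", ]
    expect_equal(nrow(d), 2)
    expect_lt(d$pAdj[d$a == "T2w+DME"], 0.05)
    expect_gt(d$pAdj[d$a == "DW"], 0.05)
})

test_that("descriptor enumeration covers all 15 subsets", {
    ds <- allDescriptors()
    expect_length(ds, 15)
    expect_equal(anyDuplicated(vapply(ds, paste, "", collapse = "+")), 0L)
    expect_true(all(vapply(ds, function(d) all(d %in% c("T2w", "T2sw", "DW", "DME")), TRUE)))
})

smallConfig <- function(nPatients = 3, kinds = list("LDA"),
                        descriptors = list("T2w", "DW", c("T2w", "DW")),
                        masterSeed = 5) {
    experimentConfig(nPatients = nPatients,
        spec = tinySpec(tumorSemiAxes = c(8, 7, 6), noise = 15,
                        observerAmplitudeMm = 1.5,
                        adc = c(tumor = 0.7e-3, normal = 1.8e-3),
                        t2wMeans = c(tumor = 750, normal = 420)),
        variation = list(semiAxesFrac = 0.1, centerMm = 1),
        masterSeed = masterSeed, kinds = kinds, descriptors = descriptors,
        marginMm = 8, register = FALSE,
        postprocessParams = list(medianRadius = 1L, hMaxima = 1))
}

test_that("the feature-set experiment runs end to end with coherent outputs", {
    cfg <- smallConfig()
    tab <- runFeaturesetComparison(cfg)
    expect_s4_class(tab, "ComparisonTable")
    expect_setequal(tab@summary$group, c("T2w", "DW", "T2w+DW"))
    expect_equal(nrow(tab@metrics), 3 * 3)
    expect_equal(tab@family, 2L)
    expect_true(all(tab@metrics$dice >= 0 & tab@metrics$dice <= 1))
    # determinism of the whole orchestration
    tab2 <- runFeaturesetComparison(cfg)
    expect_identical(tab@metrics, tab2@metrics)
})

test_that("the algorithm experiment compares the configured classifiers", {
    cfg <- smallConfig(kinds = list("LDA", "QDA"), descriptors = list("T2w"))
    tab <- runAlgorithmComparison(cfg)
    expect_setequal(tab@summary$group, c("LDA", "QDA"))
    expect_equal(nrow(tab@metrics), 6)
    expect_equal(tab@family, 1L)
    expect_true(all(c("medDice", "iqrDice", "medMsd", "iqrMsd") %in%
                    colnames(tab@summary)))
})
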