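# Orchestration of the two phantom-cohort experiments: algorithm comparison
# on T2w features, and mono-/multi-sequence feature-set comparison, with
# Friedman / Wilcoxon signed-rank / Bonferroni statistics and reporting.

#' All 15 feature-set descriptors
#'
#' Every non-empty subset of \{T2w, T2*w, DW, DME\}, ordered by subset size
#' then canonical sequence order.
#'
#' @return list of character vectors.
#' @export
allDescriptors <- function() {
    out <- list()
    for (k in 1:4)
        out <- c(out, utils::combn(SEQUENCE_NAMES, k, simplify = FALSE))
    out
}

#' Construct an ExperimentConfig
#'
#' @param nPatients cohort size (>= 2).
#' @param spec [PhantomSpec-class] template for the cohort.
#' @param variation per-patient jitter of the tumor geometry:
#'   `semiAxesFrac` (relative semi-axis range) and `centerMm` (centre
#'   displacement range, mm).
#' @param masterSeed master seed; every per-patient generation, balancing
#'   and seed-sampling stream derives from it deterministically.
#' @param kinds list of [ClassifierKind-class] (or kind names).
#' @param descriptors list of feature-set descriptors.
#' @param marginMm bounding-box margin (mm).
#' @param spacing analysis-grid spacing (mm).
#' @param register estimate rigid transforms (TRUE) or assume aligned.
#' @param postprocessParams `list(medianRadius=, hMaxima=)`.
#' @return An [ExperimentConfig-class].
#' @export
experimentConfig <- function(nPatients, spec = phantomSpec(),
    variation = list(semiAxesFrac = 0.15, centerMm = 2), masterSeed = 1L,
    kinds = list(classifierKind("ADA")), descriptors = allDescriptors(),
    marginMm = 20, spacing = 1, register = TRUE,
    postprocessParams = list(medianRadius = 1L, hMaxima = 1)) {
    kinds <- lapply(kinds, function(k)
        if (is.character(k)) classifierKind(k) else k)
    descriptors <- lapply(descriptors, normalizeDescriptor)
    new("ExperimentConfig", nPatients = as.integer(nPatients), spec = spec,
        variation = variation, masterSeed = as.integer(masterSeed),
        kinds = kinds, descriptors = descriptors,
        marginMm = as.numeric(marginMm), spacing = as.numeric(spacing),
        register = register, postprocessParams = postprocessParams)
}

jitterSpec <- function(spec, variation, seed) {
    f <- variation$semiAxesFrac %||% 0
    cmax <- variation$centerMm %||% 0
    jit <- withr::with_seed(seed, list(
        sa = stats::runif(3, 1 - f, 1 + f),
        ctr = stats::runif(3, -cmax, cmax)))
    spec@tumorSemiAxes <- spec@tumorSemiAxes * jit$sa
    spec@tumorCenter <- spec@tumorCenter + jit$ctr
    validObject(spec)
    spec
}

#' Generate and preprocess a phantom cohort
#'
#' Generates `nPatients` studies from the spec template (tumor geometry
#' jittered per patient), computes each patient's union-delineation bounding
#' box, and registers/resamples every study onto its analysis grid.
#'
#' @param config an [ExperimentConfig-class].
#' @return named list of preprocessed [MultiSequenceStudy-class].
#' @export
generateCohort <- function(config) {
    ids <- sprintf("P%02d", seq_len(config@nPatients))
    studies <- lapply(ids, function(id) {
        sp <- jitterSpec(config@spec, config@variation,
                         patientSeed(config@masterSeed, id, offset = 3L))
        st <- generateStudy(sp, patientSeed(config@masterSeed, id, offset = 4L),
                            patientId = id)
        gt <- groundTruthUnion(st@observerA, st@observerB)
        box <- computeBoundingBox(gt, config@marginMm,
                                  commonFov(st, config@spacing), config@spacing)
        registerAndResample(st, box, register = config@register)
    })
    names(studies) <- ids
    studies
}

# Per-patient metric records for a set of LOO segmentation results.
evaluateResults <- function(results, studies, algorithm, descriptor) {
    do.call(rbind, lapply(names(results), function(id) {
        gt <- groundTruthUnion(studies[[id]]@observerA, studies[[id]]@observerB)
        rec <- metricsRecord(id, algorithm, descriptor,
                             results[[id]]@final, gt)
        rec$diceRaw <- if (any(results[[id]]@raw@data != 0))
            dice(results[[id]]@raw, gt) else 0
        rec
    }))
}

#' Median and interquartile range
#'
#' @param values non-empty numeric vector.
#' @return `c(MED = median, IQR = Q3 - Q1)` with linear-interpolation
#'   (type 7) quantiles.
#' @export
summarizeMetrics <- function(values) {
    if (!length(values)) stop("cannot summarize an empty vector")
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE,
                         names = FALSE)
    c(MED = q[2], IQR = q[3] - q[1])
}

pairedWilcoxon <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 2L) return(NA_real_)
    suppressWarnings(
        stats::wilcox.test(x[ok], y[ok], paired = TRUE,
                           alternative = "two.sided")$p.value)
}

# Build a ComparisonTable from per-patient metrics. With a reference group,
# every other group is tested against it (family = nGroups - 1 per metric);
# without one, the Friedman omnibus gates all C(n,2) pairwise tests.
buildComparison <- function(metrics, reference = NULL, alpha = 0.05) {
    groups <- unique(metrics$group)
    patients <- sort(unique(metrics$patient))
    summary <- do.call(rbind, lapply(groups, function(g) {
        sub <- metrics[metrics$group == g, ]
        sd_ <- summarizeMetrics(sub$dice)
        sm <- summarizeMetrics(sub$msd)
        data.frame(group = g, medDice = sd_["MED"], iqrDice = sd_["IQR"],
                   medMsd = sm["MED"], iqrMsd = sm["IQR"], row.names = NULL)
    }))
    wide <- function(metric) {
        m <- sapply(groups, function(g) {
            sub <- metrics[metrics$group == g, ]
            sub[[metric]][match(patients, sub$patient)]
        })
        matrix(m, nrow = length(patients), dimnames = list(patients, groups))
    }
    friedman <- c(dice = NA_real_, msd = NA_real_)
    pairwise <- data.frame(a = character(), b = character(),
                           metric = character(), pRaw = numeric(),
                           pAdj = numeric())
    if (is.null(reference)) {
        pairs <- utils::combn(groups, 2, simplify = FALSE)
        family <- length(pairs)
        for (metric in c("dice", "msd")) {
            m <- wide(metric)
            if (anyNA(m) || length(groups) < 3L) next
            friedman[metric] <- stats::friedman.test(m)$p.value
            if (is.na(friedman[metric]) || friedman[metric] >= alpha) next
            for (pr in pairs) {
                p <- pairedWilcoxon(m[, pr[1]], m[, pr[2]])
                pairwise <- rbind(pairwise, data.frame(a = pr[1], b = pr[2],
                    metric = metric, pRaw = p, pAdj = min(1, p * family)))
            }
        }
    } else {
        others <- setdiff(groups, reference)
        family <- length(others)
        for (metric in c("dice", "msd")) {
            m <- wide(metric)
            for (g in others) {
                p <- pairedWilcoxon(m[, g], m[, reference])
                pairwise <- rbind(pairwise, data.frame(a = g, b = reference,
                    metric = metric, pRaw = p,
                    pAdj = if (is.na(p)) NA_real_ else min(1, p * family)))
            }
        }
    }
    new("ComparisonTable", summary = summary, friedman = friedman,
        pairwise = pairwise, family = as.integer(
            if (is.null(reference)) choose(length(groups), 2)
            else length(groups) - 1L),
        reference = reference %||% "", metrics = metrics)
}

#' Experiment 1: algorithm comparison on T2w features
#'
#' Runs patient-level LOO cross-validation for every classifier kind in the
#' config using T2w features only, applies the semi-automatic
#' post-processing, and compares the per-patient Dice and MSD across
#' algorithms with a Friedman omnibus test followed (when significant at
#' 0.05) by all pairwise two-sided Wilcoxon signed-rank tests with
#' Bonferroni correction over the C(k,2) pairs.
#'
#' @param config an [ExperimentConfig-class].
#' @param cohort optional pre-generated cohort (from [generateCohort()]).
#' @return A [ComparisonTable-class]; `attr(,"results")` holds the
#'   per-patient [SegmentationResult-class] lists.
#' @export
runAlgorithmComparison <- function(config, cohort = NULL) {
    if (is.null(cohort)) cohort <- generateCohort(config)
    full <- lapply(cohort, function(s)
        zscoreNormalize(assembleMatrix(s, "T2w")))
    pp <- config@postprocessParams
    allMetrics <- list()
    allResults <- list()
    for (kind in config@kinds) {
        res <- looCv(cohort, kind, "T2w", config@masterSeed,
                     medianRadius = pp$medianRadius %||% 1L,
                     hMaxima = pp$hMaxima %||% 1, fullMatrices = full)
        met <- evaluateResults(res, cohort, kind@kind, "T2w")
        met$group <- kind@kind
        allMetrics[[kind@kind]] <- met
        allResults[[kind@kind]] <- res
    }
    tab <- buildComparison(do.call(rbind, allMetrics), reference = NULL)
    attr(tab, "results") <- allResults
    tab
}

#' Experiment 2: mono- and multi-sequence feature-set comparison
#'
#' Runs LOO cross-validation with one classifier (the first in the config;
#' AdaBoost by default) for every feature-set descriptor and compares each
#' non-reference model against the T2w-only reference with two-sided
#' Wilcoxon signed-rank tests, Bonferroni-corrected over the number of
#' comparisons.
#'
#' @param config an [ExperimentConfig-class]; `config@descriptors` must
#'   include the `"T2w"` reference.
#' @param cohort optional pre-generated cohort.
#' @return A [ComparisonTable-class] with reference row "T2w".
#' @export
runFeaturesetComparison <- function(config, cohort = NULL) {
    if (is.null(cohort)) cohort <- generateCohort(config)
    kind <- config@kinds[[1]]
    descs <- config@descriptors
    labels <- vapply(descs, function(d) paste(d, collapse = "+"), "")
    if (!"T2w" %in% labels)
        stop("the descriptor list must include the T2w reference")
    superset <- normalizeDescriptor(unique(unlist(descs)))
    full <- lapply(cohort, function(s)
        zscoreNormalize(assembleMatrix(s, superset)))
    pp <- config@postprocessParams
    allMetrics <- list()
    allResults <- list()
    for (i in seq_along(descs)) {
        res <- looCv(cohort, kind, descs[[i]], config@masterSeed,
                     medianRadius = pp$medianRadius %||% 1L,
                     hMaxima = pp$hMaxima %||% 1, fullMatrices = full)
        met <- evaluateResults(res, cohort, kind@kind, descs[[i]])
        met$group <- labels[i]
        allMetrics[[labels[i]]] <- met
        allResults[[labels[i]]] <- res
    }
    tab <- buildComparison(do.call(rbind, allMetrics), reference = "T2w")
    attr(tab, "results") <- allResults
    tab
}
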