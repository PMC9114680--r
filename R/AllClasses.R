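#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib mpMRIseg, .registration = TRUE
NULL

SEQUENCE_NAMES <- c("T2w", "T2sw", "DW", "DME")

#' ImageVolume: a 3D scalar grid with physical geometry
#'
#' A single-channel volumetric image. Voxel data are stored as a 3D array in
#' (x, y, z) order with z the axial (slice) direction. `origin` is the world
#' coordinate (mm) of the centre of the first voxel (0-based index (0,0,0)),
#' so the centre of 0-based voxel `i` sits at `origin + i * spacing`. Grids
#' are axis-aligned; subject misalignment between sequences is modelled as a
#' rigid transform of the imaged anatomy, not of the grid.
#'
#' @slot data 3D numeric (or logical for masks) array.
#' @slot spacing voxel spacing in mm, length 3, all positive.
#' @slot origin world coordinate (mm) of the first voxel centre, length 3.
#' @slot channel free-form channel tag, e.g. `list(sequence="DW", b=1000)`.
#' @export
setClass("ImageVolume",
    representation(data = "array", spacing = "numeric", origin = "numeric",
                   channel = "list"),
    validity = function(object) {
        if (length(dim(object@data)) != 3L) return("data must be a 3D array")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            return("spacing must be 3 positive values (mm)")
        if (length(object@origin) != 3L) return("origin must have length 3")
        TRUE
    })

#' Construct an ImageVolume
#'
#' @param data 3D array.
#' @param spacing voxel spacing (mm), length 3 (recycled if scalar).
#' @param origin world position (mm) of the first voxel centre.
#' @param channel channel tag list.
#' @return An [ImageVolume-class] object.
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        channel = list()) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("ImageVolume", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin), channel = channel)
}

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("ImageVolume %d x %d x %d, spacing %s mm\n", d[1], d[2], d[3],
                paste(format(object@spacing, digits = 3), collapse = " x ")))
    if (length(object@channel))
        cat("  channel:", paste(names(object@channel),
            vapply(object@channel, function(x) paste(format(x), collapse = ","),
                   ""), sep = "=", collapse = ", "), "\n")
    invisible(NULL)
})

#' RoiBox: an axis-aligned region of interest in world coordinates
#'
#' The box is closed in mm and half-open in 0-based index space on the
#' isotropic analysis grid derived from it: the grid has
#' `floor((upper - lower)/spacing)` voxels per axis with voxel centres at
#' `lower + (i + 0.5) * spacing`.
#'
#' @slot lowerMm,upperMm box corners in mm, lower < upper on every axis.
#' @slot spacing isotropic analysis-grid spacing (mm), default 1.
#' @slot indexLower,indexUpper 0-based voxel index range (upper exclusive).
#' @export
setClass("RoiBox",
    representation(lowerMm = "numeric", upperMm = "numeric", spacing = "numeric",
                   indexLower = "integer", indexUpper = "integer"),
    validity = function(object) {
        if (any(object@upperMm < object@lowerMm))
            return("box must satisfy lower <= upper on every axis")
        if (object@spacing <= 0) return("spacing must be positive")
        TRUE
    })

#' Construct a RoiBox
#' @param lowerMm,upperMm box corners (mm).
#' @param spacing isotropic grid spacing (mm).
#' @return A [RoiBox-class].
#' @export
roiBox <- function(lowerMm, upperMm, spacing = 1) {
    n <- pmax(1L, as.integer(floor((upperMm - lowerMm) / spacing + 1e-9)))
    new("RoiBox", lowerMm = as.numeric(lowerMm), upperMm = as.numeric(upperMm),
        spacing = as.numeric(spacing), indexLower = rep(0L, 3L), indexUpper = n)
}

setMethod("show", "RoiBox", function(object) {
    cat(sprintf("RoiBox [%s] - [%s] mm, grid %s @ %g mm\n",
                paste(format(object@lowerMm, digits = 4), collapse = ", "),
                paste(format(object@upperMm, digits = 4), collapse = ", "),
                paste(object@indexUpper, collapse = " x "), object@spacing))
    invisible(NULL)
})

#' TimepointSelection: the selected dynamic acquisition subset
#'
#' @slot indices 1-based indices into the acquisition timestamp list (14).
#' @slot timestamps the selected timestamps (s), non-decreasing.
#' @slot arrival contrast-arrival time (s); the first selected image is the
#'   acquisition closest to it.
#' @export
setClass("TimepointSelection",
    representation(indices = "integer", timestamps = "numeric",
                   arrival = "numeric"),
    validity = function(object) {
        if (length(object@indices) != 14L) return("exactly 14 time points required")
        if (is.unsorted(object@timestamps)) return("timestamps must be non-decreasing")
        if (anyDuplicated(object@indices)) return("selected indices must be distinct")
        TRUE
    })

setMethod("show", "TimepointSelection", function(object) {
    cat("TimepointSelection: 14 images, t =",
        paste(format(object@timestamps - object@arrival), collapse = ", "),
        "s after arrival\n")
    invisible(NULL)
})

#' PhantomSpec: parameters of the synthetic multi-sequence study generator
#'
#' Defines the per-sequence acquisition grids (defaults follow the clinical
#' 1.5 T protocol: T2w 0.35 mm in-plane / 2.75 mm slices, T2*w 0.7/4.0 mm,
#' DW 1.25/4.3 mm, DME 0.7/5.0 mm), the tumor geometry, the two-tissue signal
#' model (mono-exponential diffusion and T2* decay, parametric contrast
#' uptake), per-sequence rigid misalignment and noise, and the simulated
#' observer perturbation amplitude.
#'
#' @slot grids named list (T2w, T2sw, DW, DME) of `list(dim, spacing)`.
#' @slot tumorCenter,tumorSemiAxes ellipsoid centre and semi-axes (mm).
#' @slot tumorIrregularityMm amplitude of smooth boundary irregularity (mm).
#' @slot adc apparent diffusion coefficients, `c(tumor=, normal=)` (mm^2/s).
#' @slot t2star T2* relaxation times, `c(tumor=, normal=)` (ms).
#' @slot t2wMeans T2w mean intensities per tissue (a.u.).
#' @slot dce uptake parameters per tissue: `list(tumor=c(A, kin, kout), ...)`
#'   (amplitude, uptake rate 1/s, washout rate 1/s).
#' @slot s0 pre-contrast baseline signal per sequence `c(T2sw=, DW=, DME=)`.
#' @slot bValues diffusion b-values (s/mm^2).
#' @slot echoTimesT2star,echoTimesDme echo times (ms).
#' @slot timestamps dynamic acquisition times (s), strictly increasing.
#' @slot arrival contrast-arrival time (s).
#' @slot misalignment named list per sequence: `list(translation, rotation)`
#'   (mm, deg); applied to the anatomy when rendering that sequence's grid.
#' @slot noiseSd additive Gaussian noise sd per sequence.
#' @slot observerAmplitudeMm boundary-displacement amplitude of the simulated
#'   observers (mm); the default is calibrated so two observers of a 30 mm
#'   sphere agree at a median Dice near 0.82.
#' @slot textureAmplitude relative amplitude of the smooth anatomical texture
#'   field shared by all sequences (gives the registration its structure).
#' @export
setClass("PhantomSpec",
    representation(grids = "list", tumorCenter = "numeric",
        tumorSemiAxes = "numeric", tumorIrregularityMm = "numeric",
        adc = "numeric", t2star = "numeric", t2wMeans = "numeric",
        dce = "list", s0 = "numeric", bValues = "numeric",
        echoTimesT2star = "numeric", echoTimesDme = "numeric",
        timestamps = "numeric", arrival = "numeric", misalignment = "list",
        noiseSd = "numeric", observerAmplitudeMm = "numeric",
        textureAmplitude = "numeric"),
    validity = function(object) {
        if (!all(SEQUENCE_NAMES %in% names(object@grids)))
            return("grids must define T2w, T2sw, DW and DME")
        for (s in SEQUENCE_NAMES) {
            g <- object@grids[[s]]
            if (any(g$spacing <= 0)) return(sprintf("%s spacing must be > 0", s))
            if (any(g$dim < 2)) return(sprintf("%s grid dim must be >= 2", s))
        }
        if (any(object@noiseSd < 0)) return("noise sd must be >= 0")
        if (length(object@bValues) != 7L) return("seven b-values required")
        if (length(object@echoTimesT2star) != 5L) return("five T2*w echo times required")
        if (length(object@echoTimesDme) != 3L) return("three DME echo times required")
        if (any(diff(object@timestamps) <= 0))
            return("dynamic timestamps must be strictly increasing")
        if (max(object@timestamps) - object@arrival < 508)
            return("dynamic timestamps must span >= 508 s after contrast arrival")
        msg <- checkTumorInFov(object)
        if (!isTRUE(msg)) return(msg)
        TRUE
    })

# tumor (including irregularity margin) must fit in every sequence FOV
checkTumorInFov <- function(spec) {
    reach <- spec@tumorSemiAxes + spec@tumorIrregularityMm
    for (s in SEQUENCE_NAMES) {
        g <- spec@grids[[s]]
        half <- g$dim * g$spacing / 2
        if (any(abs(spec@tumorCenter) + reach > half))
            return(sprintf(
                "tumor (centre %s mm, reach %s mm) lies outside the %s field of view (+/- %s mm)",
                paste(spec@tumorCenter, collapse = ","),
                paste(format(reach, digits = 3), collapse = ","), s,
                paste(format(half, digits = 4), collapse = ",")))
    }
    TRUE
}

setMethod("show", "PhantomSpec", function(object) {
    cat("PhantomSpec\n")
    for (s in SEQUENCE_NAMES) {
        g <- object@grids[[s]]
        cat(sprintf("  %-4s grid %s @ %s mm\n", s, paste(g$dim, collapse = "x"),
                    paste(format(g$spacing, digits = 3), collapse = "x")))
    }
    cat(sprintf("  tumor semi-axes %s mm, irregularity %g mm\n",
                paste(object@tumorSemiAxes, collapse = "/"),
                object@tumorIrregularityMm))
    cat(sprintf("  %d dynamic time points, arrival %g s\n",
                length(object@timestamps), object@arrival))
    invisible(NULL)
})

#' MultiSequenceStudy: one patient's multi-sequence volumes and delineations
#'
#' Holds the T2w volume, the five-echo T2*w series, the seven-b-value DW
#' series, the dynamic multi-echo (DME) contrast series (three echoes per
#' time point, time-major order), two observer tumor masks and the
#' generator-known truth mask (phantom studies). Before preprocessing each
#' sequence lives on its own acquisition grid and the masks live on the T2w
#' grid; after [registerAndResample()] everything shares the isotropic
#' analysis grid.
#'
#' @slot patientId character id.
#' @slot t2w [ImageVolume-class].
#' @slot t2star list of 5 volumes in ascending echo-time order.
#' @slot dw list of 7 volumes in ascending b-value order.
#' @slot dme list of volumes, time-major then echo; `dmeInfo` gives one row
#'   per volume (time index, echo index, timestamp, TE).
#' @slot dmeInfo data.frame describing `dme`.
#' @slot bValues,echoTimesT2star,echoTimesDme channel metadata.
#' @slot timestamps all dynamic acquisition times (s).
#' @slot arrival contrast-arrival time (s).
#' @slot observerA,observerB,truth binary masks.
#' @slot meta list: generator misalignments, preprocessing state (selection,
#'   estimated transforms, ROI box), etc.
#' @export
setClass("MultiSequenceStudy",
    representation(patientId = "character", t2w = "ImageVolume",
        t2star = "list", dw = "list", dme = "list", dmeInfo = "data.frame",
        bValues = "numeric", echoTimesT2star = "numeric",
        echoTimesDme = "numeric", timestamps = "numeric", arrival = "numeric",
        observerA = "ImageVolume", observerB = "ImageVolume",
        truth = "ImageVolume", meta = "list"),
    validity = function(object) {
        if (length(object@t2star) != 5L) return("five T2*w echoes required")
        if (length(object@dw) != 7L) return("seven DW b-value volumes required")
        if (length(object@echoTimesDme) != 3L) return("three DME echoes required")
        if (length(object@dme) %% 3L != 0L)
            return("DME volume count must be a multiple of the echo count (3)")
        if (nrow(object@dmeInfo) != length(object@dme))
            return("dmeInfo must describe every DME volume")
        dt <- dim(object@t2w@data)
        for (m in c("observerA", "observerB", "truth")) {
            mv <- slot(object, m)
            if (!identical(dim(mv@data), dt))
                return(sprintf("%s mask must live on the T2w grid", m))
            if (!all(mv@data %in% c(0, 1)))
                return(sprintf("%s mask must be binary", m))
        }
        TRUE
    })

setMethod("show", "MultiSequenceStudy", function(object) {
    cat(sprintf("MultiSequenceStudy '%s'%s\n", object@patientId,
                if (isTRUE(object@meta$preprocessed)) " (preprocessed)" else ""))
    cat(sprintf("  T2w %s | 5 T2*w echoes | 7 DW b-values | %d DME volumes\n",
                paste(dim(object@t2w@data), collapse = "x"), length(object@dme)))
    cat(sprintf("  truth mask: %d voxels; observers: %d / %d voxels\n",
                sum(object@truth@data), sum(object@observerA@data),
                sum(object@observerB@data)))
    invisible(NULL)
})

#' FeatureMatrix: voxel-by-feature table for one patient
#'
#' @slot values numeric matrix, one row per voxel.
#' @slot voxelIndex integer matrix (n x 3), 0-based voxel indices on the ROI
#'   grid.
#' @slot labels integer 0/1 per row (union ground-truth membership).
#' @slot patientId character.
#' @slot descriptor ordered subset of `c("T2w","T2sw","DW","DME")`.
#' @slot channels character per column: the image channel each feature is
#'   drawn from (the nine sorted T2w neighbourhood features share the "T2w"
#'   channel).
#' @slot normStats data.frame (channel, mean, sd) used by z-scoring; 0-row
#'   until [zscoreNormalize()] is applied.
#' @export
setClass("FeatureMatrix",
    representation(values = "matrix", voxelIndex = "matrix", labels = "integer",
        patientId = "character", descriptor = "character",
        channels = "character", normStats = "data.frame"),
    validity = function(object) {
        if (anyNA(object@values)) return("feature values must not contain NA")
        if (nrow(object@values) != length(object@labels))
            return("labels must match rows")
        if (nrow(object@values) != nrow(object@voxelIndex))
            return("voxelIndex must match rows")
        if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
        if (length(object@channels) != ncol(object@values))
            return("channels must match columns")
        if (!length(object@descriptor) ||
            !all(object@descriptor %in% SEQUENCE_NAMES))
            return("descriptor must be a non-empty subset of T2w/T2sw/DW/DME")
        exp <- featureCount(object@descriptor)
        if (ncol(object@values) != exp)
            return(sprintf("descriptor implies %d features, found %d", exp,
                           ncol(object@values)))
        TRUE
    })

setMethod("show", "FeatureMatrix", function(object) {
    cat(sprintf("FeatureMatrix '%s': %d voxels x %d features {%s}, %d tumor\n",
                object@patientId, nrow(object@values), ncol(object@values),
                paste(object@descriptor, collapse = "+"), sum(object@labels)))
    invisible(NULL)
})

#' ClassifierKind: one of the four voxel classifiers with hyperparameters
#'
#' @slot kind "LDA", "QDA", "SVM" or "ADA".
#' @slot hyper hyperparameter list. SVM: `kernel` ("linear"), `cost` (1).
#'   ADA: `rounds` (100), `learningRate` (1), `depth` (1 = decision stumps).
#' @export
setClass("ClassifierKind",
    representation(kind = "character", hyper = "list"),
    validity = function(object) {
        if (!object@kind %in% c("LDA", "QDA", "SVM", "ADA"))
            return("kind must be LDA, QDA, SVM or ADA")
        TRUE
    })

#' Construct a ClassifierKind
#' @param kind "LDA", "QDA", "SVM" or "ADA".
#' @param ... hyperparameter overrides (see [ClassifierKind-class]).
#' @return A [ClassifierKind-class].
#' @export
classifierKind <- function(kind = c("LDA", "QDA", "SVM", "ADA"), ...) {
    kind <- match.arg(kind)
    hyper <- switch(kind,
        SVM = list(kernel = "linear", cost = 1),
        ADA = list(rounds = 100L, learningRate = 1, depth = 1L),
        list())
    dots <- list(...)
    hyper[names(dots)] <- dots
    new("ClassifierKind", kind = kind, hyper = hyper)
}

setMethod("show", "ClassifierKind", function(object) {
    h <- if (length(object@hyper))
        paste0(" (", paste(names(object@hyper), vapply(object@hyper, format, ""),
                           sep = "=", collapse = ", "), ")") else ""
    cat("ClassifierKind ", object@kind, h, "\n", sep = "")
    invisible(NULL)
})

#' TrainedModel: a fitted voxel classifier
#'
#' @slot kind the [ClassifierKind-class] used.
#' @slot descriptor feature-set descriptor the model expects.
#' @slot fit opaque fitted state.
#' @slot trainPatients patient ids in the training cohort.
#' @slot seed training seed.
#' @export
setClass("TrainedModel",
    representation(kind = "ClassifierKind", descriptor = "character",
                   fit = "ANY", trainPatients = "character", seed = "integer"))

setMethod("show", "TrainedModel", function(object) {
    cat(sprintf("TrainedModel %s on {%s}, trained on %d patients\n",
                object@kind@kind, paste(object@descriptor, collapse = "+"),
                length(object@trainPatients)))
    invisible(NULL)
})

#' RegionLabelMap: watershed-separated regions of a mask
#'
#' @slot labels integer array (0 = background, regions 1..K).
#' @slot nRegions K.
#' @slot counts per-region voxel counts.
#' @slot spacing grid spacing (mm).
#' @export
setClass("RegionLabelMap",
    representation(labels = "array", nRegions = "integer", counts = "integer",
                   spacing = "numeric"),
    validity = function(object) {
        k <- object@nRegions
        if (k > 0 && !setequal(seq_len(k), unique(object@labels[object@labels > 0])))
            return("region labels must be contiguous 1..K")
        if (length(object@counts) != k) return("counts must have one entry per region")
        TRUE
    })

setMethod("show", "RegionLabelMap", function(object) {
    cat(sprintf("RegionLabelMap: %d regions (%s voxels)\n", object@nRegions,
                paste(object@counts, collapse = ", ")))
    invisible(NULL)
})

#' SeedSet: one simulated seed per axial slice of the ground truth
#'
#' @slot voxels integer matrix (n x 3) of 0-based voxel indices.
#' @slot seed RNG seed used to sample them.
#' @export
setClass("SeedSet",
    representation(voxels = "matrix", seed = "integer"),
    validity = function(object) {
        if (ncol(object@voxels) != 3L) return("voxels must be an n x 3 matrix")
        if (anyDuplicated(object@voxels[, 3L]))
            return("at most one seed per axial slice")
        TRUE
    })

setMethod("show", "SeedSet", function(object) {
    cat(sprintf("SeedSet: %d seeds (one per slice)\n", nrow(object@voxels)))
    invisible(NULL)
})

#' SegmentationResult: raw and post-processed prediction for one patient
#'
#' @slot patientId character.
#' @slot raw raw voxelwise prediction mask.
#' @slot smoothed median-filtered mask.
#' @slot labelMap watershed [RegionLabelMap-class].
#' @slot seeds [SeedSet-class] used for region selection.
#' @slot final final semi-automatic segmentation.
#' @slot meta list (classifier kind, descriptor, seeds).
#' @export
setClass("SegmentationResult",
    representation(patientId = "character", raw = "ImageVolume",
        smoothed = "ImageVolume", labelMap = "RegionLabelMap",
        seeds = "SeedSet", final = "ImageVolume", meta = "list"))

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf("SegmentationResult '%s': raw %d -> final %d voxels (%d regions kept from %d)\n",
                object@patientId, sum(object@raw@data), sum(object@final@data),
                length(object@meta$keptRegions %||% integer()),
                object@labelMap@nRegions))
    invisible(NULL)
})

#' SurfaceVoxelSet: border voxels of a mask
#'
#' Surface voxels are mask voxels with at least one face-adjacent
#' (6-connectivity) background neighbour; the volume boundary counts as
#' background.
#'
#' @slot voxels integer matrix (N x 3), 0-based indices.
#' @slot coordsMm numeric matrix (N x 3), voxel-centre world coordinates.
#' @slot count N.
#' @export
setClass("SurfaceVoxelSet",
    representation(voxels = "matrix", coordsMm = "matrix", count = "integer"))

setMethod("show", "SurfaceVoxelSet", function(object) {
    cat(sprintf("SurfaceVoxelSet: %d surface voxels\n", object@count))
    invisible(NULL)
})

#' ExperimentConfig: a phantom-cohort experiment definition
#'
#' @slot nPatients cohort size (>= 2).
#' @slot spec [PhantomSpec-class] template.
#' @slot variation per-patient jitter: `list(semiAxesFrac=, centerMm=)`.
#' @slot masterSeed master RNG seed; all per-patient and per-fold seeds
#'   derive from it deterministically.
#' @slot kinds list of [ClassifierKind-class].
#' @slot descriptors list of feature-set descriptors (character vectors).
#' @slot marginMm bounding-box margin (mm), default 20.
#' @slot spacing analysis-grid spacing (mm), default 1.
#' @slot register estimate rigid transforms (TRUE) or assume aligned.
#' @slot postprocessParams `list(medianRadius=, hMaxima=)`.
#' @export
setClass("ExperimentConfig",
    representation(nPatients = "integer", spec = "PhantomSpec",
        variation = "list", masterSeed = "integer", kinds = "list",
        descriptors = "list", marginMm = "numeric", spacing = "numeric",
        register = "logical", postprocessParams = "list"),
    validity = function(object) {
        if (object@nPatients < 2L) return("cohort size must be >= 2")
        ds <- vapply(object@descriptors, function(d) paste(d, collapse = "+"), "")
        if (anyDuplicated(ds)) return("descriptors must be unique")
        TRUE
    })

setMethod("show", "ExperimentConfig", function(object) {
    cat(sprintf("ExperimentConfig: %d patients, seed %d, %d classifier(s), %d descriptor(s)\n",
                object@nPatients, object@masterSeed, length(object@kinds),
                length(object@descriptors)))
    invisible(NULL)
})

#' ComparisonTable: summarized experiment results with statistics
#'
#' @slot summary data.frame: one row per algorithm or feature set with
#'   median and interquartile range of Dice and MSD across patients.
#' @slot friedman named numeric: Friedman omnibus p-values (NA when not run).
#' @slot pairwise data.frame of Wilcoxon signed-rank comparisons: columns
#'   a, b, metric, pRaw, pAdj (Bonferroni: `min(1, pRaw * family)`).
#' @slot family Bonferroni family size.
#' @slot reference reference row id ("" when the comparison is all-pairs).
#' @slot metrics per-patient metrics records underlying the table.
#' @export
setClass("ComparisonTable",
    representation(summary = "data.frame", friedman = "numeric",
        pairwise = "data.frame", family = "integer", reference = "character",
        metrics = "data.frame"))

setMethod("show", "ComparisonTable", function(object) {
    cat("ComparisonTable (reference:",
        if (nzchar(object@reference)) object@reference else "none", ")\n")
    print(object@summary, row.names = FALSE)
    if (length(object@friedman) && any(!is.na(object@friedman)))
        cat("Friedman p:", paste(names(object@friedman),
            format.pval(object@friedman, digits = 3), collapse = ", "), "\n")
    invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
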