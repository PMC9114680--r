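# NIfTI study I/O, experiment reports and the run manifest.

volumeToNifti <- function(vol) {
    im <- RNifti::asNifti(vol@data)
    RNifti::pixdim(im) <- vol@spacing
    aff <- diag(c(vol@spacing, 1))
    aff[1:3, 4] <- vol@origin
    RNifti::`qform<-`(im, structure(aff, code = 2L))
}

niftiToVolume <- function(path, channel = list()) {
    im <- RNifti::readNifti(path)
    aff <- RNifti::xform(im)
    imageVolume(array(as.numeric(im), dim(im)[1:3]),
                spacing = abs(diag(aff)[1:3]), origin = aff[1:3, 4],
                channel = channel)
}

#' Write a study as NIfTI volumes with a JSON sidecar
#'
#' One `.nii.gz` file per channel plus `study.json` listing the b-values,
#' echo times, dynamic timestamps, contrast-arrival time and the file map.
#'
#' @param study a [MultiSequenceStudy-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(vol, name) {
        RNifti::writeNifti(volumeToNifti(vol), file.path(dir, name))
        name
    }
    files <- list(
        t2w = wr(study@t2w, "t2w.nii.gz"),
        t2star = vapply(seq_along(study@t2star), function(i)
            wr(study@t2star[[i]], sprintf("t2sw_e%d.nii.gz", i)), ""),
        dw = vapply(seq_along(study@dw), function(i)
            wr(study@dw[[i]], sprintf("dw_b%g.nii.gz", study@bValues[i])), ""),
        dme = vapply(seq_along(study@dme), function(i)
            wr(study@dme[[i]], sprintf("dme_t%03d_e%d.nii.gz",
                study@dmeInfo$time[i], study@dmeInfo$echo[i])), ""),
        observerA = wr(study@observerA, "observerA.nii.gz"),
        observerB = wr(study@observerB, "observerB.nii.gz"),
        truth = wr(study@truth, "truth.nii.gz"))
    sidecar <- list(patientId = study@patientId, files = files,
        bValues = study@bValues, echoTimesT2star = study@echoTimesT2star,
        echoTimesDme = study@echoTimesDme, timestamps = study@timestamps,
        arrival = study@arrival, dmeInfo = study@dmeInfo,
        preprocessed = isTRUE(study@meta$preprocessed))
    jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    invisible(dir)
}

#' Read a study written by [writeStudy()]
#'
#' @param dir directory containing the NIfTI channels and `study.json`.
#' @return A [MultiSequenceStudy-class].
#' @export
readStudy <- function(dir) {
    side <- jsonlite::read_json(file.path(dir, "study.json"),
                                simplifyVector = TRUE)
    rd <- function(name, channel = list())
        niftiToVolume(file.path(dir, name), channel)
    dmeInfo <- as.data.frame(side$dmeInfo)
    new("MultiSequenceStudy", patientId = side$patientId,
        t2w = rd(side$files$t2w, list(sequence = "T2w")),
        t2star = lapply(seq_along(side$files$t2star), function(i)
            rd(side$files$t2star[i],
               list(sequence = "T2sw", te = side$echoTimesT2star[i]))),
        dw = lapply(seq_along(side$files$dw), function(i)
            rd(side$files$dw[i], list(sequence = "DW", b = side$bValues[i]))),
        dme = lapply(seq_along(side$files$dme), function(i)
            rd(side$files$dme[i], list(sequence = "DME",
                t = dmeInfo$timestamp[i], te = dmeInfo$te[i]))),
        dmeInfo = dmeInfo, bValues = side$bValues,
        echoTimesT2star = side$echoTimesT2star,
        echoTimesDme = side$echoTimesDme, timestamps = side$timestamps,
        arrival = side$arrival,
        observerA = rd(side$files$observerA, list(sequence = "mask", role = "observerA")),
        observerB = rd(side$files$observerB, list(sequence = "mask", role = "observerB")),
        truth = rd(side$files$truth, list(sequence = "mask", role = "truth")),
        meta = list(preprocessed = isTRUE(side$preprocessed)))
}

specToList <- function(spec) {
    list(grids = spec@grids, tumorCenter = spec@tumorCenter,
        tumorSemiAxes = spec@tumorSemiAxes,
        tumorIrregularityMm = spec@tumorIrregularityMm,
        adc = as.list(spec@adc), t2star = as.list(spec@t2star),
        t2wMeans = as.list(spec@t2wMeans),
        dce = lapply(spec@dce, as.list), s0 = as.list(spec@s0),
        bValues = spec@bValues, echoTimesT2star = spec@echoTimesT2star,
        echoTimesDme = spec@echoTimesDme, timestamps = spec@timestamps,
        arrival = spec@arrival, misalignment = spec@misalignment,
        noiseSd = as.list(spec@noiseSd),
        observerAmplitudeMm = spec@observerAmplitudeMm,
        textureAmplitude = spec@textureAmplitude)
}

listToSpec <- function(l) {
    nv <- function(x) {
        out <- vapply(x, as.numeric, numeric(1))
        names(out) <- names(x)
        out
    }
    phantomSpec(
        grids = lapply(l$grids, function(g)
            list(dim = as.integer(unlist(g$dim)),
                 spacing = as.numeric(unlist(g$spacing)))),
        tumorCenter = as.numeric(unlist(l$tumorCenter)),
        tumorSemiAxes = as.numeric(unlist(l$tumorSemiAxes)),
        tumorIrregularityMm = as.numeric(l$tumorIrregularityMm),
        adc = nv(l$adc), t2star = nv(l$t2star), t2wMeans = nv(l$t2wMeans),
        dce = lapply(l$dce, nv), s0 = nv(l$s0),
        bValues = as.numeric(unlist(l$bValues)),
        echoTimesT2star = as.numeric(unlist(l$echoTimesT2star)),
        echoTimesDme = as.numeric(unlist(l$echoTimesDme)),
        timestamps = as.numeric(unlist(l$timestamps)),
        arrival = as.numeric(l$arrival),
        misalignment = lapply(l$misalignment, function(m)
            list(translation = as.numeric(unlist(m$translation)),
                 rotation = as.numeric(unlist(m$rotation)))),
        noiseSd = nv(l$noiseSd),
        observerAmplitudeMm = as.numeric(l$observerAmplitudeMm),
        textureAmplitude = as.numeric(l$textureAmplitude))
}

configToList <- function(config, experiment) {
    list(experiment = experiment,
        nPatients = config@nPatients, masterSeed = config@masterSeed,
        variation = config@variation,
        kinds = lapply(config@kinds, function(k)
            list(kind = k@kind, hyper = k@hyper)),
        descriptors = config@descriptors, marginMm = config@marginMm,
        spacing = config@spacing, register = config@register,
        postprocessParams = config@postprocessParams,
        spec = specToList(config@spec))
}

listToConfig <- function(l) {
    experimentConfig(nPatients = as.integer(l$nPatients),
        spec = listToSpec(l$spec), variation = l$variation,
        masterSeed = as.integer(l$masterSeed),
        kinds = lapply(l$kinds, function(k)
            do.call(classifierKind, c(list(kind = k$kind), k$hyper))),
        descriptors = lapply(l$descriptors, unlist),
        marginMm = as.numeric(l$marginMm), spacing = as.numeric(l$spacing),
        register = isTRUE(l$register),
        postprocessParams = list(
            medianRadius = as.integer(l$postprocessParams$medianRadius),
            hMaxima = as.numeric(l$postprocessParams$hMaxima)))
}

#' Write an experiment report
#'
#' Writes the per-patient metrics (`metrics.csv`), the comparison summary
#' (`comparison_summary.csv`), the statistical tests (`comparison_tests.csv`)
#' and a run manifest (`manifest.json`) holding the full configuration —
#' master seed, derived per-patient seeds, classifier hyperparameters,
#' phantom spec — so the run can be reproduced bit-for-bit with
#' [runFromManifest()].
#'
#' @param table a [ComparisonTable-class].
#' @param outdir output directory (created if missing).
#' @param config the [ExperimentConfig-class] that produced the table.
#' @param experiment "algorithm" or "featureset".
#' @return named character vector of the written paths, invisibly.
#' @export
writeReport <- function(table, outdir, config, experiment) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
    paths <- c(metrics = file.path(outdir, "metrics.csv"),
               summary = file.path(outdir, "comparison_summary.csv"),
               tests = file.path(outdir, "comparison_tests.csv"),
               manifest = file.path(outdir, "manifest.json"))
    utils::write.csv(table@metrics, paths["metrics"], row.names = FALSE)
    utils::write.csv(table@summary, paths["summary"], row.names = FALSE)
    tests <- table@pairwise
    tests$family <- if (nrow(tests)) table@family else integer(0)
    utils::write.csv(tests, paths["tests"], row.names = FALSE)
    ids <- sprintf("P%02d", seq_len(config@nPatients))
    manifest <- c(configToList(config, experiment),
        list(friedman = as.list(table@friedman),
             patientSeeds = lapply(stats::setNames(ids, ids), function(id)
                 list(jitter = patientSeed(config@masterSeed, id, 3L),
                      generate = patientSeed(config@masterSeed, id, 4L),
                      undersample = patientSeed(config@masterSeed, id, 0L),
                      train = patientSeed(config@masterSeed, id, 1L),
                      seeds = patientSeed(config@masterSeed, id, 2L))),
             package = list(name = "mpMRIseg",
                 version = as.character(utils::packageVersion("mpMRIseg")),
                 rVersion = R.version.string)))
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}

#' Re-run an experiment from its manifest
#'
#' Reconstructs the configuration from a `manifest.json` written by
#' [writeReport()], re-runs the experiment and writes a fresh report. With
#' an unchanged package version the CSV outputs are bit-identical to the
#' original run.
#'
#' @param manifestPath path to `manifest.json`.
#' @param outdir output directory for the re-run report.
#' @return the re-run [ComparisonTable-class], invisibly.
#' @export
runFromManifest <- function(manifestPath, outdir) {
    man <- jsonlite::read_json(manifestPath, simplifyVector = FALSE)
    config <- listToConfig(man)
    table <- switch(man$experiment,
        algorithm = runAlgorithmComparison(config),
        featureset = runFeaturesetComparison(config),
        stop("unknown experiment type: ", man$experiment))
    writeReport(table, outdir, config, man$experiment)
    invisible(table)
}
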