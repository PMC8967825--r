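#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline (simulate -> surface fit
#' -> multi-layer projection -> maximum projection -> spot counting) into a
#' plain, YAML-serializable list with canonicalized types, so that
#' \code{readPipelineConfig(writePipelineConfig(cfg)) } reproduces the
#' configuration exactly. Defaults are the standard analysis settings:
#' binning 4 per axis, adaptive sensitivity 0.4, 2 um layer step, 85 degree
#' Mercator truncation.
#'
#' Exactly one of \code{input} (a TIFF path) or \code{simulate} (a list of
#' [EmbryoSpec()] arguments) should be set.
#'
#' @param input path to a volume TIFF, or \code{NULL} to simulate.
#' @param spacing optional numeric(3) um override for plain TIFF inputs.
#' @param simulate \code{NULL} or a named list of [EmbryoSpec()] arguments.
#' @param binning integer(3) binning factor.
#' @param sensitivity adaptive-binarization sensitivity.
#' @param window optional binarization window (integer(3), odd).
#' @param layerStep,layerDepthInward,layerDepthOutward layer geometry, um.
#' @param truncationLat map truncation latitude, degrees.
#' @param gridMode \code{"mercator"} or \code{"equirect"}.
#' @param sampler \code{"trilinear"} or \code{"nearest"}.
#' @param pixelSize optional um of equatorial arc per map column (default:
#'   smallest voxel spacing of the volume).
#' @param spots named list of [SpotParams()] arguments.
#' @param rois named list; each element a list with \code{lo} and \code{hi}
#'   um triples (z, y, x).
#' @param seed integer seed for the simulation stage.
#' @param outDir output directory.
#' @return A \code{SphereMapConfig} (plain named list).
#' @export
pipelineConfig <- function(input = NULL, spacing = NULL, simulate = NULL,
                           binning = c(4L, 4L, 4L), sensitivity = 0.4,
                           window = NULL, layerStep = 2,
                           layerDepthInward = 10, layerDepthOutward = 0,
                           truncationLat = 85,
                           gridMode = c("mercator", "equirect"),
                           sampler = c("trilinear", "nearest"),
                           pixelSize = NULL,
                           spots = list(), rois = list(), seed = 1L,
                           outDir = "spheremap_out") {
    cfg <- list(
        input = if (!is.null(input)) as.character(input),
        spacing = if (!is.null(spacing)) as.numeric(spacing),
        simulate = if (!is.null(simulate)) lapply(simulate, .yaml_canon),
        binning = as.integer(rep(binning, length.out = 3L)),
        sensitivity = as.numeric(sensitivity),
        window = if (!is.null(window))
            as.integer(rep(window, length.out = 3L)),
        layerStep = as.numeric(layerStep),
        layerDepthInward = as.numeric(layerDepthInward),
        layerDepthOutward = as.numeric(layerDepthOutward),
        truncationLat = as.numeric(truncationLat),
        gridMode = match.arg(gridMode),
        sampler = match.arg(sampler),
        pixelSize = if (!is.null(pixelSize)) as.numeric(pixelSize),
        spots = lapply(spots, as.numeric),
        rois = lapply(rois, function(b)
            list(lo = as.numeric(unlist(b$lo)), hi = as.numeric(unlist(b$hi)))),
        seed = as.integer(seed),
        outDir = as.character(outDir))
    structure(cfg, class = "SphereMapConfig")
}

## canonical YAML-stable scalar types for simulate arguments
.yaml_canon <- function(x) {
    if (is.character(x)) x else as.numeric(unlist(x))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a \code{SphereMapConfig} from [pipelineConfig()].
#' @param path YAML file path.
#' @return \code{writePipelineConfig}: the path, invisibly;
#'   \code{readPipelineConfig}: the parsed \code{SphereMapConfig}, equal to
#'   the one written.
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    x <- yaml::read_yaml(path)
    do.call(pipelineConfig, x[!vapply(x, is.null, logical(1))])
}

.log_line <- function(con, fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    if (!is.null(con)) writeLines(msg, con)
}

#' Run the end-to-end pipeline
#'
#' Executes simulate (or read) -> surface fit -> multi-layer Mercator
#' projection -> cross-layer maximum projection -> spot counting, writing
#' every intermediate artifact into \code{config$outDir}:
#' \code{sphere.json}, \code{layers.tif} (+ \code{layers_meta.json} with the
#' per-layer offsets and grid geometry), \code{maxproj.tif},
#' \code{spots.json}, \code{counts.csv}, \code{run.log} and a
#' \code{manifest.json} holding the config snapshot, package version,
#' per-stage timings, input checksums and output list. Any stage error
#' aborts with the stage name; given identical config, seed and inputs the
#' outputs are identical.
#'
#' @param config a \code{SphereMapConfig} from [pipelineConfig()].
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "SphereMapConfig"))
    ## validate inputs before touching the filesystem: no partial outputs
    if (is.null(config$input) && is.null(config$simulate))
        .stopf("stage 'acquire': neither an input path nor a simulation %s",
               "request is configured")
    if (!is.null(config$input) && !file.exists(config$input))
        .stopf("stage 'acquire': input path '%s' does not exist",
               config$input)

    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(config$outDir, "run.log")
    con <- file(logfile, open = "wt")
    on.exit(close(con), add = TRUE)
    timings <- list()
    outputs <- character()
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(force(expr), error = function(e)
            .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
        timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
        res
    }

    .log_line(con, "SphereMap pipeline (package version %s)",
              as.character(packageVersion("SphereMap")))
    checksums <- list()
    sim_truth <- NULL
    v <- stage("acquire", {
        if (!is.null(config$input)) {
            checksums[[config$input]] <-
                unname(tools::md5sum(config$input))
            .log_line(con, "acquire: reading '%s'", config$input)
            readVolume(config$input, spacing = config$spacing)
        } else {
            args <- config$simulate
            args$seed <- config$seed
            spec <- do.call(EmbryoSpec, args)
            .log_line(con,
                "acquire: simulating %d cells, R = %g um, noise '%s', seed %d",
                spec@nCells, spec@sphereRadius, spec@noiseModel, spec@seed)
            sim <- generateVolume(spec, timepoint = "sim")
            sim_truth <- sim$truth
            sim$volume
        }
    })

    sphere <- stage("fit-sphere", {
        .log_line(con,
            "fit-sphere: binning (%s), sensitivity %g",
            paste(config$binning, collapse = ","), config$sensitivity)
        s <- estimateSurface(v, config$binning, config$sensitivity,
                             config$window)
        f <- file.path(config$outDir, "sphere.json")
        writeSphereModel(s, f)
        outputs <- c(outputs, f)
        .log_line(con,
            "fit-sphere: center (%.2f, %.2f, %.2f) um, radius %.2f um (rms %.3f, n = %d)",
            s@center[1], s@center[2], s@center[3], s@radius,
            s@rmsResidual, s@nPoints)
        s
    })

    stack <- stage("project", {
        px <- if (!is.null(config$pixelSize)) config$pixelSize
              else min(spacing(v))
        grid <- makeGrid(R = sphere@radius,
                         truncationLat = config$truncationLat,
                         mode = config$gridMode, pixelSize = px)
        offs <- layerOffsets(config$layerStep, config$layerDepthInward,
                             config$layerDepthOutward)
        .log_line(con,
            "project: %d layers (step %g um), grid %d x %d (%s, |lat| <= %g)",
            length(offs), config$layerStep, length(grid@latitudes),
            length(grid@longitudes), config$gridMode, config$truncationLat)
        st <- projectMultilayer(v, sphere, offs, grid,
                                sampler = config$sampler)
        arr <- array(0, dim = c(length(offs), dim(grid)))
        for (k in seq_along(offs)) arr[k, , ] <- st@layers[[k]]
        px_um <- 2 * pi * sphere@radius / length(grid@longitudes)
        lv <- VoxelVolume(arr, c(max(config$layerStep, 1e-6), px_um, px_um))
        f <- file.path(config$outDir, "layers.tif")
        writeVolume(lv, f)
        meta <- list(offsets_um = offs, n_rows = length(grid@latitudes),
                     n_cols = length(grid@longitudes),
                     truncation_lat_deg = grid@truncationLat,
                     reference_radius_um = grid@referenceRadius,
                     mode = grid@mode, sampler = config$sampler)
        fm <- file.path(config$outDir, "layers_meta.json")
        jsonlite::write_json(meta, fm, digits = NA, auto_unbox = TRUE)
        outputs <- c(outputs, f, fm)
        st
    })

    stage("max-project", {
        mp <- maxProjectLayers(stack)
        px_um <- 2 * pi * sphere@radius / ncol(mp)
        f <- file.path(config$outDir, "maxproj.tif")
        writeVolume(VoxelVolume(array(mp, c(1L, dim(mp))),
                                c(1, px_um, px_um)), f)
        outputs <- c(outputs, f)
        NULL
    })

    counts <- stage("count", {
        sp <- do.call(SpotParams, config$spots)
        rois <- lapply(names(config$rois), function(nm)
            ROIBox(nm, config$rois[[nm]]$lo, config$rois[[nm]]$hi))
        tp <- if (!is.na(timepoint(v))) timepoint(v) else "t0"
        rec <- list(list(volume = v, timepoint = tp, condition = "na",
                         embryo_id = "embryo1"))
        tab <- quantifyTimecourse(rec, sp, rois)
        fc <- file.path(config$outDir, "counts.csv")
        writeCountTable(tab, fc)
        spots <- detectSpots(v, sp, timepoint = tp)
        fs <- file.path(config$outDir, "spots.json")
        jsonlite::write_json(
            list(centroids_um = spots@centroids,
                 peak_intensities = spots@peakIntensities),
            fs, digits = NA)
        outputs <- c(outputs, fc, fs)
        .log_line(con, "count: %d spots in whole volume", length(spots))
        tab
    })

    manifest <- list(
        config = unclass(config),
        version = as.character(packageVersion("SphereMap")),
        timings_s = as.list(timings),
        input_checksums = checksums,
        outputs = basename(c(outputs, logfile)),
        counts = counts,
        ground_truth_counts = if (!is.null(sim_truth))
            as.list(trueCounts(sim_truth)))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    .log_line(con, "done: outputs in '%s'", config$outDir)
    invisible(manifest)
}
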