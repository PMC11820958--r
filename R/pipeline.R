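# End-to-end orchestration: premask -> beta-mixture fit -> threshold ->
# median filter -> 4D CCL -> split-merge -> size filter -> fate reporting.

#' Parameter presets
#'
#' Documented defaults per target cell type. The oligodendrocyte preset uses
#' the 99th-percentile background pre-mask and 80th-percentile fallback
#' threshold; the astrocyte preset relaxes them to 98 and 70 (astrocyte
#' processes differ from myelin sheaths, so more candidate voxels are kept).
#' All other tunables are shared.
#'
#' @param preset \code{"oligodendrocyte"} or \code{"astrocyte"}.
#' @return Named list of pipeline parameters.
#' @export
presetParams <- function(preset = c("oligodendrocyte", "astrocyte")) {
  preset <- match.arg(preset)
  p <- list(premaskPercentile = 99, fallbackPercentile = 80,
            minValues = 50L, maxIter = 200L, tol = 1e-6,
            medianWindow = c(11L, 11L, 3L), cclKernel = c(3L, 3L, 3L, 3L),
            mergeHalfwidth = c(2L, 2L, 2L), mergeGap = 1L,
            minComponentSize = 30L, depthBinUm = 100)
  if (preset == "astrocyte") {
    p$premaskPercentile <- 98
    p$fallbackPercentile <- 70
  }
  p
}

#' Assemble a pipeline run configuration
#'
#' Starts from a preset and applies explicit overrides. A configuration can
#' also be loaded from a YAML file whose keys mirror the parameter names.
#'
#' @param input character vector of input TIFF paths (one per timepoint, or
#'   a single hyperstack), or NULL when a stack is passed to [runPipeline()]
#'   directly.
#' @param preset parameter preset name; see [presetParams()].
#' @param outputDir directory for the output bundle.
#' @param seed integer seed for the per-slice EM initializations.
#' @param cores worker processes for slice fitting.
#' @param voxelSize numeric(3), micrometres per voxel.
#' @param nz,timeMajor hyperstack layout, passed to [readStack()].
#' @param ... parameter overrides (any name in [presetParams()]).
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(input = NULL, preset = "oligodendrocyte",
                      outputDir = tempfile("somatrack_run_"), seed = 1L,
                      cores = 1L, voxelSize = c(1, 1, 1), nz = NULL,
                      timeMajor = FALSE, ...) {
  params <- presetParams(preset)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params[names(overrides)] <- overrides
  structure(list(input = input, preset = preset, outputDir = outputDir,
                 seed = as.integer(seed), cores = as.integer(cores),
                 voxelSize = voxelSize, nz = nz, timeMajor = timeMajor,
                 params = params),
            class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file; top-level keys are [runConfig()] arguments and
#'   parameter names.
#' @return A \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

#' Run the full segmentation-and-tracking pipeline
#'
#' Executes the stages in order (per-slice pre-mask, beta-mixture fit and
#' threshold; 3D binary median filter per timepoint; 4D connected-component
#' labeling; temporal split-merge; minimum-size filter; fate
#' classification) and writes the output bundle: the denoised binary stack
#' and the label stack as multi-page TIFFs, the per-cell and per-timepoint
#' fate CSVs, the per-slice fit diagnostics CSV, and a JSON manifest of all
#' effective parameters. Runs are reproducible given (config, seed); serial
#' and parallel executions produce identical outputs.
#'
#' @param config a \code{"RunConfig"} from [runConfig()].
#' @param stack optionally, an in-memory \linkS4class{ImageStack4D}
#'   (bypasses \code{config$input}).
#' @param writeOutputs logical; set FALSE to skip writing files and only
#'   return results.
#' @return Invisibly, a list with \code{binary}, \code{components},
#'   \code{fates}, \code{cells}, \code{cellRows}, \code{diagnostics} and
#'   \code{paths}.
#' @export
runPipeline <- function(config, stack = NULL, writeOutputs = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  p <- config$params
  if (is.null(stack)) {
    stopifnot(!is.null(config$input))
    stack <- readStack(config$input, nz = config$nz,
                       timeMajor = config$timeMajor,
                       voxelSize = config$voxelSize)
  }
  stopifnot(methods::is(stack, "ImageStack4D"))
  bin <- binarizeStack(stack,
                       premaskPercentile = p$premaskPercentile,
                       fallbackPercentile = p$fallbackPercentile,
                       minValues = p$minValues, maxIter = p$maxIter,
                       tol = p$tol, seed = config$seed,
                       cores = config$cores)
  den <- medianFilter3D(bin$binary, window = p$medianWindow)
  comps <- labelComponents4D(den, kernel = p$cclKernel,
                             voxelSize = voxelSize(stack))
  comps <- mergeSplitComponents(comps, halfwidth = p$mergeHalfwidth,
                                gap = p$mergeGap)
  comps <- filterSmallComponents(comps, minSize = p$minComponentSize)
  cf <- classifyFates(comps)
  rows <- cellTable(comps)
  paths <- list()
  if (writeOutputs) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    paths$binary <- file.path(config$outputDir, "binary.tif")
    writeLabelStack(den, paths$binary)
    paths$labels <- file.path(config$outputDir, "labels.tif")
    writeLabelStack(comps, paths$labels)
    paths$cells <- file.path(config$outputDir, "cells.csv")
    writeCellTable(rows, paths$cells)
    paths$fates <- file.path(config$outputDir, "fates.csv")
    writeFateTable(cf$fates, paths$fates)
    paths$diagnostics <- file.path(config$outputDir, "diagnostics.csv")
    dg <- bin$diagnostics
    .writeCSV(names(dg),
              do.call(paste, c(lapply(dg, function(col) {
                if (is.numeric(col) && !is.integer(col))
                  ifelse(is.na(col), "", sprintf("%.8g", col))
                else as.character(col)
              }), sep = ",")),
              paths$diagnostics)
    paths$manifest <- file.path(config$outputDir, "manifest.json")
    manifest <- list(preset = config$preset, seed = config$seed,
                     cores = config$cores, voxelSize = config$voxelSize,
                     parameters = p, dims = dim(stack),
                     nComponents = nCells(comps),
                     fallbackSlices = sum(dg$thresholdSource ==
                                            "fallback_percentile"),
                     degenerateSlices = sum(dg$thresholdSource ==
                                              "degenerate"))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(binary = den, components = comps, fates = cf$fates,
                 cells = cf$cells, cellRows = rows,
                 diagnostics = bin$diagnostics, paths = paths))
}
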