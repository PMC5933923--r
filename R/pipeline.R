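#' Read a pipeline run configuration
#'
#' A run configuration is a YAML or JSON file (by extension) with a
#' \code{stage} field naming the analysis to run and stage-specific
#' parameters; see \code{\link{runPipeline}} for the stages and their
#' parameters. Flags given to \code{runPipeline(..., overrides = )} take
#' precedence over file values.
#'
#' @param path config file (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return named list of parameters.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::fromJSON(path, simplifyVector = TRUE)
    else stop("config must be .yaml/.yml or .json")
    if (is.null(cfg$stage)) stop("config needs a 'stage' field")
    cfg
}

.pipelineStages <- c("simulate_chip", "simulate_nuclei", "simulate_frap",
                     "chip_normalize", "ribbon", "zoning", "frap_fit",
                     "coloc")

.requireParams <- function(cfg, params) {
    missing <- setdiff(params, names(cfg))
    if (length(missing))
        stop("stage '", cfg$stage, "' needs parameter(s): ",
             paste(missing, collapse = ", "))
}

#' Run one pipeline stage reproducibly
#'
#' Uniform front end over the package's stages. Every run writes its
#' artifacts plus a \code{provenance.json} recording the stage,
#' parameters, seed and package version, so identical config + seed
#' reproduce identical numerical outputs. Stages and key parameters:
#' \describe{
#'   \item{simulate_chip}{\code{n_isolates}, \code{seed}; writes one
#'     bedgraph per isolate from \code{\link{simulateChipCoverage}} on
#'     \code{\link{toyGenome}} with default \code{\link{enrichmentModel}}
#'     settings (override via \code{multipliers}, \code{baseline},
#'     \code{spike_mix_fraction}, \code{overdispersion}).}
#'   \item{simulate_nuclei}{\code{n_cells}, \code{peripheral_bias},
#'     \code{seed}; writes a cells TSV.}
#'   \item{simulate_frap}{\code{true_k}, \code{seed} (and optional
#'     \code{true_plateau}, \code{true_y0}, \code{noise_sd},
#'     \code{interval}, \code{n_timepoints}, \code{n_cells}); writes a
#'     traces TSV.}
#'   \item{chip_normalize}{\code{coverage} (bedgraph paths),
#'     \code{spike_interval}, \code{reference_interval},
#'     \code{constant}; writes normalized bedgraphs and a scale-factor
#'     table.}
#'   \item{ribbon}{\code{coverage}, \code{region}, \code{window},
#'     \code{step}; writes a ribbon TSV.}
#'   \item{zoning}{\code{input} (cells TSV), \code{test}; writes a
#'     summary TSV.}
#'   \item{frap_fit}{\code{input} (traces TSV), \code{mode}; writes a
#'     fit report JSON.}
#'   \item{coloc}{\code{input_a}, \code{input_b} (TSV matrices),
#'     \code{threshold}, \code{cutoff_um}; writes dots/pairs TSVs and a
#'     summary JSON.}
#' }
#'
#' @param config list (e.g. from \code{\link{readRunConfig}}) or a config
#'   file path.
#' @param outputDir directory for artifacts (created if needed).
#' @param overrides named list overriding config values.
#' @return named list of artifact paths (plus the provenance path),
#'   invisibly.
#' @export
runPipeline <- function(config, outputDir, overrides = list()) {
    if (is.character(config)) config <- readRunConfig(config)
    config[names(overrides)] <- overrides
    stage <- config$stage
    if (!stage %in% .pipelineStages)
        stop("unknown stage '", stage, "'; available: ",
             paste(.pipelineStages, collapse = ", "))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- switch(stage,
        simulate_chip = .stageSimulateChip(config, outputDir),
        simulate_nuclei = .stageSimulateNuclei(config, outputDir),
        simulate_frap = .stageSimulateFrap(config, outputDir),
        chip_normalize = .stageChipNormalize(config, outputDir),
        ribbon = .stageRibbon(config, outputDir),
        zoning = .stageZoning(config, outputDir),
        frap_fit = .stageFrapFit(config, outputDir),
        coloc = .stageColoc(config, outputDir))
    prov <- list(stage = stage, parameters = config,
                 seed = config$seed,
                 package = list(name = "perinuc",
                                version = as.character(
                                    utils::packageVersion("perinuc"))),
                 artifacts = out)
    provPath <- file.path(outputDir, "provenance.json")
    jsonlite::write_json(prov, provPath, auto_unbox = TRUE, null = "null",
                         digits = NA)
    invisible(c(out, provenance = provPath))
}

.stageSimulateChip <- function(cfg, dir) {
    .requireParams(cfg, c("n_isolates", "seed"))
    genome <- toyGenome()
    args <- list()
    if (!is.null(cfg$multipliers))
        args$multipliers <- unlist(cfg$multipliers)
    for (p in c("baseline", "overdispersion"))
        if (!is.null(cfg[[p]])) args[[p]] <- cfg[[p]]
    if (!is.null(cfg$spike_mix_fraction))
        args$spikeMixFraction <- cfg$spike_mix_fraction
    model <- do.call(enrichmentModel, args)
    tracks <- simulateChipCoverage(genome, model,
                                   nIsolates = cfg$n_isolates,
                                   seed = cfg$seed)
    paths <- vapply(seq_along(tracks), function(i) {
        p <- file.path(dir, sprintf("isolate%02d.bedgraph", i))
        writeBedGraph(tracks[[i]], p)
        p
    }, character(1))
    list(bedgraphs = paths)
}

.stageSimulateNuclei <- function(cfg, dir) {
    .requireParams(cfg, c("n_cells", "seed"))
    obs <- simulateNuclei(nCells = cfg$n_cells,
                          radius = cfg$radius %||% 1.74,
                          peripheralBias = cfg$peripheral_bias %||% 0,
                          stageMix = cfg$stage_mix %||% 0.5,
                          strain = cfg$strain %||% "wt",
                          replicate = cfg$replicate %||% 1L,
                          seed = cfg$seed)
    p <- file.path(dir, "cells.tsv")
    writeNucleiTSV(obs, p)
    list(cells = p)
}

.stageSimulateFrap <- function(cfg, dir) {
    .requireParams(cfg, c("true_k", "seed"))
    traces <- simulateFrap(trueK = cfg$true_k,
                           truePlateau = cfg$true_plateau %||% 0.9,
                           trueY0 = cfg$true_y0 %||% 0.2,
                           noiseSd = cfg$noise_sd %||% 0.05,
                           interval = cfg$interval %||% 2,
                           nTimepoints = cfg$n_timepoints %||% 60L,
                           nCells = cfg$n_cells %||% 12L,
                           seed = cfg$seed)
    p <- file.path(dir, "traces.tsv")
    writeFrapTSV(traces, p)
    list(traces = p)
}

.spikeCfgFromList <- function(cfg) {
    SpikeNormConfig(
        spikeInterval = cfg$spike_interval,
        referenceInterval = cfg$reference_interval,
        constant = cfg$constant %||% 10,
        excludeSpike = isTRUE(cfg$exclude_spike))
}

.stageChipNormalize <- function(cfg, dir) {
    .requireParams(cfg, c("coverage", "spike_interval",
                          "reference_interval"))
    scfg <- .spikeCfgFromList(cfg)
    outPaths <- character(0); log <- NULL
    for (p in cfg$coverage) {
        if (!file.exists(p)) stop("missing coverage file: ", p)
        tr <- readBedGraph(p)
        S <- spikeScaleFactor(tr, scfg)
        norm <- normalizeTrack(tr, S)
        op <- file.path(dir, sub("\\.bedgraph$", ".norm.bedgraph",
                                 basename(p)))
        writeBedGraph(norm, op)
        outPaths <- c(outPaths, op)
        log <- rbind(log, data.frame(input = p,
                                     m_spike = attr(S, "mSpike"),
                                     m_ref = attr(S, "mRef"),
                                     scale_factor = as.numeric(S)))
    }
    lp <- file.path(dir, "scale_factors.tsv")
    write.table(log, lp, sep = "\t", quote = FALSE, row.names = FALSE)
    list(normalized = outPaths, scale_factors = lp)
}

.stageRibbon <- function(cfg, dir) {
    .requireParams(cfg, c("coverage", "region"))
    tracks <- lapply(cfg$coverage, function(p) {
        if (!file.exists(p)) stop("missing coverage file: ", p)
        readBedGraph(p)
    })
    rp <- ribbonProfile(tracks, region = cfg$region,
                        window = cfg$window %||% 250L,
                        step = cfg$step %||% 25L,
                        isolateSummary = cfg$isolate_summary %||% "mean")
    p <- file.path(dir, "ribbon.tsv")
    writeRibbonTSV(rp, p)
    list(ribbon = p)
}

.stageZoning <- function(cfg, dir) {
    .requireParams(cfg, "input")
    if (!file.exists(cfg$input)) stop("missing input: ", cfg$input)
    obs <- readNucleiTSV(cfg$input)
    summ <- testZone1Enrichment(obs,
                                expected = cfg$expected %||% (1 / 3),
                                method = cfg$test %||% "ttest")
    p <- file.path(dir, "zoning_summary.tsv")
    write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
    list(summary = p)
}

.stageFrapFit <- function(cfg, dir) {
    .requireParams(cfg, "input")
    if (!file.exists(cfg$input)) stop("missing input: ", cfg$input)
    traces <- readFrapTSV(cfg$input)
    avg <- averageTraces(traces, mode = cfg$mode %||% "subtracted")
    fit <- fitRecovery(avg)
    p <- file.path(dir, "frap_fit.json")
    jsonlite::write_json(list(k = fit@k, half_life = fit@halfLife,
                              y0 = fit@y0, plateau = fit@plateau,
                              r_squared = fit@rSquared,
                              n_timepoints = fit@n,
                              n_cells = avg$n[1],
                              degenerate = fit@degenerate),
                         p, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    list(fit = p)
}

.stageColoc <- function(cfg, dir) {
    .requireParams(cfg, c("input_a", "input_b", "threshold"))
    readMat <- function(p) {
        if (!file.exists(p)) stop("missing input: ", p)
        as.matrix(read.delim(p, header = FALSE))
    }
    a <- readMat(cfg$input_a); b <- readMat(cfg$input_b)
    px <- cfg$pixel_size %||% 1
    dotsA <- detectDots(a, threshold = cfg$threshold,
                        minSize = cfg$min_size %||% 2L, pixelSize = px)
    dotsB <- detectDots(b, threshold = cfg$threshold,
                        minSize = cfg$min_size %||% 2L, pixelSize = px)
    res <- assignColocalization(dotsA, dotsB,
                                cutoff = cfg$cutoff_um %||% 0.25)
    pa <- file.path(dir, "dots_a.tsv"); pb <- file.path(dir, "dots_b.tsv")
    pp <- file.path(dir, "pairs.tsv")
    write.table(dotsA, pa, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dotsB, pb, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$pairs, pp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ps <- file.path(dir, "coloc_summary.json")
    jsonlite::write_json(list(n_a = res$nA, n_b = res$nB,
                              n_paired = res$nPaired,
                              pearson = pearsonColoc(a, b)),
                         ps, auto_unbox = TRUE, digits = NA)
    list(dots_a = pa, dots_b = pb, pairs = pp, summary = ps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
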