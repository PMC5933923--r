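#' Genome layout for simulation and coverage bookkeeping
#'
#' A \code{GenomeSpec} names the chromosomes of a (toy or real) reference and
#' annotates domains with a chromatin class. Domain classes drive the
#' expected ChIP enrichment in \code{\link{simulateChipCoverage}}:
#' \code{subtelomere}, \code{pericentromere} and \code{mat} are
#' heterochromatic, \code{euchromatin} is baseline, and \code{spike_locus}
#' marks the single ectopic reference locus carried by the spike strain.
#'
#' @slot seqlengths named integer vector of chromosome lengths (bp).
#' @slot domains \code{GRanges} with metadata columns \code{domain_class}
#'   and \code{name}.
#' @export
setClass("GenomeSpec",
    representation(seqlengths = "integer", domains = "GRanges"))

.DOMAIN_CLASSES <- c("subtelomere", "pericentromere", "mat",
                     "euchromatin", "spike_locus")

setValidity("GenomeSpec", function(object) {
    msg <- character()
    sl <- object@seqlengths
    if (length(sl) == 0L || is.null(names(sl)) || any(!nzchar(names(sl))))
        msg <- c(msg, "seqlengths must be a named integer vector")
    if (any(sl <= 0L))
        msg <- c(msg, "chromosome lengths must be positive")
    d <- object@domains
    if (!all(c("domain_class", "name") %in% colnames(mcols(d))))
        msg <- c(msg, "domains need 'domain_class' and 'name' columns")
    else {
        cls <- mcols(d)$domain_class
        if (!all(cls %in% .DOMAIN_CLASSES))
            msg <- c(msg, paste0("unknown domain_class; allowed: ",
                                 paste(.DOMAIN_CLASSES, collapse = ", ")))
        if (sum(cls == "spike_locus") > 1L)
            msg <- c(msg, "at most one spike_locus domain is allowed")
        chr <- as.character(seqnames(d))
        if (!all(chr %in% names(sl)))
            msg <- c(msg, "domain on unknown chromosome")
        else if (any(start(d) < 1L) || any(end(d) > sl[chr]))
            msg <- c(msg, "domain interval outside its chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Expected-depth model for simulated ChIP coverage
#'
#' Per-domain-class mean depth multipliers over a baseline depth, the
#' fraction of the mixed culture contributed by the spike strain, and a
#' negative-binomial overdispersion. Overdispersion \code{phi} parameterizes
#' Var = mu + phi * mu^2; \code{phi = 0} reduces to Poisson counts.
#'
#' @slot multipliers named numeric, one entry per domain class (>= 0). The
#'   \code{spike_locus} entry is the enrichment of the ectopic reference
#'   locus in the spike strain; sample strains are euchromatic there.
#' @slot baseline expected euchromatic depth, reads per base.
#' @slot spikeMixFraction fraction of reads contributed by the spike strain
#'   (1:4 culture mix = 0.2), assumed proportional to the culture mix.
#' @slot overdispersion phi >= 0.
#' @export
setClass("EnrichmentModel",
    representation(multipliers = "numeric", baseline = "numeric",
                   spikeMixFraction = "numeric", overdispersion = "numeric"))

setValidity("EnrichmentModel", function(object) {
    msg <- character()
    m <- object@multipliers
    if (is.null(names(m)) || !all(names(m) %in% .DOMAIN_CLASSES))
        msg <- c(msg, "multipliers must be named by domain class")
    if (any(m < 0)) msg <- c(msg, "multipliers must be >= 0")
    if (object@baseline <= 0) msg <- c(msg, "baseline must be > 0")
    f <- object@spikeMixFraction
    if (f < 0 || f > 1) msg <- c(msg, "spikeMixFraction must be in [0, 1]")
    if (object@overdispersion < 0)
        msg <- c(msg, "overdispersion must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Per-base read coverage over a genome
#'
#' A run-length encoded per-base depth vector per chromosome, with a flag
#' recording whether spike normalization has been applied. Coordinates are
#' 0-based half-open in bedgraph files and 1-based in R, following the
#' usual rtracklayer conventions.
#'
#' @slot depths \code{RleList}, one \code{Rle} of depths per chromosome.
#' @slot normalized \code{logical(1)}; \code{TRUE} after
#'   \code{\link{normalizeTrack}}.
#' @export
setClass("CoverageTrack",
    representation(depths = "RleList", normalized = "logical"))

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (length(object@normalized) != 1L || is.na(object@normalized))
        msg <- c(msg, "normalized must be TRUE or FALSE")
    if (is.null(names(object@depths)))
        msg <- c(msg, "depths must be named by chromosome")
    mins <- vapply(object@depths, function(x) {
        v <- runValue(x)
        if (length(v)) min(v) else 0
    }, numeric(1))
    if (any(mins < 0)) msg <- c(msg, "depths must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Spike normalization configuration
#'
#' Holds the spike (ectopic \code{ade6+}) interval, the flanking euchromatic
#' reference interval, and the scale constant \eqn{c}. The scale factor is
#' \eqn{S = c / (m_{spike} - m_{ref})} where \eqn{m} are per-base depth
#' medians over the two intervals. Defaults follow the published intervals
#' on chromosome III (1-based inclusive: spike 1316291-1318035, reference
#' 1304000-1380000, \eqn{c = 10}). The published reference interval encloses
#' the spike locus; \code{excludeSpike = TRUE} removes the spike bases from
#' the reference median.
#'
#' @slot spikeInterval,referenceInterval single-range \code{GRanges}.
#' @slot constant positive scale constant \eqn{c}.
#' @slot excludeSpike logical; drop spike bases from the reference median.
#' @export
setClass("SpikeNormConfig",
    representation(spikeInterval = "GRanges", referenceInterval = "GRanges",
                   constant = "numeric", excludeSpike = "logical"))

setValidity("SpikeNormConfig", function(object) {
    msg <- character()
    if (length(object@spikeInterval) != 1L ||
        length(object@referenceInterval) != 1L)
        msg <- c(msg, "spike and reference intervals must each be one range")
    else if (as.character(seqnames(object@spikeInterval)) !=
             as.character(seqnames(object@referenceInterval)))
        msg <- c(msg, "spike and reference intervals must share a chromosome")
    if (length(object@constant) != 1L || object@constant <= 0)
        msg <- c(msg, "constant must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Replicate ribbon profile
#'
#' Sliding-window summary across replicate isolates of normalized coverage:
#' per window, each isolate is summarized (mean or median per-base depth),
#' then the median, minimum and maximum across isolates form the ribbon.
#'
#' @slot windows \code{GRanges} with metadata columns \code{median},
#'   \code{min}, \code{max}.
#' @slot window,step window length and step, bp.
#' @slot isolateSummary \code{"mean"} or \code{"median"}.
#' @slot nIsolates number of tracks summarized.
#' @export
setClass("RibbonProfile",
    representation(windows = "GRanges", window = "integer", step = "integer",
                   isolateSummary = "character", nIsolates = "integer"))

setValidity("RibbonProfile", function(object) {
    msg <- character()
    m <- mcols(object@windows)
    if (!all(c("median", "min", "max") %in% colnames(m)))
        msg <- c(msg, "windows need median/min/max columns")
    else if (any(m$min > m$median + 1e-9) || any(m$median > m$max + 1e-9))
        msg <- c(msg, "ribbon must satisfy min <= median <= max")
    if (object@window < object@step || object@step < 1L)
        msg <- c(msg, "need window >= step >= 1")
    if (length(msg)) msg else TRUE
})

#' Raw FRAP time series for one cell
#'
#' Summed pixel intensities inside the bleached ROI and inside an equal-size
#' background region beside the nucleus, at post-bleach times (t = 0 is the
#' first image after bleaching), plus the corresponding pre-bleach sums.
#'
#' @slot cell cell identifier.
#' @slot times seconds, strictly increasing, >= 0.
#' @slot roi,background summed ROI / background intensities, same length as
#'   \code{times}.
#' @slot preRoi,preBackground pre-bleach sums;
#'   \code{preRoi - preBackground > 0}.
#' @export
setClass("FrapTrace",
    representation(cell = "character", times = "numeric", roi = "numeric",
                   background = "numeric", preRoi = "numeric",
                   preBackground = "numeric"))

setValidity("FrapTrace", function(object) {
    msg <- character()
    n <- length(object@times)
    if (n < 1L) msg <- c(msg, "empty trace")
    if (any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (length(object@roi) != n || length(object@background) != n)
        msg <- c(msg, "roi/background must match times in length")
    if (object@preRoi - object@preBackground <= 0)
        msg <- c(msg, "pre-bleach ROI must exceed pre-bleach background")
    if (length(msg)) msg else TRUE
})

#' One-phase association fit of a FRAP recovery
#'
#' Parameters of \eqn{Y(t) = Y_0 + (P - Y_0)(1 - e^{-kt})} fitted to a
#' normalized recovery series. The mobile fraction is the plateau \eqn{P};
#' the half-life is \eqn{\ln 2 / k}. \code{rSquared} is
#' \eqn{1 - SS_{res}/SS_{tot}} on the fitted data and is \code{NA} for a
#' degenerate (immobile, flat) series.
#'
#' @slot k rate constant, 1/s.
#' @slot y0 normalized intensity at t = 0.
#' @slot plateau fitted plateau (mobile fraction), normalized intensity.
#' @slot halfLife \eqn{\ln 2 / k}, seconds.
#' @slot rSquared goodness of fit, or \code{NA} when degenerate.
#' @slot n number of fitted points.
#' @slot degenerate \code{TRUE} for a flat (immobile) series.
#' @export
setClass("FrapFit",
    representation(k = "numeric", y0 = "numeric", plateau = "numeric",
                   halfLife = "numeric", rSquared = "numeric", n = "integer",
                   degenerate = "logical"))

setValidity("FrapFit", function(object) {
    msg <- character()
    if (!object@degenerate) {
        if (object@k <= 0) msg <- c(msg, "k must be > 0")
        else if (abs(object@halfLife * object@k - log(2)) > 1e-8)
            msg <- c(msg, "halfLife * k must equal log(2)")
        r2 <- object@rSquared
        if (!is.na(r2) && (r2 > 1 + 1e-12))
            msg <- c(msg, "rSquared cannot exceed 1")
    }
    if (length(msg)) msg else TRUE
})

#' Estimated nuclear boundary (circle or sphere)
#'
#' Least-squares circle (2D) or sphere (3D) approximating the nuclear edge,
#' typically fitted to the rim of a nucleoplasmic-background mask.
#'
#' @slot center numeric of length 2 or 3, in the same units as the input.
#' @slot radius positive radius.
#' @slot residual root-mean-square radial residual of the fit.
#' @slot multiNucleus \code{TRUE} when more than one candidate nucleus mask
#'   was found (the largest was kept).
#' @export
setClass("NuclearBoundary",
    representation(center = "numeric", radius = "numeric",
                   residual = "numeric", multiNucleus = "logical"))

setValidity("NuclearBoundary", function(object) {
    msg <- character()
    if (!length(object@center) %in% c(2L, 3L))
        msg <- c(msg, "center must have 2 or 3 coordinates")
    if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
    if (length(msg)) msg else TRUE
})
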