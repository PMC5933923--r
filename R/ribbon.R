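#' Replicate ribbon profile over sliding windows
#'
#' Summarizes replicate coverage tracks (isolates of one genotype) for
#' ribbon line-plots: within each sliding window, each isolate's per-base
#' depths are reduced to one number (mean by default, median optionally);
#' the median across isolates is the plot line and the min/max give the
#' ribbon. With a single track, median = min = max.
#'
#' @param tracks list of \code{\linkS4class{CoverageTrack}} with identical
#'   chromosomes; typically already spike-normalized.
#' @param region a single-range \code{GRanges} or \code{"chr:start-end"}.
#' @param window window length in bp (default 250).
#' @param step step between window starts in bp (default 25; set
#'   \code{step = window} for non-overlapping windows).
#' @param isolateSummary per-isolate within-window statistic:
#'   \code{"mean"} (default) or \code{"median"}.
#' @return a \code{\linkS4class{RibbonProfile}}.
#' @examples
#' trs <- lapply(1:3, function(k)
#'     CoverageTrack(list(chr = rep(k, 1000))))
#' rp <- ribbonProfile(trs, "chr:1-1000", window = 250, step = 250)
#' mcols(ribbonWindows(rp))
#' @export
ribbonProfile <- function(tracks, region, window = 250L, step = 25L,
                          isolateSummary = c("mean", "median")) {
    isolateSummary <- match.arg(isolateSummary)
    if (!length(tracks)) stop("need at least one track")
    if (is(tracks, "CoverageTrack")) tracks <- list(tracks)
    window <- as.integer(window); step <- as.integer(step)
    if (step < 1L || window < step)
        stop("need window >= step >= 1")
    sls <- lapply(tracks, seqlengths)
    if (length(tracks) > 1L &&
        !all(vapply(sls[-1], identical, logical(1), sls[[1]])))
        stop("tracks must share chromosomes and lengths")
    region <- .asRegion(region)
    chr <- as.character(seqnames(region))
    if (!chr %in% names(sls[[1]]) || start(region) < 1L ||
        end(region) > sls[[1]][chr])
        stop("region outside track bounds")

    starts <- seq.int(start(region), by = step,
                      length.out = max(1L, (width(region) - window) %/%
                                            step + 1L))
    starts <- starts[starts + window - 1L <= end(region)]
    if (!length(starts))
        stop("region shorter than one window")
    ends <- starts + window - 1L

    statFun <- if (isolateSummary == "mean") mean else median
    perIso <- vapply(tracks, function(tr) {
        d <- trackDepths(tr)[[chr]]
        v <- Views(d, start = starts, end = ends)
        viewApply(v, function(x) statFun(as.numeric(x)))
    }, numeric(length(starts)))
    perIso <- matrix(perIso, nrow = length(starts))

    gr <- GRanges(chr, IRanges(starts, ends),
                  median = apply(perIso, 1L, median),
                  min = apply(perIso, 1L, min),
                  max = apply(perIso, 1L, max))
    new("RibbonProfile", windows = gr, window = window, step = step,
        isolateSummary = isolateSummary, nIsolates = length(tracks))
}

#' @rdname RibbonProfile-class
#' @param x a \code{RibbonProfile}.
#' @export
setMethod("ribbonWindows", "RibbonProfile", function(x) x@windows)

setMethod("show", "RibbonProfile", function(object) {
    cat(sprintf(paste0("RibbonProfile: %d windows (%d bp, step %d bp), ",
                       "%d isolate(s), per-isolate %s\n"),
                length(object@windows), object@window, object@step,
                object@nIsolates, object@isolateSummary))
})

#' Export a ribbon profile as TSV
#'
#' Columns: chromosome, start, end (1-based inclusive), median, min, max.
#'
#' @param profile a \code{\linkS4class{RibbonProfile}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRibbonTSV <- function(profile, path) {
    g <- profile@windows
    df <- data.frame(chromosome = as.character(seqnames(g)),
                     start = start(g), end = end(g),
                     median = mcols(g)$median, min = mcols(g)$min,
                     max = mcols(g)$max)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
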