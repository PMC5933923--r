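#' Construct a SpikeNormConfig
#'
#' @param spikeInterval,referenceInterval single-range \code{GRanges} or
#'   \code{"chr:start-end"} strings (1-based inclusive). Defaults are the
#'   published chromosome III intervals for the ectopic \code{ade6+} spike
#'   locus and its flanking euchromatin.
#' @param constant positive scale constant \eqn{c} (default 10).
#' @param excludeSpike drop spike-locus bases from the reference median
#'   (the default reference interval encloses the spike locus).
#' @return a \code{\linkS4class{SpikeNormConfig}}.
#' @export
SpikeNormConfig <- function(spikeInterval = "chrIII:1316291-1318035",
                            referenceInterval = "chrIII:1304000-1380000",
                            constant = 10, excludeSpike = FALSE) {
    new("SpikeNormConfig",
        spikeInterval = .asRegion(spikeInterval),
        referenceInterval = .asRegion(referenceInterval),
        constant = as.numeric(constant),
        excludeSpike = isTRUE(excludeSpike))
}

setMethod("show", "SpikeNormConfig", function(object) {
    fmt <- function(g) sprintf("%s:%d-%d", as.character(seqnames(g)),
                               start(g), end(g))
    cat("SpikeNormConfig: S = c / (m_spike - m_ref)\n",
        "  spike:     ", fmt(object@spikeInterval), "\n",
        "  reference: ", fmt(object@referenceInterval),
        if (object@excludeSpike) "  (spike bases excluded)" else "", "\n",
        "  c = ", object@constant, "\n", sep = "")
})

#' Spike-in normalization scale factor
#'
#' Computes \eqn{S = c / (m_{spike} - m_{ref})}: \eqn{m_{spike}} is the
#' median per-base depth over the spike (ectopic \code{ade6+}) locus and
#' \eqn{m_{ref}} the median over the neighbouring euchromatic reference
#' interval. Because the spike strain is the only source of reads enriched
#' at the spike locus, the excess \eqn{m_{spike} - m_{ref}} is a constant
#' reference across samples; dividing \eqn{c} by it gives a factor that
#' puts all samples on a common scale without input normalization.
#'
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param cfg a \code{\linkS4class{SpikeNormConfig}}.
#' @param verbose log \eqn{m_{spike}}, \eqn{m_{ref}} and \eqn{S} with
#'   \code{message()}.
#' @return the scale factor \eqn{S} (numeric), with attributes
#'   \code{mSpike} and \code{mRef}.
#' @examples
#' tr <- CoverageTrack(list(chr = c(rep(5, 50), rep(25, 20), rep(5, 30))))
#' cfg <- SpikeNormConfig("chr:51-70", "chr:1-100", constant = 10,
#'                        excludeSpike = TRUE)
#' spikeScaleFactor(tr, cfg)
#' @export
spikeScaleFactor <- function(track, cfg, verbose = FALSE) {
    stopifnot(is(track, "CoverageTrack"), is(cfg, "SpikeNormConfig"))
    spikeDepths <- regionDepths(track, cfg@spikeInterval)
    refDepths <- regionDepths(track, cfg@referenceInterval)
    if (cfg@excludeSpike) {
        pos <- start(cfg@referenceInterval):end(cfg@referenceInterval)
        inSpike <- pos >= start(cfg@spikeInterval) &
                   pos <= end(cfg@spikeInterval)
        refDepths <- refDepths[!inSpike]
        if (!length(refDepths))
            stop("reference interval empty after excluding the spike locus")
    }
    mSpike <- median(spikeDepths)
    mRef <- median(refDepths)
    if (mSpike <= mRef)
        stop(sprintf(paste0("no spike enrichment: median spike depth ",
                            "(%.4g) does not exceed reference median ",
                            "(%.4g)"), mSpike, mRef))
    S <- cfg@constant / (mSpike - mRef)
    if (verbose)
        message(sprintf("m_spike = %.6g, m_ref = %.6g, S = %.6g",
                        mSpike, mRef, S))
    structure(S, mSpike = mSpike, mRef = mRef)
}

#' Apply a spike scale factor to a coverage track
#'
#' Multiplies every per-base depth by \code{S} and marks the track as
#' normalized. No input-chromatin normalization is applied. Because
#' \eqn{S} is inversely proportional to overall depth, the normalized
#' track is invariant to rescaling the raw depths by any constant.
#'
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param S positive scale factor, usually from
#'   \code{\link{spikeScaleFactor}}.
#' @return a normalized \code{\linkS4class{CoverageTrack}}.
#' @export
normalizeTrack <- function(track, S) {
    stopifnot(is(track, "CoverageTrack"))
    S <- as.numeric(S)
    if (length(S) != 1L || !is.finite(S) || S <= 0)
        stop("S must be a single positive number")
    CoverageTrack(track@depths * S, normalized = TRUE)
}

#' Spike-normalize a set of replicate tracks
#'
#' Convenience wrapper: computes each track's own scale factor and applies
#' it, so replicate isolates become directly comparable.
#'
#' @param tracks list of \code{\linkS4class{CoverageTrack}}.
#' @param cfg a \code{\linkS4class{SpikeNormConfig}}.
#' @param verbose log per-track medians and factors.
#' @return list of normalized tracks, same names/order.
#' @export
normalizeTracks <- function(tracks, cfg, verbose = FALSE) {
    lapply(tracks, function(tr)
        normalizeTrack(tr, spikeScaleFactor(tr, cfg, verbose = verbose)))
}
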