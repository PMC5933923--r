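#' Construct an EnrichmentModel
#'
#' @param multipliers named per-domain-class depth multipliers. The
#'   defaults emulate wild-type H3K9me2 ChIP enrichment: strong signal at
#'   subtelomeres, pericentromeres and the \emph{mat} locus over a
#'   euchromatic baseline, and a strongly enriched ectopic \code{ade6+}
#'   locus in the spike strain.
#' @param baseline expected euchromatic depth, reads/bp (default 10).
#' @param spikeMixFraction read fraction contributed by the spike strain;
#'   default 0.2 (a 1:4 culture mix, read share assumed proportional).
#' @param overdispersion negative-binomial phi (Var = mu + phi mu^2);
#'   0 gives Poisson counts. Default 0.1.
#' @return an \code{\linkS4class{EnrichmentModel}}.
#' @export
enrichmentModel <- function(multipliers = c(subtelomere = 8,
                                            pericentromere = 10, mat = 8,
                                            euchromatin = 1,
                                            spike_locus = 10),
                            baseline = 10, spikeMixFraction = 0.2,
                            overdispersion = 0.1) {
    full <- c(subtelomere = 1, pericentromere = 1, mat = 1,
              euchromatin = 1, spike_locus = 1)
    full[names(multipliers)] <- multipliers
    new("EnrichmentModel", multipliers = full,
        baseline = as.numeric(baseline),
        spikeMixFraction = as.numeric(spikeMixFraction),
        overdispersion = as.numeric(overdispersion))
}

setMethod("show", "EnrichmentModel", function(object) {
    cat("EnrichmentModel: baseline", object@baseline, "reads/bp,",
        "spike fraction", object@spikeMixFraction, ", phi",
        object@overdispersion, "\n  multipliers:",
        paste(names(object@multipliers), object@multipliers, sep = "=",
              collapse = ", "), "\n")
})

# Expected per-base depth for one chromosome: baseline times the sample's
# domain-class multiplier, plus a spike term confined to the spike locus,
# mu_spike_extra = baseline * spike_locus multiplier * spikeMixFraction
# (sample strains are euchromatic at the spike locus; the spike strain's
# contribution scales with its share of the mixed culture).
.expectedDepth <- function(genome, model, chr) {
    len <- seqlengths(genome)[[chr]]
    mu <- rep(model@baseline * model@multipliers[["euchromatin"]], len)
    d <- domains(genome)
    d <- d[as.character(seqnames(d)) == chr]
    for (i in seq_along(d)) {
        cls <- mcols(d)$domain_class[i]
        span <- start(d)[i]:end(d)[i]
        if (cls == "spike_locus") {
            mu[span] <- mu[span] + model@baseline *
                model@multipliers[["spike_locus"]] * model@spikeMixFraction
        } else {
            mu[span] <- model@baseline * model@multipliers[[cls]]
        }
    }
    mu
}

#' Simulate spiked ChIP coverage tracks
#'
#' Draws per-base depths for \code{nIsolates} independent isolates of one
#' genotype from an overdispersed count model whose expectation follows
#' the domain layout of \code{genome}: expected depth = baseline x
#' domain-class multiplier, plus, over the spike locus only, a
#' spike-strain contribution proportional to \code{spikeMixFraction}
#' (baseline x spike multiplier x fraction).
#'
#' @param genome a \code{\linkS4class{GenomeSpec}}; must contain a
#'   \code{spike_locus} domain whenever \code{spikeMixFraction > 0}.
#' @param model an \code{\linkS4class{EnrichmentModel}}.
#' @param nIsolates number of replicate isolates.
#' @param seed RNG seed; the same seed reproduces identical tracks.
#' @param depthScale optional multiplier applied to each isolate's
#'   expected depth (recycled), emulating library-size differences.
#' @return list of raw \code{\linkS4class{CoverageTrack}}.
#' @export
simulateChipCoverage <- function(genome, model, nIsolates = 3L,
                                 seed = NULL, depthScale = 1) {
    stopifnot(is(genome, "GenomeSpec"), is(model, "EnrichmentModel"))
    if (model@spikeMixFraction > 0 &&
        !any(mcols(domains(genome))$domain_class == "spike_locus"))
        stop("spikeMixFraction > 0 but genome has no spike_locus domain")
    depthScale <- rep_len(depthScale, nIsolates)
    mus <- lapply(names(seqlengths(genome)), function(chr)
        .expectedDepth(genome, model, chr))
    names(mus) <- names(seqlengths(genome))
    phi <- model@overdispersion
    .withSeed(seed, {
        lapply(seq_len(nIsolates), function(i) {
            depths <- lapply(mus, function(mu) {
                m <- mu * depthScale[i]
                if (phi > 0) Rle(rnbinom(length(m), mu = m, size = 1 / phi))
                else Rle(rpois(length(m), m))
            })
            CoverageTrack(RleList(depths), normalized = FALSE)
        })
    })
}

#' Expected per-base depth of the simulation model
#'
#' The closed-form expectation used by \code{\link{simulateChipCoverage}};
#' useful as an oracle for checking empirical means.
#'
#' @inheritParams simulateChipCoverage
#' @param chr chromosome name.
#' @return numeric vector of expected depths over \code{chr}.
#' @export
expectedChipDepth <- function(genome, model, chr)
    .expectedDepth(genome, model, chr)

#' Simulate locus positions inside spherical nuclei
#'
#' Each cell gets a spherical nucleus; with probability
#' \code{peripheralBias} the locus is drawn uniformly within the
#' outermost equal-volume shell (Zone I), otherwise uniformly in the
#' whole sphere. Cell-cycle stages are assigned by \code{stageMix}. The
#' expected Zone-I fraction is \code{peripheralBias +
#' (1 - peripheralBias) / 3}.
#'
#' @param nCells number of cells.
#' @param radius nuclear radius (um, default 1.74).
#' @param peripheralBias probability a locus is placed in Zone I.
#' @param stageMix fraction of cells in early/mid S (binucleate).
#' @param strain strain label.
#' @param replicate replicate id.
#' @param seed RNG seed.
#' @return data.frame, one row per cell: \code{strain},
#'   \code{replicate}, \code{stage}, \code{n_nuclei}, nucleus center
#'   \code{cx,cy,cz}, \code{radius}, locus \code{x,y,z}.
#' @export
simulateNuclei <- function(nCells, radius = 1.74, peripheralBias = 0,
                           stageMix = 0.5, strain = "wt", replicate = 1L,
                           seed = NULL) {
    if (nCells < 1) stop("nCells must be >= 1")
    if (peripheralBias < 0 || peripheralBias > 1 ||
        stageMix < 0 || stageMix > 1)
        stop("probabilities must be in [0, 1]")
    if (radius <= 0) stop("radius must be > 0")
    .withSeed(seed, {
        inZone1 <- runif(nCells) < peripheralBias
        # radial CDF: uniform ball ~ U^(1/3); outer equal-volume shell
        # occupies the volume fraction (2/3, 1]
        u <- runif(nCells)
        vol <- ifelse(inZone1, 2 / 3 + u / 3, u)
        r <- radius * vol^(1 / 3)
        # isotropic direction
        z <- runif(nCells, -1, 1)
        phi <- runif(nCells, 0, 2 * pi)
        s <- sqrt(1 - z^2)
        early <- runif(nCells) < stageMix
        data.frame(strain = strain, replicate = replicate,
                   stage = factor(ifelse(early, "early_mid_S",
                                         "late_S_G2"),
                                  levels = c("early_mid_S", "late_S_G2")),
                   n_nuclei = ifelse(early, 2L, 1L),
                   cx = 0, cy = 0, cz = 0, radius = radius,
                   x = r * s * cos(phi), y = r * s * sin(phi), z = r * z)
    })
}

#' Simulate FRAP recovery traces
#'
#' Each cell's normalized recovery follows the one-phase association
#' \eqn{Y(t) = Y_0 + (P - Y_0)(1 - e^{-kt})} plus iid Gaussian noise.
#' Raw ROI/background sums are populated so that
#' \code{\link{normalizeTrace}} (subtracted mode) returns exactly the
#' noisy normalized values, with the pre-bleach level at 1.0.
#'
#' @param trueK rate constant (1/s); half-life = ln(2)/trueK.
#' @param truePlateau plateau (mobile fraction), normalized.
#' @param trueY0 normalized intensity at t = 0.
#' @param noiseSd Gaussian noise sd on the normalized scale.
#' @param interval acquisition interval (s, default 2).
#' @param nTimepoints timepoints per trace (default 60).
#' @param nCells number of cells (default 12).
#' @param amplitude pre-bleach background-subtracted ROI sum (a.u.).
#' @param backgroundLevel background sum (a.u.).
#' @param seed RNG seed.
#' @return list of \code{\linkS4class{FrapTrace}}.
#' @export
simulateFrap <- function(trueK, truePlateau = 0.9, trueY0 = 0.2,
                         noiseSd = 0.05, interval = 2, nTimepoints = 60L,
                         nCells = 12L, amplitude = 1000,
                         backgroundLevel = 200, seed = NULL) {
    if (trueK <= 0) stop("trueK must be > 0")
    if (interval <= 0) stop("interval must be > 0")
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    if (trueY0 < 0 || truePlateau < trueY0 || truePlateau > 1.2)
        stop("need 0 <= Y0 <= plateau <= 1.2")
    times <- seq(0, by = interval, length.out = nTimepoints)
    model <- trueY0 + (truePlateau - trueY0) * (1 - exp(-trueK * times))
    .withSeed(seed, {
        lapply(seq_len(nCells), function(i) {
            y <- model + rnorm(nTimepoints, 0, noiseSd)
            FrapTrace(times, roi = y * amplitude + backgroundLevel,
                      background = rep(backgroundLevel, nTimepoints),
                      preRoi = amplitude + backgroundLevel,
                      preBackground = backgroundLevel,
                      cell = paste0("cell", i))
        })
    })
}

#' Simulate a two-channel fluorescence image
#'
#' Each channel is a sum of isotropic Gaussian spots, an optional
#' nuclear-envelope ring (Gaussian radial profile around a circle), and
#' Gaussian background noise.
#'
#' @param size image size in px (square).
#' @param spotsA,spotsB data.frames with \code{x}, \code{y} (px) and
#'   \code{amplitude} per spot, for the two channels. NULL for none.
#' @param psfSigma point-spread sigma (px, default 1.5).
#' @param ringCenter,ringRadius,ringAmplitude,ringSigma optional ring
#'   (NULL radius disables it); added to both channels.
#' @param backgroundMean,backgroundSd background level and noise sd.
#' @param pixelSize um/px (metadata only; default 0.1).
#' @param seed RNG seed.
#' @return list with matrices \code{a}, \code{b} and the \code{pixelSize}.
#' @export
simulateImage <- function(size = 64L, spotsA = NULL, spotsB = NULL,
                          psfSigma = 1.5, ringCenter = NULL,
                          ringRadius = NULL, ringAmplitude = 2,
                          ringSigma = 1.5, backgroundMean = 1,
                          backgroundSd = 0.1, pixelSize = 0.1,
                          seed = NULL) {
    if (psfSigma <= 0) stop("psfSigma must be > 0")
    size <- as.integer(size)
    xs <- matrix(rep(seq_len(size) - 0.5, each = size), size)   # column
    ys <- matrix(rep(seq_len(size) - 0.5, times = size), size)  # row
    renderSpots <- function(spots) {
        img <- matrix(0, size, size)
        if (is.null(spots) || !nrow(spots)) return(img)
        if (any(spots$x < 0 | spots$x > size |
                spots$y < 0 | spots$y > size))
            stop("spot center outside the image")
        for (i in seq_len(nrow(spots)))
            img <- img + spots$amplitude[i] *
                exp(-((xs - spots$x[i])^2 + (ys - spots$y[i])^2) /
                        (2 * psfSigma^2))
        img
    }
    ring <- matrix(0, size, size)
    if (!is.null(ringRadius)) {
        ctr <- if (is.null(ringCenter)) c(size / 2, size / 2)
               else ringCenter
        rr <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)
        ring <- ringAmplitude * exp(-(rr - ringRadius)^2 /
                                        (2 * ringSigma^2))
    }
    .withSeed(seed, {
        noiseA <- matrix(rnorm(size^2, backgroundMean, backgroundSd),
                         size)
        noiseB <- matrix(rnorm(size^2, backgroundMean, backgroundSd),
                         size)
        list(a = renderSpots(spotsA) + ring + noiseA,
             b = renderSpots(spotsB) + ring + noiseB,
             pixelSize = pixelSize)
    })
}

#' Write locus observations as TSV
#'
#' @param observations data.frame from \code{\link{simulateNuclei}} (or
#'   with the same columns).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNucleiTSV <- function(observations, path) {
    write.table(observations, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read locus observations from TSV
#'
#' @param path TSV written by \code{\link{writeNucleiTSV}} or assembled
#'   by hand with the same columns.
#' @return data.frame of per-cell locus observations.
#' @export
readNucleiTSV <- function(path) {
    df <- read.delim(path)
    if ("stage" %in% names(df))
        df$stage <- factor(df$stage,
                           levels = c("early_mid_S", "late_S_G2"))
    df
}
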