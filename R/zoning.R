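#' Zone boundaries of the equal-volume nuclear zoning assay
#'
#' The nucleus is modelled as a sphere of radius R partitioned into three
#' concentric shells of equal volume. Zone I, the outermost shell (the
#' "periphery", the outer third of the nuclear volume), begins at radial
#' coordinate \eqn{r_1 = R (2/3)^{1/3}}; Zone II begins at
#' \eqn{r_2 = R (1/3)^{1/3}}. A uniformly random position falls in each
#' zone with probability exactly 1/3. For R = 1.74 um (a typical fission
#' yeast nucleus) the Zone-I shell is ~0.22 um thick.
#'
#' @param R nuclear radius (um).
#' @return named numeric: \code{r1}, \code{r2}.
#' @examples
#' zoneBoundaries(1)        # 0.8736, 0.6934
#' 1.74 * (1 - (2/3)^(1/3)) # Zone-I thickness at R = 1.74 um
#' @export
zoneBoundaries <- function(R) {
    if (any(R <= 0)) stop("R must be > 0")
    c(r1 = R * (2 / 3)^(1 / 3), r2 = R * (1 / 3)^(1 / 3))
}

.radialCoord <- function(position, center) {
    position <- as.numeric(position); center <- as.numeric(center)
    if (length(position) != length(center))
        stop("position and center dimensions differ")
    sqrt(sum((position - center)^2))
}

#' Distance from a locus to the nuclear envelope
#'
#' \code{R - |position - center|}, clamped to [0, R]. Loci measured up to
#' \code{tol * R} outside the sphere (segmentation jitter) are clamped to
#' the surface (distance 0); farther out is an error.
#'
#' @param position locus coordinates (um), length 2 or 3.
#' @param center nucleus center (um), same length.
#' @param R nuclear radius (um).
#' @param tol relative tolerance for positions outside the sphere
#'   (default 0.02).
#' @return distance to the envelope (um).
#' @examples
#' locusNEDistance(c(0, 0, 0), c(0, 0, 0), R = 1)       # 1
#' locusNEDistance(c(1.52, 0, 0), c(0, 0, 0), R = 1.74) # 0.22
#' @export
locusNEDistance <- function(position, center, R, tol = 0.02) {
    if (R <= 0) stop("R must be > 0")
    r <- .radialCoord(position, center)
    if (r > R * (1 + tol))
        stop(sprintf("locus %.4g um outside the nuclear radius %.4g", r, R))
    max(0, min(R, R - r))
}

#' Assign a locus to a nuclear zone
#'
#' Zone by radial coordinate against \code{\link{zoneBoundaries}}; ties on
#' a boundary go to the more peripheral zone (radial coordinate exactly
#' \eqn{r_1} is Zone I).
#'
#' @inheritParams locusNEDistance
#' @return factor level \code{"I"}, \code{"II"} or \code{"III"}.
#' @export
assignZone <- function(position, center, R, tol = 0.02) {
    d <- locusNEDistance(position, center, R, tol)  # validates geometry
    r <- R - d
    b <- zoneBoundaries(R)
    z <- if (r >= b["r1"]) "I" else if (r >= b["r2"]) "II" else "III"
    factor(z, levels = c("I", "II", "III"))
}

#' Cell-cycle stage from the number of nuclei in a cell
#'
#' Fission yeast enters S phase before cytokinesis completes, so
#' interphase binucleate cells are in early/mid S phase; mononucleate
#' interphase cells are in late S/G2.
#'
#' @param nNuclei integer vector of nucleate counts (1 or 2).
#' @return factor with levels \code{early_mid_S}, \code{late_S_G2}.
#' @examples
#' classifyStage(c(2, 1))
#' @export
classifyStage <- function(nNuclei) {
    if (any(!nNuclei %in% c(1L, 2L)))
        stop("nucleate count must be 1 or 2 (others are mitotic/aberrant, ",
             "unclassifiable)")
    factor(ifelse(nNuclei == 2L, "early_mid_S", "late_S_G2"),
           levels = c("early_mid_S", "late_S_G2"))
}

.zoneIndicator <- function(observations, tol = 0.02) {
    need <- c("x", "y", "z", "cx", "cy", "cz", "radius")
    if (!all(need %in% names(observations)))
        stop("observations need columns: ", paste(need, collapse = ", "))
    vapply(seq_len(nrow(observations)), function(i) {
        o <- observations[i, ]
        assignZone(c(o$x, o$y, o$z), c(o$cx, o$cy, o$cz), o$radius,
                   tol = tol) == "I"
    }, logical(1))
}

#' Test Zone-I enrichment against the random-localization expectation
#'
#' For each (strain, stage) group, scores each cell's locus as Zone I or
#' not and tests the Zone-I fraction against the uniform expectation of
#' 1/3. The default test is a one-sample two-tailed t-test on the per-cell
#' Zone-I indicators pooled across replicates; an exact binomial test is
#' offered (and substituted automatically, with a message, when all
#' indicators are identical and the t-test is undefined). Per-replicate
#' counts n1, n2, ... are reported alongside.
#'
#' @param observations data.frame with one row per cell: columns
#'   \code{strain}, \code{replicate}, \code{stage} (or \code{n_nuclei} to
#'   be classified via \code{\link{classifyStage}}), nucleus center
#'   \code{cx}, \code{cy}, \code{cz}, \code{radius}, and locus position
#'   \code{x}, \code{y}, \code{z} (um).
#' @param expected expected Zone-I fraction under random positioning
#'   (default 1/3).
#' @param method \code{"ttest"} (default) or \code{"binomial"}.
#' @param tol geometry tolerance passed to \code{\link{assignZone}}.
#' @return data.frame with one row per (strain, stage): n, per-replicate
#'   ns (comma-separated in \code{n_by_replicate}), \code{zone1},
#'   \code{fraction}, \code{expected}, \code{p_value}, \code{test}.
#' @export
testZone1Enrichment <- function(observations, expected = 1 / 3,
                                method = c("ttest", "binomial"),
                                tol = 0.02) {
    method <- match.arg(method)
    if (nrow(observations) < 2L) stop("need at least 2 observations")
    obs <- as.data.frame(observations)
    if (!"stage" %in% names(obs)) {
        if (!"n_nuclei" %in% names(obs))
            stop("observations need a 'stage' or 'n_nuclei' column")
        obs$stage <- classifyStage(obs$n_nuclei)
    }
    if (!"strain" %in% names(obs)) obs$strain <- "strain1"
    if (!"replicate" %in% names(obs)) obs$replicate <- 1L
    obs$zone1 <- .zoneIndicator(obs, tol = tol)

    groups <- split(obs, list(obs$strain, obs$stage), drop = TRUE)
    res <- lapply(groups, function(g) {
        ind <- g$zone1
        n <- length(ind)
        nRep <- vapply(split(ind, g$replicate), length, integer(1))
        useMethod <- method
        if (method == "ttest" && length(unique(ind)) == 1L) {
            message("all Zone-I indicators identical in ", g$strain[1],
                    "/", g$stage[1],
                    ": t-test undefined, using exact binomial")
            useMethod <- "binomial"
        }
        p <- if (useMethod == "ttest") {
            t.test(as.numeric(ind), mu = expected,
                   alternative = "two.sided")$p.value
        } else {
            binom.test(sum(ind), n, p = expected,
                       alternative = "two.sided")$p.value
        }
        data.frame(strain = as.character(g$strain[1]),
                   stage = as.character(g$stage[1]), n = n,
                   n_by_replicate = paste(nRep, collapse = ","),
                   zone1 = sum(ind), fraction = mean(ind),
                   expected = expected, p_value = p, test = useMethod)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Monte-Carlo Zone-I fraction under uniform positioning
#'
#' Samples \code{n} points uniformly inside a sphere and returns the
#' fraction whose radial coordinate falls in the outermost of three
#' equal-volume shells. The exact limit is 1/3; this reproduces the
#' dashed-line random-localization expectation (~33%) of the zoning assay.
#'
#' @param n number of points.
#' @param seed optional RNG seed for reproducibility.
#' @return fraction in Zone I.
#' @examples
#' monteCarloRandomZone1(1e5, seed = 1)
#' @export
monteCarloRandomZone1 <- function(n, seed = NULL) {
    if (n < 1) stop("n must be >= 1")
    .withSeed(seed, {
        r <- runif(n)^(1 / 3)       # radial CDF of a uniform ball
        mean(r >= (2 / 3)^(1 / 3))
    })
}
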