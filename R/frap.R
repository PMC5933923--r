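#' Construct a FrapTrace
#'
#' @param times post-bleach acquisition times (s), t = 0 immediately after
#'   bleaching.
#' @param roi summed pixel intensity inside the bleached ROI at each time.
#' @param background summed intensity of an equal-size region beside the
#'   nucleus at each time.
#' @param preRoi,preBackground the same two sums in the pre-bleach image.
#' @param cell cell identifier.
#' @return a \code{\linkS4class{FrapTrace}}.
#' @export
FrapTrace <- function(times, roi, background, preRoi, preBackground,
                      cell = "cell1") {
    new("FrapTrace", cell = as.character(cell), times = as.numeric(times),
        roi = as.numeric(roi), background = as.numeric(background),
        preRoi = as.numeric(preRoi),
        preBackground = as.numeric(preBackground))
}

setMethod("show", "FrapTrace", function(object) {
    cat(sprintf("FrapTrace '%s': %d timepoints, t = %g..%g s\n",
                object@cell, length(object@times), min(object@times),
                max(object@times)))
})

#' Normalize a FRAP trace
#'
#' Background is subtracted from the ROI signal and the result divided by
#' the pre-bleach ROI signal, so the pre-bleach level is 1.0 by
#' construction. In the default \code{"subtracted"} mode the pre-bleach
#' denominator is also background-subtracted
#' (\code{(roi - bg) / (preRoi - preBg)}), keeping the recovery on a 0-1
#' scale; \code{"literal"} divides by the raw pre-bleach ROI sum instead.
#'
#' @param trace a \code{\linkS4class{FrapTrace}}.
#' @param mode \code{"subtracted"} (default) or \code{"literal"}.
#' @return data.frame with columns \code{time}, \code{intensity}.
#' @examples
#' tr <- FrapTrace(0:3, roi = c(150, 175, 200, 225),
#'                 background = rep(50, 4), preRoi = 250,
#'                 preBackground = 50)
#' normalizeTrace(tr)   # 0.5, 0.625, 0.75, 0.875
#' @export
setMethod("normalizeTrace", "FrapTrace", function(trace,
        mode = c("subtracted", "literal")) {
    mode <- match.arg(mode)
    denom <- if (mode == "subtracted")
        trace@preRoi - trace@preBackground else trace@preRoi
    if (denom <= 0) stop("nonpositive pre-bleach denominator")
    data.frame(time = trace@times,
               intensity = (trace@roi - trace@background) / denom)
})

#' Average normalized traces over cells
#'
#' Normalized intensities are averaged per corresponding timepoint across
#' cells; all traces must share the acquisition grid (within \code{tol}
#' seconds).
#'
#' @param traces list of \code{\linkS4class{FrapTrace}} or of normalized
#'   data.frames from \code{\link{normalizeTrace}}.
#' @param mode normalization mode, passed to \code{\link{normalizeTrace}}.
#' @param tol maximum allowed time-grid discrepancy (s).
#' @return data.frame with columns \code{time}, \code{intensity},
#'   \code{n}.
#' @export
averageTraces <- function(traces, mode = "subtracted", tol = 1e-6) {
    if (!length(traces)) stop("no traces")
    norm <- lapply(traces, function(tr) {
        if (is(tr, "FrapTrace")) normalizeTrace(tr, mode = mode) else tr
    })
    t0 <- norm[[1]]$time
    for (nm in norm) {
        if (length(nm$time) != length(t0) || any(abs(nm$time - t0) > tol))
            stop("traces do not share a common time grid")
    }
    ints <- vapply(norm, `[[`, numeric(length(t0)), "intensity")
    ints <- matrix(ints, nrow = length(t0))
    data.frame(time = t0, intensity = rowMeans(ints),
               n = length(norm))
}

# Deterministic starting values: plateau from the last-quartile mean, Y0
# from the first point, k from a log-linear regression on
# log((P - Y) / (P - Y0)).
.frapStart <- function(time, y) {
    p0 <- mean(y[time >= stats::quantile(time, 0.75)])
    y00 <- y[which.min(time)]
    if (p0 <= y00) p0 <- max(y) + 1e-3
    frac <- (p0 - y) / (p0 - y00)
    ok <- frac > 1e-3 & time > min(time)
    k0 <- if (sum(ok) >= 2) {
        fit <- stats::lm(log(frac[ok]) ~ time[ok])
        max(1e-4, -coef(fit)[2])
    } else 1 / max(time)
    list(k = as.numeric(k0), y0 = y00, plateau = p0)
}

#' Fit a one-phase association to a FRAP recovery
#'
#' Least-squares fit of \eqn{Y(t) = Y_0 + (P - Y_0)(1 - e^{-kt})} by
#' bounded Levenberg-Marquardt (\code{minpack.lm::nlsLM}), with
#' deterministic initialization from a log-linear estimate. Returns the
#' rate constant k, the intercept \eqn{Y_0}, the plateau P (the mobile
#' fraction), the half-life \eqn{\ln 2 / k} and \eqn{R^2}. A flat series
#' is flagged immobile (degenerate): \eqn{P = Y_0} and \eqn{R^2} is
#' reported as \code{NA}.
#'
#' @param series data.frame with columns \code{time} (s, >= 0) and
#'   \code{intensity} (normalized), e.g. from \code{\link{averageTraces}}.
#' @param kBounds allowed range for k (1/s).
#' @return a \code{\linkS4class{FrapFit}}.
#' @examples
#' t <- seq(0, 60, by = 2)
#' y <- 0.2 + (0.9 - 0.2) * (1 - exp(-log(2) / 5 * t))
#' fit <- fitRecovery(data.frame(time = t, intensity = y))
#' halfLife(fit)   # 5
#' @export
fitRecovery <- function(series, kBounds = c(1e-6, 1e3)) {
    time <- series$time; y <- series$intensity
    if (length(time) < 4L) stop("need at least 4 timepoints")
    if (any(time < 0)) stop("times must be >= 0")
    sstot <- sum((y - mean(y))^2)
    if (sstot < 1e-20 * max(1, mean(y)^2)) {
        return(new("FrapFit", k = NA_real_, y0 = y[1], plateau = y[1],
                   halfLife = NA_real_, rSquared = NA_real_,
                   n = length(y), degenerate = TRUE))
    }
    st <- .frapStart(time, y)
    st$k <- min(max(st$k, kBounds[1] * 1.01), kBounds[2] * 0.99)
    fit <- tryCatch(
        nlsLM(intensity ~ y0 + (plateau - y0) * (1 - exp(-k * time)),
              data = data.frame(time = time, intensity = y),
              start = list(k = st$k, y0 = st$y0, plateau = st$plateau),
              lower = c(kBounds[1], -Inf, -Inf),
              upper = c(kBounds[2], Inf, Inf),
              control = nls.lm.control(maxiter = 200)),
        error = function(e)
            stop("one-phase association fit failed to converge: ",
                 conditionMessage(e), call. = FALSE))
    cf <- coef(fit)
    k <- as.numeric(cf["k"])
    if (k <= kBounds[1] * 1.001 || k >= kBounds[2] * 0.999)
        warning("rate constant estimate at its bound (k = ",
                signif(k, 4), " 1/s); fit unreliable")
    ssres <- sum(stats::resid(fit)^2)
    new("FrapFit", k = k, y0 = as.numeric(cf["y0"]),
        plateau = as.numeric(cf["plateau"]), halfLife = log(2) / k,
        rSquared = 1 - ssres / sstot, n = length(y), degenerate = FALSE)
}

#' @rdname FrapFit-class
#' @param x a \code{FrapFit}.
#' @export
setMethod("halfLife", "FrapFit", function(x) x@halfLife)

#' @rdname FrapFit-class
#' @export
setMethod("mobileFraction", "FrapFit", function(x) x@plateau)

#' @rdname FrapFit-class
#' @export
setMethod("rateConstant", "FrapFit", function(x) x@k)

#' @rdname FrapFit-class
#' @export
setMethod("rSquared", "FrapFit", function(x) x@rSquared)

setMethod("show", "FrapFit", function(object) {
    if (object@degenerate) {
        cat("FrapFit: degenerate (immobile) series, plateau = Y0 =",
            signif(object@plateau, 4), "; R^2 not applicable\n")
    } else {
        cat(sprintf(paste0("FrapFit: k = %.4g 1/s, half-life = %.4g s, ",
                           "Y0 = %.3g, mobile fraction (plateau) = ",
                           "%.1f%%, R^2 = %.4g, n = %d\n"),
                    object@k, object@halfLife, object@y0,
                    100 * object@plateau, object@rSquared, object@n))
    }
})

#' Read FRAP traces from a TSV file
#'
#' Expected columns: \code{cell}, \code{time}, \code{roi},
#' \code{background}, \code{pre_roi}, \code{pre_background}.
#'
#' @param path TSV file.
#' @return list of \code{\linkS4class{FrapTrace}}, one per cell.
#' @export
readFrapTSV <- function(path) {
    df <- read.delim(path)
    need <- c("cell", "time", "roi", "background", "pre_roi",
              "pre_background")
    if (!all(need %in% names(df)))
        stop("FRAP TSV needs columns: ", paste(need, collapse = ", "))
    lapply(split(df, df$cell), function(g) {
        g <- g[order(g$time), ]
        FrapTrace(g$time, g$roi, g$background, g$pre_roi[1],
                  g$pre_background[1], cell = as.character(g$cell[1]))
    })
}

#' Write FRAP traces to a TSV file
#'
#' @param traces list of \code{\linkS4class{FrapTrace}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFrapTSV <- function(traces, path) {
    rows <- lapply(traces, function(tr)
        data.frame(cell = tr@cell, time = tr@times, roi = tr@roi,
                   background = tr@background, pre_roi = tr@preRoi,
                   pre_background = tr@preBackground))
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
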