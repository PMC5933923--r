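#' Detect fluorescent dots by constant thresholding
#'
#' Pixels above a constant threshold are grouped into connected components
#' (8-connectivity, via \code{EBImage::bwlabel}); components of at least
#' \code{minSize} pixels become dots. The centroid is the intensity-
#' weighted mean pixel position; detection is fully deterministic.
#'
#' @param image numeric matrix (a single channel, single z-plane).
#' @param threshold constant intensity threshold; must exceed the image
#'   minimum (otherwise everything is suprathreshold).
#' @param minSize minimum component size in pixels (default 2).
#' @param pixelSize physical pixel size (um/px, default 1): centroids are
#'   reported in um.
#' @return data.frame with one row per dot: \code{x}, \code{y} (um;
#'   \code{x} = column, \code{y} = row, pixel centers at 0.5, 1.5, ...),
#'   \code{peak}, \code{integrated} intensity, \code{area} (px).
#' @examples
#' img <- matrix(0, 20, 20); img[10, 10] <- 5; img[10, 11] <- 4
#' detectDots(img, threshold = 1)
#' @export
detectDots <- function(image, threshold, minSize = 2L, pixelSize = 1) {
    image <- as.matrix(image)
    if (threshold <= min(image))
        stop("threshold at or below the image minimum: ",
             "everything would be suprathreshold")
    mask <- image > threshold
    if (!any(mask))
        return(data.frame(x = numeric(0), y = numeric(0),
                          peak = numeric(0), integrated = numeric(0),
                          area = integer(0)))
    lab <- EBImage::bwlabel(mask + 0)
    labv <- as.integer(lab)
    idx <- which(labv > 0L)
    comp <- labv[idx]
    rows <- ((idx - 1L) %% nrow(image)) + 1L
    cols <- ((idx - 1L) %/% nrow(image)) + 1L
    ints <- image[idx]
    area <- tabulate(comp)
    keep <- which(area >= minSize)
    if (!length(keep))
        return(data.frame(x = numeric(0), y = numeric(0),
                          peak = numeric(0), integrated = numeric(0),
                          area = integer(0)))
    res <- lapply(keep, function(cc) {
        sel <- comp == cc
        w <- ints[sel]
        data.frame(x = (sum((cols[sel] - 0.5) * w) / sum(w)) * pixelSize,
                   y = (sum((rows[sel] - 0.5) * w) / sum(w)) * pixelSize,
                   peak = max(w), integrated = sum(w),
                   area = area[cc])
    })
    out <- do.call(rbind, res)
    out[order(-out$integrated), , drop = FALSE]
}

# Algebraic (Kasa) least-squares circle fit to boundary points.
.fitCircle <- function(x, y) {
    A <- cbind(2 * x, 2 * y, 1)
    b <- x^2 + y^2
    sol <- qr.solve(A, b)
    cx <- sol[1]; cy <- sol[2]
    r <- sqrt(sol[3] + cx^2 + cy^2)
    resid <- sqrt(mean((sqrt((x - cx)^2 + (y - cy)^2) - r)^2))
    list(center = c(cx, cy), radius = r, residual = resid)
}

#' Estimate the nuclear boundary from nucleoplasmic background
#'
#' The diffuse fluorescence background inside the nucleus is used to
#' approximate its boundary: the image is Gaussian-smoothed, thresholded
#' at the intensity that minimizes intra-class variance (Otsu's bimodal
#' split), the largest connected component is kept, and a circle is
#' fitted to the component's rim pixels by least squares.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian smoothing sigma in px (default 2; typically the
#'   PSF sigma).
#' @param pixelSize um/px (default 1).
#' @return a \code{\linkS4class{NuclearBoundary}} (center and radius in
#'   um).
#' @export
estimateNuclearBoundary <- function(image, sigma = 2, pixelSize = 1) {
    image <- as.matrix(image)
    rng <- range(image)
    if (diff(rng) <= 0)
        stop("flat image: no foreground/background separation")
    sm <- as.matrix(EBImage::gblur(image, sigma = sigma))
    norm <- (sm - min(sm)) / diff(range(sm))
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    fg <- mean(norm[norm > thr]); bg <- mean(norm[norm <= thr])
    if (!is.finite(fg) || !is.finite(bg) || fg - bg < 0.1)
        stop("no bimodal foreground/background separation")
    mask <- norm > thr
    lab <- EBImage::bwlabel(mask + 0)
    area <- tabulate(as.integer(lab))
    if (!length(area)) stop("empty mask")
    big <- which.max(area)
    mask <- matrix(as.integer(lab) == big, nrow(image), ncol(image))
    if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
        any(mask[, 1]) || any(mask[, ncol(mask)]))
        stop("nucleus mask touches the image border")
    # rim = mask pixels with at least one 4-neighbour outside the mask
    inner <- mask[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] &
             mask[1:(nrow(mask) - 2), 2:(ncol(mask) - 1)] &
             mask[3:nrow(mask), 2:(ncol(mask) - 1)] &
             mask[2:(nrow(mask) - 1), 1:(ncol(mask) - 2)] &
             mask[2:(nrow(mask) - 1), 3:ncol(mask)]
    rim <- mask
    rim[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] <-
        mask[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] & !inner
    idx <- which(rim)
    ry <- ((idx - 1L) %% nrow(rim)) + 1L
    rx <- ((idx - 1L) %/% nrow(rim)) + 1L
    fitc <- .fitCircle((rx - 0.5) * pixelSize, (ry - 0.5) * pixelSize)
    new("NuclearBoundary", center = as.numeric(fitc$center),
        radius = fitc$radius, residual = fitc$residual,
        multiNucleus = sum(area > max(9, 0.01 * max(area))) > 1L)
}

setMethod("show", "NuclearBoundary", function(object) {
    cat(sprintf(paste0("NuclearBoundary: center (%.3g, %.3g), radius ",
                       "%.3g, rms residual %.3g%s\n"),
                object@center[1], object@center[2], object@radius,
                object@residual,
                if (object@multiNucleus) " [multi-nucleus]" else ""))
})

#' One-to-one dot colocalization by mutual nearest neighbours
#'
#' Candidate pairs are all cross-channel dot pairs within \code{cutoff};
#' pairs are accepted greedily by ascending distance, each dot used at
#' most once. The result is symmetric in channel order. The default
#' cutoff of 0.25 um sits below the ~300 nm lateral resolution of
#' conventional wide-field imaging.
#'
#' @param dotsA,dotsB data.frames with \code{x}, \code{y} (um), e.g. from
#'   \code{\link{detectDots}} on the two channels.
#' @param cutoff maximum pairing distance (um, default 0.25).
#' @return list with \code{pairs} (data.frame \code{a}, \code{b} row
#'   indices and \code{distance}), and counts \code{nA}, \code{nB},
#'   \code{nPaired}.
#' @export
assignColocalization <- function(dotsA, dotsB, cutoff = 0.25) {
    nA <- nrow(dotsA); nB <- nrow(dotsB)
    pairs <- data.frame(a = integer(0), b = integer(0),
                        distance = numeric(0))
    if (nA && nB) {
        d <- outer(seq_len(nA), seq_len(nB), function(i, j)
            sqrt((dotsA$x[i] - dotsB$x[j])^2 +
                 (dotsA$y[i] - dotsB$y[j])^2))
        cand <- which(d <= cutoff, arr.ind = TRUE)
        if (nrow(cand)) {
            ord <- order(d[cand])
            usedA <- logical(nA); usedB <- logical(nB)
            for (k in ord) {
                i <- cand[k, 1]; j <- cand[k, 2]
                if (!usedA[i] && !usedB[j]) {
                    usedA[i] <- TRUE; usedB[j] <- TRUE
                    pairs <- rbind(pairs,
                                   data.frame(a = i, b = j,
                                              distance = d[i, j]))
                }
            }
        }
    }
    list(pairs = pairs, nA = nA, nB = nB, nPaired = nrow(pairs))
}

#' Distance from dot centroids to the nuclear edge
#'
#' \code{radius - |centroid - center|}, clamped like
#' \code{\link{locusNEDistance}}; feeds \code{\link{assignZone}}-style
#' peripheral scoring of colocalized dots.
#'
#' @param dots data.frame with \code{x}, \code{y} (um).
#' @param boundary a \code{\linkS4class{NuclearBoundary}}.
#' @param tol relative tolerance for dots outside the boundary.
#' @return numeric vector of distances to the edge (um).
#' @export
distanceToEdge <- function(dots, boundary, tol = 0.02) {
    stopifnot(is(boundary, "NuclearBoundary"))
    vapply(seq_len(nrow(dots)), function(i)
        locusNEDistance(c(dots$x[i], dots$y[i]),
                        boundary@center[1:2], boundary@radius, tol = tol),
        numeric(1))
}

#' Pixelwise Pearson colocalization
#'
#' Pearson correlation of the two channels' intensities over the masked
#' pixels.
#'
#' @param imageA,imageB numeric matrices of identical dimension.
#' @param mask optional logical matrix selecting pixels (default: all).
#' @return Pearson r in [-1, 1].
#' @examples
#' a <- matrix(rnorm(100), 10); pearsonColoc(a, a)   # 1
#' @export
pearsonColoc <- function(imageA, imageB, mask = NULL) {
    imageA <- as.matrix(imageA); imageB <- as.matrix(imageB)
    if (!all(dim(imageA) == dim(imageB)))
        stop("channel dimensions differ")
    if (is.null(mask)) mask <- matrix(TRUE, nrow(imageA), ncol(imageA))
    a <- imageA[mask]; b <- imageB[mask]
    if (length(a) < 2L) stop("need at least 2 masked pixels")
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("zero variance in a channel over the mask")
    cor(a, b)
}
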