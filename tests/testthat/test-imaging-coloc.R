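test_that("constant-threshold detection localizes Gaussian spots", {
    img <- simulateImage(size = 64,
                         spotsA = data.frame(x = 20.5, y = 33.5,
                                             amplitude = 10),
                         backgroundMean = 1, backgroundSd = 0.1,
                         seed = 1)$a
    dots <- detectDots(img, threshold = 2)
    expect_equal(nrow(dots), 1)
    expect_lt(sqrt((dots$x - 20.5)^2 + (dots$y - 33.5)^2), 1)
    two <- simulateImage(size = 64,
                         spotsA = data.frame(x = c(15, 48),
                                             y = c(15, 48),
                                             amplitude = 10),
                         backgroundMean = 1, backgroundSd = 0.1,
                         seed = 2)$a
    expect_equal(nrow(detectDots(two, threshold = 2)), 2)
    expect_error(detectDots(matrix(1, 5, 5), threshold = 0.5),
                 "suprathreshold")
})

test_that("blank noise images produce (near) zero detections at mean + 5 sigma", {
    set.seed(3)
    img <- matrix(rnorm(100 * 100, 1, 0.1), 100)
    dots <- detectDots(img, threshold = 1 + 5 * 0.1, minSize = 1)
    # expected Gaussian-tail count: 1e4 * P(Z > 5) ~ 0.003
    expect_lte(nrow(dots), 1)
})

test_that("detection is translation-equivariant and scale-covariant", {
    base <- simulateImage(size = 64,
                          spotsA = data.frame(x = 20, y = 20,
                                              amplitude = 10),
                          backgroundMean = 1, backgroundSd = 0,
                          seed = 1)$a
    shifted <- simulateImage(size = 64,
                             spotsA = data.frame(x = 30, y = 25,
                                                 amplitude = 10),
                             backgroundMean = 1, backgroundSd = 0,
                             seed = 1)$a
    d0 <- detectDots(base, threshold = 2)
    d1 <- detectDots(shifted, threshold = 2)
    expect_equal(d1$x - d0$x, 10, tolerance = 1e-6)
    expect_equal(d1$y - d0$y, 5, tolerance = 1e-6)
    d2 <- detectDots(base * 7, threshold = 2 * 7)
    expect_equal(d2$x, d0$x, tolerance = 1e-12)
    expect_equal(d2$area, d0$area)
})

test_that("nuclear boundary is recovered from a uniform disk", {
    img <- diskImage(size = 64, center = c(30, 36), radius = 20,
                     noiseSd = 0.1, seed = 4)
    b <- estimateNuclearBoundary(img, sigma = 1)
    expect_lt(abs(b@radius - 20), 1)
    expect_lt(sqrt(sum((b@center - c(30, 36))^2)), 1.5)
    expect_false(b@multiNucleus)
    expect_error(estimateNuclearBoundary(matrix(1, 32, 32)), "flat")
    # mask reaching the border is rejected
    big <- diskImage(size = 40, center = c(20, 20), radius = 19.8)
    expect_error(estimateNuclearBoundary(big, sigma = 1), "border")
})

test_that("two nuclei keep the largest mask and set the multi-nucleus flag", {
    xs <- matrix(rep(seq_len(96) - 0.5, each = 96), 96)
    ys <- matrix(rep(seq_len(96) - 0.5, times = 96), 96)
    img <- ifelse(sqrt((xs - 28)^2 + (ys - 48)^2) <= 16 |
                      sqrt((xs - 72)^2 + (ys - 48)^2) <= 9, 5, 1)
    b <- estimateNuclearBoundary(img, sigma = 1)
    expect_true(b@multiNucleus)
    expect_lt(abs(b@radius - 16), 1.5)
    expect_lt(abs(b@center[1] - 28), 2)
})

test_that("greedy mutual-NN matching is one-to-one, symmetric and optimal here", {
    a <- data.frame(x = c(1, 2, 3), y = c(0, 0, 0))
    expect_equal(assignColocalization(a, a, cutoff = 0.5)$nPaired, 3)
    expect_true(all(assignColocalization(a, a, 0.5)$pairs$distance == 0))
    far <- data.frame(x = 10, y = 0)
    near <- data.frame(x = 10.6, y = 0)   # 2.4x the 0.25 cutoff
    expect_equal(assignColocalization(far, near, 0.25)$nPaired, 0)

    # crafted 3-vs-3 where greedy ascending must match brute force
    da <- data.frame(x = c(0.0, 1.0, 2.0), y = c(0, 0, 0))
    db <- data.frame(x = c(0.4, 1.1, 2.5), y = c(0, 0, 0))
    res <- assignColocalization(da, db, cutoff = 0.6)
    # brute-force minimum-total-distance one-to-one matching
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    cost <- function(p) {
        d <- abs(da$x - db$x[p])
        if (any(d > 0.6)) Inf else sum(d)
    }
    best <- perms[[which.min(vapply(perms, cost, numeric(1)))]]
    got <- res$pairs[order(res$pairs$a), ]
    expect_equal(got$b, best[got$a])
    # symmetry in channel order
    rev <- assignColocalization(db, da, cutoff = 0.6)
    expect_equal(rev$nPaired, res$nPaired)
    expect_equal(sort(rev$pairs$distance), sort(res$pairs$distance))
    # degenerate inputs allowed
    empty <- data.frame(x = numeric(0), y = numeric(0))
    expect_equal(assignColocalization(empty, da, 0.25)$nPaired, 0)
})

test_that("estimated colocalization fraction tracks the generator truth", {
    set.seed(9)
    nCells <- 60
    trueColoc <- 0.6
    est <- vapply(seq_len(nCells), function(i) {
        coloc <- runif(1) < trueColoc
        xa <- runif(1, 15, 49); ya <- runif(1, 15, 49)
        if (coloc) { xb <- xa; yb <- ya }
        else { xb <- (xa + 20) %% 34 + 15; yb <- (ya + 13) %% 34 + 15 }
        img <- simulateImage(size = 64,
                             spotsA = data.frame(x = xa, y = ya,
                                                 amplitude = 10),
                             spotsB = data.frame(x = xb, y = yb,
                                                 amplitude = 10),
                             backgroundMean = 1, backgroundSd = 0.2,
                             seed = 1000 + i)
        da <- detectDots(img$a, threshold = 3, pixelSize = 0.1)
        db <- detectDots(img$b, threshold = 3, pixelSize = 0.1)
        assignColocalization(da, db, cutoff = 0.25)$nPaired > 0
    }, logical(1))
    expect_lt(abs(mean(est) - trueColoc), 0.15)
})

test_that("distance to the nuclear edge mirrors the zoning geometry", {
    b <- new("NuclearBoundary", center = c(5, 5), radius = 1.74,
             residual = 0, multiNucleus = FALSE)
    dots <- data.frame(x = c(5, 5 + 1.74, 5 + 1.52), y = c(5, 5, 5))
    d <- distanceToEdge(dots, b)
    expect_equal(d, c(1.74, 0, 0.22), tolerance = 1e-12)
    outside <- data.frame(x = 5 + 2.0, y = 5)
    expect_error(distanceToEdge(outside, b), "outside")
})

test_that("Pearson colocalization matches direct covariance computation", {
    set.seed(6)
    a <- matrix(rnorm(100 * 100), 100)
    expect_equal(pearsonColoc(a, a), 1)
    expect_equal(pearsonColoc(a, -a + 3), -1)
    b <- matrix(rnorm(100 * 100), 100)
    expect_lt(abs(pearsonColoc(a, b)), 0.05)
    # two-pass covariance oracle on masked pixels
    mask <- matrix(runif(100 * 100) < 0.4, 100)
    av <- a[mask]; bv <- b[mask]
    direct <- sum((av - mean(av)) * (bv - mean(bv))) /
        sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
    expect_equal(pearsonColoc(a, b, mask), direct, tolerance = 1e-12)
    expect_error(pearsonColoc(matrix(1, 4, 4), a[1:4, 1:4]),
                 "zero variance")
    expect_error(pearsonColoc(a, b[1:50, 1:50]), "dimensions")
})
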