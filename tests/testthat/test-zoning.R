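test_that("equal-volume zone boundaries are the exact cube roots", {
    b <- zoneBoundaries(1)
    expect_equal(unname(b["r1"]), (2 / 3)^(1 / 3), tolerance = 1e-12)
    expect_equal(unname(b["r2"]), (1 / 3)^(1 / 3), tolerance = 1e-12)
    expect_equal(unname(b["r1"]), 0.873580464, tolerance = 1e-8)
    expect_equal(unname(b["r2"]), 0.693361274, tolerance = 1e-8)
    # each shell holds exactly a third of the sphere volume
    R <- 1.74
    bb <- zoneBoundaries(R)
    vols <- c(R^3 - bb["r1"]^3, bb["r1"]^3 - bb["r2"]^3, bb["r2"]^3) *
        4 / 3 * pi
    expect_equal(unname(vols), rep(4 / 3 * pi * R^3 / 3, 3),
                 tolerance = 1e-12)
    # Zone-I shell thickness at the typical nuclear radius is ~0.22 um
    expect_equal(R * (1 - (2 / 3)^(1 / 3)), 0.2199700, tolerance = 1e-6)
    expect_error(zoneBoundaries(0), "R must be")
})

test_that("locus-NE distance is R minus the radial coordinate, clamped", {
    expect_equal(locusNEDistance(c(0, 0, 0), c(0, 0, 0), R = 1), 1)
    expect_equal(locusNEDistance(c(1, 0, 0), c(0, 0, 0), R = 1), 0)
    expect_equal(locusNEDistance(c(1.52, 0, 0), c(0, 0, 0), R = 1.74),
                 0.22, tolerance = 1e-12)
    # up to 2% outside the radius clamps to the surface
    expect_equal(locusNEDistance(c(1.01, 0, 0), c(0, 0, 0), R = 1), 0)
    expect_error(locusNEDistance(c(1.05, 0, 0), c(0, 0, 0), R = 1),
                 "outside")
})

test_that("zones are assigned by radial coordinate with peripheral tie-breaks", {
    expect_equal(as.character(assignZone(c(0.9, 0, 0), c(0, 0, 0), 1)),
                 "I")
    expect_equal(as.character(assignZone(c(0, 0, 0), c(0, 0, 0), 1)),
                 "III")
    r1 <- (2 / 3)^(1 / 3)
    expect_equal(as.character(assignZone(c(r1, 0, 0), c(0, 0, 0), 1)),
                 "I")
    r2 <- (1 / 3)^(1 / 3)
    expect_equal(as.character(assignZone(c(r2, 0, 0), c(0, 0, 0), 1)),
                 "II")
    expect_equal(as.character(assignZone(c(0.8, 0, 0), c(0, 0, 0), 1)),
                 "II")
})

test_that("nucleate count maps to cell-cycle stage", {
    s <- classifyStage(c(2, 1, 2))
    expect_equal(as.character(s), c("early_mid_S", "late_S_G2",
                                    "early_mid_S"))
    expect_error(classifyStage(3), "unclassifiable")
})

test_that("Monte-Carlo uniform sampling reproduces the 1/3 expectation", {
    f <- monteCarloRandomZone1(1e5, seed = 101)
    expect_lt(abs(f - 1 / 3), 0.01)
    expect_identical(monteCarloRandomZone1(1e4, seed = 5),
                     monteCarloRandomZone1(1e4, seed = 5))
    expect_true(monteCarloRandomZone1(1, seed = 1) %in% c(0, 1))
})

test_that("each zone's occupancy is uniform across seeds (chi-square screen)", {
    passes <- vapply(1:20, function(seed) {
        obs <- simulateNuclei(1e4, peripheralBias = 0, seed = seed)
        r <- sqrt(obs$x^2 + obs$y^2 + obs$z^2) / obs$radius
        zone <- cut(r, breaks = c(-Inf, (1 / 3)^(1 / 3),
                                  (2 / 3)^(1 / 3), Inf))
        stats::chisq.test(table(zone), p = rep(1 / 3, 3))$p.value > 0.01
    }, logical(1))
    expect_gte(sum(passes), 19)
})

test_that("enrichment test matches frozen exact-binomial arithmetic", {
    mk <- function(radii, n = length(radii)) {
        data.frame(strain = "s", replicate = rep(1:2, length.out = n),
                   stage = "late_S_G2", cx = 0, cy = 0, cz = 0,
                   radius = 1, x = radii, y = 0, z = 0)
    }
    # all 30 cells in Zone I: minimum-likelihood two-sided binomial
    # p-value is (1/3)^30 (no other outcome is as unlikely)
    allIn <- mk(rep(0.95, 30))
    res <- testZone1Enrichment(allIn, method = "binomial")
    expect_equal(res$p_value, (1 / 3)^30, tolerance = 1e-6)
    expect_equal(res$fraction, 1)
    expect_equal(res$n_by_replicate, "15,15")
    # observed fraction exactly the expectation: binomial p = 1
    third <- mk(c(rep(0.95, 10), rep(0.3, 20)))
    res3 <- testZone1Enrichment(third, method = "binomial")
    expect_equal(res3$p_value, 1)
    # zero-variance indicators force the binomial fallback under ttest
    expect_message(resT <- testZone1Enrichment(allIn, method = "ttest"),
                   "binomial")
    expect_equal(resT$test, "binomial")
    expect_equal(resT$p_value, (1 / 3)^30, tolerance = 1e-6)
})

test_that("t-test and binomial agree qualitatively on simulated populations", {
    obs <- simulateNuclei(300, peripheralBias = 0.7, stageMix = 0,
                          seed = 8)
    tt <- testZone1Enrichment(obs, method = "ttest")
    bb <- testZone1Enrichment(obs, method = "binomial")
    expect_lt(tt$p_value, 0.001)
    expect_lt(bb$p_value, 0.001)
    expect_true(all(c(tt$p_value, bb$p_value) >= 0))
    expect_true(all(c(tt$p_value, bb$p_value) <= 1))
    # binomial p is exchangeable under relabeling of replicates
    obs2 <- obs
    obs2$replicate <- rev(rep(1:2, length.out = nrow(obs)))
    expect_equal(testZone1Enrichment(obs2, method = "binomial")$p_value,
                 bb$p_value)
    # uniform populations stay near the null in most samples
    nullOk <- vapply(1:10, function(seed) {
        unif <- simulateNuclei(1000, peripheralBias = 0, stageMix = 0,
                               seed = 1200 + seed)
        un <- testZone1Enrichment(unif, method = "ttest")
        abs(un$fraction - 1 / 3) < 0.06 && un$p_value > 0.05
    }, logical(1))
    expect_gte(sum(nullOk), 8)
})

test_that("summaries stratify by strain and stage with per-replicate counts", {
    a <- simulateNuclei(60, peripheralBias = 0.7, stageMix = 0.5,
                        strain = "wt", replicate = 1, seed = 21)
    b <- simulateNuclei(40, peripheralBias = 0.7, stageMix = 0.5,
                        strain = "wt", replicate = 2, seed = 22)
    c2 <- simulateNuclei(50, peripheralBias = 0, stageMix = 0.5,
                         strain = "mut", replicate = 1, seed = 23)
    res <- testZone1Enrichment(rbind(a, b, c2), method = "binomial")
    expect_equal(nrow(res), 4)   # 2 strains x 2 stages
    expect_setequal(unique(res$strain), c("wt", "mut"))
    expect_equal(sum(res$n), 150)
    wtRows <- res[res$strain == "wt", ]
    expect_true(all(vapply(strsplit(wtRows$n_by_replicate, ","),
                           length, integer(1)) == 2))
})
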