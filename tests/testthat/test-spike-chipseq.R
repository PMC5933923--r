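test_that("5' trimming shortens reads in place and rejects degenerate input", {
    reads <- c(strrep("A", 50), paste0("CGT", strrep("T", 47)))
    out <- trimReads(reads, 3)
    expect_equal(nchar(out), c(47, 47))
    expect_equal(out[2], strrep("T", 47))
    expect_identical(trimReads(reads, 0), reads)
    expect_error(trimReads("ACG", 3), "longer than")
    dss <- Biostrings::DNAStringSet(reads)
    expect_equal(as.character(trimReads(dss, 3)), unname(out))
})

test_that("coverage counts overlapping alignments and conserves aligned bases", {
    sl <- c(chrA = 100L)
    one <- computeCoverage(data.frame(chromosome = "chrA", start = 0,
                                      end = 47), sl)
    d <- as.numeric(trackDepths(one)$chrA)
    expect_equal(d[1:47], rep(1, 47))
    expect_equal(d[48:100], rep(0, 53))
    two <- computeCoverage(data.frame(chromosome = "chrA",
                                      start = c(10, 10), end = c(20, 20)),
                           sl)
    expect_equal(as.numeric(trackDepths(two)$chrA)[11:20], rep(2, 10))
    set.seed(1)
    starts <- sample(0:80, 50, replace = TRUE)
    lens <- sample(5:20, 50, replace = TRUE)
    aln <- data.frame(chromosome = "chrA", start = starts,
                      end = pmin(starts + lens, 100))
    tr <- computeCoverage(aln, sl)
    expect_equal(sum(as.numeric(trackDepths(tr)$chrA)),
                 sum(aln$end - aln$start))
    expect_error(computeCoverage(data.frame(chromosome = "chrA",
                                            start = 90, end = 110), sl),
                 "bounds")
})

test_that("spike scale factor follows S = c / (m_spike - m_ref)", {
    tr <- flatTrack(c(chr = 5), lengths = 200)
    tr@depths$chr[51:70] <- 25
    cfg <- SpikeNormConfig("chr:51-70", "chr:101-200", constant = 10)
    S <- spikeScaleFactor(tr, cfg)
    expect_equal(as.numeric(S), 0.5)        # 10 / (25 - 5)
    expect_equal(attr(S, "mSpike"), 25)
    expect_equal(attr(S, "mRef"), 5)
    # homogeneity: doubling all depths halves S
    S2 <- spikeScaleFactor(normalizeTrack(tr, 2), cfg)
    expect_equal(as.numeric(S2), 0.25)
    flat <- flatTrack(c(chr = 5), lengths = 200)
    expect_error(spikeScaleFactor(flat, cfg), "no spike enrichment")
})

test_that("reference interval enclosing the spike can exclude spike bases", {
    tr <- flatTrack(c(chr = 5), lengths = 200)
    tr@depths$chr[51:70] <- 25
    enclosing <- SpikeNormConfig("chr:51-70", "chr:1-200", constant = 10,
                                 excludeSpike = TRUE)
    S <- spikeScaleFactor(tr, enclosing)
    expect_equal(attr(S, "mRef"), 5)        # spike bases dropped
    literal <- SpikeNormConfig("chr:51-70", "chr:1-200", constant = 10,
                               excludeSpike = FALSE)
    # median over 200 bases of which 20 are 25 is still 5 (robustness)
    expect_equal(attr(spikeScaleFactor(tr, literal), "mRef"), 5)
})

test_that("normalization scales depths and is invariant to raw depth rescaling", {
    tr <- flatTrack(c(chr = 20), lengths = 100)
    expect_equal(as.numeric(trackDepths(normalizeTrack(tr, 1))$chr),
                 rep(20, 100))
    half <- normalizeTrack(tr, 0.5)
    expect_equal(as.numeric(trackDepths(half)$chr), rep(10, 100))
    expect_true(isNormalized(half))
    expect_error(normalizeTrack(tr, -1), "positive")

    gs <- toyGenome()
    sim <- simulateChipCoverage(gs, enrichmentModel(), 1, seed = 21)[[1]]
    cfg <- toySpikeConfig()
    base <- normalizeTrack(sim, spikeScaleFactor(sim, cfg))
    for (k in c(0.5, 2, 10)) {
        scaled <- normalizeTrack(sim, k)  # raw track times k
        scaled@normalized <- FALSE
        renorm <- normalizeTrack(scaled, spikeScaleFactor(scaled, cfg))
        for (chr in names(trackDepths(base))) {
            a <- as.numeric(trackDepths(base)[[chr]])
            b <- as.numeric(trackDepths(renorm)[[chr]])
            expect_equal(b, a, tolerance = 1e-9)
        }
    }
})

test_that("ribbon profiles give exact order statistics across isolates", {
    trs <- lapply(1:3, function(v) flatTrack(c(chr = v), lengths = 1000))
    same <- ribbonProfile(list(trs[[2]], trs[[2]], trs[[2]]),
                          "chr:1-1000", window = 250, step = 25)
    m <- mcols(ribbonWindows(same))
    expect_true(all(m$max - m$min == 0))
    rp <- ribbonProfile(trs, "chr:1-1000", window = 250, step = 250)
    m <- mcols(ribbonWindows(rp))
    expect_equal(length(ribbonWindows(rp)), 4)
    expect_true(all(m$median == 2 & m$min == 1 & m$max == 3))
    single <- ribbonProfile(trs[1], "chr:1-1000")
    ms <- mcols(ribbonWindows(single))
    expect_true(all(ms$median == ms$min & ms$median == ms$max))
})

test_that("ribbon ordering min <= median <= max holds on random tracks", {
    set.seed(77)
    for (rep in 1:5) {
        trs <- lapply(1:4, function(i)
            CoverageTrack(list(chr = rpois(2000, runif(1, 1, 30)))))
        rp <- ribbonProfile(trs, "chr:1-2000", window = 250,
                            step = sample(c(25, 125, 250), 1),
                            isolateSummary = sample(c("mean", "median"), 1))
        m <- mcols(ribbonWindows(rp))
        expect_true(all(m$min <= m$median & m$median <= m$max))
    }
})

test_that("bedgraph round trip is value-exact and malformed input is caught", {
    tr <- CoverageTrack(list(chrI = c(rep(0, 10), rep(2.5, 5),
                                      rep(7, 85)),
                             chrII = rep(1.25, 50)))
    p <- tempfile(fileext = ".bedgraph")
    writeBedGraph(tr, p)
    back <- readBedGraph(p, seqlengths = c(chrI = 100, chrII = 50))
    expect_equal(lapply(trackDepths(back), as.numeric),
                 lapply(trackDepths(tr), as.numeric))

    p2 <- tempfile(fileext = ".bedgraph")
    writeLines("chrI\t0\t5\t2.5", p2)
    t2 <- readBedGraph(p2)
    expect_equal(as.numeric(trackDepths(t2)$chrI), rep(2.5, 5))

    p3 <- tempfile(fileext = ".bedgraph")
    writeLines(c("chrI\t0\t10\t1", "chrI\t5\t15\t2"), p3)
    expect_error(readBedGraph(p3), "overlap")
})

test_that("dcr1-like pericentric multiplier is recovered from normalized ribbons", {
    gs <- toyGenome()
    wtModel <- enrichmentModel(overdispersion = 0.1)
    dcrModel <- enrichmentModel(
        multipliers = c(subtelomere = 8, pericentromere = 2, mat = 8,
                        euchromatin = 1, spike_locus = 10),
        overdispersion = 0.1)
    cfg <- toySpikeConfig()
    wt <- normalizeTracks(simulateChipCoverage(gs, wtModel, 3, seed = 31,
                                               depthScale = c(1, 1.5, 0.7)),
                          cfg)
    dcr <- normalizeTracks(simulateChipCoverage(gs, dcrModel, 3,
                                                seed = 32,
                                                depthScale = c(2, 1, 1.2)),
                           cfg)
    reg <- "toy_I:27001-33000"
    med <- function(tracks) {
        perIso <- vapply(tracks, function(t) mean(regionDepths(t, reg)),
                         numeric(1))
        list(mean = mean(perIso), se = stats::sd(perIso) / sqrt(3))
    }
    w <- med(wt); d <- med(dcr)
    ratio <- d$mean / w$mean
    seRatio <- ratio * sqrt((d$se / d$mean)^2 + (w$se / w$mean)^2)
    expect_lt(abs(ratio - 0.2), 3 * max(seRatio, 0.01))
})
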