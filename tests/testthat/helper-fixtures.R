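# Shared fixtures built in code.

# A flat CoverageTrack: one value per chromosome, recycled over lengths.
flatTrack <- function(values, lengths = 1000L, normalized = FALSE) {
    lengths <- rep_len(lengths, length(values))
    if (is.null(names(values)))
        names(values) <- paste0("chr", seq_along(values))
    depths <- Map(function(v, l) rep(v, l), values, lengths)
    CoverageTrack(depths, normalized = normalized)
}

# Spike config matching toyGenome(): spike locus toy_III:45001-46750,
# euchromatic reference flanking it.
toySpikeConfig <- function(excludeSpike = TRUE) {
    SpikeNormConfig(spikeInterval = "toy_III:45001-46750",
                    referenceInterval = "toy_III:40001-55000",
                    constant = 10, excludeSpike = excludeSpike)
}

# Uniform-disk image: constant foreground on background, for boundary
# estimation tests.
diskImage <- function(size = 64L, center = c(32, 32), radius = 20,
                      fg = 5, bg = 1, noiseSd = 0, seed = 1) {
    xs <- matrix(rep(seq_len(size) - 0.5, each = size), size)
    ys <- matrix(rep(seq_len(size) - 0.5, times = size), size)
    img <- ifelse(sqrt((xs - center[1])^2 + (ys - center[2])^2) <= radius,
                  fg, bg)
    if (noiseSd > 0) {
        set.seed(seed)
        img <- img + matrix(rnorm(size^2, 0, noiseSd), size)
    }
    img
}
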