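#' Construct a GenomeSpec
#'
#' @param seqlengths named vector of chromosome lengths (bp).
#' @param domains \code{GRanges} with metadata columns \code{domain_class}
#'   (one of \code{subtelomere}, \code{pericentromere}, \code{mat},
#'   \code{euchromatin}, \code{spike_locus}) and \code{name}, or a
#'   data.frame with columns \code{name}, \code{chromosome}, \code{start},
#'   \code{end}, \code{domain_class} (1-based inclusive coordinates).
#' @return a \code{\linkS4class{GenomeSpec}}.
#' @examples
#' gs <- toyGenome()
#' domains(gs)
#' @export
GenomeSpec <- function(seqlengths, domains) {
    sl <- setNames(as.integer(seqlengths), names(seqlengths))
    if (is.data.frame(domains)) {
        domains <- GRanges(domains$chromosome,
                           IRanges(domains$start, domains$end),
                           domain_class = domains$domain_class,
                           name = domains$name)
    }
    new("GenomeSpec", seqlengths = sl, domains = domains)
}

#' @rdname GenomeSpec-class
#' @param x a \code{GenomeSpec}.
#' @export
setMethod("domains", "GenomeSpec", function(x) x@domains)

#' @rdname GenomeSpec-class
#' @export
setMethod("seqlengths", "GenomeSpec", function(x) x@seqlengths)

setMethod("show", "GenomeSpec", function(object) {
    cat("GenomeSpec:", length(object@seqlengths), "chromosome(s),",
        sum(as.numeric(object@seqlengths)), "bp total\n")
    tab <- table(mcols(object@domains)$domain_class)
    cat("  domains:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
})

#' A small fission-yeast-like toy genome
#'
#' Three short chromosomes carrying the domain kinds profiled in the
#' H3K9me2 analyses: subtelomeres at chromosome ends, a pericentromeric
#' block per chromosome, the \emph{mat} locus on chromosome II, and a
#' spike (ectopic \code{ade6+}) locus embedded in euchromatin of
#' chromosome III with euchromatic flanks usable as the reference
#' interval. Sized so simulations cover > 1e5 bases quickly.
#'
#' @param scale multiply all lengths by this factor (default 1).
#' @return a \code{\linkS4class{GenomeSpec}}.
#' @export
toyGenome <- function(scale = 1) {
    s <- function(x) as.integer(round(x * scale))
    sl <- c(toy_I = s(60000), toy_II = s(60000), toy_III = s(60000))
    d <- rbind(
        data.frame(name = "subtel_1L", chromosome = "toy_I",
                   start = s(1), end = s(6000),
                   domain_class = "subtelomere"),
        data.frame(name = "subtel_1R", chromosome = "toy_I",
                   start = s(54001), end = s(60000),
                   domain_class = "subtelomere"),
        data.frame(name = "percen_1", chromosome = "toy_I",
                   start = s(27001), end = s(33000),
                   domain_class = "pericentromere"),
        data.frame(name = "mat", chromosome = "toy_II",
                   start = s(40001), end = s(44000),
                   domain_class = "mat"),
        data.frame(name = "percen_2", chromosome = "toy_II",
                   start = s(27001), end = s(33000),
                   domain_class = "pericentromere"),
        data.frame(name = "percen_3", chromosome = "toy_III",
                   start = s(27001), end = s(33000),
                   domain_class = "pericentromere"),
        data.frame(name = "ade6_spike", chromosome = "toy_III",
                   start = s(45001), end = s(46750),
                   domain_class = "spike_locus"))
    GenomeSpec(sl, d)
}

#' Construct a CoverageTrack
#'
#' @param depths an \code{RleList} (or list of numeric vectors) of per-base
#'   depths, named by chromosome.
#' @param normalized has spike normalization been applied?
#' @return a \code{\linkS4class{CoverageTrack}}.
#' @export
CoverageTrack <- function(depths, normalized = FALSE) {
    if (!is(depths, "RleList"))
        depths <- RleList(lapply(depths, Rle))
    new("CoverageTrack", depths = depths, normalized = normalized)
}

#' @rdname CoverageTrack-class
#' @param x a \code{CoverageTrack}.
#' @export
setMethod("trackDepths", "CoverageTrack", function(x) x@depths)

#' @rdname CoverageTrack-class
#' @export
setMethod("isNormalized", "CoverageTrack", function(x) x@normalized)

#' @rdname CoverageTrack-class
#' @export
setMethod("seqlengths", "CoverageTrack",
    function(x) setNames(vapply(x@depths, length, integer(1)),
                         names(x@depths)))

setMethod("show", "CoverageTrack", function(object) {
    sl <- seqlengths(object)
    means <- vapply(object@depths, function(d) mean(as.numeric(d)),
                    numeric(1))
    cat("CoverageTrack (", if (object@normalized) "normalized" else "raw",
        "): ", length(sl), " chromosome(s)\n", sep = "")
    for (i in seq_along(sl))
        cat(sprintf("  %s: %d bp, mean depth %.3g\n",
                    names(sl)[i], sl[i], means[i]))
})

#' Trim bases from the 5' end of reads
#'
#' Library construction can prepend template-switching bases that must be
#' removed before alignment; 50 bp reads trimmed by 3 leave 47 bp.
#'
#' @param reads a character vector or \code{Biostrings::XStringSet}.
#' @param nTrim number of 5' bases to remove.
#' @return the trimmed reads, same class and order as the input.
#' @examples
#' trimReads(c("ACGTACGT", "TTTTAAAA"), 3)
#' @export
trimReads <- function(reads, nTrim = 3L) {
    nTrim <- as.integer(nTrim)
    if (nTrim < 0L) stop("nTrim must be >= 0")
    if (nTrim == 0L) return(reads)
    if (is(reads, "XStringSet")) {
        if (any(Biostrings::width(reads) <= nTrim))
            stop("all reads must be longer than nTrim")
        return(Biostrings::subseq(reads, start = nTrim + 1L))
    }
    if (any(nchar(reads) <= nTrim))
        stop("all reads must be longer than nTrim")
    substring(reads, nTrim + 1L)
}

.alignmentsToGRanges <- function(alignments) {
    if (is(alignments, "GRanges")) return(alignments)
    # data.frame convention: 0-based half-open (BED-like)
    GRanges(alignments$chromosome,
            IRanges(alignments$start + 1L, alignments$end))
}

#' Per-base coverage from alignment intervals
#'
#' Depth at each base is the number of alignment intervals overlapping it;
#' every reported location of a multi-mapped read contributes full weight.
#'
#' @param alignments a \code{GRanges}, or a data.frame with columns
#'   \code{chromosome}, \code{start}, \code{end} in 0-based half-open
#'   (BED-like) coordinates.
#' @param genome a \code{\linkS4class{GenomeSpec}} (or named vector of
#'   chromosome lengths) fixing chromosome names and lengths.
#' @return a raw \code{\linkS4class{CoverageTrack}}.
#' @examples
#' gs <- toyGenome()
#' aln <- data.frame(chromosome = "toy_I", start = 0, end = 47)
#' computeCoverage(aln, gs)
#' @export
computeCoverage <- function(alignments, genome) {
    sl <- if (is(genome, "GenomeSpec")) seqlengths(genome)
          else setNames(as.integer(genome), names(genome))
    gr <- .alignmentsToGRanges(alignments)
    chr <- as.character(seqnames(gr))
    if (!all(chr %in% names(sl)))
        stop("alignment on unknown chromosome: ",
             paste(unique(setdiff(chr, names(sl))), collapse = ", "))
    if (any(start(gr) < 1L) || any(end(gr) > sl[chr]))
        stop("alignment outside chromosome bounds")
    gr <- GRanges(chr, IRanges(start(gr), end(gr)), seqlengths = sl)
    cov <- coverage(gr)
    CoverageTrack(cov[names(sl)], normalized = FALSE)
}

#' Read a bedgraph file into a CoverageTrack
#'
#' Four-column bedgraph (chrom, start, end, value), 0-based half-open.
#' Records must not overlap; bases not covered by any record get depth 0.
#'
#' @param path bedgraph file.
#' @param seqlengths optional named chromosome lengths; inferred from the
#'   rightmost record per chromosome when missing.
#' @param normalized mark the track as spike-normalized.
#' @return a \code{\linkS4class{CoverageTrack}}.
#' @export
readBedGraph <- function(path, seqlengths = NULL, normalized = FALSE) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) > 1L) {
        red <- reduce(gr)
        if (sum(width(red)) != sum(width(gr)))
            stop("overlapping bedgraph records in ", path)
    }
    sl <- if (is.null(seqlengths)) {
        vapply(split(end(gr), as.character(seqnames(gr))), max, numeric(1))
    } else setNames(as.numeric(seqlengths), names(seqlengths))
    gr2 <- GRanges(as.character(seqnames(gr)),
                   IRanges(start(gr), end(gr)),
                   seqlengths = setNames(as.integer(sl), names(sl)))
    cov <- coverage(gr2, weight = gr$score)
    # weighted coverage accumulates +w/-w pairs; squash float residue
    cov <- S4Vectors::endoapply(cov, function(x) {
        v <- runValue(x)
        v[abs(v) < 1e-9] <- 0
        if (any(v < 0)) stop("negative depth in ", path)
        runValue(x) <- v
        x
    })
    CoverageTrack(cov[names(sl)], normalized = normalized)
}

#' Write a CoverageTrack as bedgraph
#'
#' Adjacent equal-value runs are merged; zero-depth runs are omitted.
#' The round trip through \code{\link{readBedGraph}} is value-exact.
#'
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(track, path) {
    stopifnot(is(track, "CoverageTrack"))
    lines <- character(0)
    for (chr in names(track@depths)) {
        d <- track@depths[[chr]]
        v <- runValue(d)
        ends <- cumsum(runLength(d))
        starts <- ends - runLength(d)      # 0-based half-open
        keep <- v != 0
        if (any(keep))
            lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chr,
                                      starts[keep], ends[keep],
                                      format(v[keep], scientific = FALSE,
                                             trim = TRUE, digits = 15)))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Extract per-base depths over an interval
#'
#' @param track a \code{\linkS4class{CoverageTrack}}.
#' @param region a single-range \code{GRanges}, or \code{"chr:start-end"}
#'   (1-based inclusive).
#' @return numeric vector of depths, one per base.
#' @export
regionDepths <- function(track, region) {
    region <- .asRegion(region)
    chr <- as.character(seqnames(region))
    if (!chr %in% names(track@depths))
        stop("chromosome not in track: ", chr)
    d <- track@depths[[chr]]
    if (start(region) < 1L || end(region) > length(d))
        stop("region outside track bounds")
    as.numeric(d[start(region):end(region)])
}

.asRegion <- function(region) {
    if (is(region, "GRanges")) {
        stopifnot(length(region) == 1L)
        return(region)
    }
    m <- regmatches(region,
                    regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L)
        stop("cannot parse region string: ", region)
    GRanges(m[2], IRanges(as.integer(m[3]), as.integer(m[4])))
}
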