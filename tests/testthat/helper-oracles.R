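# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately avoid the code paths they check: overlap counting
# is done by all-pairs comparison in base R, and the hypergeometric tail by
# explicit enumeration of point masses via log-binomials.

library(GenomicRanges)

gr <- function(chrom, start, end) GRanges(chrom, IRanges(start, end))

# O(n*m) all-pairs oracle for overlapSupport(): number of query regions
# sharing >= minOverlap bp with any subject region (1-based closed coords).
bruteOverlapCount <- function(qgr, sgr, minOverlap = 1) {
    sIdx <- split(seq_along(sgr), as.character(seqnames(sgr)))
    ss <- start(sgr); se <- end(sgr)
    qc <- as.character(seqnames(qgr)); qs <- start(qgr); qe <- end(qgr)
    hits <- 0L
    for (i in seq_along(qs)) {
        j <- sIdx[[qc[i]]]
        if (is.null(j)) next
        ov <- pmin(qe[i], se[j]) - pmax(qs[i], ss[j]) + 1L
        if (any(ov >= minOverlap)) hits <- hits + 1L
    }
    hits
}

# Exhaustive upper-tail hypergeometric oracle: P(X >= a) with margins fixed,
# summing point masses C(a+b, x) * C(c+d, k-x) / C(n, k) over the tail.
fisherTailOracle <- function(a, b, c, d) {
    m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
    xs <- seq(a, min(m1, k))
    xs <- xs[k - xs <= m2]
    if (!length(xs)) return(0)
    sum(exp(lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(n, k)))
}

# Random region set on a small genome; duplicates and overlaps allowed
# before normalization.
randomRegionGRanges <- function(n, chroms = c("chr1", "chr2", "chr3"),
                                maxPos = 5000, maxLen = 60) {
    if (n == 0) return(GRanges())
    s <- sample.int(maxPos, n, replace = TRUE)
    w <- sample.int(maxLen, n, replace = TRUE)
    GRanges(sample(chroms, n, replace = TRUE), IRanges(s, s + w - 1))
}

writeBedLines <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame()),
                          file = "regions.bed") {
    path <- file.path(dir, file)
    writeLines(lines, path)
    path
}

# Build a small on-disk reference database tree. `spec` is a named list:
# collection name -> named list of file -> character vector of BED lines.
makeDbTree <- function(root, spec, index = list()) {
    for (coll in names(spec)) {
        rdir <- file.path(root, coll, "regions")
        dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
        for (fn in names(spec[[coll]]))
            writeLines(spec[[coll]][[fn]], file.path(rdir, fn))
        if (!is.null(index[[coll]]))
            write.table(index[[coll]], file.path(root, coll, "index.txt"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    root
}

# Region-by-region equality of two RegionDB objects.
expect_same_db <- function(x, y) {
    expect_equal(length(x), length(y))
    ax <- dbAnnotation(x); ay <- dbAnnotation(y)
    expect_equal(ax[names(ay)], ay)
    for (i in seq_len(length(x))) {
        gx <- regions(dbEntries(x)[[i]]); gy <- regions(dbEntries(y)[[i]])
        expect_equal(as.character(seqnames(gx)), as.character(seqnames(gy)))
        expect_equal(start(gx), start(gy))
        expect_equal(end(gx), end(gy))
    }
}
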