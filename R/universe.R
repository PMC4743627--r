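# Background-universe construction and diagnostics. The universe is the set
# of regions that could, in principle, have been included in the query; it
# defines the sampling frame of the exact test, so a mismatched universe is
# the most common way to get a misleading enrichment.

#' Build a restricted universe from query sets
#'
#' Returns the merged union of all regions across the given query sets: the
#' concatenation of the queries, normalized and coalesced with
#' \code{\link{mergeRegions}}, so the result is disjoint and non-bookended.
#' This is the natural background for testing two (or more) region sets for
#' differential enrichment against the same database: each query is a subset
#' of the universe by construction.
#'
#' The operation is idempotent and invariant to the order of its inputs.
#'
#' @param queries a \linkS4class{RegionSet} or list of them.
#' @param name identifier for the resulting set.
#' @return a disjoint, normalized \linkS4class{RegionSet}.
#' @examples
#' a <- RegionSet("a", GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)))
#' b <- RegionSet("b", GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 20)))
#' regions(buildRestrictedUniverse(list(a, b)))
#' @export
buildRestrictedUniverse <- function(queries, name = "restrictedUniverse") {
    if (is(queries, "RegionSet"))
        queries <- list(queries)
    stopifnot(length(queries) >= 1L,
              all(vapply(queries, is, logical(1), "RegionSet")))
    grl <- lapply(queries, regions)
    if (sum(vapply(grl, length, integer(1))) == 0L)
        stop("all query sets are empty; an empty universe is unusable")
    combined <- GRanges(
        unlist(lapply(grl, function(g) as.character(seqnames(g))),
               use.names = FALSE),
        IRanges(unlist(lapply(grl, start), use.names = FALSE),
                unlist(lapply(grl, end), use.names = FALSE)))
    mergeRegions(RegionSet(name, combined))
}

#' Restrict a universe to the regions a query touches
#'
#' Returns the subset of universe regions overlapping (by at least 1 bp) at
#' least one query region. Use this when the query was produced by a
#' different segmentation than the universe, so that query and universe are
#' counted in the same units before building contingency tables. This
#' remapping is deliberately an explicit step: the main analysis never
#' remaps the query silently, because doing so changes counts invisibly.
#'
#' @param query,universe \linkS4class{RegionSet} objects.
#' @return a \linkS4class{RegionSet}: the touched subset of the universe
#'   (named after the query).
#' @seealso \code{\link{checkUniverseAppropriateness}}
#' @export
redefineQueryToUniverse <- function(query, universe) {
    stopifnot(is(query, "RegionSet"), is(universe, "RegionSet"))
    ugr <- regions(universe)
    qgr <- regions(query)
    lv <- sort(union(seqlevels(ugr), seqlevels(qgr)))
    seqlevels(ugr) <- lv
    seqlevels(qgr) <- lv
    hit <- countOverlaps(ugr, qgr, ignore.strand = TRUE) > 0L
    RegionSet(regionSetName(query), ugr[hit])
}

#' Diagnose whether a universe suits a query
#'
#' Reports (i) the fraction of query regions overlapping at least one
#' universe region, (ii) the query and universe sizes, and (iii) the
#' chromosomes present in the query but absent from the universe (chromosome
#' names are matched as exact strings, so a genome-naming mismatch such as
#' "chr1" vs "1" shows up here rather than silently zeroing every overlap).
#' A warning is emitted when the coverage fraction falls below 0.95 or when
#' the query is larger than the universe; query regions outside the universe
#' still count toward the query total in the contingency table, so low
#' coverage signals a biased test, not dropped data.
#'
#' @param query,universe \linkS4class{RegionSet} objects.
#' @return (invisibly) a list of class \code{universeCheck} with elements
#'   \code{queryName}, \code{coverage}, \code{querySize},
#'   \code{universeSize} and \code{missingChroms}.
#' @export
checkUniverseAppropriateness <- function(query, universe) {
    stopifnot(is(query, "RegionSet"), is(universe, "RegionSet"))
    qs <- length(query)
    us <- length(universe)
    covered <- if (qs) overlapSupport(query, universe, 1L) / qs else 1
    qChrom <- as.character(unique(seqnames(regions(query))))
    uChrom <- as.character(unique(seqnames(regions(universe))))
    missing <- setdiff(qChrom, uChrom)
    if (length(missing))
        warning("query chromosomes absent from the universe: ",
                paste(missing, collapse = ", "),
                " (check genome build / naming convention)")
    if (covered < 0.95)
        warning(sprintf(
            "only %.1f%% of query regions overlap the universe; the universe may not contain the query",
            100 * covered))
    if (qs > us)
        warning("query (", qs, " regions) is larger than the universe (",
                us, " regions)")
    out <- list(queryName = regionSetName(query), coverage = covered,
                querySize = qs, universeSize = us, missingChroms = missing)
    class(out) <- "universeCheck"
    invisible(out)
}

#' @export
print.universeCheck <- function(x, ...) {
    cat("Universe check for query '", x$queryName, "'\n", sep = "")
    cat(sprintf("  coverage: %.3f of %d query regions overlap the universe (%d regions)\n",
                x$coverage, x$querySize, x$universeSize))
    if (length(x$missingChroms))
        cat("  chromosomes missing from universe:",
            paste(x$missingChroms, collapse = ", "), "\n")
    invisible(x)
}
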