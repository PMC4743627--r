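# The statistical core: contingency tables at the region level, a one-sided
# exact test, BH false-discovery-rate correction, a smoothed log odds ratio,
# and the composite max-rank score that orders the final results table.

#' Build the 2x2 contingency table for one query / database-set pair
#'
#' Counts are at the region level, treating each region as an independent
#' unit, and the four cells partition the universe: \code{a} query regions
#' overlap the database set (by at least \code{minOverlap} bp), \code{b}
#' other universe regions overlap it, \code{c} query regions do not, and
#' \code{d} is the remainder. The universe is assumed to contain the query
#' ("could have been included"); when it does not, i.e. more query than
#' universe regions hit the database set, \code{b} is clamped to 0 with a
#' warning rather than going negative — run
#' \code{\link{checkUniverseAppropriateness}} or
#' \code{\link{redefineQueryToUniverse}} when you see that warning.
#'
#' @param query,universe,dbSet \linkS4class{RegionSet} objects.
#' @param minOverlap minimum shared base pairs for an overlap (default 1).
#' @return a \linkS4class{ContingencyTable}.
#' @examples
#' u <- RegionSet("u", GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(seq(1, 991, by = 10), width = 5)))
#' q <- RegionSet("q", regions(u)[1:10])
#' s <- RegionSet("s", regions(u)[6:12])
#' buildContingency(q, u, s)
#' @export
buildContingency <- function(query, universe, dbSet, minOverlap = 1L) {
    stopifnot(is(query, "RegionSet"), is(universe, "RegionSet"),
              is(dbSet, "RegionSet"))
    qs <- length(query)
    us <- length(universe)
    if (qs > us)
        stop("query (", qs, " regions) is larger than the universe (", us,
             " regions); see checkUniverseAppropriateness() and ",
             "redefineQueryToUniverse()")
    a <- overlapSupport(query, dbSet, minOverlap)
    u <- overlapSupport(universe, dbSet, minOverlap)
    if (u < a)
        warning("query does not appear to be a subset of the universe (",
                a, " query hits vs ", u, " universe hits on '",
                regionSetName(dbSet), "'); clamping cell b to 0")
    b <- max(u - a, 0L)
    cc <- qs - a
    d <- us - a - b - cc
    if (d < 0L)
        stop("inconsistent universe: cell d is negative for database set '",
             regionSetName(dbSet), "'")
    ContingencyTable(a, b, cc, d)
}

# Vectorized one-sided upper-tail hypergeometric probability.
# P(X >= a) with X ~ Hypergeom(white = a+b, black = c+d, drawn = a+c);
# phyper works in log space internally, so this is stable for margins
# well beyond 1e6. Clamped into (0, 1].
.pFisherGreater <- function(a, b, c, d) {
    p <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
    pmin(pmax(p, .Machine$double.xmin), 1)
}

#' One-sided Fisher's exact test for overlap enrichment
#'
#' Exact hypergeometric tail probability of observing support \code{a} or
#' larger with all table margins fixed — the enrichment direction of
#' Fisher's exact test. Depletion is deliberately not tested: the results
#' ranking is about enrichment, and a two-sided p-value would let strong
#' depletions masquerade as top hits.
#'
#' @param t a \linkS4class{ContingencyTable}.
#' @return a p-value in (0, 1]; exactly 1 when the observed support is the
#'   smallest achievable.
#' @examples
#' fisherExactGreater(ContingencyTable(5, 0, 0, 5))  # 1/choose(10, 5)
#' @export
fisherExactGreater <- function(t) {
    stopifnot(is(t, "ContingencyTable"))
    .pFisherGreater(t@a, t@b, t@c, t@d)
}

# Haldane-Anscombe smoothed sample log odds ratio, finite on zero cells.
.logOR <- function(a, b, c, d) {
    log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
}

#' Smoothed log odds ratio of a contingency table
#'
#' Natural log of the sample odds ratio with the Haldane–Anscombe
#' correction, \code{((a+0.5)(d+0.5)) / ((b+0.5)(c+0.5))}, which keeps the
#' statistic finite when any cell is zero. This is the closed-form sample
#' estimator, not the conditional maximum-likelihood estimator reported by
#' some exact-test implementations; the two order tables almost identically
#' but differ in small samples, so expect small numeric differences when
#' comparing against other tools.
#'
#' @param t a \linkS4class{ContingencyTable}.
#' @return a finite real number.
#' @export
logOddsRatio <- function(t) {
    stopifnot(is(t, "ContingencyTable"))
    .logOR(t@a, t@b, t@c, t@d)
}

#' Benjamini–Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, clamped to at most 1, returned in input
#' order. Adjusted values never fall below the raw p-values and preserve
#' their ordering up to ties.
#'
#' @param pValues numeric vector of raw p-values in (0, 1].
#' @return numeric vector of adjusted values, same length and order.
#' @export
adjustFDR <- function(pValues) {
    if (!length(pValues))
        return(numeric(0))
    if (anyNA(pValues) || any(pValues <= 0 | pValues > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(pValues, method = "BH")
}

# Competition ranking: ties share the smallest applicable rank (1, 2, 2, 4).
.competitionRank <- function(x, decreasing = FALSE) {
    if (decreasing) x <- -x
    as.integer(rank(x, ties.method = "min"))
}

#' Rank enrichment results by the composite max-rank score
#'
#' Given the per-database-set results of one query, assigns three
#' competition ranks — p-value ascending, log odds ratio descending, support
#' descending — and scores each database set by the worst (largest) of the
#' three. The max-rank score emphasizes database sets that do well on all
#' three measures: a tiny p-value cannot compensate for a weak odds ratio or
#' a handful of overlapping regions. Results are returned sorted by
#' (\code{maxRank}, \code{pValue}, \code{dbSet}) so output files are fully
#' reproducible.
#'
#' @param results a \code{data.frame} of results for a single query, with at
#'   least columns \code{dbSet}, \code{pValue}, \code{logOddsRatio} and
#'   \code{support}.
#' @return the same \code{data.frame} with columns \code{rankP},
#'   \code{rankOR}, \code{rankSupport} and \code{maxRank} filled in, sorted.
#' @export
rankResults <- function(results) {
    stopifnot(is.data.frame(results))
    if (!nrow(results))
        return(results)
    need <- c("dbSet", "pValue", "logOddsRatio", "support")
    miss <- setdiff(need, names(results))
    if (length(miss))
        stop("results lack column(s): ", paste(miss, collapse = ", "))
    if ("queryName" %in% names(results) &&
        length(unique(results$queryName)) > 1L)
        stop("rankResults() expects the results of a single query set")
    results$rankP <- .competitionRank(results$pValue)
    results$rankOR <- .competitionRank(results$logOddsRatio, decreasing = TRUE)
    results$rankSupport <- .competitionRank(results$support, decreasing = TRUE)
    results$maxRank <- pmax(results$rankP, results$rankOR,
                            results$rankSupport)
    ord <- order(results$maxRank, results$pValue, results$dbSet)
    results <- results[ord, , drop = FALSE]
    rownames(results) <- NULL
    results
}

# Pool all database entries into one GRanges plus a group index so the
# per-entry support of a region set is computed with a single findOverlaps
# call instead of one interval query per entry.
.poolEntries <- function(entries) {
    grl <- lapply(entries, regions)
    n <- vapply(grl, length, integer(1))
    chrom <- unlist(lapply(grl, function(g) as.character(seqnames(g))),
                    use.names = FALSE)
    if (is.null(chrom)) chrom <- character(0)
    gr <- GRanges(chrom,
                  IRanges(unlist(lapply(grl, start), use.names = FALSE),
                          unlist(lapply(grl, end), use.names = FALSE)))
    list(gr = gr, grp = rep(seq_along(grl), n), nEntries = length(grl))
}

# Number of `gr` regions overlapping each pooled entry by >= minOverlap bp
# (each region counted once per entry).
.supportCounts <- function(gr, pool, minOverlap) {
    pgr <- pool$gr
    if (!identical(seqlevels(gr), seqlevels(pgr))) {
        lv <- sort(union(seqlevels(gr), seqlevels(pgr)))
        seqlevels(gr) <- lv
        seqlevels(pgr) <- lv
    }
    h <- findOverlaps(gr, pgr, minoverlap = as.integer(minOverlap),
                      ignore.strand = TRUE)
    grp <- pool$grp[subjectHits(h)]
    key <- as.numeric(queryHits(h)) * (pool$nEntries + 1) + grp
    tabulate(grp[!duplicated(key)], nbins = pool$nEntries)
}

#' Run the full overlap-enrichment analysis
#'
#' For every (query, database entry) pair: count overlaps, build the
#' contingency table, compute the one-sided exact test p-value and the
#' smoothed log odds ratio; then, within each query set, apply
#' Benjamini–Hochberg FDR correction jointly across all database entries of
#' all collections and assign the composite max-rank score. The universe's
#' overlap with each database entry is computed once and shared across
#' queries. Output is fully deterministic.
#'
#' A database entry whose BED file was empty simply yields a row with zero
#' support, not an error.
#'
#' @param queries a \linkS4class{RegionSet} or list of them.
#' @param universe the background \linkS4class{RegionSet}.
#' @param db a \linkS4class{RegionDB}.
#' @param minOverlap minimum shared base pairs for an overlap (default 1).
#' @return a \code{data.frame} with one row per (query, database entry):
#'   \code{queryName}, \code{collection}, \code{dbSet}, \code{description},
#'   \code{cellType}, \code{antibody}, \code{treatment}, \code{support},
#'   \code{b}, \code{c}, \code{d}, \code{pValue}, \code{qValue},
#'   \code{logOddsRatio}, \code{rankP}, \code{rankOR}, \code{rankSupport},
#'   \code{maxRank}; rows sorted within each query by
#'   (\code{maxRank}, \code{pValue}, \code{dbSet}).
#' @seealso \code{\link{writeResults}}
#' @export
runAnalysis <- function(queries, universe, db, minOverlap = 1L) {
    if (is(queries, "RegionSet"))
        queries <- list(queries)
    stopifnot(length(queries) >= 1L,
              all(vapply(queries, is, logical(1), "RegionSet")),
              is(universe, "RegionSet"), is(db, "RegionDB"))
    if (!length(db))
        stop("the reference database is empty")
    entries <- dbEntries(db)
    anno <- dbAnnotation(db)
    us <- length(universe)
    pool <- .poolEntries(entries)
    uHits <- .supportCounts(regions(universe), pool, minOverlap)
    blocks <- lapply(queries, function(query) {
        qs <- length(query)
        if (qs > us)
            stop("query '", regionSetName(query), "' (", qs,
                 " regions) is larger than the universe (", us,
                 " regions); see checkUniverseAppropriateness() and ",
                 "redefineQueryToUniverse()")
        a <- .supportCounts(regions(query), pool, minOverlap)
        over <- uHits < a
        if (any(over))
            warning("query '", regionSetName(query),
                    "' is not a subset of the universe for ", sum(over),
                    " database set(s); clamping cell b to 0")
        b <- pmax(uHits - a, 0L)
        cc <- qs - a
        d <- us - a - b - cc
        if (any(d < 0L))
            stop("inconsistent universe: negative cell d for database set '",
                 tools::file_path_sans_ext(anno$filename[which(d < 0L)[1L]]),
                 "'")
        p <- .pFisherGreater(a, b, cc, d)
        res <- data.frame(
            queryName = regionSetName(query),
            collection = anno$collection,
            dbSet = tools::file_path_sans_ext(anno$filename),
            description = anno$description,
            cellType = anno$cellType,
            antibody = anno$antibody,
            treatment = anno$treatment,
            support = as.integer(a),
            b = as.integer(b),
            c = as.integer(cc),
            d = as.integer(d),
            pValue = p,
            qValue = adjustFDR(p),
            logOddsRatio = .logOR(a, b, cc, d),
            stringsAsFactors = FALSE)
        rankResults(res)
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
}

.fmtP <- function(p) {
    ifelse(p < 1e-4, sprintf("%.4e", p), sprintf("%.6g", p))
}

#' Write a results table as TSV
#'
#' Writes the results of \code{\link{runAnalysis}} as a tab-separated file
#' with a header. p- and q-values below 1e-4 are written in scientific
#' notation, all other reals with 6 significant digits, so repeated runs on
#' identical inputs produce byte-identical files.
#'
#' @param results a results \code{data.frame} from \code{\link{runAnalysis}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeResults <- function(results, path) {
    stopifnot(is.data.frame(results))
    out <- results
    for (cn in c("pValue", "qValue"))
        out[[cn]] <- .fmtP(results[[cn]])
    out$logOddsRatio <- sprintf("%.6g", results$logOddsRatio)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
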