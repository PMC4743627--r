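# Central S4 classes. All region containers hold GRanges in the usual
# Bioconductor 1-based closed convention; BED I/O converts at the boundary.

## ---- RegionSet --------------------------------------------------------------

#' RegionSet: a named, normalized collection of genomic regions
#'
#' A \code{RegionSet} wraps a \link[GenomicRanges]{GRanges} that is kept in
#' normalized form: regions strictly sorted by (chromosome, start, end) with
#' exact duplicates removed, all regions at least 1 bp wide, strand ignored.
#' Chromosome order is plain lexicographic on the chromosome name, so
#' normalization is deterministic and independent of input order.
#'
#' Queries, background universes and reference-database entries are all
#' \code{RegionSet} objects.
#'
#' @slot name single identifier string.
#' @slot regions normalized \code{GRanges}.
#'
#' @seealso \code{\link{readBed}}, \code{\link{mergeRegions}},
#'   \code{\link{overlapSupport}}
#' @export
setClass("RegionSet", slots = c(name = "character", regions = "GRanges"))

# Normalize a GRanges: drop metadata/strand, lexicographic seqlevels,
# sort by (chrom, start, end), drop duplicates. Rejects zero-length regions
# and whitespace-containing chromosome names.
.normalizeGRanges <- function(gr, context = "regions") {
    chrom <- as.character(seqnames(gr))
    if (any(grepl("[[:space:]]", chrom)))
        stop(context, ": chromosome names must not contain whitespace")
    if (length(gr) && any(width(gr) < 1L))
        stop(context, ": zero-length regions are not allowed")
    lv <- sort(unique(chrom))
    out <- GRanges(factor(chrom, levels = lv),
                   IRanges(start(gr), end(gr)))
    unique(sort(out))
}

# Internal fast path: the caller guarantees `gr` is already normalized
# (e.g. a subset of a normalized set taken with increasing indices), so the
# full normalization and validity scan are skipped.
.RegionSetTrusted <- function(name, gr) {
    S4Vectors::new2("RegionSet", name = name, regions = gr, check = FALSE)
}

.isNormalizedGRanges <- function(gr) {
    lv <- as.character(unique(seqnames(gr)))
    if (is.unsorted(lv, strictly = TRUE))
        return(FALSE)
    key <- order(as.integer(seqnames(gr)), start(gr), end(gr))
    if (!identical(key, seq_along(gr)))
        return(FALSE)
    id <- paste(as.character(seqnames(gr)), start(gr), end(gr))
    !anyDuplicated(id) && (length(gr) == 0L || all(width(gr) >= 1L))
}

setValidity("RegionSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (!.isNormalizedGRanges(object@regions))
        msg <- c(msg, "'regions' must be sorted by (chrom, start, end), duplicate-free, all widths >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a RegionSet
#'
#' Normalizes the supplied regions (sort, deduplicate, drop strand and
#' metadata). Zero-length regions are an error, not silently dropped: they
#' cannot participate in base-pair overlap and would distort universe counts.
#'
#' @param name identifier string.
#' @param regions a \code{GRanges} (1-based closed coordinates), may be empty.
#' @return a \linkS4class{RegionSet}.
#' @examples
#' rs <- RegionSet("ex", GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)))
#' length(rs)
#' @export
RegionSet <- function(name, regions = GRanges()) {
    new("RegionSet", name = as.character(name),
        regions = .normalizeGRanges(regions, context = name))
}

#' @describeIn RegionSet number of regions in the set.
#' @param x a \code{RegionSet}.
#' @export
setMethod("length", "RegionSet", function(x) length(x@regions))

#' @rdname regions
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)

#' @rdname regionSetName
#' @export
setMethod("regionSetName", "RegionSet", function(x) x@name)

setMethod("show", "RegionSet", function(object) {
    gr <- object@regions
    cat("RegionSet '", object@name, "': ", length(gr), " regions on ",
        length(unique(seqnames(gr))), " chromosome(s)\n", sep = "")
    if (length(gr)) {
        n <- min(length(gr), 3L)
        for (i in seq_len(n))
            cat("  ", as.character(seqnames(gr))[i], ":",
                start(gr)[i] - 1L, "-", end(gr)[i], "\n", sep = "")
        if (length(gr) > n) cat("  ...\n")
    }
})

## ---- RegionDB ---------------------------------------------------------------

.DB_ANNO_COLS <- c("filename", "description", "cellType", "antibody",
                   "treatment", "collection")

#' RegionDB: a reference database of annotated region sets
#'
#' Collections of annotated \linkS4class{RegionSet} entries, loaded from a
#' directory tree of BED files by \code{\link{loadRegionDB}} or built in
#' memory by \code{\link{simulateScenario}}. Entry order is deterministic:
#' collections in lexicographic order, files in lexicographic order within a
#' collection. The annotation table has one row per entry, in entry order,
#' with at least the columns \code{filename}, \code{description},
#' \code{cellType}, \code{antibody}, \code{treatment}, \code{collection};
#' extra columns from a database's \code{index.txt} are carried through.
#'
#' @slot root source directory path ("" for in-memory databases).
#' @slot genomeLabel optional free-text genome tag.
#' @slot entries list of normalized \code{RegionSet} objects.
#' @slot anno annotation \code{data.frame}, one row per entry.
#'
#' @seealso \code{\link{loadRegionDB}}, \code{\link{runAnalysis}}
#' @export
setClass("RegionDB",
         slots = c(root = "character", genomeLabel = "character",
                   entries = "list", anno = "data.frame"))

setValidity("RegionDB", function(object) {
    msg <- character()
    if (!all(vapply(object@entries, is, logical(1), "RegionSet")))
        msg <- c(msg, "'entries' must all be RegionSet objects")
    if (nrow(object@anno) != length(object@entries))
        msg <- c(msg, "'anno' must have one row per entry")
    miss <- setdiff(.DB_ANNO_COLS, names(object@anno))
    if (length(miss))
        msg <- c(msg, paste0("'anno' lacks required column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

RegionDB <- function(root, entries, anno, genomeLabel = "") {
    rownames(anno) <- NULL
    new("RegionDB", root = as.character(root), genomeLabel = genomeLabel,
        entries = entries, anno = anno)
}

#' @describeIn RegionDB number of database entries.
#' @param x a \code{RegionDB}.
#' @export
setMethod("length", "RegionDB", function(x) length(x@entries))

#' @rdname dbEntries
#' @export
setMethod("dbEntries", "RegionDB", function(x) x@entries)

#' @rdname dbEntries
#' @export
setMethod("dbAnnotation", "RegionDB", function(x) x@anno)

setMethod("show", "RegionDB", function(object) {
    cat("RegionDB with ", length(object@entries), " entries in ",
        length(unique(object@anno$collection)), " collection(s)\n", sep = "")
    if (nzchar(object@root)) cat("  root: ", object@root, "\n", sep = "")
    if (nzchar(object@genomeLabel))
        cat("  genome: ", object@genomeLabel, "\n", sep = "")
    tab <- table(object@anno$collection)
    for (nm in names(tab))
        cat("  ", nm, ": ", tab[[nm]], " set(s)\n", sep = "")
})

## ---- ContingencyTable -------------------------------------------------------

#' ContingencyTable: the 2x2 counts behind one enrichment test
#'
#' Region-level counts partitioning the universe with respect to one query
#' and one database set:
#' \describe{
#'   \item{a}{query regions overlapping the database set (the "support")}
#'   \item{b}{non-query universe regions overlapping the database set}
#'   \item{c}{query regions not overlapping it}
#'   \item{d}{remaining universe regions}
#' }
#' so that \code{a + c} is the query size and \code{a + b + c + d} the
#' universe size.
#'
#' @slot a,b,c,d non-negative integer region counts.
#' @seealso \code{\link{buildContingency}}, \code{\link{fisherExactGreater}}
#' @export
setClass("ContingencyTable",
         slots = c(a = "integer", b = "integer", c = "integer", d = "integer"))

setValidity("ContingencyTable", function(object) {
    v <- c(object@a, object@b, object@c, object@d)
    if (length(v) != 4L || anyNA(v) || any(v < 0L))
        "cells a, b, c, d must each be a single non-negative integer"
    else TRUE
})

#' Construct a ContingencyTable
#'
#' @param a,b,c,d non-negative integer region counts (see
#'   \linkS4class{ContingencyTable} for the cell meanings).
#' @return a \code{ContingencyTable}.
#' @examples
#' ContingencyTable(8, 4, 2, 86)
#' @export
ContingencyTable <- function(a, b, c, d) {
    new("ContingencyTable", a = as.integer(a), b = as.integer(b),
        c = as.integer(c), d = as.integer(d))
}

#' @describeIn ContingencyTable the counts as a 2x2 matrix (rows: in/out of
#'   the database set's territory; columns: query / rest of universe).
#' @param x a \code{ContingencyTable}.
#' @param ... unused.
#' @export
setMethod("as.matrix", "ContingencyTable", function(x, ...) {
    matrix(c(x@a, x@c, x@b, x@d), nrow = 2,
           dimnames = list(c("inDbSet", "outDbSet"), c("query", "rest")))
})

setMethod("show", "ContingencyTable", function(object) {
    cat("ContingencyTable (a, b, c, d) = (", object@a, ", ", object@b, ", ",
        object@c, ", ", object@d, ")\n", sep = "")
})

## ---- SimulationConfig -------------------------------------------------------

#' SimulationConfig: parameters of a planted-enrichment scenario
#'
#' Describes a fully seeded synthetic scenario: a genome of named
#' chromosomes, a universe of equal-length disjoint regions placed uniformly,
#' a query sampled from the universe, a collection of null database sets
#' (independent uniform samples of universe regions) and, optionally, a
#' planted database set overlapping a controlled fraction of the query.
#'
#' Defaults encode the package's reference study conditions: a
#' 1000-region universe of 1-kb regions on two 5-Mb chromosomes, a 50-region
#' query, 99 null sets of 50 regions, and a planted set overlapping 80% of
#' the query plus 10 background regions.
#'
#' @slot chromSizes named numeric, chromosome lengths in bp.
#' @slot universeSize number of universe regions.
#' @slot regionLength universe region length in bp.
#' @slot querySize number of query regions (at most \code{universeSize}).
#' @slot nNullSets number of null database sets.
#' @slot nullSetSize regions per null set.
#' @slot plantedFraction fraction of query regions the planted set overlaps.
#' @slot plantedBackground extra planted regions overlapping non-query
#'   universe regions.
#' @slot seed integer seed driving all randomness.
#' @seealso \code{\link{simulateScenario}}
#' @export
setClass("SimulationConfig",
         slots = c(chromSizes = "numeric", universeSize = "numeric",
                   regionLength = "numeric", querySize = "numeric",
                   nNullSets = "numeric", nullSetSize = "numeric",
                   plantedFraction = "numeric", plantedBackground = "numeric",
                   seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (!length(object@chromSizes) || is.null(names(object@chromSizes)) ||
        any(!nzchar(names(object@chromSizes))) || any(object@chromSizes < 1))
        msg <- c(msg, "'chromSizes' must be a named vector of positive lengths")
    scalars <- c(universeSize = object@universeSize,
                 regionLength = object@regionLength,
                 querySize = object@querySize, nNullSets = object@nNullSets,
                 nullSetSize = object@nullSetSize,
                 plantedBackground = object@plantedBackground)
    if (anyNA(scalars) || any(scalars != round(scalars)) ||
        any(scalars[c("universeSize", "regionLength", "querySize",
                      "nullSetSize")] < 1) ||
        any(scalars[c("nNullSets", "plantedBackground")] < 0))
        msg <- c(msg, "size/count parameters must be whole numbers (universeSize, regionLength, querySize, nullSetSize >= 1)")
    if (object@querySize > object@universeSize)
        msg <- c(msg, "'querySize' must not exceed 'universeSize'")
    if (object@nullSetSize > object@universeSize)
        msg <- c(msg, "'nullSetSize' must not exceed 'universeSize'")
    if (object@plantedFraction < 0 || object@plantedFraction > 1)
        msg <- c(msg, "'plantedFraction' must be in [0, 1]")
    if (object@universeSize * object@regionLength > sum(object@chromSizes))
        msg <- c(msg, "universe does not fit the genome: universeSize * regionLength exceeds total chromosome length")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param universeSize,regionLength,querySize,nNullSets,nullSetSize,plantedFraction,plantedBackground,seed
#'   see \linkS4class{SimulationConfig}.
#' @return a validated \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 7)
#' cfg
#' @export
simulationConfig <- function(chromSizes = c(chr1 = 5e6, chr2 = 5e6),
                             universeSize = 1000, regionLength = 1000,
                             querySize = 50, nNullSets = 99,
                             nullSetSize = 50, plantedFraction = 0.8,
                             plantedBackground = 10, seed = 1) {
    new("SimulationConfig", chromSizes = chromSizes,
        universeSize = as.numeric(universeSize),
        regionLength = as.numeric(regionLength),
        querySize = as.numeric(querySize), nNullSets = as.numeric(nNullSets),
        nullSetSize = as.numeric(nullSetSize),
        plantedFraction = as.numeric(plantedFraction),
        plantedBackground = as.numeric(plantedBackground),
        seed = as.numeric(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: universe ", object@universeSize, " x ",
        object@regionLength, " bp on ", length(object@chromSizes),
        " chromosome(s); query ", object@querySize, "; ",
        object@nNullSets, " null set(s) of ", object@nullSetSize,
        "; plantedFraction ", object@plantedFraction,
        " (+", object@plantedBackground, " background); seed ",
        object@seed, "\n", sep = "")
})
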