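# BED3 I/O and core interval operations. BED coordinates are 0-based
# half-open on disk; internally everything is a GRanges (1-based closed),
# converted only at the file boundary.

.BED_SKIP_RE <- "^(track|browser|#)"

#' Read a BED file into a RegionSet
#'
#' Reads the first three columns (chrom, chromStart, chromEnd) of a BED file,
#' tolerating extra columns, tab or space separation, and \code{track},
#' \code{browser} or \code{#} header lines. Coordinates are interpreted as
#' BED 0-based half-open. The result is normalized: sorted by (chromosome,
#' start, end) with exact duplicate regions collapsed. Strand and all columns
#' beyond the third are ignored; overlap in this package is purely
#' coordinate-based.
#'
#' Malformed lines (fewer than 3 fields, non-integer coordinates, negative
#' start, or \code{end <= start}) raise an error naming the file and line
#' number. Zero-length intervals are rejected because they cannot satisfy the
#' shared-base-pair overlap rule and would silently distort universe counts.
#' A file that is empty after header skipping yields an empty RegionSet with
#' a warning.
#'
#' @param path path to a BED file.
#' @param name set identifier; defaults to the file name without extension.
#' @return a normalized \linkS4class{RegionSet}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr2\t5\t8", "chr1\t100\t200"), bed)
#' readBed(bed)
#' @seealso \code{\link{writeBed}}
#' @export
readBed <- function(path, name = NULL) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    if (is.null(name))
        name <- tools::file_path_sans_ext(basename(path))
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl(.BED_SKIP_RE, lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        warning("BED file '", path, "' contains no regions; returning an empty set")
        return(RegionSet(name, GRanges()))
    }
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L)) {
        i <- which(nf < 3L)[1L]
        stop("malformed BED line (fewer than 3 fields) in '", path,
             "', line ", lineNo[i])
    }
    chrom <- vapply(fields, `[[`, character(1), 1L)
    startTxt <- vapply(fields, `[[`, character(1), 2L)
    endTxt <- vapply(fields, `[[`, character(1), 3L)
    start0 <- suppressWarnings(as.numeric(startTxt))
    end0 <- suppressWarnings(as.numeric(endTxt))
    bad <- is.na(start0) | is.na(end0) |
        start0 != floor(start0) | end0 != floor(end0)
    if (any(bad)) {
        i <- which(bad)[1L]
        stop("non-integer coordinate '", startTxt[i], "'/'", endTxt[i],
             "' in '", path, "', line ", lineNo[i])
    }
    bad <- start0 < 0
    if (any(bad)) {
        i <- which(bad)[1L]
        stop("negative start coordinate in '", path, "', line ", lineNo[i])
    }
    bad <- end0 <= start0
    if (any(bad)) {
        i <- which(bad)[1L]
        stop("end <= start (zero-length or inverted region) in '", path,
             "', line ", lineNo[i])
    }
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
    RegionSet(name, gr)
}

#' Write a RegionSet as a 3-column BED file
#'
#' Writes one tab-separated \code{chrom\tstart\tend} line per region in
#' normalized order, converting back to BED 0-based half-open coordinates.
#' \code{readBed(writeBed(rs))} reproduces \code{rs} exactly.
#'
#' @param rs a \linkS4class{RegionSet}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeBed <- function(rs, path) {
    stopifnot(is(rs, "RegionSet"))
    gr <- regions(rs)
    lines <- if (length(gr)) {
        paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr), sep = "\t")
    } else character()
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Merge overlapping and bookended regions
#'
#' Coalesces every run of overlapping or bookended (end == next start)
#' regions on the same chromosome into its union, so that in the result any
#' two regions on one chromosome are separated by at least 1 bp of gap.
#' Total covered base pairs are preserved exactly.
#'
#' @param rs a \linkS4class{RegionSet}.
#' @return a \code{RegionSet} with the same name, disjoint and non-bookended.
#' @examples
#' rs <- RegionSet("x", GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 6), c(10, 15))))
#' regions(mergeRegions(rs))
#' @export
mergeRegions <- function(rs) {
    stopifnot(is(rs, "RegionSet"))
    RegionSet(regionSetName(rs), reduce(regions(rs)))
}

#' Count query regions overlapping a subject set
#'
#' Returns the number of query regions sharing at least \code{minOverlap}
#' base pairs with at least one subject region. Each query region counts at
#' most once no matter how many subject regions it hits; strand is ignored.
#' With the default \code{minOverlap = 1}, a single shared base pair
#' suffices. The count is the "support" cell of the enrichment contingency
#' table when the subject is a database set.
#'
#' Overlap detection uses the IRanges interval machinery (sorted interval
#' trees), so cost grows as O((n+m) log(n+m)) rather than all-pairs.
#'
#' @param query,subject \linkS4class{RegionSet} objects.
#' @param minOverlap minimum shared base pairs (integer >= 1).
#' @return a non-negative integer count of query regions.
#' @examples
#' q <- RegionSet("q", GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)))
#' s <- RegionSet("s", GenomicRanges::GRanges("chr1", IRanges::IRanges(9, 20)))
#' overlapSupport(q, s, minOverlap = 2)  # shares bases 9 and 10 -> 1
#' overlapSupport(q, s, minOverlap = 3)  # only 2 shared bases  -> 0
#' @export
overlapSupport <- function(query, subject, minOverlap = 1L) {
    stopifnot(is(query, "RegionSet"), is(subject, "RegionSet"))
    if (length(minOverlap) != 1L || is.na(minOverlap) || minOverlap < 1 ||
        minOverlap != round(minOverlap))
        stop("'minOverlap' must be a single integer >= 1")
    qgr <- regions(query)
    sgr <- regions(subject)
    # harmonize seqlevels so findOverlaps does not warn on disjoint genomes
    if (!identical(seqlevels(qgr), seqlevels(sgr))) {
        lv <- sort(union(seqlevels(qgr), seqlevels(sgr)))
        seqlevels(qgr) <- lv
        seqlevels(sgr) <- lv
    }
    hits <- countOverlaps(qgr, sgr, minoverlap = as.integer(minOverlap),
                          ignore.strand = TRUE)
    sum(hits > 0L)
}
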