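#' @import methods
#' @importFrom GenomicRanges GRanges granges countOverlaps reduce seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols runValue new2 queryHits subjectHits
#' @importFrom GenomicRanges findOverlaps
#' @importFrom GenomeInfoDb seqlevels seqlevels<-
#' @importFrom stats phyper p.adjust
#' @importFrom utils read.delim write.table
NULL

#' Region accessor
#'
#' Extract the genomic regions of an object as a \link[GenomicRanges]{GRanges}.
#'
#' @param x an object holding genomic regions.
#' @return a \code{GRanges}.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' Name accessor for region sets
#'
#' @param x a \linkS4class{RegionSet}.
#' @return a single character string.
#' @export
setGeneric("regionSetName", function(x) standardGeneric("regionSetName"))

#' Database entry accessors
#'
#' \code{dbEntries} returns the list of \linkS4class{RegionSet} entries of a
#' \linkS4class{RegionDB}; \code{dbAnnotation} returns its annotation table
#' (one row per entry, same order).
#'
#' @param x a \linkS4class{RegionDB}.
#' @return a list of \code{RegionSet} objects, or a \code{data.frame}.
#' @export
setGeneric("dbEntries", function(x) standardGeneric("dbEntries"))

#' @rdname dbEntries
#' @export
setGeneric("dbAnnotation", function(x) standardGeneric("dbAnnotation"))
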