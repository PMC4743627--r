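# Reference-database loading and caching.
#
# Layout on disk: root/<collection>/regions/*.bed, plus an optional
# root/<collection>/index.txt (TSV, header with at least "filename") and an
# optional free-text root/<collection>/collection.txt. The BED files are
# always the source of truth; the cache is a derived artifact keyed by file
# fingerprints and is silently rebuilt whenever it cannot be trusted.

# rbind data.frames with possibly different columns, filling with NA
.rbindFill <- function(dfs) {
    cols <- unique(unlist(lapply(dfs, names)))
    do.call(rbind, lapply(dfs, function(d) {
        for (cn in setdiff(cols, names(d))) d[[cn]] <- NA_character_
        d[cols]
    }))
}

# Scan the database tree: resolve collections, enumerate BED files in
# deterministic (lexicographic) order, and assemble the annotation table
# from index.txt where present. Returns the annotation data.frame plus a
# parallel vector of absolute BED paths.
.scanRegionDB <- function(root, collections = NULL) {
    if (!dir.exists(root))
        stop("database root not found: ", root)
    found <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    found <- found[dir.exists(file.path(root, found, "regions"))]
    if (is.null(collections)) {
        use <- found
    } else {
        missing <- setdiff(collections, found)
        if (length(missing))
            stop("collection(s) not found under ", root, ": ",
                 paste(missing, collapse = ", "))
        use <- sort(unique(collections))
    }
    if (!length(use))
        stop("no collections with a 'regions/' subdirectory under ", root)
    pieces <- lapply(use, function(coll) {
        rdir <- file.path(root, coll, "regions")
        beds <- sort(list.files(rdir, pattern = "\\.bed$"))
        if (!length(beds))
            stop("collection '", coll, "' has no BED files in ", rdir)
        anno <- data.frame(filename = beds,
                           description = tools::file_path_sans_ext(beds),
                           cellType = NA_character_,
                           antibody = NA_character_,
                           treatment = NA_character_,
                           collection = coll,
                           stringsAsFactors = FALSE)
        idxPath <- file.path(root, coll, "index.txt")
        if (file.exists(idxPath)) {
            idx <- utils::read.delim(idxPath, sep = "\t", header = TRUE,
                                     colClasses = "character",
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE)
            if (!"filename" %in% names(idx))
                stop("index.txt in collection '", coll,
                     "' lacks the required 'filename' column")
            orphan <- setdiff(idx$filename, beds)
            if (length(orphan))
                stop("index.txt in collection '", coll,
                     "' references nonexistent file(s): ",
                     paste(orphan, collapse = ", "))
            hit <- match(anno$filename, idx$filename)
            for (cn in setdiff(names(idx), "filename")) {
                vals <- ifelse(is.na(hit), NA_character_, idx[[cn]][hit])
                vals[!is.na(vals) & !nzchar(vals)] <- NA_character_
                if (cn %in% names(anno)) {
                    # blank/missing index values keep the default annotation
                    anno[[cn]] <- ifelse(is.na(vals), anno[[cn]], vals)
                } else {
                    anno[[cn]] <- vals
                }
            }
        }
        anno
    })
    anno <- .rbindFill(pieces)
    # required columns first, extra index.txt columns carried after
    anno <- anno[c(.DB_ANNO_COLS, setdiff(names(anno), .DB_ANNO_COLS))]
    rownames(anno) <- NULL
    list(anno = anno,
         paths = file.path(root, anno$collection, "regions", anno$filename),
         keys = file.path(anno$collection, anno$filename))
}

#' Load a reference database from a directory tree
#'
#' Reads every BED file of every requested collection under \code{root}
#' into a \linkS4class{RegionDB}. A collection is a subdirectory of
#' \code{root} containing a \code{regions/} folder of BED files and an
#' optional \code{index.txt} annotation table (TSV with a header naming at
#' least \code{filename}; recognized optional columns are
#' \code{description}, \code{cellType}, \code{antibody}, \code{treatment};
#' unknown columns are carried through untouched). Files absent from
#' \code{index.txt} receive a default annotation whose description is the
#' file stem. Entry order is deterministic: collections lexicographically,
#' then files lexicographically within each collection.
#'
#' @param root database root directory.
#' @param collections optional character vector restricting which
#'   collections to load; default loads all.
#' @param genomeLabel optional free-text genome tag stored on the result.
#' @return a \linkS4class{RegionDB}.
#' @seealso \code{\link{cacheRegionDB}}, \code{\link{loadCachedDB}},
#'   \code{\link{runAnalysis}}
#' @export
loadRegionDB <- function(root, collections = NULL, genomeLabel = "") {
    scan <- .scanRegionDB(root, collections)
    entries <- lapply(scan$paths, readBed)
    names(entries) <- scan$keys
    RegionDB(root = root, entries = entries, anno = scan$anno,
             genomeLabel = genomeLabel)
}

.dbFingerprints <- function(paths, keys) {
    data.frame(key = keys, size = file.size(paths),
               mtime = as.numeric(file.mtime(paths)),
               stringsAsFactors = FALSE)
}

#' Cache a parsed reference database
#'
#' Serializes a fully parsed \linkS4class{RegionDB} together with a
#' per-source-file fingerprint (size and modification time) so later loads
#' can skip re-parsing unchanged BED files. The cache is never
#' authoritative: \code{\link{loadCachedDB}} re-parses any file whose
#' fingerprint changed and falls back to a full re-parse when the cache is
#' unreadable, so cached and fresh loads are always identical.
#'
#' @param db a \code{RegionDB} loaded from disk (its \code{root} must point
#'   at the source tree).
#' @param cachePath file path for the cache.
#' @return invisibly, \code{cachePath}.
#' @export
cacheRegionDB <- function(db, cachePath) {
    stopifnot(is(db, "RegionDB"))
    if (!nzchar(db@root) || !dir.exists(db@root))
        stop("cannot cache a database whose source root does not exist")
    keys <- file.path(db@anno$collection, db@anno$filename)
    paths <- file.path(db@root, db@anno$collection, "regions",
                       db@anno$filename)
    payload <- list(format = 1L, genomeLabel = db@genomeLabel,
                    entries = stats::setNames(db@entries, keys),
                    fp = .dbFingerprints(paths, keys))
    dir.create(dirname(cachePath), showWarnings = FALSE, recursive = TRUE)
    saveRDS(payload, cachePath)
    invisible(cachePath)
}

#' Load a reference database through its cache
#'
#' Rescans the source tree (annotations in \code{index.txt} are always read
#' fresh) and serves each BED file's parsed regions from the cache when its
#' size and modification time are unchanged, re-parsing only modified or new
#' files. The result is identical, entry by entry and region by region, to
#' \code{\link{loadRegionDB}} on the same tree. A missing or corrupted cache
#' degrades to a full re-parse with a warning, never an error.
#'
#' @param cachePath cache file written by \code{\link{cacheRegionDB}}.
#' @param root database root directory (source of truth).
#' @param collections optional collection filter, as in
#'   \code{\link{loadRegionDB}}.
#' @param genomeLabel optional free-text genome tag.
#' @return a \linkS4class{RegionDB}.
#' @export
loadCachedDB <- function(cachePath, root, collections = NULL,
                         genomeLabel = "") {
    payload <- tryCatch(readRDS(cachePath), error = function(e) NULL,
                        warning = function(w) NULL)
    ok <- is.list(payload) && identical(payload$format, 1L) &&
        is.list(payload$entries) && is.data.frame(payload$fp)
    if (!ok) {
        warning("cache at '", cachePath,
                "' is missing or unreadable; re-parsing the database")
        return(loadRegionDB(root, collections, genomeLabel))
    }
    scan <- .scanRegionDB(root, collections)
    fresh <- .dbFingerprints(scan$paths, scan$keys)
    cachedIdx <- match(fresh$key, payload$fp$key)
    reuse <- !is.na(cachedIdx) &
        payload$fp$size[cachedIdx] == fresh$size &
        payload$fp$mtime[cachedIdx] == fresh$mtime
    entries <- vector("list", length(scan$keys))
    for (i in seq_along(entries)) {
        entries[[i]] <- if (reuse[i]) {
            payload$entries[[fresh$key[i]]]
        } else {
            readBed(scan$paths[i])
        }
    }
    names(entries) <- scan$keys
    RegionDB(root = root, entries = entries, anno = scan$anno,
             genomeLabel = genomeLabel)
}
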