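# Seeded generator of synthetic scenarios: a genome, a universe of
# equal-length disjoint regions, a query sampled from the universe, null
# database sets and an optional planted set with controlled enrichment.
#
# Universe regions are equal-length and pairwise disjoint (never bookended)
# by construction, and every database set samples whole universe regions.
# This makes the independence assumption of the exact test literally true
# in the harness — the null distribution of the support is exactly
# hypergeometric — so statistical calibration can be tested in isolation
# from the overlap engine.

# Evaluate expr with the RNG seeded, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    expr
}

# Uniformly place n disjoint, non-bookended regions of length w on 0..L.
# Bijection with n-subsets of {1, ..., F+n} where F = L - n*(w+1) + 1:
# starts are strictly increasing with pairwise gaps >= 1 bp.
.placeDisjoint <- function(n, w, L) {
    if (n == 0L)
        return(integer(0))
    F <- L - n * (w + 1) + 1
    if (F < 0)
        stop("cannot place ", n, " disjoint regions of ", w,
             " bp (plus 1 bp gaps) on a ", L, " bp chromosome")
    z <- sort(sample.int(F + n, n))
    z - seq_len(n) + (seq_len(n) - 1L) * (w + 1)
}

# Largest-remainder allocation of n regions across chromosomes,
# proportional to length and capped by per-chromosome capacity.
.allocateRegions <- function(n, chromSizes, w) {
    cap <- floor((chromSizes + 1) / (w + 1))
    if (sum(cap) < n)
        stop("genome capacity exceeded: can place at most ", sum(cap),
             " disjoint regions of ", w, " bp, need ", n)
    raw <- n * chromSizes / sum(chromSizes)
    alloc <- floor(raw)
    rem <- n - sum(alloc)
    if (rem > 0) {
        extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1
    }
    # move overflow beyond capacity to the chromosomes with most slack
    excess <- sum(pmax(alloc - cap, 0))
    alloc <- pmin(alloc, cap)
    while (excess > 0) {
        i <- which.max(cap - alloc)
        take <- min(cap[i] - alloc[i], excess)
        alloc[i] <- alloc[i] + take
        excess <- excess - take
    }
    as.integer(alloc)
}

#' Simulate a planted-enrichment scenario
#'
#' Generates, fully reproducibly from \code{cfg@seed}: a universe of
#' \code{universeSize} disjoint regions of \code{regionLength} bp placed
#' uniformly on the configured chromosomes (with at least 1 bp between
#' regions); a query of \code{querySize} universe regions sampled uniformly;
#' \code{nNullSets} null database sets, each an independent uniform sample
#' of \code{nullSetSize} universe regions; and — when
#' \code{plantedFraction > 0} or \code{plantedBackground > 0} — a planted
#' database set consisting of \code{ceiling(plantedFraction * querySize)}
#' distinct query regions plus \code{plantedBackground} non-query universe
#' regions, so its support against the query is known exactly by
#' construction.
#'
#' Null sets are arranged as collection \code{"null"} and the planted set as
#' collection \code{"planted"}. With \code{dir} given, the scenario is also
#' written to disk as \code{universe.bed}, \code{query.bed} and a database
#' tree under \code{dir/db} loadable by \code{\link{loadRegionDB}}; the
#' returned in-memory database is identical to loading that tree.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param dir optional output directory; created if needed.
#' @return a list with elements \code{universe} and \code{query}
#'   (\linkS4class{RegionSet}), \code{db} (\linkS4class{RegionDB}),
#'   \code{plantedSupport} (the constructed overlap count of the planted
#'   set, or NA when absent) and \code{config}.
#' @examples
#' sc <- simulateScenario(simulationConfig(universeSize = 100,
#'     querySize = 10, nNullSets = 5, seed = 42))
#' sc$db
#' @export
simulateScenario <- function(cfg, dir = NULL) {
    stopifnot(is(cfg, "SimulationConfig"))
    validObject(cfg)
    U <- as.integer(cfg@universeSize)
    Q <- as.integer(cfg@querySize)
    w <- as.integer(cfg@regionLength)
    nNull <- as.integer(cfg@nNullSets)
    nullSize <- as.integer(cfg@nullSetSize)
    k <- as.integer(ceiling(cfg@plantedFraction * Q))
    bg <- as.integer(cfg@plantedBackground)
    if (bg > U - Q)
        stop("plantedBackground (", bg, ") exceeds the ", U - Q,
             " non-query universe regions available")
    .withSeed(as.integer(cfg@seed) %% .Machine$integer.max, {
        alloc <- .allocateRegions(U, cfg@chromSizes, w)
        starts0 <- lapply(seq_along(alloc), function(i)
            .placeDisjoint(alloc[i], w, as.integer(cfg@chromSizes[i])))
        universe <- RegionSet("universe", GRanges(
            rep(names(cfg@chromSizes), lengths(starts0)),
            IRanges(unlist(starts0, use.names = FALSE) + 1, width = w)))
        ugr <- regions(universe)
        qIdx <- sort(sample.int(U, Q))
        query <- .RegionSetTrusted("query", ugr[qIdx])
        nullIdx <- lapply(seq_len(nNull),
                          function(i) sort(sample.int(U, nullSize)))
        planted <- NULL
        if (k > 0L || bg > 0L) {
            pIdx <- if (k > 0L) sort(sample(qIdx, k)) else integer(0)
            bgIdx <- if (bg > 0L)
                sort(sample(setdiff(seq_len(U), qIdx), bg)) else integer(0)
            planted <- sort(c(pIdx, bgIdx))
        }
        pad <- max(4L, nchar(as.character(nNull)))
        nullNames <- sprintf(paste0("nullSet%0", pad, "d"), seq_len(nNull))
        entries <- lapply(seq_len(nNull), function(i)
            .RegionSetTrusted(nullNames[i], ugr[nullIdx[[i]]]))
        anno <- data.frame(filename = paste0(nullNames, ".bed"),
                           description = paste("uniform null sample",
                                               seq_len(nNull)),
                           cellType = NA_character_,
                           antibody = NA_character_,
                           treatment = NA_character_,
                           collection = rep("null", nNull),
                           stringsAsFactors = FALSE)
        if (!is.null(planted)) {
            entries <- c(entries, .RegionSetTrusted("plantedSet", ugr[planted]))
            anno <- rbind(anno, data.frame(
                filename = "plantedSet.bed",
                description = sprintf(
                    "planted set overlapping %d query regions (+%d background)",
                    k, bg),
                cellType = NA_character_, antibody = NA_character_,
                treatment = NA_character_, collection = "planted",
                stringsAsFactors = FALSE))
        }
        root <- ""
        if (!is.null(dir)) {
            root <- file.path(dir, "db")
            writeScenarioDir(dir, universe, query, entries, anno)
        }
        names(entries) <- file.path(anno$collection, anno$filename)
        db <- RegionDB(root = root, entries = entries, anno = anno,
                       genomeLabel = "synthetic")
        list(universe = universe, query = query, db = db,
             plantedSupport = if (is.null(planted)) NA_integer_ else k,
             config = cfg)
    })
}

# Write a simulated scenario to disk in loadRegionDB() layout.
writeScenarioDir <- function(dir, universe, query, entries, anno) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeBed(universe, file.path(dir, "universe.bed"))
    writeBed(query, file.path(dir, "query.bed"))
    for (coll in unique(anno$collection)) {
        rdir <- file.path(dir, "db", coll, "regions")
        dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
        rows <- which(anno$collection == coll)
        for (i in rows)
            writeBed(entries[[i]], file.path(rdir, anno$filename[i]))
        idx <- anno[rows, c("filename", "description")]
        utils::write.table(idx, file.path(dir, "db", coll, "index.txt"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}

# Read a SimulationConfig from a YAML file whose keys mirror the
# simulationConfig() arguments.
.configFromYaml <- function(path, seed = NULL) {
    raw <- yaml::read_yaml(path)
    known <- c("chromSizes", "universeSize", "regionLength", "querySize",
               "nNullSets", "nullSetSize", "plantedFraction",
               "plantedBackground", "seed")
    unknown <- setdiff(names(raw), known)
    if (length(unknown))
        stop("unknown simulation config field(s): ",
             paste(unknown, collapse = ", "))
    if (!is.null(raw$chromSizes))
        raw$chromSizes <- unlist(raw$chromSizes)
    if (!is.null(seed))
        raw$seed <- seed
    do.call(simulationConfig, raw)
}
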