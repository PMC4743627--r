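# Contingency construction, the exact test, FDR, odds ratios, ranking and
# the assembled analysis.

# a universe of 100 disjoint 50-bp regions; query = first 10
toyUniverse <- function() {
    RegionSet("u", gr("chr1", seq(1, by = 100, length.out = 100),
                      seq(50, by = 100, length.out = 100)))
}

test_that("buildContingency partitions the universe at the region level", {
    uni <- toyUniverse()
    ugr <- regions(uni)
    q <- RegionSet("q", ugr[1:10])

    # db set hit by 8 query regions and 12 universe regions total
    s <- RegionSet("s", ugr[c(1:8, 11:14)])
    t <- buildContingency(q, uni, s)
    expect_equal(as.vector(as.matrix(t)), c(8L, 2L, 4L, 86L))  # a, c, b, d

    # query == universe forces b == 0 and d == 0
    t2 <- buildContingency(uni, uni, s)
    m2 <- as.matrix(t2)
    expect_equal(m2["inDbSet", "rest"], 0L)
    expect_equal(m2["outDbSet", "rest"], 0L)

    # db set overlapping nothing
    t3 <- buildContingency(q, uni, RegionSet("none", gr("chr9", 1, 10)))
    expect_equal(as.vector(as.matrix(t3)), c(0L, 10L, 0L, 90L))

    # universe smaller than query is a hard error pointing at the remedy
    expect_error(buildContingency(uni, q, s), "checkUniverseAppropriateness")

    # query outside the universe: b clamps to 0 with a warning
    qOut <- RegionSet("qo", gr("chr7", c(1, 101), c(50, 150)))
    sOut <- RegionSet("so", gr("chr7", 1, 150))
    expect_warning(tOut <- buildContingency(qOut, uni, sOut), "clamping")
    expect_equal(as.matrix(tOut)["inDbSet", "rest"], 0L)
})

test_that("fisherExactGreater reproduces closed-form and enumerated tail probabilities", {
    # single attainable point mass: all query draws in the db territory
    expect_equal(fisherExactGreater(ContingencyTable(5, 0, 0, 5)),
                 1 / choose(10, 5), tolerance = 1e-15)
    # observed support is the minimum achievable -> p exactly 1
    expect_equal(fisherExactGreater(ContingencyTable(0, 5, 5, 5)), 1)

    set.seed(52)
    for (i in 1:200) {
        cells <- as.integer(sample(0:15, 4, replace = TRUE))
        expect_equal(fisherExactGreater(do.call(ContingencyTable,
                                                as.list(cells))),
                     do.call(fisherTailOracle, as.list(cells)),
                     tolerance = 1e-12)
    }
})

test_that("increasing support (margins fixed) never increases the p-value", {
    # move one region from cell c into a, compensating in b and d
    for (a in 0:9) {
        p1 <- fisherExactGreater(ContingencyTable(a, 12 - a, 10 - a, 78 + a))
        p2 <- fisherExactGreater(ContingencyTable(a + 1, 11 - a, 9 - a, 79 + a))
        expect_lte(p2, p1)
    }
})

test_that("logOddsRatio is the smoothed sample estimator, finite on zero cells", {
    expect_identical(logOddsRatio(ContingencyTable(3, 3, 7, 7)), 0)
    expect_equal(logOddsRatio(ContingencyTable(8, 4, 2, 86)),
                 log((8.5 * 86.5) / (4.5 * 2.5)))
    lo <- logOddsRatio(ContingencyTable(0, 10, 10, 0))
    expect_true(is.finite(lo) && lo < 0)
})

test_that("adjustFDR implements Benjamini-Hochberg step-up", {
    expect_equal(adjustFDR(0.2), 0.2)
    expect_equal(adjustFDR(rep(0.03, 5)), rep(0.03, 5))
    expect_equal(adjustFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_identical(adjustFDR(numeric(0)), numeric(0))
    expect_error(adjustFDR(c(0.5, 0)), "\\(0, 1\\]")
    expect_error(adjustFDR(1.2), "\\(0, 1\\]")

    # pointwise >= input and order-preserving up to ties
    set.seed(6)
    p <- runif(50)
    q <- adjustFDR(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("rankResults assigns competition ranks and the worst-rank composite", {
    res <- data.frame(
        dbSet = c("s1", "s2", "s3"),
        pValue = c(0.001, 0.010, 0.100),     # ranks 1, 2, 3
        logOddsRatio = c(3, 5, 1),           # ranks 2, 1, 3
        support = c(10, 50, 30))             # ranks 3, 1, 2
    r <- rankResults(res)
    expect_equal(r$dbSet, c("s2", "s1", "s3"))  # maxRanks 2, 3, 3; p breaks tie
    expect_equal(r$maxRank, c(2L, 3L, 3L))
    expect_equal(r$maxRank, pmax(r$rankP, r$rankOR, r$rankSupport))

    # ties share the smallest applicable rank (1, 2, 2, 4)
    res2 <- data.frame(dbSet = letters[1:4],
                       pValue = c(0.01, 0.05, 0.05, 0.2),
                       logOddsRatio = c(4, 3, 3, 1),
                       support = c(9, 7, 7, 2))
    r2 <- rankResults(res2)
    expect_equal(sort(r2$rankP), c(1L, 2L, 2L, 4L))

    expect_equal(nrow(rankResults(res[0, ])), 0L)
    expect_error(rankResults(cbind(res, queryName = c("x", "y", "x"))),
                 "single query")
})

test_that("runAnalysis ties the pieces together deterministically", {
    uni <- toyUniverse()
    ugr <- regions(uni)
    q <- RegionSet("setA", ugr[1:10])
    entries <- list(RegionSet("self", ugr[1:10]),
                    RegionSet("partial", ugr[c(5:8, 30:45)]),
                    RegionSet("miss", gr("chr9", 1, 10)))
    anno <- data.frame(filename = c("self.bed", "partial.bed", "miss.bed"),
                       description = c("the query itself", "partial", "none"),
                       cellType = NA_character_, antibody = NA_character_,
                       treatment = NA_character_,
                       collection = "toy", stringsAsFactors = FALSE)
    db <- new("RegionDB", root = "", genomeLabel = "", entries = entries,
              anno = anno)

    res <- runAnalysis(q, uni, db)
    expect_equal(nrow(res), 3L)
    # a db entry equal to the query itself must top the table
    expect_equal(res$dbSet[1], "self")
    expect_equal(res$maxRank[1], 1L)
    expect_equal(res$support[1], 10L)
    # the empty-overlap entry is a row, not an error
    miss <- res[res$dbSet == "miss", ]
    expect_equal(c(miss$support, miss$b), c(0L, 0L))
    # conservation and FDR invariants on every row
    expect_true(all(res$support + res$b + res$c + res$d == length(uni)))
    expect_true(all(res$qValue >= res$pValue))
    expect_true(all(res$maxRank >= 1 & res$maxRank <= nrow(res)))

    # two identical queries give two identical blocks
    res2 <- runAnalysis(list(q, RegionSet("setA", ugr[1:10])), uni, db)
    blockA <- res2[1:3, ]
    blockB <- res2[4:6, ]
    rownames(blockA) <- rownames(blockB) <- NULL
    expect_identical(blockA, blockB)

    # repeated runs are identical
    expect_identical(res, runAnalysis(q, uni, db))
})

test_that("writeResults formats p-values reproducibly", {
    res <- data.frame(queryName = "q", collection = "c", dbSet = c("x", "y"),
                      description = "d", cellType = NA, antibody = NA,
                      treatment = NA, support = c(40L, 2L), b = c(1L, 9L),
                      c = c(10L, 48L), d = c(949L, 941L),
                      pValue = c(3.21e-47, 0.2345678),
                      qValue = c(6.42e-45, 0.2345678),
                      logOddsRatio = c(7.123456789, -0.04),
                      rankP = 1:2, rankOR = 1:2, rankSupport = 1:2,
                      maxRank = 1:2)
    path <- file.path(withr::local_tempdir(), "res.tsv")
    writeResults(res, path)
    lines <- readLines(path)
    expect_length(lines, 3L)
    expect_match(lines[2], "3\\.2100e-47")
    expect_match(lines[3], "0\\.234568")
    expect_match(lines[2], "7\\.12346")
    writeResults(res, paste0(path, "2"))
    expect_identical(readLines(paste0(path, "2")), lines)
})
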