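# The seeded scenario generator: reproducibility, geometry of the universe,
# planted-overlap guarantees, and the on-disk layout.

smallCfg <- function(...) {
    args <- utils::modifyList(
        list(chromSizes = c(chrA = 4e5, chrB = 6e5), universeSize = 200,
             regionLength = 500, querySize = 30, nNullSets = 8,
             nullSetSize = 30, plantedFraction = 0.8, plantedBackground = 5,
             seed = 3),
        list(...))
    do.call(simulationConfig, args)
}

test_that("the same seed reproduces the scenario exactly; other seeds differ", {
    s1 <- simulateScenario(smallCfg())
    s2 <- simulateScenario(smallCfg())
    expect_identical(regions(s1$universe), regions(s2$universe))
    expect_identical(regions(s1$query), regions(s2$query))
    expect_same_db(s1$db, s2$db)

    s3 <- simulateScenario(smallCfg(seed = 4))
    expect_false(identical(start(regions(s3$query)),
                           start(regions(s1$query))))
})

test_that("simulateScenario does not disturb the caller's RNG stream", {
    set.seed(1000)
    before <- runif(3)
    set.seed(1000)
    invisible(simulateScenario(smallCfg()))
    expect_identical(runif(3), before)
})

test_that("universe regions are equal-length, pairwise disjoint and never bookended", {
    sc <- simulateScenario(smallCfg())
    u <- sc$universe
    expect_equal(length(u), 200L)
    expect_true(all(width(regions(u)) == 500L))
    expect_equal(length(mergeRegions(u)), length(u))
    # regions stay within their chromosome
    expect_true(all(end(regions(u)) <= c(chrA = 4e5, chrB = 6e5)[
        as.character(seqnames(regions(u)))]))
})

test_that("the query is a region-for-region subset of the universe", {
    sc <- simulateScenario(smallCfg())
    expect_no_warning(rep <- checkUniverseAppropriateness(sc$query, sc$universe))
    expect_equal(rep$coverage, 1)
    expect_equal(overlapSupport(sc$query, sc$universe), length(sc$query))
})

test_that("planted support is exact by construction", {
    sc <- simulateScenario(smallCfg())  # ceil(0.8 * 30) = 24
    planted <- dbEntries(sc$db)[["planted/plantedSet.bed"]]
    expect_equal(overlapSupport(sc$query, planted), 24L)
    expect_equal(sc$plantedSupport, 24L)
    expect_equal(length(planted), 24L + 5L)

    # plantedFraction 1 with no background: contingency has b == 0, a == querySize
    scFull <- simulateScenario(smallCfg(plantedFraction = 1,
                                        plantedBackground = 0))
    t <- buildContingency(scFull$query, scFull$universe,
                          dbEntries(scFull$db)[["planted/plantedSet.bed"]])
    m <- as.matrix(t)
    expect_equal(m["inDbSet", "query"], 30L)
    expect_equal(m["inDbSet", "rest"], 0L)

    # no planted overlap and no background -> the planted collection is absent
    scNull <- simulateScenario(smallCfg(plantedFraction = 0,
                                        plantedBackground = 0))
    expect_equal(unique(dbAnnotation(scNull$db)$collection), "null")
    expect_equal(length(scNull$db), 8L)
})

test_that("the on-disk scenario is a valid database tree matching the in-memory one", {
    dir <- withr::local_tempdir()
    sc <- simulateScenario(smallCfg(), dir = dir)
    expect_true(file.exists(file.path(dir, "universe.bed")))
    expect_true(file.exists(file.path(dir, "query.bed")))
    expect_same_db(loadRegionDB(file.path(dir, "db")), sc$db)
    uBack <- readBed(file.path(dir, "universe.bed"))
    expect_identical(regions(uBack), regions(sc$universe))

    # writing twice with one seed produces identical files
    dir2 <- withr::local_tempdir()
    simulateScenario(smallCfg(), dir = dir2)
    expect_identical(readLines(file.path(dir, "query.bed")),
                     readLines(file.path(dir2, "query.bed")))
})

test_that("infeasible configurations are rejected with the violated capacity", {
    expect_error(simulationConfig(chromSizes = c(c1 = 1e4),
                                  universeSize = 100, regionLength = 500),
                 "does not fit")
    # fits by raw bp but not with 1-bp gaps between regions
    tight <- simulationConfig(chromSizes = c(c1 = 1e5),
                              universeSize = 200, regionLength = 500,
                              querySize = 10, nullSetSize = 10)
    expect_error(simulateScenario(tight), "capacity")
    expect_error(simulationConfig(querySize = 2000), "querySize")
    expect_error(smallCfg(plantedFraction = 2), "plantedFraction")
    expect_error(simulateScenario(smallCfg(plantedBackground = 180)),
                 "non-query universe regions")
})
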