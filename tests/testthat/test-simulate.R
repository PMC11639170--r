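test_that("the rate-scale work-around adjusts sampling and divergence times", {
    # s < 1: P2 sampled (1-s) * tSplit generations ago, all else unchanged
    dem <- buildDemography(scenarioConfig(tSplit = 1e7, s = 0.25))
    times <- vapply(dem$samples, `[[`, numeric(1), "time")
    pops <- vapply(dem$samples, `[[`, character(1), "population")
    expect_equal(times[pops == "P2"], 7.5e6)
    expect_equal(unname(times[pops != "P2"]), rep(0, 3))
    expect_equal(vapply(dem$splits, `[[`, numeric(1), "time"),
                 c(1e7, 2e7, 3e7))

    # s = 1: everything at the present
    dem1 <- buildDemography(scenarioConfig(tSplit = 1e7, s = 1))
    expect_equal(vapply(dem1$samples, `[[`, numeric(1), "time"), rep(0, 4))

    # s > 1: divergences and the migration window shift (s-1)*tSplit deeper,
    # P2 stays at the present, all other tips move to the shift time
    dem4 <- buildDemography(scenarioConfig(tSplit = 1e7, s = 4, m = 1e-7))
    expect_equal(vapply(dem4$splits, `[[`, numeric(1), "time"),
                 c(4e7, 5e7, 6e7))
    times4 <- vapply(dem4$samples, `[[`, numeric(1), "time")
    pops4 <- vapply(dem4$samples, `[[`, character(1), "population")
    expect_equal(unname(times4[pops4 == "P2"]), 0)
    expect_equal(unname(times4[pops4 != "P2"]), rep(3e7, 3))
    expect_equal(dem4$migration$end, 4e7)
    expect_equal(dem4$migration$start, 4e7 - 2.5e6)
})

test_that("the migration window opens at the split and lasts 2.5e6 generations", {
    dem <- buildDemography(scenarioConfig(tSplit = 2e7, m = 1e-8))
    expect_equal(dem$migration$end, 2e7)
    expect_equal(dem$migration$start, 2e7 - 2.5e6)
    expect_equal(dem$migration$rate, 1e-8)
    expect_equal(sort(dem$migration$between), c("P2", "P3"))
    # a window longer than the branch it sits on is rejected
    expect_error(scenarioConfig(tSplit = 2e6, migDuration = 2.5e6),
                 "migration window")
})

test_that("scenario configs round-trip through JSON and grids expand fully", {
    cfg <- scenarioConfig(tSplit = 3e7, Ne = 1e4, m = 1e-8, s = 0.5,
                          L = 12345, seed = 99L)
    f <- tempfile(fileext = ".json")
    writeScenarioConfig(cfg, f)
    back <- readScenarioConfig(f)
    for (sl in slotNames(cfg))
        expect_equal(slot(back, sl), slot(cfg, sl), label = sl)
    # the canonical study grid has 300 parameter combinations
    expect_length(scenarioGrid(), 300L)
    small <- scenarioGrid(tSplit = 1e7, Ne = 1e5, m = c(0, 1e-7),
                          mu = 2e-9, s = c(0.25, 1, 4), replicates = 3)
    expect_length(small, 18L)
    expect_equal(vapply(small, function(x) x@seed, integer(1)), 1:18)
})

test_that("interval and tract helpers follow the merge rules", {
    expect_equal(introgressedFraction(cbind(100, 200), L = 1000), 0.1)
    expect_equal(introgressedFraction(matrix(numeric(), ncol = 2), 1000), 0)
    # overlapping and adjacent intervals merge before measuring
    iv <- rbind(c(0, 50), c(40, 100), c(100, 120), c(500, 600))
    expect_equal(mergeIntervals(iv), rbind(c(0, 120), c(500, 600)))
    expect_equal(introgressedFraction(iv, 1200), 220 / 1200)

    runs <- data.frame(left = c(0, 10, 30, 70), right = c(10, 30, 70, 100),
                       topology = c("P1P2", "P1P2", "P2P3", "P1P2"))
    tr <- mergeTopologyTracts(runs)
    expect_equal(nrow(tr), 3L)
    expect_equal(tr$left, c(0, 30, 70))
    expect_equal(tr$right, c(30, 70, 100))
    expect_equal(tr$topology, c("P1P2", "P2P3", "P1P2"))
})

test_that("identical configs and seeds reproduce byte-identical VCFs", {
    cfg <- scenarioConfig(tSplit = 1e7, Ne = 1e4, mu = 2e-9, L = 5e4,
                          seed = 7L)
    s1 <- simulateDataset(cfg, dir = tempfile("det1"))
    s2 <- simulateDataset(cfg, dir = tempfile("det2"))
    expect_identical(unname(tools::md5sum(s1$vcf)),
                     unname(tools::md5sum(s2$vcf)))
    expect_equal(s1$truth@nVariable, s2$truth@nVariable)
    cfg@seed <- 8L
    s3 <- simulateDataset(cfg, dir = tempfile("det3"))
    expect_false(tools::md5sum(s3$vcf) == tools::md5sum(s1$vcf))
})

test_that("without migration no chromosome region is introgressed", {
    sim <- cachedSim("null_small", scenarioConfig(
        tSplit = 1e7, Ne = 1e4, mu = 2e-9, s = 1, m = 0, L = 2e5,
        seed = 301L))
    expect_equal(sim$truth@introgressedFraction, 0)
    # near-absent ILS: the chromosome is dominated by the species topology
    tr <- sim$truth@topoTracts
    expect_lte(nrow(tr), 5L)
    expect_equal(as.character(tr$topology[which.max(tr$right - tr$left)]),
                 "P1P2")
})

test_that("observed dxy matches the coalescent expectation within 5%", {
    sim <- cachedSim("null_small", scenarioConfig(
        tSplit = 1e7, Ne = 1e4, mu = 2e-9, s = 1, m = 0, L = 2e5,
        seed = 301L))
    cfg <- sim$config
    expected12 <- cfg@mu * (2 * cfg@tSplit + 4 * cfg@Ne)
    expect_equal(sim$truth@dxy["P1", "P2"], expected12, tolerance = 0.05)
    expected13 <- cfg@mu * (2 * (cfg@tSplit + cfg@gapP3) + 4 * cfg@Ne)
    # deeper pairs accumulate homoplasies, observed <= expected
    expect_lte(sim$truth@dxy["P1", "P3"], expected13)
    expect_gte(sim$truth@dxy["P1", "P3"], 0.85 * expected13)
})

test_that("the work-around scales P2 mutation input like a slow branch", {
    sim <- cachedSim("slow_small", scenarioConfig(
        tSplit = 1e7, Ne = 1e4, mu = 2e-9, s = 0.25, m = 0, L = 2e5,
        seed = 302L))
    cfg <- sim$config
    expected <- cfg@mu * ((1 + cfg@s) * cfg@tSplit + 4 * cfg@Ne)
    expect_equal(sim$truth@dxy["P1", "P2"], expected, tolerance = 0.06)
})

test_that("the direct branch-rate mode agrees with the work-around", {
    cfg <- scenarioConfig(tSplit = 1e7, Ne = 1e4, mu = 2e-9, s = 0.5,
                          m = 0, L = 1e5, seed = 303L)
    wa <- cachedSim("wa_s05", cfg)
    br <- simulateDataset(cfg, dir = tempfile("br"),
                          rateScaling = "branch_rate")
    expected <- cfg@mu * (1.5 * cfg@tSplit + 4 * cfg@Ne)
    expect_equal(wa$truth@dxy["P1", "P2"], expected, tolerance = 0.07)
    expect_equal(br$truth@dxy["P1", "P2"], expected, tolerance = 0.07)
})

test_that("migrant-ancestry fraction grows with the migration rate", {
    fracs <- vapply(c(0, 1e-8, 1e-7), function(m) {
        tag <- paste0("mig_", m)
        sim <- cachedSim(tag, scenarioConfig(
            tSplit = 1e7, Ne = 1e4, mu = 2e-9, s = 1, m = m, L = 1e5,
            seed = 304L))
        sim$truth@introgressedFraction
    }, numeric(1))
    expect_true(all(diff(fracs) >= 0))
    expect_equal(fracs[[1]], 0)
    expect_gt(fracs[[3]], fracs[[1]])
})

test_that("true local time trees feed the dMRCA statistic near zero", {
    sim <- cachedSim("null_trees", scenarioConfig(
        tSplit = 1e7, Ne = 1e4, mu = 2e-9, s = 1, m = 0, L = 1e5,
        seed = 305L), localTrees = 200L)
    ts <- readTreeSet(ape::read.tree(text = sim$localTrees))
    r <- mms17dMRCA(ts)
    # both deep pairs date the same node: trio root, ~ tSplit + gap + 2Ne
    expect_setequal(r@oldestPairs, c("P1P3", "P2P3"))
    rootAge <- 1e7 + 1e7
    expect_lt(r@dMRCA, 0.05 * rootAge)
    expect_gt(min(r@meanAges), 1e7)
})

test_that("window alignments reduce data exactly as specified", {
    # spacing: window starts are L/n apart
    f <- quartetVCF(tempfile(fileext = ".vcf"),
                    pos = c(150, 420, 1150),
                    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                    gts = list(c("0/1", "1/1", "0/0", "0/0"),
                               c("1/1", "0/0", "1/1", "0/0"),
                               c("0/0", "0/1", "1/1", "0/0")))
    al <- extractWindowAlignments(f, quartetMap, L = 2000, n = 4,
                                  width = 200, seed = 5)
    expect_length(al, 4L)
    expect_equal(unique(vapply(al, function(a) unique(Biostrings::width(a)),
                               numeric(1))), 200)
    # window 1 covers 1-200: site 150 is variable; P1 is het 0/1 but only
    # the first allele (REF = A) is taken
    w1 <- as.matrix(al[[1]])
    expect_equal(unname(w1[, 150]), c("A", "G", "A", "A"))
    # all other columns are invariant: a single random base shared by all
    inv <- w1[, -150, drop = FALSE]
    expect_true(all(apply(inv, 2, function(col) length(unique(col)) == 1L)))
    # window 2 covers 501-700: no variable sites at all
    w2 <- as.matrix(al[[2]])
    expect_true(all(apply(w2, 2, function(col) length(unique(col)) == 1L)))
    # windows beyond the chromosome end are refused
    expect_error(extractWindowAlignments(f, quartetMap, L = 2000, n = 4,
                                         width = 600, seed = 5),
                 "exceeds the chromosome")
    # determinism of the random fill
    al2 <- extractWindowAlignments(f, quartetMap, L = 2000, n = 4,
                                   width = 200, seed = 5)
    expect_equal(as.character(al2[[3]]), as.character(al[[3]]))
})
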