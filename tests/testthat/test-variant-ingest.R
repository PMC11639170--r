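test_that("per-species derived-allele frequencies are computed from genotypes", {
    f <- quartetVCF(tempfile(fileext = ".vcf"),
                    pos = 100, ref = "A", alt = "G",
                    gts = list(c("0/0", "1/1", "1/1", "0/0")))
    st <- readSiteTable(f, quartetMap)
    expect_equal(nSites(st), 1L)
    expect_equal(unname(derivedFreq(st)[1, ]), c(0, 1, 1, 0))
})

test_that("a 50/50 outgroup is resolved to the globally rarer allele and logged", {
    f <- quartetVCF(tempfile(fileext = ".vcf"),
                    pos = 100, ref = "A", alt = "G",
                    gts = list(c("0/0", "0/0", "1/1", "0/1")))
    expect_message(st <- readSiteTable(f, quartetMap), "50/50 outgroup")
    # ALT is globally rarer (3 vs 5 calls) -> derived is ALT
    expect_equal(unname(derivedFreq(st)[1, ]), c(0, 0, 1, 0.5))
    expect_equal(unname(metadata(st)$counts["outgroup_tie"]), 1)
    # with tieRule = "drop" the site is removed instead
    stDrop <- suppressMessages(readSiteTable(f, quartetMap, tieRule = "drop"))
    expect_equal(nSites(stDrop), 0L)
})

test_that("multi-allelic sites are ignored", {
    f <- quartetVCF(tempfile(fileext = ".vcf"),
                    pos = seq(100, 1000, by = 100), ref = rep("A", 10),
                    alt = rep("C,G", 10),
                    gts = rep(list(c("0/0", "1/1", "2/2", "0/0")), 10))
    st <- readSiteTable(f, quartetMap)
    expect_equal(nSites(st), 0L)
    expect_equal(unname(metadata(st)$counts["multi_allelic"]), 10)
})

test_that("sites multi-allelic in the VCF but bi-allelic among mapped samples are kept", {
    f <- quartetVCF(tempfile(fileext = ".vcf"),
                    pos = 100, ref = "A", alt = "C,G",
                    gts = list(c("0/0", "2/2", "2/2", "0/0")))
    st <- readSiteTable(f, quartetMap)
    expect_equal(nSites(st), 1L)
    expect_equal(unname(derivedFreq(st)[1, ]), c(0, 1, 1, 0))
})

test_that("polarization is invariant to REF/ALT relabelling", {
    pos <- c(100, 200, 300)
    gtsA <- list(c("0/0", "0/1", "1/1", "0/0"),
                 c("0/1", "1/1", "0/0", "0/0"),
                 c("1/1", "0/0", "0/1", "1/1"))
    # same data with REF and ALT swapped (0 <-> 1)
    flip <- function(g) chartr("01", "10", g)
    f1 <- quartetVCF(tempfile(fileext = ".vcf"), pos,
                     ref = c("A", "C", "T"), alt = c("G", "T", "A"),
                     gts = gtsA)
    f2 <- quartetVCF(tempfile(fileext = ".vcf"), pos,
                     ref = c("G", "T", "A"), alt = c("A", "C", "T"),
                     gts = lapply(gtsA, flip))
    st1 <- readSiteTable(f1, quartetMap)
    st2 <- readSiteTable(f2, quartetMap)
    expect_equal(derivedFreq(st1), derivedFreq(st2))
})

test_that("dropped-site categories account for every input record", {
    f <- writeTestVCF(tempfile(fileext = ".vcf"),
        samples = c("s1", "s2", "s3", "s4"),
        pos = c(100, 200, 300, 400, 500, 600),
        ref = c("A", "A", "AT", "A", "A", "A"),
        alt = c("G", "C,G", "T", "G", "G", "G"),
        gts = list(c("0/0", "1/1", "1/1", "0/0"),   # kept
                   c("0/0", "1/1", "2/2", "0/0"),   # multi-allelic
                   c("0/0", "1/1", "1/1", "0/0"),   # indel
                   c("0/0", "0/0", "0/0", "0/0"),   # monomorphic
                   c("./.", "1/1", "1/1", "0/0"),   # species without calls
                   c("0/1", "1/1", "0/0", "0/0")))  # kept
    st <- readSiteTable(f, quartetMap)
    cnt <- metadata(st)$counts
    expect_equal(unname(cnt["input"]), 6)
    expect_equal(unname(cnt["retained"]), nSites(st))
    expect_equal(unname(cnt["retained"] + cnt["not_snp"] +
                        cnt["multi_allelic"] + cnt["missing_species"] +
                        cnt["monomorphic"] + cnt["duplicate_pos"]),
                 unname(cnt["input"]))
})

test_that("subsetting samples changes frequencies but not site ordering", {
    f <- writeTestVCF(tempfile(fileext = ".vcf"),
        samples = c("a1", "a2", "b1", "c1", "o1"),
        pos = c(100, 250, 900),
        ref = c("A", "A", "A"), alt = c("G", "G", "G"),
        gts = list(c("0/1", "0/0", "1/1", "1/1", "0/0"),
                   c("1/1", "0/1", "0/0", "1/1", "0/0"),
                   c("0/0", "0/1", "1/1", "0/1", "0/0")))
    mapFull <- speciesMap(c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", o1 = "O"),
                          trio = c("A", "B", "C"), outgroup = "O")
    mapSub <- speciesMap(c(a1 = "A", b1 = "B", c1 = "C", o1 = "O"),
                         trio = c("A", "B", "C"), outgroup = "O")
    stF <- readSiteTable(f, mapFull)
    stS <- readSiteTable(f, mapSub)
    expect_equal(GenomicRanges::start(rowRanges(stF)),
                 GenomicRanges::start(rowRanges(stS)))
    expect_equal(unname(derivedFreq(stF)[, "P1"]), c(0.25, 0.75, 0.25))
    expect_equal(unname(derivedFreq(stS)[, "P1"]), c(0.5, 1, 0))
})

test_that("unknown samples in the map raise a configuration error", {
    f <- quartetVCF(tempfile(fileext = ".vcf"),
                    pos = 100, ref = "A", alt = "G",
                    gts = list(c("0/0", "1/1", "1/1", "0/0")))
    badMap <- speciesMap(c(s1 = "A", s2 = "B", s3 = "C", ghost = "O"),
                         trio = c("A", "B", "C"), outgroup = "O")
    expect_error(readSiteTable(f, badMap), "absent from VCF")
})

test_that("SETS files identify the outgroup and trio ordering", {
    sets <- tempfile(fileext = ".tsv")
    writeLines(c("s1\tA", "s2\tB", "s3\tC", "s4\tOutgroup"), sets)
    map <- readSpeciesMap(sets)
    expect_equal(map@trio, c("A", "B", "C"))
    expect_equal(map@outgroup, "Outgroup")
    map2 <- readSpeciesMap(sets, trio = c("C", "A", "B"))
    expect_equal(map2@trio, c("C", "A", "B"))
    writeLines(c("s1\tA", "s2\tB", "s3\tC", "s4\tD"), sets)
    expect_error(readSpeciesMap(sets), "no outgroup")
    expect_equal(readSpeciesMap(sets, outgroup = "D")@outgroup, "D")
})

test_that("rotateTrio swaps the P1/P2 columns and the metadata flag", {
    st <- siteTable("chr1", c(10L, 20L),
                    rbind(c(0.1, 0.9, 0.5, 0), c(0.2, 0.4, 1, 0)),
                    map = quartetMap)
    rt <- rotateTrio(st)
    expect_equal(unname(derivedFreq(rt)[, "P1"]), c(0.9, 0.4))
    expect_equal(unname(derivedFreq(rt)[, "P2"]), c(0.1, 0.2))
    expect_true(metadata(rt)$rotated)
    expect_equal(metadata(rt)$speciesMap@trio, c("B", "A", "C"))
    expect_false(metadata(rotateTrio(rt))$rotated)
})

test_that("per-chromosome tables combine into one joint dataset", {
    a <- siteTable("chr1", c(10L, 20L), rbind(c(0, 1, 1, 0), c(1, 0, 1, 0)),
                   counts = c(input = 3, retained = 2))
    b <- siteTable("chr2", 15L, rbind(c(0, 1, 0.5, 0)),
                   counts = c(input = 2, retained = 1))
    ab <- bindSiteTables(a, b)
    expect_equal(nSites(ab), 3L)
    expect_equal(as.character(GenomicRanges::seqnames(rowRanges(ab))),
                 c("chr1", "chr1", "chr2"))
    expect_equal(unname(metadata(ab)$counts["input"]), 5)
    expect_equal(unname(countPatterns(ab)["CABBA"]), 1.5)
    expect_identical(bindSiteTables(a), a)
})

test_that("SiteTable validity rejects malformed tables", {
    expect_error(siteTable("chr1", c(10L, 10L),
                           rbind(c(0, 1, 1, 0), c(0, 1, 1, 0))) |>
                     validObject(), "strictly increasing")
    expect_error(siteTable("chr1", 10L, rbind(c(0, 1, 2, 0))) |>
                     validObject(), "frequencies")
})
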