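#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
NULL

# Smallest p-value reported by any test in the package; values below are
# floored so that p-values remain comparable across very long chromosomes.
P_FLOOR <- 2.3e-16

#' Sample-to-species assignment for a quartet analysis
#'
#' Maps VCF sample identifiers to species names and fixes the analysis roles:
#' an ordered ingroup trio (P1, P2, P3), where P1 and P2 are putative sister
#' species, and an outgroup P4 used to polarize alleles.
#'
#' @slot samples named character vector; names are VCF sample ids, values are
#'   species names.
#' @slot trio character vector of length 3 giving the species placed in roles
#'   P1, P2 and P3 (in this order).
#' @slot outgroup single species name used as outgroup P4.
#'
#' @seealso [speciesMap()], [readSpeciesMap()]
#' @export
setClass("SpeciesMap", representation(
    samples  = "character",
    trio     = "character",
    outgroup = "character"
))

setValidity("SpeciesMap", function(object) {
    sp <- c(object@trio, object@outgroup)
    if (length(object@trio) != 3L || length(object@outgroup) != 1L)
        return("trio must have length 3 and outgroup length 1")
    if (anyDuplicated(sp))
        return("trio and outgroup species names must be distinct")
    if (is.null(names(object@samples)) || any(names(object@samples) == ""))
        return("'samples' must be a named character vector (sample -> species)")
    missing <- setdiff(sp, object@samples)
    if (length(missing))
        return(paste0("no samples assigned to species: ",
                      paste(missing, collapse = ", ")))
    TRUE
})

#' Per-site derived-allele frequencies for a species quartet
#'
#' A \linkS4class{RangedSummarizedExperiment} holding, for every retained
#' bi-allelic polymorphic site, the frequency of the derived allele in each of
#' the four species. Rows are sites (with chromosome and 1-based position in
#' `rowRanges`), columns are the four analysis roles P1, P2, P3 and P4. The
#' derived allele at each site is the allele at lower frequency among the
#' outgroup's called alleles.
#'
#' The single assay is named `"derivedFreq"`. `metadata()` carries the
#' [SpeciesMap-class], per-category dropped-site counts (`counts`), and a
#' `rotated` flag set when P1 and P2 have been swapped to make D non-negative.
#'
#' @seealso [readSiteTable()], [siteTable()]
#' @export
setClass("SiteTable", contains = "RangedSummarizedExperiment")

setValidity("SiteTable", function(object) {
    if (!"derivedFreq" %in% SummarizedExperiment::assayNames(object))
        return("assay 'derivedFreq' is required")
    f <- SummarizedExperiment::assay(object, "derivedFreq")
    if (ncol(f) != 4L || !identical(colnames(f), c("P1", "P2", "P3", "P4")))
        return("derivedFreq must have columns P1, P2, P3, P4")
    if (nrow(f) && (min(f) < 0 || max(f) > 1))
        return("derived-allele frequencies must lie in [0, 1]")
    pos <- GenomicRanges::start(rowRanges(object))
    chr <- as.character(seqnames(rowRanges(object)))
    if (nrow(f) > 1L) {
        same <- chr[-1L] == chr[-length(chr)]
        if (any(same & diff(pos) <= 0))
            return("positions must be strictly increasing within a chromosome")
    }
    TRUE
})

#' Patterson's D-statistic result
#'
#' @slot CABBA frequency-weighted ABBA sum.
#' @slot CBABA frequency-weighted BABA sum.
#' @slot D the D-statistic, `(CABBA - CBABA) / (CABBA + CBABA)`.
#' @slot Z block-jackknife Z-score (`NA` until [jackknifeD()] is run).
#' @slot p two-sided normal p-value, floored at 2.3e-16.
#' @slot rotated `TRUE` if P1 and P2 were swapped so that D >= 0.
#' @slot nBlocks number of jackknife blocks.
#' @slot blockD delete-one-block D values.
#' @slot nSites number of sites that entered the sums.
#' @slot status `"ok"`, `"undefined"` (CABBA + CBABA = 0) or
#'   `"degenerate_variance"` (zero jackknife variance).
#' @export
setClass("DStatResult", representation(
    CABBA = "numeric", CBABA = "numeric", D = "numeric",
    Z = "numeric", p = "numeric", rotated = "logical",
    nBlocks = "integer", blockD = "numeric", nSites = "integer",
    status = "character"
))

#' Strong ABBA / BABA site classification
#'
#' Per-site labels from the frequency-product rule: a site is a strong ABBA
#' site when most sampled alleles jointly support the ABBA pattern (in either
#' polarization), analogously for strong BABA sites; all other sites are
#' labelled `"other"`.
#'
#' @slot chrom chromosome of each site.
#' @slot pos 1-based position of each site.
#' @slot label factor with levels `strong_ABBA`, `strong_BABA`, `other`.
#' @slot threshold score threshold used (default 0.5).
#' @export
setClass("StrongSiteClassification", representation(
    chrom = "character", pos = "integer", label = "factor",
    threshold = "numeric"
))

#' Input vectors for the ABBA-site clustering test
#'
#' @slot version `"sensitive"` (background: all polymorphic sites) or
#'   `"robust"` (background: strong ABBA and strong BABA sites only).
#' @slot idx 0-based ordinals of strong ABBA sites within the concatenated
#'   background vector.
#' @slot idxNorm `idx` divided by the background length, in `[0, 1]`.
#' @slot nBackground total background length over all chromosomes.
#' @slot nStrongABBA,nStrongBABA strong-site counts.
#' @export
setClass("ClusteringInput", representation(
    version = "character", idx = "integer", idxNorm = "numeric",
    nBackground = "integer", nStrongABBA = "integer", nStrongBABA = "integer"
))

#' ABBA-site clustering test result
#'
#' @slot version `"sensitive"` or `"robust"`.
#' @slot statistic one-sample Kolmogorov-Smirnov statistic.
#' @slot p p-value against Uniform(0,1), floored at 2.3e-16; `NA` when
#'   `status != "ok"`.
#' @slot nStrongABBA,nStrongBABA,nBackground site counts.
#' @slot status `"ok"` or `"insufficient_sites"`.
#' @export
setClass("ClusterTestResult", representation(
    version = "character", statistic = "numeric", p = "numeric",
    nStrongABBA = "integer", nStrongBABA = "integer", nBackground = "integer",
    status = "character"
))

#' A set of rooted four-taxon trees
#'
#' @slot trees a `multiPhylo` of rooted trees whose tips are relabelled to the
#'   roles P1..P4.
#' @slot internalBranch length (substitutions/site) of the single internal
#'   branch of the ingroup trio after pruning P4.
#' @slot topology factor giving the trio topology of each tree
#'   (`P1P2`, `P1P3`, `P2P3`).
#' @slot filtered `TRUE` for trees whose internal branch is shorter than the
#'   filter threshold (excluded from Dtree counts).
#' @slot threshold the filter threshold used.
#' @slot nSkipped number of input trees dropped (unparseable/missing taxa).
#' @export
setClass("TreeSet", representation(
    trees = "ANY", internalBranch = "numeric", topology = "factor",
    filtered = "logical", threshold = "numeric", nSkipped = "integer"
))

#' Constrained Dtree result
#'
#' @slot counts named integer vector of trio-topology counts
#'   (`P1P2`, `P1P3`, `P2P3`) among unfiltered trees.
#' @slot dtree `(C_P2P3 - C_P1P3) / (C_P2P3 + C_P1P3)`; `NA` when the
#'   denominator is zero.
#' @slot p one-sided exact binomial tail `P(X >= C_P2P3)` with
#'   `n = C_P2P3 + C_P1P3`, success probability 1/2.
#' @slot nUsed,nFiltered tree counts.
#' @export
setClass("DtreeResult", representation(
    counts = "integer", dtree = "numeric", p = "numeric",
    nUsed = "integer", nFiltered = "integer"
))

#' dMRCA (MMS17) result
#'
#' @slot meanAges named numeric vector of mean pairwise MRCA ages for
#'   P1-P2, P1-P3 and P2-P3 over all trees (time units of the input trees).
#' @slot dMRCA absolute difference between the two largest mean ages.
#' @slot oldestPairs names of the two pairs with the largest mean ages; when
#'   these are not P1-P3 and P2-P3 the statistic is not interpretable as
#'   introgression evidence.
#' @slot nTrees number of trees used.
#' @export
setClass("MMS17Result", representation(
    meanAges = "numeric", dMRCA = "numeric", oldestPairs = "character",
    nTrees = "integer"
))

#' Simulation scenario
#'
#' Parameters of the four-taxon coalescent scenario: an asymmetric species
#' tree (P1,P2) sister, P3 and P4 branching 1e7 and 2e7 generations earlier,
#' constant diploid population size, HKY mutations, uniform recombination, a
#' symmetric P2-P3 migration window starting at the P1/P2 divergence and
#' lasting 2.5e6 generations toward the present, and a P2 branch-rate scale
#' factor s realized through shifted sampling/divergence times.
#'
#' @slot tSplit P1/P2 divergence time in generations before present.
#' @slot gapP3,gapP4 extra generations until the P3 and P4 splits (defaults
#'   1e7 and 2e7).
#' @slot Ne diploid effective population size (all species, constant).
#' @slot m symmetric P2-P3 migration rate per individual per generation.
#' @slot migDuration length of the migration window in generations.
#' @slot r per-site per-generation recombination rate.
#' @slot mu per-site per-generation mutation rate.
#' @slot kappa HKY transition/transversion rate ratio.
#' @slot s P2 branch rate scale factor (> 0).
#' @slot L chromosome length in bp.
#' @slot nDip diploid individuals sampled per species.
#' @slot seed random seed (integer).
#' @export
setClass("ScenarioConfig", representation(
    tSplit = "numeric", gapP3 = "numeric", gapP4 = "numeric",
    Ne = "numeric", m = "numeric", migDuration = "numeric",
    r = "numeric", mu = "numeric", kappa = "numeric", s = "numeric",
    L = "numeric", nDip = "integer", seed = "integer"
))

setValidity("ScenarioConfig", function(object) {
    if (object@s <= 0) return("s must be > 0")
    if (object@migDuration > object@tSplit)
        return("migration window must fit between the P1/P2 divergence and the present")
    if (any(c(object@m, object@r, object@mu, object@Ne, object@L) < 0))
        return("rates, Ne and L must be non-negative")
    TRUE
})

#' Ground-truth summaries of a simulated dataset
#'
#' @slot nVariable number of sites variable among the sampled haplotypes.
#' @slot nMultiallelic number of sites with more than two sampled alleles.
#' @slot dxy matrix of mean pairwise per-site differences between species.
#' @slot introgressedFraction fraction of the chromosome where at least one
#'   sampled lineage's ancestry crossed between P2 and P3 by migration.
#' @slot migrantIntervals two-column matrix of merged migrant-ancestry
#'   intervals (0-based, half-open).
#' @slot topoTracts data.frame of single-topology tracts (`left`, `right`,
#'   `topology`) from one haploid genome per species, adjacent equal
#'   topologies merged.
#' @slot cGeneMean mean length (bp) of recombination-unbroken segments,
#'   `L / number of distinct local trees`.
#' @slot L chromosome length.
#' @export
setClass("SimTruth", representation(
    nVariable = "numeric", nMultiallelic = "numeric", dxy = "matrix",
    introgressedFraction = "numeric", migrantIntervals = "matrix",
    topoTracts = "data.frame", cGeneMean = "numeric", L = "numeric"
))
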