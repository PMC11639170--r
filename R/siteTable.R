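#' Build a SiteTable from raw vectors
#'
#' Low-level constructor, mainly useful for tests and for programmatic
#' construction of small tables. Most users will call [readSiteTable()].
#'
#' @param chrom character vector of chromosome ids.
#' @param pos integer vector of 1-based positions.
#' @param freq numeric matrix with one row per site and columns P1..P4 of
#'   derived-allele frequencies (column names are set automatically).
#' @param map optional [SpeciesMap-class] stored in the metadata.
#' @param counts optional named numeric vector of dropped-site counts.
#' @return a [SiteTable-class].
#' @export
siteTable <- function(chrom, pos, freq, map = NULL, counts = numeric()) {
    freq <- as.matrix(freq)
    colnames(freq) <- c("P1", "P2", "P3", "P4")
    rr <- GRanges(chrom, IRanges(start = as.integer(pos), width = 1L))
    se <- SummarizedExperiment(
        assays = list(derivedFreq = freq),
        rowRanges = rr,
        colData = DataFrame(role = c("P1", "P2", "P3", "P4"),
                            row.names = c("P1", "P2", "P3", "P4")))
    out <- new("SiteTable", se)
    metadata(out)$speciesMap <- map
    metadata(out)$counts <- counts
    metadata(out)$rotated <- FALSE
    out
}

#' Read a VCF into a per-site derived-allele frequency table
#'
#' For each SNP record, allele frequencies are computed per species over the
#' non-missing allele calls of the mapped samples. The derived allele "B" is
#' the allele with the lower frequency among the outgroup's called alleles.
#' Sites are dropped when (i) they are not SNPs, (ii) more than two alleles
#' are observed across the four species, (iii) any of the four species has no
#' called allele, or (iv) only one allele is observed (monomorphic). Dropped
#' counts are recorded in `metadata(x)$counts`.
#'
#' When the outgroup is exactly 50/50 polymorphic, the derived allele is the
#' globally rarer allele (summed over all four species); a remaining tie is
#' broken toward the VCF ALT allele. With `tieRule = "drop"` such sites are
#' dropped instead. Either way the number of ties is logged.
#'
#' @param vcf path to a VCF (plain or gzipped), or a `vcfR` object.
#' @param map a [SpeciesMap-class].
#' @param tieRule `"global_rare"` (default) or `"drop"`.
#' @return a [SiteTable-class].
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "introClust")
#' sm <- readSpeciesMap(system.file("extdata", "toy_sets.tsv",
#'                                  package = "introClust"))
#' st <- readSiteTable(vcf, sm)
#' derivedFreq(st)
#' @export
readSiteTable <- function(vcf, map, tieRule = c("global_rare", "drop")) {
    tieRule <- match.arg(tieRule)
    stopifnot(is(map, "SpeciesMap"))
    v <- if (is.character(vcf)) vcfR::read.vcfR(vcf, verbose = FALSE) else vcf
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    n0 <- nrow(fix)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                       dimnames = list(NULL, names(gt)))
    unknown <- setdiff(names(map@samples), colnames(gt))
    if (length(unknown))
        stop("samples in species map absent from VCF: ",
             paste(unknown, collapse = ", "))
    gt <- gt[, names(map@samples), drop = FALSE]

    chrom <- fix[, "CHROM"]
    pos   <- as.integer(fix[, "POS"])
    ref   <- fix[, "REF"]
    alt   <- fix[, "ALT"]
    altList <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
    nAlt <- lengths(altList)
    isSNP <- nchar(ref) == 1L & ref != "." &
        vapply(altList, function(a) all(nchar(a) == 1L & a != "*"), logical(1))
    tooMany <- nAlt > 9L   # two-character allele indices are not supported

    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    a1[a1 == "." | a1 == ""] <- NA
    a2[a2 == "." | a2 == ""] <- NA

    roles <- c(map@trio, map@outgroup)
    roleCols <- lapply(roles, function(sp) which(map@samples == sp))
    vals <- as.character(0:max(1L, min(max(nAlt), 9L)))

    # per-role, per-allele call counts (sites x alleles)
    cnt <- lapply(roleCols, function(cols) {
        m <- matrix(0L, nrow = n0, ncol = length(vals),
                    dimnames = list(NULL, vals))
        for (valc in vals) {
            m[, valc] <- rowSums(a1[, cols, drop = FALSE] == valc, na.rm = TRUE) +
                         rowSums(a2[, cols, drop = FALSE] == valc, na.rm = TRUE)
        }
        m
    })
    calls <- vapply(cnt, rowSums, numeric(n0))
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
    tot <- Reduce(`+`, cnt)                       # across the four species
    nObserved <- rowSums(tot > 0L)

    dropNotSNP   <- !isSNP | tooMany
    dropMissing  <- !dropNotSNP & rowSums(calls == 0) > 0L
    dropMulti    <- !dropNotSNP & !dropMissing & nObserved > 2L
    dropMono     <- !dropNotSNP & !dropMissing & !dropMulti & nObserved < 2L
    keep <- !(dropNotSNP | dropMissing | dropMulti | dropMono)

    # duplicate positions (same chrom+pos) cannot be ordered: keep the first
    dup <- duplicated(paste(chrom, pos)) & keep
    keep <- keep & !dup

    ki <- which(keep)
    obs <- tot[ki, , drop = FALSE] > 0L
    v1 <- max.col(obs, ties.method = "first")     # lower allele index
    v2 <- max.col(obs, ties.method = "last")      # higher allele index
    p4cnt <- cnt[[4L]][ki, , drop = FALSE]
    idx1 <- cbind(seq_along(ki), v1)
    idx2 <- cbind(seq_along(ki), v2)
    c4a <- p4cnt[idx1]; c4b <- p4cnt[idx2]
    g1 <- tot[ki, , drop = FALSE][idx1]
    g2 <- tot[ki, , drop = FALSE][idx2]
    f4a <- c4a / (c4a + c4b)
    tie <- f4a == 0.5
    # lower outgroup frequency wins; ties: globally rarer, then the ALT
    derivedHi <- (c4b < c4a) | (tie & (g2 < g1 | g2 == g1))
    nTies <- sum(tie)
    if (tieRule == "drop" && nTies) {
        sel <- !tie
        ki <- ki[sel]; v1 <- v1[sel]; v2 <- v2[sel]
        derivedHi <- derivedHi[sel]
        idx1 <- cbind(seq_along(ki), v1); idx2 <- cbind(seq_along(ki), v2)
    }
    dcol <- ifelse(derivedHi, v2, v1)
    dIdx <- cbind(seq_along(ki), dcol)
    freq <- vapply(cnt, function(m) m[ki, , drop = FALSE][dIdx] /
                       rowSums(m[ki, , drop = FALSE]), numeric(length(ki)))
    if (is.null(dim(freq))) freq <- matrix(freq, nrow = length(ki))

    counts <- c(input = n0, retained = length(ki),
                not_snp = sum(dropNotSNP), multi_allelic = sum(dropMulti),
                missing_species = sum(dropMissing), monomorphic = sum(dropMono),
                duplicate_pos = sum(dup),
                outgroup_tie = if (tieRule == "drop") nTies else sum(tie),
                tie_dropped = if (tieRule == "drop") nTies else 0L)
    if (counts[["outgroup_tie"]] > 0)
        message(counts[["outgroup_tie"]], " site(s) with a 50/50 outgroup; ",
                if (tieRule == "drop") "dropped" else
                    "derived allele set to the globally rarer allele")

    out <- siteTable(chrom[ki], pos[ki], freq, map = map, counts = counts)
    validObject(out)
    out
}

#' @rdname SiteTable-class
#' @export
setMethod("derivedFreq", "SiteTable",
          function(x) SummarizedExperiment::assay(x, "derivedFreq"))

#' @rdname SiteTable-class
#' @export
setMethod("nSites", "SiteTable", function(x) nrow(x))

#' Combine SiteTables from several chromosomes into one dataset
#'
#' Concatenates per-chromosome tables (e.g. separately simulated or
#' separately ingested chromosomes) into a single [SiteTable-class] for a
#' joint analysis; dropped-site counts are summed.
#'
#' @param ... [SiteTable-class] objects with distinct chromosomes.
#' @return a [SiteTable-class].
#' @export
bindSiteTables <- function(...) {
    tabs <- list(...)
    stopifnot(length(tabs) >= 1L, all(vapply(tabs, is, logical(1),
                                             "SiteTable")))
    if (length(tabs) == 1L) return(tabs[[1L]])
    # distinct chromosomes by design: silence the disjoint-seqlevels note
    out <- new("SiteTable", suppressWarnings(
        do.call(rbind, lapply(tabs, as, "RangedSummarizedExperiment"))))
    cnts <- lapply(tabs, function(t) metadata(t)$counts)
    metadata(out)$counts <- if (all(lengths(cnts) > 0)) Reduce(`+`, cnts)
                            else numeric()
    metadata(out)$speciesMap <- metadata(tabs[[1L]])$speciesMap
    metadata(out)$rotated <- FALSE
    validObject(out)
    out
}

#' Swap the P1 and P2 roles of a SiteTable
#'
#' Exchanges the P1 and P2 frequency columns (and thereby CABBA and CBABA),
#' flipping the sign of D. Used to orient the trio so that D >= 0.
#'
#' @param x a [SiteTable-class].
#' @return the reoriented [SiteTable-class] with the `rotated` metadata flag
#'   toggled.
#' @export
rotateTrio <- function(x) {
    f <- SummarizedExperiment::assay(x, "derivedFreq")
    f <- f[, c(2L, 1L, 3L, 4L), drop = FALSE]
    colnames(f) <- c("P1", "P2", "P3", "P4")
    SummarizedExperiment::assay(x, "derivedFreq") <- f
    if (!is.null(metadata(x)$speciesMap)) {
        sm <- metadata(x)$speciesMap
        sm@trio <- sm@trio[c(2L, 1L, 3L)]
        metadata(x)$speciesMap <- sm
    }
    metadata(x)$rotated <- !isTRUE(metadata(x)$rotated)
    x
}

setMethod("show", "SiteTable", function(object) {
    cat("SiteTable with", nrow(object), "sites on",
        length(unique(as.character(seqnames(rowRanges(object))))),
        "chromosome(s)\n")
    cnt <- metadata(object)$counts
    if (length(cnt))
        cat("  dropped: ", paste0(names(cnt), "=", cnt, collapse = ", "),
            "\n", sep = "")
    if (isTRUE(metadata(object)$rotated))
        cat("  P1/P2 rotated so that D >= 0\n")
})
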