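#' Classify strong ABBA / strong BABA sites
#'
#' A site is a *strong ABBA site* when
#' \deqn{(1-f_{P1}) f_{P2} f_{P3} (1-f_{P4}) + f_{P1} (1-f_{P2}) (1-f_{P3}) f_{P4} > 0.5,}
#' i.e. when most sampled alleles jointly support the ABBA pattern in either
#' polarization; *strong BABA sites* satisfy the analogous expression with
#' the P1 and P2 roles exchanged. All other sites are `"other"`.
#'
#' @param table a [SiteTable-class].
#' @param threshold score threshold (default 0.5).
#' @return a [StrongSiteClassification-class].
#' @examples
#' st <- siteTable("chr1", c(10L, 20L, 30L),
#'                 rbind(c(0, 1, 1, 0), c(1, 0, 0, 1), c(.5, .5, .5, .5)))
#' classifyStrongSites(st)@label   # strong_ABBA, strong_ABBA, other
#' @export
classifyStrongSites <- function(table, threshold = 0.5) {
    if (nrow(table) < 1L) stop("empty SiteTable")
    f <- derivedFreq(table)
    p1 <- f[, "P1"]; p2 <- f[, "P2"]; p3 <- f[, "P3"]; p4 <- f[, "P4"]
    abba <- (1 - p1) * p2 * p3 * (1 - p4) + p1 * (1 - p2) * (1 - p3) * p4
    baba <- p1 * (1 - p2) * p3 * (1 - p4) + (1 - p1) * p2 * (1 - p3) * p4
    lab <- rep("other", length(p1))
    lab[abba > threshold] <- "strong_ABBA"
    lab[baba > threshold & !(abba > threshold)] <- "strong_BABA"
    new("StrongSiteClassification",
        chrom = as.character(seqnames(rowRanges(table))),
        pos = GenomicRanges::start(rowRanges(table)),
        label = factor(lab, levels = c("strong_ABBA", "strong_BABA", "other")),
        threshold = threshold)
}

#' Build the clustering-test index vectors
#'
#' For the *sensitive* version, the background vector is all retained
#' polymorphic sites; for the *robust* version it is only the strong ABBA
#' and strong BABA sites. The index vector holds the 0-based ordinals of
#' strong ABBA sites within the background; for multiple chromosomes, the
#' per-chromosome vectors are concatenated with cumulative offsets (which is
#' automatic here because sites are stored in per-chromosome order). The
#' normalized vector divides the ordinals by the background length.
#'
#' @param classification a [StrongSiteClassification-class].
#' @param version `"sensitive"` or `"robust"`.
#' @return a [ClusteringInput-class].
#' @export
buildClusterVectors <- function(classification,
                                version = c("sensitive", "robust")) {
    version <- match.arg(version)
    lab <- classification@label
    inBackground <- if (version == "sensitive") rep(TRUE, length(lab))
                    else lab != "other"
    bg <- lab[inBackground]
    idx <- which(bg == "strong_ABBA") - 1L
    nBg <- length(bg)
    new("ClusteringInput", version = version, idx = as.integer(idx),
        idxNorm = if (nBg) idx / nBg else numeric(),
        nBackground = nBg,
        nStrongABBA = sum(lab == "strong_ABBA"),
        nStrongBABA = sum(lab == "strong_BABA"))
}

#' Kolmogorov-Smirnov test for ABBA-site clustering
#'
#' Tests the normalized strong-ABBA ordinals against Uniform(0,1) with a
#' one-sample KS test. A significant result means that strong ABBA sites
#' cluster along chromosomes — the hallmark of introgressed haplotypes, as
#' opposed to the homogeneous scatter expected of homoplasies. The exact
#' small-sample KS distribution is used below 50 sites, the asymptotic
#' Kolmogorov distribution above; p-values are floored at 2.3e-16.
#'
#' @param input a [ClusteringInput-class].
#' @param minSites minimum number of strong ABBA sites required to report a
#'   p-value (default 10).
#' @return a [ClusterTestResult-class].
#' @export
ksClusterTest <- function(input, minSites = 10L) {
    if (input@nStrongABBA < minSites || input@nBackground == 0L) {
        return(new("ClusterTestResult", version = input@version,
                   statistic = NA_real_, p = NA_real_,
                   nStrongABBA = input@nStrongABBA,
                   nStrongBABA = input@nStrongBABA,
                   nBackground = input@nBackground,
                   status = "insufficient_sites"))
    }
    d <- .ksStatUnif(input@idxNorm)
    p <- max(.ksPvalue(d, length(input@idxNorm)), P_FLOOR)
    new("ClusterTestResult", version = input@version, statistic = d, p = p,
        nStrongABBA = input@nStrongABBA, nStrongBABA = input@nStrongBABA,
        nBackground = input@nBackground, status = "ok")
}

#' Run both versions of the ABBA-site clustering test
#'
#' Orients the trio as in [computeD()] (so that "ABBA" is the excess
#' pattern), classifies strong sites once, and evaluates the sensitive and
#' robust test versions.
#'
#' @param table a [SiteTable-class].
#' @param rotate apply D-orientation rotation before classification
#'   (default `TRUE`).
#' @param threshold strong-site score threshold.
#' @param minSites minimum strong-ABBA count for a p-value.
#' @return named list with elements `sensitive` and `robust`, each a
#'   [ClusterTestResult-class], plus the `classification`.
#' @examples
#' set.seed(42)
#' f <- matrix(runif(400), ncol = 4)
#' st <- siteTable("chr1", sort(sample.int(1e5, 100)), f)
#' runClusterTests(st)$sensitive
#' @export
runClusterTests <- function(table, rotate = TRUE, threshold = 0.5,
                            minSites = 10L) {
    if (rotate) {
        res <- computeD(table, rotate = TRUE)
        table <- attr(res, "table")
    }
    cls <- classifyStrongSites(table, threshold = threshold)
    list(sensitive = ksClusterTest(buildClusterVectors(cls, "sensitive"),
                                   minSites = minSites),
         robust = ksClusterTest(buildClusterVectors(cls, "robust"),
                                minSites = minSites),
         classification = cls)
}

#' @rdname ClusterTestResult-class
#' @param object a [ClusterTestResult-class].
#' @export
setMethod("pValue", "ClusterTestResult", function(object) object@p)

setMethod("show", "ClusterTestResult", function(object) {
    cat(sprintf("ABBA-site clustering test (%s)\n", object@version))
    cat(sprintf("  strong ABBA: %d, strong BABA: %d, background: %d\n",
                object@nStrongABBA, object@nStrongBABA, object@nBackground))
    if (object@status == "ok")
        cat(sprintf("  KS statistic = %.4f, p = %.4g\n",
                    object@statistic, object@p))
    else cat("  status:", object@status, "\n")
})

#' TSV summary of clustering-test results
#'
#' @param results list as returned by [runClusterTests()].
#' @param file path, or `""` for stdout.
#' @return the data.frame, invisibly.
#' @export
writeClusterTSV <- function(results, file = "") {
    row <- function(r) data.frame(version = r@version, KS_stat = r@statistic,
                                  p = r@p, n_strong_ABBA = r@nStrongABBA,
                                  n_strong_BABA = r@nStrongBABA,
                                  n_background = r@nBackground,
                                  status = r@status)
    df <- rbind(row(results$sensitive), row(results$robust))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Per-site strong-site labels as a BED-like table
#'
#' Useful for plotting rank-vs-position curves of strong ABBA sites along
#' chromosomes (e.g. to locate low-recombination regions or inversions).
#'
#' @param classification a [StrongSiteClassification-class].
#' @param file path, or `""` for stdout.
#' @return the data.frame, invisibly.
#' @export
writeSiteLabelsTSV <- function(classification, file = "") {
    df <- data.frame(chrom = classification@chrom,
                     pos = classification@pos,
                     label = as.character(classification@label))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
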