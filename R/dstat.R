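#' Frequency-weighted ABBA / BABA sums
#'
#' Computes the frequency-based pattern sums over all retained sites i:
#' \deqn{C_{ABBA} = \sum_i (1 - f_{P1,i}) f_{P2,i} f_{P3,i}}
#' \deqn{C_{BABA} = \sum_i f_{P1,i} (1 - f_{P2,i}) f_{P3,i}}
#' where f is the derived-allele frequency in the respective species.
#'
#' @param table a [SiteTable-class] with at least one site.
#' @return named numeric vector `c(CABBA = ..., CBABA = ...)`.
#' @export
countPatterns <- function(table) {
    f <- derivedFreq(table)
    if (nrow(f) < 1L) dataError("no informative sites")
    c(CABBA = sum((1 - f[, "P1"]) * f[, "P2"] * f[, "P3"]),
      CBABA = sum(f[, "P1"] * (1 - f[, "P2"]) * f[, "P3"]))
}

#' Patterson's D-statistic
#'
#' D = (CABBA - CBABA) / (CABBA + CBABA). With `rotate = TRUE` (the default)
#' the P1 and P2 roles are swapped whenever D < 0, so that the reported D is
#' non-negative and "ABBA" always denotes the excess pattern; the `rotated`
#' flag records whether this happened.
#'
#' @param table a [SiteTable-class].
#' @param rotate swap P1/P2 so that D >= 0?
#' @return a [DStatResult-class] (jackknife fields unset; see [jackknifeD()]).
#'   The reoriented table is attached as attribute `"table"` for downstream
#'   use (e.g. the clustering test).
#' @examples
#' st <- siteTable("chr1", c(100L, 200L, 300L),
#'                 rbind(c(0, 1, 1, 0), c(0, 1, 1, 0), c(1, 0, 1, 0)))
#' res <- computeD(st)
#' res   # D = 1/3
#' @export
computeD <- function(table, rotate = TRUE) {
    cc <- countPatterns(table)
    rot <- FALSE
    if (cc[["CABBA"]] + cc[["CBABA"]] == 0) {
        res <- new("DStatResult", CABBA = cc[["CABBA"]], CBABA = cc[["CBABA"]],
                   D = NA_real_, Z = NA_real_, p = NA_real_, rotated = FALSE,
                   nBlocks = 0L, blockD = numeric(), nSites = nrow(table),
                   status = "undefined")
        attr(res, "table") <- table
        return(res)
    }
    D <- (cc[["CABBA"]] - cc[["CBABA"]]) / (cc[["CABBA"]] + cc[["CBABA"]])
    if (rotate && D < 0) {
        table <- rotateTrio(table)
        cc <- cc[c(2L, 1L)]
        names(cc) <- c("CABBA", "CBABA")
        D <- -D
        rot <- TRUE
    }
    res <- new("DStatResult", CABBA = cc[["CABBA"]], CBABA = cc[["CBABA"]],
               D = D, Z = NA_real_, p = NA_real_, rotated = rot,
               nBlocks = 0L, blockD = numeric(), nSites = nrow(table),
               status = "ok")
    attr(res, "table") <- table
    res
}

# contiguous block assignment: equal numbers of retained sites per block,
# never spanning chromosome boundaries; remainder sites go to the last
# block within each chromosome's group of blocks
.blockAssign <- function(chrom, nBlocks) {
    n <- length(chrom)
    chrRle <- rle(chrom)
    nChr <- length(chrRle$values)
    if (nChr > nBlocks)
        stop("more chromosomes (", nChr, ") than blocks (", nBlocks, ")")
    # blocks per chromosome, proportional to site counts, at least one each
    nb <- pmax(1L, floor(nBlocks * chrRle$lengths / n))
    while (sum(nb) < nBlocks) {
        i <- which.max(chrRle$lengths / nb)
        nb[i] <- nb[i] + 1L
    }
    while (sum(nb) > nBlocks) {
        i <- which(nb > 1L)[which.min((chrRle$lengths / nb)[nb > 1L])]
        nb[i] <- nb[i] - 1L
    }
    out <- integer(n)
    off <- 0L; bOff <- 0L
    for (i in seq_len(nChr)) {
        nc <- chrRle$lengths[i]
        size <- nc %/% nb[i]
        b <- pmin(((seq_len(nc) - 1L) %/% size) + 1L, nb[i])
        out[off + seq_len(nc)] <- bOff + b
        off <- off + nc; bOff <- bOff + nb[i]
    }
    out
}

#' Block-jackknife significance for Patterson's D
#'
#' Splits the retained sites into `nBlocks` contiguous blocks of (near-)equal
#' site count (never spanning chromosomes; `equalBp = TRUE` uses equal
#' physical spans instead), computes delete-one-block D values, and derives
#' the jackknife standard error, `Z = D / SE(D)` and a two-sided normal
#' p-value floored at 2.3e-16.
#'
#' @param table a [SiteTable-class]; its orientation should already be fixed
#'   (see [computeD()]).
#' @param nBlocks number of jackknife blocks (default 20).
#' @param rotate passed to [computeD()].
#' @param equalBp use blocks of equal physical length instead of equal
#'   variant count.
#' @return a [DStatResult-class] with Z and p set. Zero jackknife variance
#'   yields `status = "degenerate_variance"` and `p = NA`.
#' @examples
#' set.seed(1)
#' st <- siteTable("chr1", sort(sample.int(1e6, 400)),
#'                 matrix(runif(1600), ncol = 4))
#' jackknifeD(st)
#' @export
jackknifeD <- function(table, nBlocks = 20L, rotate = TRUE, equalBp = FALSE) {
    res <- computeD(table, rotate = rotate)
    if (res@status != "ok") return(res)
    table <- attr(res, "table")
    n <- nrow(table)
    if (n < nBlocks)
        stop("need at least nBlocks = ", nBlocks, " sites, got ", n)
    f <- derivedFreq(table)
    chrom <- as.character(seqnames(rowRanges(table)))
    if (equalBp) {
        pos <- GenomicRanges::start(rowRanges(table))
        blk <- integer(n)
        chrRle <- rle(chrom)
        nb <- pmax(1L, round(nBlocks * chrRle$lengths / n))
        off <- 0L; bOff <- 0L
        for (i in seq_along(chrRle$values)) {
            idx <- off + seq_len(chrRle$lengths[i])
            p <- pos[idx]
            cuts <- seq(min(p), max(p), length.out = nb[i] + 1L)
            b <- pmin(findInterval(p, cuts, rightmost.closed = TRUE), nb[i])
            blk[idx] <- bOff + b
            off <- off + chrRle$lengths[i]; bOff <- bOff + nb[i]
        }
    } else {
        blk <- .blockAssign(chrom, nBlocks)
    }
    abba <- (1 - f[, "P1"]) * f[, "P2"] * f[, "P3"]
    baba <- f[, "P1"] * (1 - f[, "P2"]) * f[, "P3"]
    sa <- rowsum(abba, blk); sb <- rowsum(baba, blk)
    g <- nrow(sa)
    ta <- sum(sa); tb <- sum(sb)
    blockD <- as.numeric((ta - sa - (tb - sb)) / (ta - sa + (tb - sb)))
    Dbar <- mean(blockD)
    se <- sqrt((g - 1) / g * sum((blockD - Dbar)^2))
    res@nBlocks <- as.integer(g)
    res@blockD <- blockD
    if (se == 0) {
        res@status <- "degenerate_variance"
        res@Z <- NA_real_; res@p <- NA_real_
        return(res)
    }
    res@Z <- res@D / se
    res@p <- max(2 * stats::pnorm(-abs(res@Z)), P_FLOOR)
    res
}

#' Bonferroni-adjusted significance helper
#'
#' The package reports raw p-values; when many trios or datasets are tested
#' jointly, multiply by the number of tests (capped at 1).
#'
#' @param p numeric vector of p-values.
#' @param nTests number of tests performed.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, nTests) pmin(1, p * nTests)

#' @rdname DStatResult-class
#' @export
setMethod("pValue", "DStatResult", function(object) object@p)

#' @rdname DStatResult-class
#' @export
setMethod("rotated", "DStatResult", function(object) object@rotated)

setMethod("show", "DStatResult", function(object) {
    cat("Patterson's D\n")
    cat(sprintf("  CABBA = %.4f, CBABA = %.4f over %d sites\n",
                object@CABBA, object@CBABA, object@nSites))
    cat(sprintf("  D = %.6g%s\n", object@D,
                if (object@rotated) "  (P1/P2 rotated)" else ""))
    if (object@nBlocks > 0L)
        cat(sprintf("  jackknife (%d blocks): Z = %.3f, p = %.4g\n",
                    object@nBlocks, object@Z, object@p))
    if (object@status != "ok") cat("  status:", object@status, "\n")
})

#' One-row TSV summary of a D-statistic analysis
#'
#' @param res a [DStatResult-class].
#' @param map optional [SpeciesMap-class] for the species names.
#' @param file path, or `""` for stdout.
#' @return the data.frame, invisibly.
#' @export
writeDStatTSV <- function(res, map = NULL, file = "") {
    trio <- if (!is.null(map)) map@trio else c("P1", "P2", "P3")
    df <- data.frame(P1 = trio[1], P2 = trio[2], P3 = trio[3],
                     CABBA = res@CABBA, CBABA = res@CBABA, D = res@D,
                     Z = res@Z, p = res@p, rotated = res@rotated,
                     n_sites = res@nSites, status = res@status)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
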