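#' Read a set of rooted four-taxon trees
#'
#' Reads newick trees (one or more per file), maps tip labels to the roles
#' P1..P4, roots each tree on P4 when the input is unrooted, determines the
#' ingroup trio topology, and flags trees whose single internal branch
#' (after pruning P4) is shorter than `filterThreshold` as uninformative.
#' Trees that cannot be parsed, lack one of the four taxa, or cannot be
#' rooted on P4 are skipped with a warning.
#'
#' @param trees path to a newick file, a `phylo`, or a `multiPhylo`.
#' @param taxonMap named character vector mapping tip labels to
#'   `"P1".."P4"`, or a path to a two-column TSV (taxon, role). `NULL` if
#'   tips are already named P1..P4.
#' @param filterThreshold internal-branch filter in substitutions/site
#'   (default 0.001).
#' @return a [TreeSet-class].
#' @examples
#' txt <- c("(((P1:1,P2:1):0.01,P3:2):1,P4:3);",
#'          "(((P1:1,P3:1):0.02,P2:2):1,P4:3);")
#' ts <- readTreeSet(ape::read.tree(text = txt))
#' ts@topology
#' @export
readTreeSet <- function(trees, taxonMap = NULL, filterThreshold = 0.001) {
    if (is.character(trees) && length(trees) == 1L && file.exists(trees)) {
        lines <- readLines(trees)
        lines <- lines[nzchar(trimws(lines))]
        parsed <- lapply(lines, function(l)
            suppressWarnings(tryCatch(ape::read.tree(text = l),
                                      error = function(e) NULL)))
    } else if (inherits(trees, "phylo")) {
        parsed <- list(trees)
    } else if (inherits(trees, "multiPhylo")) {
        parsed <- unclass(trees)
    } else stop("'trees' must be a newick file path, phylo or multiPhylo")

    if (is.character(taxonMap) && length(taxonMap) == 1L &&
        file.exists(taxonMap)) {
        tm <- utils::read.table(taxonMap, sep = "\t", header = FALSE,
                                colClasses = "character")
        taxonMap <- stats::setNames(tm[[2L]], tm[[1L]])
    }

    roles <- c("P1", "P2", "P3", "P4")
    keptTrees <- list(); ib <- numeric(); topo <- character()
    nSkipped <- 0L
    for (tr in parsed) {
        if (is.null(tr) || is.null(tr$tip.label)) { nSkipped <- nSkipped + 1L; next }
        if (!is.null(taxonMap)) {
            hit <- taxonMap[tr$tip.label]
            if (anyNA(hit)) { nSkipped <- nSkipped + 1L; next }
            tr$tip.label <- unname(hit)
        }
        if (!setequal(tr$tip.label, roles) || length(tr$tip.label) != 4L) {
            nSkipped <- nSkipped + 1L; next
        }
        if (!ape::is.rooted(tr)) {
            tr <- tryCatch(ape::root(tr, outgroup = "P4", resolve.root = TRUE),
                           error = function(e) NULL)
            if (is.null(tr)) { nSkipped <- nSkipped + 1L; next }
        }
        info <- .trioInfo(tr)
        if (is.null(info)) { nSkipped <- nSkipped + 1L; next }
        keptTrees[[length(keptTrees) + 1L]] <- tr
        ib <- c(ib, info$internal)
        topo <- c(topo, info$topology)
    }
    if (nSkipped > 0L)
        warning(nSkipped, " tree(s) skipped (unparseable, missing taxa, or unrootable)")
    mp <- keptTrees
    class(mp) <- "multiPhylo"
    new("TreeSet", trees = mp, internalBranch = ib,
        topology = factor(topo, levels = c("P1P2", "P1P3", "P2P3")),
        filtered = ib < filterThreshold, threshold = filterThreshold,
        nSkipped = nSkipped)
}

# trio topology and internal-branch length after pruning P4
.trioInfo <- function(tr) {
    trio <- tryCatch(ape::keep.tip(tr, c("P1", "P2", "P3")),
                     error = function(e) NULL)
    if (is.null(trio)) return(NULL)
    ntip <- length(trio$tip.label)
    if (ntip != 3L) return(NULL)
    kids <- tabulate(trio$edge[, 1L], nbins = ntip + trio$Nnode)
    if (trio$Nnode == 1L) {
        # root polytomy: no internal branch
        return(list(topology = NA_character_, internal = 0))
    }
    root <- ntip + 1L
    inner <- setdiff(unique(trio$edge[, 1L]), root)
    cherryTips <- trio$edge[trio$edge[, 1L] == inner & trio$edge[, 2L] <= ntip, 2L]
    if (length(cherryTips) != 2L) return(NULL)
    pair <- sort(trio$tip.label[cherryTips])
    topology <- paste0(pair[1L], pair[2L])
    internal <- trio$edge.length[trio$edge[, 1L] == root & trio$edge[, 2L] == inner]
    list(topology = topology, internal = internal)
}

#' Constrained Dtree test
#'
#' Counts the three rooted trio topologies among the unfiltered trees and
#' computes \deqn{D_{tree} = (C_{P2,P3} - C_{P1,P3}) / (C_{P2,P3} + C_{P1,P3})}
#' with a one-sided exact binomial test of whether C_P2,P3 exceeds C_P1,P3.
#' With `constrained = FALSE`, the counts of the second- and third-most
#' frequent topologies are compared instead (useful when the most frequent
#' topology may not be the species tree).
#'
#' @param treeSet a [TreeSet-class].
#' @param constrained compare P2P3 vs P1P3 (default) rather than 2nd vs 3rd
#'   most frequent.
#' @return a [DtreeResult-class].
#' @export
dtreeTest <- function(treeSet, constrained = TRUE) {
    topo <- treeSet@topology[!treeSet@filtered]
    counts <- table(topo)
    counts <- stats::setNames(as.integer(counts), names(counts))
    if (constrained) {
        c1 <- counts[["P2P3"]]; c2 <- counts[["P1P3"]]
    } else {
        ord <- sort(counts, decreasing = TRUE)
        c1 <- ord[[2L]]; c2 <- ord[[3L]]
    }
    n <- c1 + c2
    if (n == 0L) {
        dtree <- NA_real_; p <- 1
    } else {
        dtree <- (c1 - c2) / n
        p <- stats::pbinom(c1 - 1L, n, 0.5, lower.tail = FALSE)
    }
    new("DtreeResult", counts = counts, dtree = dtree, p = p,
        nUsed = length(topo) - sum(is.na(topo)),
        nFiltered = sum(treeSet@filtered))
}

#' dMRCA statistic on ultrametric local trees
#'
#' For every tree, the ages of the most recent common ancestors of the pairs
#' P1-P2, P1-P3 and P2-P3 are extracted; the per-pair means over all trees
#' are compared and `dMRCA` is the difference between the two largest means.
#' Under the species tree without introgression, the P1-P3 and P2-P3 means
#' coincide (both equal the trio root age) and dMRCA is near zero;
#' introgression between non-sister species lowers one of them. The
#' identities of the two oldest pairs are reported: when they are not P1-P3
#' and P2-P3, dMRCA is not interpretable as introgression evidence.
#'
#' Trees are expected to be ultrametric in time units; trees whose
#' root-to-tip spread exceeds `tol` (relative to tree height) trigger a
#' warning and their tip ages are averaged. No internal-branch filter is
#' applied.
#'
#' @param treeSet a [TreeSet-class] of ultrametric trees.
#' @param tol relative root-to-tip spread tolerated (default 1e-6).
#' @return a [MMS17Result-class].
#' @examples
#' txt <- "(((P1:6,P2:6):4,P3:10):5,P4:15);"
#' ts <- readTreeSet(ape::read.tree(text = txt))
#' mms17dMRCA(ts)
#' @export
mms17dMRCA <- function(treeSet, tol = 1e-6) {
    trees <- treeSet@trees
    if (length(trees) == 0L) stop("empty tree set")
    pairs <- list(P1P2 = c("P1", "P2"), P1P3 = c("P1", "P3"),
                  P2P3 = c("P2", "P3"))
    ages <- matrix(NA_real_, nrow = length(trees), ncol = 3L,
                   dimnames = list(NULL, names(pairs)))
    nWarn <- 0L
    for (i in seq_along(trees)) {
        tr <- trees[[i]]
        depth <- ape::node.depth.edgelength(tr)
        tipDepth <- depth[seq_along(tr$tip.label)]
        h <- max(tipDepth)
        if (h > 0 && (max(tipDepth) - min(tipDepth)) / h > tol) {
            nWarn <- nWarn + 1L
            h <- mean(tipDepth)
        }
        for (p in names(pairs)) {
            node <- ape::getMRCA(tr, pairs[[p]])
            ages[i, p] <- h - depth[node]
        }
    }
    if (nWarn > 0L)
        warning(nWarn, " tree(s) not ultrametric within tolerance; ",
                "mean tip height used")
    means <- colMeans(ages)
    ord <- order(means, decreasing = TRUE)
    new("MMS17Result", meanAges = means,
        dMRCA = unname(means[ord[1L]] - means[ord[2L]]),
        oldestPairs = names(means)[ord[1:2]],
        nTrees = length(trees))
}

setMethod("show", "TreeSet", function(object) {
    cat("TreeSet:", length(object@trees), "trees (",
        sum(object@filtered), "filtered at threshold", object@threshold,
        ";", object@nSkipped, "skipped )\n")
    print(table(object@topology))
})

setMethod("show", "DtreeResult", function(object) {
    cat("Constrained Dtree\n  counts:",
        paste0(names(object@counts), "=", object@counts, collapse = ", "),
        "\n")
    cat(sprintf("  Dtree = %.4g, one-sided binomial p = %.4g (n used = %d, filtered = %d)\n",
                object@dtree, object@p, object@nUsed, object@nFiltered))
})

setMethod("show", "MMS17Result", function(object) {
    cat("dMRCA (mean pairwise MRCA ages over", object@nTrees, "trees)\n")
    cat("  ", paste0(names(object@meanAges), "=",
                     signif(object@meanAges, 6), collapse = ", "), "\n")
    cat(sprintf("  dMRCA = %.6g (oldest pairs: %s, %s)\n", object@dMRCA,
                object@oldestPairs[1L], object@oldestPairs[2L]))
})

#' @rdname DtreeResult-class
#' @param object a [DtreeResult-class].
#' @export
setMethod("pValue", "DtreeResult", function(object) object@p)

#' TSV summary of tree-set statistics
#'
#' @param dtree a [DtreeResult-class] or `NULL`.
#' @param mms17 a [MMS17Result-class] or `NULL`.
#' @param file path, or `""` for stdout.
#' @return the data.frame, invisibly.
#' @export
writeTreeStatsTSV <- function(dtree = NULL, mms17 = NULL, file = "") {
    df <- data.frame(row.names = 1L)
    if (!is.null(dtree))
        df <- cbind(df, data.frame(C_P1P2 = dtree@counts[["P1P2"]],
                                   C_P1P3 = dtree@counts[["P1P3"]],
                                   C_P2P3 = dtree@counts[["P2P3"]],
                                   Dtree = dtree@dtree, p_binomial = dtree@p,
                                   n_used = dtree@nUsed,
                                   n_filtered = dtree@nFiltered))
    if (!is.null(mms17))
        df <- cbind(df, data.frame(mean_tP1P2 = mms17@meanAges[["P1P2"]],
                                   mean_tP1P3 = mms17@meanAges[["P1P3"]],
                                   mean_tP2P3 = mms17@meanAges[["P2P3"]],
                                   dMRCA = mms17@dMRCA,
                                   oldest_pairs = paste(mms17@oldestPairs,
                                                        collapse = ",")))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
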