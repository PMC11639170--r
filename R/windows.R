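#' Extract window alignments for tree-based analyses
#'
#' Cuts equally spaced windows across a simulated chromosome and writes a
#' four-sequence FASTA alignment per window, reducing the data the same way
#' tree-based introgression pipelines do: per species and variable site only
#' the first allele of the first individual is used, and every invariant
#' position is filled with a random nucleotide (identical across the four
#' taxa, drawn i.i.d. from A/C/G/T). Window starts are spaced `L / n` bp
#' apart, so the canonical schemes 5000 x 200 bp, 2000 x 500 bp and
#' 1000 x 1000 bp each cover 1 Mbp of a 20-Mbp chromosome.
#'
#' @param vcf path to the simulated VCF (single chromosome) or a `vcfR`
#'   object.
#' @param map a [SpeciesMap-class]; the first sample listed for each role is
#'   used.
#' @param L chromosome length in bp.
#' @param n number of windows.
#' @param width window width in bp.
#' @param seed seed for the random invariant fill.
#' @param dir output directory for `window_<i>.fa` files; `NULL` returns the
#'   alignments without writing.
#' @return invisibly, a list of `Biostrings::DNAStringSet` alignments
#'   (named `window_<i>`), each with sequences P1..P4.
#' @export
extractWindowAlignments <- function(vcf, map, L, n = 1000L, width = 1000L,
                                    seed = 1L, dir = NULL) {
    v <- if (is.character(vcf)) vcfR::read.vcfR(vcf, verbose = FALSE) else vcf
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    spacing <- L / n
    starts <- floor((seq_len(n) - 1L) * spacing)       # 0-based starts
    if (any(starts + width > L))
        stop("window scheme exceeds the chromosome: last window ends at ",
             max(starts + width), " > L = ", L)
    roles <- c(map@trio, map@outgroup)
    firstSample <- vapply(roles, function(sp)
        names(map@samples)[map@samples == sp][1L], character(1))
    gt <- vcfR::extract.gt(v)[, firstSample, drop = FALSE]
    allele1 <- substr(gt, 1L, 1L)                      # first allele only
    pos <- as.integer(fix[, "POS"])
    altMat <- t(vapply(strsplit(ifelse(is.na(fix[, "ALT"]), "",
                                       fix[, "ALT"]), ",", fixed = TRUE),
                       function(a) { length(a) <- 9L; a }, character(9)))
    alleles <- cbind(fix[, "REF"], altMat)   # columns = allele index 0..9
    set.seed(seed)
    out <- vector("list", n)
    names(out) <- sprintf("window_%d", seq_len(n))
    if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (w in seq_len(n)) {
        lo <- starts[w] + 1L; hi <- starts[w] + width  # 1-based inclusive
        fill <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
        rows <- matrix(rep(fill, 4L), nrow = 4L, byrow = TRUE)
        sel <- which(pos >= lo & pos <= hi)
        for (i in sel) {
            col <- pos[i] - lo + 1L
            for (k in 1:4) {
                a <- allele1[i, k]
                if (!is.na(a) && a != ".") {
                    base <- alleles[i, as.integer(a) + 1L]
                    if (!is.na(base) && nchar(base) == 1L)
                        rows[k, col] <- base
                }
            }
        }
        seqs <- Biostrings::DNAStringSet(apply(rows, 1L, paste0,
                                               collapse = ""))
        names(seqs) <- c("P1", "P2", "P3", "P4")
        out[[w]] <- seqs
        if (!is.null(dir))
            Biostrings::writeXStringSet(seqs,
                                        file.path(dir, paste0(names(out)[w],
                                                              ".fa")))
    }
    invisible(out)
}
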