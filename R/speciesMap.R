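#' Construct a SpeciesMap
#'
#' @param samples named character vector mapping VCF sample ids to species
#'   names.
#' @param trio character vector of length 3: species for roles P1, P2, P3.
#' @param outgroup species used as outgroup P4.
#' @return a [SpeciesMap-class] object.
#' @examples
#' sm <- speciesMap(
#'     samples = c(a1 = "spA", b1 = "spB", c1 = "spC", o1 = "spO"),
#'     trio = c("spA", "spB", "spC"), outgroup = "spO")
#' @export
speciesMap <- function(samples, trio, outgroup) {
    new("SpeciesMap", samples = samples, trio = as.character(trio),
        outgroup = as.character(outgroup))
}

#' Read a sample-to-species map from a TSV / SETS file
#'
#' The file has two tab-separated columns (sample, species), without header.
#' Samples whose species is the literal `"Outgroup"` are taken as the
#' outgroup, as in Dsuite SETS files; alternatively the outgroup species can
#' be named explicitly. Unless given, the trio is the remaining species in
#' order of first appearance (there must be exactly three).
#'
#' @param file path to the two-column TSV.
#' @param trio optional character vector of length 3 (roles P1, P2, P3).
#' @param outgroup optional outgroup species name.
#' @return a [SpeciesMap-class] object.
#' @export
readSpeciesMap <- function(file, trio = NULL, outgroup = NULL) {
    tab <- utils::read.table(file, sep = "\t", header = FALSE,
                             col.names = c("sample", "species"),
                             colClasses = "character")
    samples <- stats::setNames(tab$species, tab$sample)
    if (is.null(outgroup)) {
        if ("Outgroup" %in% tab$species) outgroup <- "Outgroup"
        else stop("no outgroup: label outgroup samples 'Outgroup' or pass `outgroup=`")
    }
    if (is.null(trio)) {
        trio <- setdiff(unique(tab$species), outgroup)
        if (length(trio) != 3L)
            stop("expected exactly 3 non-outgroup species, found ",
                 length(trio), "; pass `trio=` explicitly")
    }
    speciesMap(samples, trio, outgroup)
}

setMethod("show", "SpeciesMap", function(object) {
    cat("SpeciesMap:", length(object@samples), "samples\n")
    for (i in seq_len(3))
        cat("  P", i, ": ", object@trio[i], " (",
            sum(object@samples == object@trio[i]), " samples)\n", sep = "")
    cat("  P4: ", object@outgroup, " (outgroup, ",
        sum(object@samples == object@outgroup), " samples)\n", sep = "")
})
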