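# Shared fixtures: in-code VCF construction, the standard simulated-sample
# species map, and a per-session cache for coalescent simulations so that
# several test files can share one simulated dataset.

# species map matching the simulator's sample naming (P1_0 .. P4_<n-1>)
simSpeciesMap <- function(nDip = 5L) {
    species <- paste0("P", 1:4)
    samples <- stats::setNames(rep(species, each = nDip),
                               paste0(rep(species, each = nDip), "_",
                                      seq_len(nDip) - 1L))
    speciesMap(samples, trio = c("P1", "P2", "P3"), outgroup = "P4")
}

# write a minimal VCF: `gts` is a list of character vectors (one per site)
# of genotype strings per sample; `ref`/`alt` are per-site alleles
writeTestVCF <- function(file, samples, pos, ref, alt, gts,
                         chrom = rep("chr1", length(pos))) {
    hdr <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1,length=10000000>",
             "##contig=<ID=chr2,length=10000000>",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    rows <- vapply(seq_along(pos), function(i)
        paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".",
                "GT", gts[[i]]), collapse = "\t"), character(1))
    writeLines(c(hdr, rows), file)
    file
}

# one diploid sample per species; genotypes given as e.g. "0/0"
quartetVCF <- function(file, pos, ref, alt, gts, ...) {
    writeTestVCF(file, c("s1", "s2", "s3", "s4"), pos, ref, alt, gts, ...)
}

quartetMap <- speciesMap(
    c(s1 = "A", s2 = "B", s3 = "C", s4 = "O"),
    trio = c("A", "B", "C"), outgroup = "O")

# session-level simulation cache ------------------------------------------

.simCache <- new.env(parent = emptyenv())

cachedSim <- function(tag, config, ...) {
    if (!exists(tag, envir = .simCache)) {
        dir <- file.path(tempdir(), paste0("introclust_sim_", tag))
        sim <- simulateDataset(config, dir = dir, ...)
        sim$siteTable <- suppressMessages(
            readSiteTable(sim$vcf, simSpeciesMap(config@nDip)))
        assign(tag, sim, envir = .simCache)
    }
    get(tag, envir = .simCache)
}
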