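.pythonBin <- function() {
    bin <- getOption("introClust.python", Sys.getenv("INTROCLUST_PYTHON", ""))
    if (!nzchar(bin)) bin <- Sys.which("python")
    if (!nzchar(bin)) bin <- Sys.which("python3")
    if (!nzchar(bin))
        stop("no python interpreter found; the simulation module needs ",
             "python with msprime installed (set options(introClust.python=))")
    bin
}

#' Simulate a four-taxon genomic dataset
#'
#' Runs the coalescent-with-recombination scenario described by a
#' [ScenarioConfig-class] (via the bundled msprime driver), overlays HKY
#' mutations, writes a VCF of the sampled diploid genomes (samples named
#' `P1_0` .. `P4_<nDip-1>`), and extracts ground-truth summaries from the
#' genealogical record. Deterministic given the config seed.
#'
#' @param config a [ScenarioConfig-class].
#' @param dir output directory (created if needed).
#' @param vcf write the VCF? (default `TRUE`)
#' @param trees also dump the tskit tree sequence (default `FALSE`).
#' @param truth extract ground truth? (default `TRUE`)
#' @param rateScaling passed to [buildDemography()].
#' @param contig chromosome name used in the VCF.
#' @param localTrees if > 0, also export that many true local genealogies
#'   (one haploid genome per species, branch lengths in generations) at
#'   equally spaced positions, as newick strings in the `localTrees` element.
#' @return list with elements `vcf` (path or `NULL`), `truth`
#'   (a [SimTruth-class] or `NULL`), `trees` (path or `NULL`), `localTrees`
#'   (character or `NULL`) and `config`.
#' @seealso [buildDemography()], [extractTruth()]
#' @export
simulateDataset <- function(config, dir = tempfile("sim"), vcf = TRUE,
                            trees = FALSE, truth = TRUE,
                            rateScaling = c("sampling_time", "branch_rate"),
                            contig = "chr1", localTrees = 0L) {
    rateScaling <- match.arg(rateScaling)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dem <- buildDemography(config, rateScaling = rateScaling)
    job <- c(dem, list(
        L = config@L, r = config@r, seed = config@seed, contig = contig,
        local_trees = as.integer(localTrees),
        vcf = if (vcf) file.path(dir, "sim.vcf") else NULL,
        trees = if (trees) file.path(dir, "sim.trees") else NULL,
        truth = if (truth || localTrees > 0)
            file.path(dir, "truth.json") else NULL))
    jobPath <- file.path(dir, "job.json")
    jsonlite::write_json(job, jobPath, auto_unbox = TRUE, digits = NA,
                         null = "null")
    driver <- system.file("python", "sim_driver.py", package = "introClust",
                          mustWork = TRUE)
    status <- system2(.pythonBin(), c(driver, jobPath),
                      stdout = file.path(dir, "driver.log"),
                      stderr = file.path(dir, "driver.log"))
    if (status != 0L)
        stop("simulation driver failed (exit ", status, "); config: ",
             paste(readLines(jobPath), collapse = ""), "\nlog:\n",
             paste(readLines(file.path(dir, "driver.log")), collapse = "\n"))
    out <- list(vcf = job$vcf, trees = job$trees, truth = NULL,
                localTrees = NULL, config = config)
    if (!is.null(job$truth)) {
        raw <- jsonlite::read_json(job$truth, simplifyVector = TRUE)
        if (truth) out$truth <- extractTruth(raw, config)
        if (localTrees > 0) out$localTrees <- raw$local_trees
    }
    out
}

#' Extract ground-truth summaries from a genealogical record
#'
#' Summarises the raw genealogical material of a simulated dataset:
#' the fraction of the chromosome carrying P2-P3 migrant ancestry (any
#' sampled lineage), single-topology tracts (adjacent local trees with the
#' same rooted trio topology merged, for one haploid genome per species),
#' mean recombination-segment ("c-gene") length `L / #distinct trees`,
#' per-species-pair dxy, and site counts.
#'
#' @param raw path to the driver's truth JSON, or the parsed list.
#' @param config the [ScenarioConfig-class] used for the simulation.
#' @return a [SimTruth-class].
#' @export
extractTruth <- function(raw, config) {
    if (is.character(raw)) raw <- jsonlite::read_json(raw,
                                                      simplifyVector = TRUE)
    if (config@m > 0 && is.null(raw$migrant_intervals))
        stop("migration records missing; re-run the simulation with ",
             "migration record-keeping enabled")
    L <- raw$L
    mi <- raw$migrant_intervals
    iv <- if (is.null(mi) || length(mi) == 0L) matrix(numeric(), ncol = 2)
          else if (is.matrix(mi)) mergeIntervals(mi)
          else mergeIntervals(matrix(unlist(mi), ncol = 2, byrow = TRUE))
    runs <- raw$topology_runs
    if (is.list(runs) && length(runs))
        runs <- do.call(rbind, lapply(runs, unlist))
    tracts <- if (length(runs)) {
        df <- as.data.frame(runs, stringsAsFactors = FALSE)
        names(df) <- c("left", "right", "topology")
        df$left <- as.numeric(df$left); df$right <- as.numeric(df$right)
        mergeTopologyTracts(df)
    } else data.frame(left = numeric(), right = numeric(),
                      topology = character())
    dxy <- matrix(NA_real_, 4, 4,
                  dimnames = list(paste0("P", 1:4), paste0("P", 1:4)))
    diag(dxy) <- 0
    if (length(raw$dxy)) {
        prs <- raw$dxy_pairs
        if (is.list(prs)) prs <- do.call(rbind, lapply(prs, unlist))
        for (k in seq_len(nrow(prs))) {
            dxy[prs[k, 1], prs[k, 2]] <- raw$dxy[k]
            dxy[prs[k, 2], prs[k, 1]] <- raw$dxy[k]
        }
    }
    new("SimTruth",
        nVariable = as.numeric(raw$n_variable),
        nMultiallelic = as.numeric(raw$n_multiallelic),
        dxy = dxy,
        introgressedFraction = introgressedFraction(iv, L),
        migrantIntervals = iv,
        topoTracts = tracts,
        cGeneMean = L / max(1, raw$n_trees),
        L = L)
}

#' Merge overlapping or adjacent half-open intervals
#'
#' @param intervals two-column matrix of `[left, right)` intervals.
#' @return merged, sorted matrix.
#' @export
mergeIntervals <- function(intervals) {
    if (nrow(intervals) == 0L) return(intervals)
    o <- order(intervals[, 1L])
    intervals <- intervals[o, , drop = FALSE]
    out <- intervals[1L, , drop = FALSE]
    for (i in seq_len(nrow(intervals) - 1L) + 1L) {
        if (intervals[i, 1L] <= out[nrow(out), 2L])
            out[nrow(out), 2L] <- max(out[nrow(out), 2L], intervals[i, 2L])
        else out <- rbind(out, intervals[i, , drop = FALSE])
    }
    out
}

#' Fraction of a chromosome covered by migrant-ancestry intervals
#'
#' @param intervals two-column matrix of `[left, right)` intervals (bp).
#' @param L chromosome length.
#' @return fraction in `[0, 1]`.
#' @examples
#' introgressedFraction(cbind(100, 200), L = 1000)  # 0.1
#' @export
introgressedFraction <- function(intervals, L) {
    if (nrow(intervals) == 0L) return(0)
    iv <- mergeIntervals(intervals)
    sum(iv[, 2L] - iv[, 1L]) / L
}

#' Merge adjacent equal-topology local-tree intervals into tracts
#'
#' @param runs data.frame with columns `left`, `right`, `topology` in
#'   genomic order.
#' @return data.frame of merged single-topology tracts.
#' @export
mergeTopologyTracts <- function(runs) {
    if (nrow(runs) == 0L) return(runs)
    new <- c(TRUE, runs$topology[-1L] != runs$topology[-nrow(runs)])
    grp <- cumsum(new)
    data.frame(left = tapply(runs$left, grp, min),
               right = tapply(runs$right, grp, max),
               topology = runs$topology[new],
               row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth (L =", format(object@L, big.mark = ","), "bp)\n")
    cat(sprintf("  variable sites: %g (multi-allelic: %g)\n",
                object@nVariable, object@nMultiallelic))
    cat(sprintf("  introgressed fraction: %.4f over %d interval(s)\n",
                object@introgressedFraction, nrow(object@migrantIntervals)))
    cat(sprintf("  single-topology tracts: %d (mean %.0f bp); mean c-gene %.1f bp\n",
                nrow(object@topoTracts),
                if (nrow(object@topoTracts))
                    mean(object@topoTracts$right - object@topoTracts$left)
                else object@L, object@cGeneMean))
    cat("  dxy(P1,P2) =", signif(object@dxy["P1", "P2"], 4), "\n")
})

#' Mean single-topology tract length
#'
#' @param truth a [SimTruth-class].
#' @return mean tract length in bp (the full chromosome length when the
#'   whole chromosome shares one topology).
#' @export
meanTractLength <- function(truth) {
    if (nrow(truth@topoTracts) == 0L) return(truth@L)
    mean(truth@topoTracts$right - truth@topoTracts$left)
}
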