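#' Construct a simulation scenario
#'
#' Defaults reproduce the central simulated condition: a 20-Mbp chromosome,
#' four species with five diploid samples each, constant diploid Ne, uniform
#' recombination at 1e-8, HKY mutations with kappa = 2, P3/P4 branching 1e7
#' and 2e7 generations before the P1/P2 split, and a symmetric P2-P3
#' migration window opening at the P1/P2 split and closing 2.5e6 generations
#' later (toward the present).
#'
#' @param tSplit P1/P2 divergence (generations ago); canonical values
#'   1e7, 2e7, 3e7.
#' @param Ne diploid effective population size (1e4 or 1e5 canonical).
#' @param m symmetric P2-P3 migration rate per individual per generation
#'   (canonical grid: 0, 1e-9, 1e-8, 1e-7, 1e-6).
#' @param r recombination rate per site per generation.
#' @param mu mutation rate per site per generation (1e-9 or 2e-9 canonical).
#' @param kappa HKY transition/transversion ratio.
#' @param s P2 branch rate scale factor (canonical: 0.25, 0.5, 1, 2, 4).
#' @param L chromosome length in bp.
#' @param nDip diploid samples per species.
#' @param migDuration migration window length in generations.
#' @param gapP3,gapP4 generations between the P1/P2 split and the P3 / P4
#'   splits.
#' @param seed integer random seed.
#' @return a [ScenarioConfig-class].
#' @examples
#' cfg <- scenarioConfig(tSplit = 1e7, s = 0.25, L = 1e6, seed = 7)
#' @export
scenarioConfig <- function(tSplit = 1e7, Ne = 1e5, m = 0, r = 1e-8,
                           mu = 2e-9, kappa = 2, s = 1, L = 2e7,
                           nDip = 5L, migDuration = 2.5e6,
                           gapP3 = 1e7, gapP4 = 2e7, seed = 1L) {
    new("ScenarioConfig", tSplit = tSplit, gapP3 = gapP3, gapP4 = gapP4,
        Ne = Ne, m = m, migDuration = migDuration, r = r, mu = mu,
        kappa = kappa, s = s, L = L, nDip = as.integer(nDip),
        seed = as.integer(seed))
}

#' Expand a parameter grid into scenario configurations
#'
#' Takes lists of parameter values and returns one [ScenarioConfig-class]
#' per combination of the cross-product, with seeds incremented per
#' replicate. The canonical study grid
#' (`tSplit` in \{1e7, 2e7, 3e7\} x `Ne` in \{1e4, 1e5\} x
#' `m` in \{0, 1e-9, 1e-8, 1e-7, 1e-6\} x `mu` in \{1e-9, 2e-9\} x
#' `s` in \{0.25, 0.5, 1, 2, 4\}) yields 300 parameter combinations.
#'
#' @param tSplit,Ne,m,mu,s vectors of parameter values to cross.
#' @param replicates number of replicate seeds per combination.
#' @param seed base seed; replicate seeds count up from it.
#' @param ... further arguments passed to [scenarioConfig()] (e.g. `L`).
#' @return list of [ScenarioConfig-class] objects.
#' @export
scenarioGrid <- function(tSplit = c(1e7, 2e7, 3e7), Ne = c(1e4, 1e5),
                         m = c(0, 1e-9, 1e-8, 1e-7, 1e-6),
                         mu = c(1e-9, 2e-9), s = c(0.25, 0.5, 1, 2, 4),
                         replicates = 1L, seed = 1L, ...) {
    grid <- expand.grid(tSplit = tSplit, Ne = Ne, m = m, mu = mu, s = s,
                        rep = seq_len(replicates))
    out <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        out[[i]] <- scenarioConfig(tSplit = grid$tSplit[i], Ne = grid$Ne[i],
                                   m = grid$m[i], mu = grid$mu[i],
                                   s = grid$s[i],
                                   seed = seed + i - 1L, ...)
    }
    attr(out, "grid") <- grid
    out
}

#' @describeIn scenarioConfig round-trip a scenario through JSON
#' @param config a [ScenarioConfig-class].
#' @param file path to write to (or read from, for `readScenarioConfig`).
#' @export
writeScenarioConfig <- function(config, file) {
    sl <- slotNames(config)
    x <- stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
    invisible(file)
}

#' @describeIn scenarioConfig read a scenario from JSON
#' @export
readScenarioConfig <- function(file) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    do.call(scenarioConfig, x)
}

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf(
        "ScenarioConfig: tSplit=%g Ne=%g m=%g mu=%g r=%g s=%g L=%g nDip=%d seed=%d\n",
        object@tSplit, object@Ne, object@m, object@mu, object@r, object@s,
        object@L, object@nDip, object@seed))
})
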