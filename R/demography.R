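#' Build an explicit demography specification from a scenario
#'
#' Translates a [ScenarioConfig-class] into an explicit list of populations,
#' split events, sampling times and the migration window, applying the
#' sampling-time work-around that realizes the P2 branch-rate scale factor s
#' without branch-specific mutation rates:
#' \itemize{
#'   \item `s < 1`: P2 is sampled `(1 - s) * tSplit` generations in the past
#'     (its terminal branch, and hence its mutation input, is shortened by
#'     the factor s); all other tips are sampled at the present.
#'   \item `s = 1`: all tips sampled at the present.
#'   \item `s > 1`: all divergence times and the migration window are
#'     shifted `(s - 1) * tSplit` generations into the past; P2 is sampled
#'     at the present while P1, P3 and P4 are sampled at the shift time, so
#'     only the P2 terminal branch is extended.
#' }
#' Symmetric P2-P3 migration at rate `m` is active only inside the (possibly
#' shifted) window, which opens at the P1/P2 divergence and closes
#' `migDuration` generations later toward the present.
#'
#' The alternative `rateScaling = "branch_rate"` skips the work-around and
#' requests a genuinely scaled mutation rate on the P2 terminal branch from
#' the simulation engine (useful to cross-validate the work-around).
#'
#' @param config a [ScenarioConfig-class].
#' @param rateScaling `"sampling_time"` (default) or `"branch_rate"`.
#' @return a list with elements `populations`, `splits`, `samples`,
#'   `migration` and `mutation` understood by [simulateDataset()].
#' @examples
#' dem <- buildDemography(scenarioConfig(tSplit = 1e7, s = 0.25))
#' dem$samples   # P2 sampled 7.5e6 generations in the past
#' @export
buildDemography <- function(config,
                            rateScaling = c("sampling_time", "branch_rate")) {
    rateScaling <- match.arg(rateScaling)
    validObject(config)
    t1 <- config@tSplit
    useWorkaround <- rateScaling == "sampling_time"
    shift <- if (useWorkaround && config@s > 1) (config@s - 1) * t1 else 0
    T1 <- t1 + shift
    T2 <- t1 + config@gapP3 + shift
    T3 <- t1 + config@gapP4 + shift
    tP2 <- if (useWorkaround && config@s < 1) (1 - config@s) * t1 else 0
    tOther <- shift
    migStart <- T1 - config@migDuration   # recent edge of the window
    migEnd <- T1                          # old edge = the P1/P2 divergence
    if (migStart < 0)
        stop("migration window extends beyond the present")
    pops <- c("P1", "P2", "P3", "P4", "anc12", "anc123", "anc1234")
    list(
        populations = lapply(pops, function(p)
            list(name = p, size = config@Ne)),
        splits = list(
            list(time = T1, derived = c("P1", "P2"), ancestral = "anc12"),
            list(time = T2, derived = c("anc12", "P3"), ancestral = "anc123"),
            list(time = T3, derived = c("anc123", "P4"), ancestral = "anc1234")),
        samples = list(
            list(population = "P1", n = config@nDip, time = tOther),
            list(population = "P2", n = config@nDip, time = tP2),
            list(population = "P3", n = config@nDip, time = tOther),
            list(population = "P4", n = config@nDip, time = tOther)),
        migration = list(rate = config@m, between = c("P2", "P3"),
                         start = migStart, end = migEnd),
        mutation = list(mu = config@mu, kappa = config@kappa,
                        rateScaling = rateScaling,
                        p2RateScale = if (useWorkaround) 1 else config@s))
}
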