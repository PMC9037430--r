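#' Build a plate-simulation configuration
#'
#' Defaults emulate a continuous-read viability experiment: 300 cells seeded
#' per well, a 24 h doubling time, readings every 4 h for 120 h, 3 replicate
#' wells, an 8-point half-log dilution series, and 5% multiplicative
#' measurement noise. Reagent consumption (`gamma`) is set so the undrugged
#' trace rises, stays linear through most of the assay and peaks near 90 h;
#' `aScale` fixes the signal at 100 RLU per cell. The count channel images a
#' tenth of each well, mimicking montage imaging of a well subregion.
#'
#' @param n0 initial cells per well.
#' @param doublingTimeH undrugged population doubling time, hours.
#' @param drugParams `data.frame` with columns `cell_line`, `drug`, `emax`,
#'   `ec50_M`, `hill` (optional `e0`, default 1): the programmed
#'   dose-response of the growth rate.
#' @param concentrationsM drugged concentrations in molar (all > 0); the
#'   zero-concentration control is added automatically per cell line.
#' @param gamma reagent consumption, per cell per hour.
#' @param aScale RLU per live cell at full reagent.
#' @param cv coefficient of variation of the multiplicative measurement
#'   noise.
#' @param imagedFraction fraction of the well counted on the count channel.
#' @param sampleIntervalH,durationH sampling interval and assay length,
#'   hours. Use `sampleIntervalH = 12, durationH = 100` for the sparser
#'   incubator-transfer protocol.
#' @param nReplicates replicate wells per condition.
#' @param seed RNG seed; simulation is fully deterministic given the seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(n0 = 300,
                             doublingTimeH = 24,
                             drugParams = data.frame(
                                 cell_line = "SIM1", drug = "drugA",
                                 emax = -0.5, ec50_M = 1e-8, hill = 1),
                             concentrationsM = 10^seq(-10.5, -7, by = 0.5),
                             gamma = 7e-6,
                             aScale = 100,
                             cv = 0.05,
                             imagedFraction = 0.1,
                             sampleIntervalH = 4,
                             durationH = 120,
                             nReplicates = 3L,
                             seed = 1L) {
    if (!"e0" %in% colnames(drugParams)) drugParams$e0 <- 1
    new("SimulationConfig", n0 = n0, doublingTimeH = doublingTimeH,
        drugParams = drugParams, concentrationsM = concentrationsM,
        gamma = gamma, aScale = aScale, cv = cv,
        imagedFraction = imagedFraction,
        sampleIntervalH = sampleIntervalH, durationH = durationH,
        nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Programmed growth rate as a function of drug concentration
#'
#' The simulator makes the exponential growth rate itself log-logistic in
#' concentration:
#' \deqn{k(c) = k_0 \left[E_{max} + (E_0 - E_{max}) / (1 + (c/EC_{50})^h)\right]}
#' with \eqn{k_0 = \ln 2 / \mathrm{doubling time}}. At `c = 0` this is
#' exactly `k0` (for `e0 = 1`); at saturating dose it tends to
#' `emax * k0`, negative for a cytotoxic drug.
#'
#' @param concentrationM molar concentration(s), >= 0.
#' @param emax,ec50M,hill,e0 programmed dose-response parameters.
#' @param doublingTimeH undrugged doubling time in hours.
#' @return Growth rate(s) in per hour.
#' @export
growthRate <- function(concentrationM, emax, ec50M, hill, e0 = 1,
                       doublingTimeH = 24) {
    stopifnot(all(concentrationM >= 0), ec50M > 0, hill > 0,
              doublingTimeH > 0)
    k0 <- log(2) / doublingTimeH
    k0 * (emax + (e0 - emax) / (1 + (concentrationM / ec50M)^hill))
}

#' Noise-free luminescence trace under reagent depletion
#'
#' Live cells `N(t) = n0 exp(k t)` consume the assay reagent at `gamma` per
#' cell per hour, so the remaining reagent fraction is
#' \deqn{R(t) = \exp\!\left(-\gamma n_0 (e^{kt} - 1)/k\right)}
#' (`exp(-gamma n0 t)` in the limit `k = 0`), and the signal is
#' `L(t) = aScale * N(t) * R(t)`. The product rises, peaks and declines: the
#' interior peak sits at `t* = ln(k / (gamma n0)) / k` whenever
#' `k > gamma * n0`, else the trace is monotone on `t >= 0`.
#'
#' @param t time(s) in hours.
#' @param k growth rate, per hour.
#' @param n0,gamma,aScale see [simulationConfig()].
#' @return RLU value(s).
#' @export
luminescenceCurve <- function(t, k, n0 = 300, gamma = 7e-6, aScale = 100) {
    stopifnot(n0 > 0, gamma >= 0, aScale > 0)
    N <- n0 * exp(k * t)
    depleted <- if (k == 0) gamma * n0 * t
                else gamma * n0 * (exp(k * t) - 1) / k
    aScale * N * exp(-depleted)
}

#' Analytic peak time of the noise-free luminescence trace
#'
#' @inheritParams luminescenceCurve
#' @return Peak time in hours, or `NA` when no interior peak exists
#'   (`k <= gamma * n0`, including all non-growing populations).
#' @export
analyticPeakTime <- function(k, n0 = 300, gamma = 7e-6) {
    if (gamma <= 0 || k <= gamma * n0) return(NA_real_)
    log(k / (gamma * n0)) / k
}

#' Simulate a complete assay plate with ground truth
#'
#' Generates every (cell line, drug, concentration, replicate) well of the
#' configured screen: exponential growth at the programmed log-logistic rate,
#' reagent-depletion luminescence, truncated multiplicative Gaussian noise
#' (`RLU >= 0`), and a count channel obtained by binomial imaging of
#' `imagedFraction` of the well, scaled back up. One control
#' (zero-concentration, drug `"control"`) condition is generated per cell
#' line. Fully deterministic given `config@seed`.
#'
#' @param config A [SimulationConfig-class] (see [simulationConfig()]).
#' @return list with `plate` (a [LumPlate-class]; metadata records the seed
#'   and interval) and `truth` (`data.frame` per condition: programmed
#'   `rate_h` = k(c), `normalized_response` = k(c)/k0, and analytic
#'   luminescence `peak_h`, `NA` when the trace has no interior peak).
#' @export
simulatePlate <- function(config = simulationConfig()) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    times <- seq(0, config@durationH, by = config@sampleIntervalH)
    k0 <- log(2) / config@doublingTimeH
    dp <- config@drugParams
    rows <- list(); truth <- list()

    simWell <- function(cl, drug, conc, rep_, k) {
        L <- luminescenceCurve(times, k, config@n0, config@gamma,
                               config@aScale)
        if (config@cv > 0)
            L <- L * pmax(1 + stats::rnorm(length(times), 0, config@cv), 0)
        N <- round(config@n0 * exp(k * times))
        count <- if (config@imagedFraction < 1)
            round(stats::rbinom(length(times), N,
                                config@imagedFraction) /
                  config@imagedFraction)
        else N
        data.frame(cell_line = cl, drug = drug, concentration_M = conc,
                   replicate = rep_, time_h = times, rlu = L, count = count)
    }

    for (cl in unique(dp$cell_line)) {
        for (r in seq_len(config@nReplicates))
            rows[[length(rows) + 1L]] <-
                simWell(cl, "control", 0, r, k0)
        truth[[length(truth) + 1L]] <- data.frame(
            cell_line = cl, drug = "control", concentration_M = 0,
            rate_h = k0, normalized_response = 1,
            peak_h = analyticPeakTime(k0, config@n0, config@gamma))
        for (i in which(dp$cell_line == cl)) {
            for (conc in config@concentrationsM) {
                k <- growthRate(conc, dp$emax[i], dp$ec50_M[i], dp$hill[i],
                                dp$e0[i], config@doublingTimeH)
                for (r in seq_len(config@nReplicates))
                    rows[[length(rows) + 1L]] <-
                        simWell(cl, dp$drug[i], conc, r, k)
                truth[[length(truth) + 1L]] <- data.frame(
                    cell_line = cl, drug = dp$drug[i],
                    concentration_M = conc, rate_h = k,
                    normalized_response = k / k0,
                    peak_h = analyticPeakTime(k, config@n0, config@gamma))
            }
        }
    }
    plate <- LumPlate(do.call(rbind, rows),
                      metadata = list(simulated = TRUE, seed = config@seed,
                                      interval_h = config@sampleIntervalH))
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(plate = plate, truth = truth)
}

#' Write the simulator's ground-truth sidecar table
#'
#' @param truth the `truth` component of [simulatePlate()]'s result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
    utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
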