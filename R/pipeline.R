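#' Run the full analysis pipeline
#'
#' Chains every stage on one input: plate acquisition (read a long CSV, or
#' simulate one), rate extraction on the luminescence channel (and the count
#' channel when present), basal-rate normalization and dose-response fitting,
#' and — when both channels exist — the cross-channel Wilcoxon/concordance
#' comparison. All outputs are plain CSV/JSON in `outDir`; running twice with
#' the same input and seed reproduces them byte for byte.
#'
#' Files written: `plate.csv` + `ground_truth.csv` (simulation only),
#' `rates_lum.csv`, `result_table.csv`, and with a count channel also
#' `rates_count.csv` and `compare.json`.
#'
#' @param input path to a long-format plate CSV, or `NULL` to simulate.
#' @param outDir output directory, created if needed.
#' @param config [SimulationConfig-class] used when `input` is `NULL`.
#' @param seed overrides `config@seed` when simulating.
#' @param schema [plateSchema()] for reading `input`.
#' @param minPoints,perReplicate,linearityThreshold see [plateRates()].
#' @param fitConfig,tolZero,tolOne see [fit4PL()].
#' @param alpha level for the comparison's critical value.
#' @param quiet suppress progress messages (they go to `stderr`).
#' @return Invisibly, a list with `plate`, `rates` (per channel), `fits`,
#'   `table`, `comparison` (or `NULL`) and `paths` of everything written.
#' @export
runPipeline <- function(input = NULL, outDir,
                        config = simulationConfig(), seed = NULL,
                        schema = plateSchema(), minPoints = 5L,
                        perReplicate = FALSE, linearityThreshold = 0.9,
                        fitConfig = fit4plConfig(), tolZero = 0.1,
                        tolOne = 0.1, alpha = 0.05, quiet = FALSE) {
    say <- function(...) if (!quiet) message(...)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    if (is.null(input)) {
        if (!is.null(seed)) config@seed <- as.integer(seed)
        say("simulating plate (seed ", config@seed, ")")
        sim <- simulatePlate(config)
        plate <- sim$plate
        paths$plate <- writePlate(plate, file.path(outDir, "plate.csv"))
        paths$ground_truth <- writeGroundTruth(
            sim$truth, file.path(outDir, "ground_truth.csv"))
    } else {
        say("reading plate from ", input)
        plate <- readPlate(input, schema)
    }

    channels <- c("lum", if ("count" %in% assayNames(plate)) "count")
    rates <- list(); fits <- list(); tables <- list()
    for (ch in channels) {
        say("extracting ", ch, " rates")
        r <- plateRates(plate, channel = ch, minPoints = minPoints,
                        perReplicate = perReplicate,
                        linearityThreshold = linearityThreshold)
        rates[[ch]] <- r
        paths[[paste0("rates_", ch)]] <-
            writeRates(r, file.path(outDir, paste0("rates_", ch, ".csv")))
        dt <- if (ch == "lum") "Lum" else "Direct"
        say("fitting dose-response curves (", dt, ")")
        f <- fitDoseResponse(r, dataType = dt, config = fitConfig,
                             tolZero = tolZero, tolOne = tolOne)
        fits[[ch]] <- f$fits
        tables[[ch]] <- f$table
    }
    table <- do.call(rbind, unname(tables))
    paths$result_table <- writeResultTable(
        table, file.path(outDir, "result_table.csv"))

    comparison <- NULL
    if (length(channels) == 2L) {
        say("comparing channels")
        comparison <- compareChannels(table, alpha = alpha,
                                      ec50Bounds = fitConfig$ec50Bounds,
                                      tolZero = tolZero, tolOne = tolOne)
        report <- list(
            w = comparison$w, p = comparison$p, n = comparison$n,
            critical_value = comparison$critical_value,
            significant = comparison$significant,
            n_pairs = comparison$concordance$n_pairs,
            n_concordant = comparison$concordance$n_concordant,
            discordant_keys = comparison$concordance$discordant_keys)
        paths$compare <- file.path(outDir, "compare.json")
        jsonlite::write_json(report, paths$compare, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    }
    invisible(list(plate = plate, rates = rates, fits = fits,
                   table = table, comparison = comparison, paths = paths))
}

# Build a SimulationConfig from a YAML list (CLI support); flags already
# parsed by the caller win over file values.
.configFromYaml <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$drug_params))
        cfg$drugParams <- do.call(rbind, lapply(cfg$drug_params,
                                                as.data.frame))
    cfg$drug_params <- NULL
    known <- names(formals(simulationConfig))
    do.call(simulationConfig, cfg[intersect(names(cfg), known)])
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `rates`, `fit`, `compare` and `pipeline`
#' subcommands over the package's functions; the installed script
#' `inst/scripts/luminrate` forwards `commandArgs()` here and quits with the
#' returned status. Diagnostics go to `stderr`; results only to files.
#'
#' @param args character vector of command-line arguments
#'   (subcommand first).
#' @return Integer exit code: 0 on success, 1 on a processing/validation
#'   error, 2 on a usage error.
#' @examples
#' \dontrun{
#' luminrateCLI(c("pipeline", "--simulate", "--seed", "7",
#'                "--out", tempdir()))
#' }
#' @export
luminrateCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
    usage <- function() {
        message("usage: luminrate <simulate|rates|fit|compare|pipeline> [options]")
        2L
    }
    if (!length(args) || args[1] %in% c("-h", "--help")) return(usage())
    sub <- args[1]; rest <- args[-1]
    if (!sub %in% c("simulate", "rates", "fit", "compare", "pipeline"))
        return(usage())

    mkParser <- function(opts) optparse::OptionParser(
        option_list = opts, add_help_option = TRUE,
        prog = paste("luminrate", sub))
    o <- optparse::make_option

    parsed <- tryCatch(switch(sub,
        simulate = optparse::parse_args(mkParser(list(
            o("--out", type = "character", default = "."),
            o("--seed", type = "integer", default = 1L),
            o("--config", type = "character", default = NULL))), rest),
        rates = optparse::parse_args(mkParser(list(
            o("--input", type = "character"),
            o("--out", type = "character", default = "rates.csv"),
            o("--channel", type = "character", default = "lum"),
            o("--min-points", type = "integer", default = 5L,
              dest = "min_points"),
            o("--per-replicate", action = "store_true", default = FALSE,
              dest = "per_replicate"),
            o("--linearity-threshold", type = "double", default = 0.9,
              dest = "linearity_threshold"),
            o("--schema", type = "character", default = NULL))), rest),
        fit = optparse::parse_args(mkParser(list(
            o("--input", type = "character"),
            o("--out", type = "character", default = "result_table.csv"),
            o("--data-type", type = "character", default = "Lum",
              dest = "data_type"),
            o("--emax-floor", type = "double", default = -5,
              dest = "emax_floor"),
            o("--hill-max", type = "double", default = 15,
              dest = "hill_max"),
            o("--tol-zero", type = "double", default = 0.1,
              dest = "tol_zero"),
            o("--tol-one", type = "double", default = 0.1,
              dest = "tol_one"))), rest),
        compare = optparse::parse_args(mkParser(list(
            o("--input", type = "character"),
            o("--input-b", type = "character", default = NULL,
              dest = "input_b"),
            o("--out", type = "character", default = "compare.json"),
            o("--alpha", type = "double", default = 0.05))), rest),
        pipeline = optparse::parse_args(mkParser(list(
            o("--input", type = "character", default = NULL),
            o("--simulate", action = "store_true", default = FALSE),
            o("--seed", type = "integer", default = 1L),
            o("--out", type = "character", default = "."),
            o("--config", type = "character", default = NULL),
            o("--min-points", type = "integer", default = 5L,
              dest = "min_points"))), rest)),
        error = function(e) e)
    if (inherits(parsed, "error") || inherits(parsed, "condition")) {
        message("argument error: ", conditionMessage(parsed))
        return(2L)
    }

    run <- function(expr) tryCatch({ expr; 0L }, error = function(e) {
        message("error: ", conditionMessage(e))
        1L
    })
    message("luminrate ", sub, " | ",
            paste(sprintf("%s=%s", names(parsed),
                          vapply(parsed, function(v)
                              paste(format(v), collapse = ","),
                              character(1))),
                  collapse = " "))
    switch(sub,
        simulate = run({
            cfg <- if (!is.null(parsed$config))
                .configFromYaml(parsed$config) else simulationConfig()
            cfg@seed <- parsed$seed
            sim <- simulatePlate(cfg)
            dir.create(parsed$out, showWarnings = FALSE, recursive = TRUE)
            writePlate(sim$plate, file.path(parsed$out, "plate.csv"))
            writeGroundTruth(sim$truth,
                             file.path(parsed$out, "ground_truth.csv"))
        }),
        rates = run({
            if (is.null(parsed$input)) stop("--input is required")
            schema <- if (!is.null(parsed$schema))
                readSchema(parsed$schema) else plateSchema()
            plate <- readPlate(parsed$input, schema)
            writeRates(plateRates(plate, channel = parsed$channel,
                                  minPoints = parsed$min_points,
                                  perReplicate = parsed$per_replicate,
                                  linearityThreshold =
                                      parsed$linearity_threshold),
                       parsed$out)
        }),
        fit = run({
            if (is.null(parsed$input)) stop("--input is required")
            rates <- readRates(parsed$input)
            cfg <- fit4plConfig(emaxFloor = parsed$emax_floor,
                                hillMax = parsed$hill_max)
            res <- fitDoseResponse(rates, dataType = parsed$data_type,
                                   config = cfg,
                                   tolZero = parsed$tol_zero,
                                   tolOne = parsed$tol_one)
            writeResultTable(res$table, parsed$out)
        }),
        compare = run({
            if (is.null(parsed$input)) stop("--input is required")
            tab <- readResultTable(parsed$input)
            tabB <- if (!is.null(parsed$input_b))
                readResultTable(parsed$input_b)
            cmp <- compareChannels(tab, tableB = tabB,
                                   alpha = parsed$alpha)
            jsonlite::write_json(
                list(w = cmp$w, p = cmp$p, n = cmp$n,
                     critical_value = cmp$critical_value,
                     significant = cmp$significant,
                     n_pairs = cmp$concordance$n_pairs,
                     n_concordant = cmp$concordance$n_concordant,
                     discordant_keys = cmp$concordance$discordant_keys),
                parsed$out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        }),
        pipeline = run({
            if (is.null(parsed$input) && !parsed$simulate)
                stop("give --input or --simulate")
            cfg <- if (!is.null(parsed$config))
                .configFromYaml(parsed$config) else simulationConfig()
            runPipeline(input = parsed$input, outDir = parsed$out,
                        config = cfg, seed = parsed$seed,
                        minPoints = parsed$min_points, quiet = FALSE)
        }))
}
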