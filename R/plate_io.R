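#' Column schema for plate-reader CSV exports
#'
#' Instrument exports vary in column naming and units; a schema maps them onto
#' the canonical long format (`cell_line`, `drug`, `concentration_M`,
#' `replicate`, `time_h`, `rlu`, optional `count`). Multipliers convert the
#' file's units to hours and molar (e.g. `time_multiplier = 1/60` for
#' minutes, `concentration_multiplier = 1e-6` for micromolar). Rows whose drug
#' matches a `control_alias` (case-insensitive) are treated as vehicle
#' controls: their concentration is set to 0.
#'
#' @param columns named list mapping canonical names to file column names.
#'   Omitted entries default to the canonical name itself.
#' @param control_aliases drug names to be coerced to concentration 0.
#' @param time_multiplier,concentration_multiplier unit conversion factors
#'   applied on read.
#' @return A list of class `plate_schema`.
#' @seealso [readSchema()] to load one from a YAML file, [readPlate()].
#' @export
plateSchema <- function(columns = list(),
                        control_aliases = c("control", "vehicle", "dmso",
                                            "pbs"),
                        time_multiplier = 1,
                        concentration_multiplier = 1) {
    canon <- c("cell_line", "drug", "concentration_M", "replicate",
               "time_h", "rlu", "count")
    bad <- setdiff(names(columns), canon)
    if (length(bad))
        stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    cols <- as.list(stats::setNames(canon, canon))
    cols[names(columns)] <- columns
    structure(list(columns = cols,
                   control_aliases = tolower(control_aliases),
                   time_multiplier = time_multiplier,
                   concentration_multiplier = concentration_multiplier),
              class = "plate_schema")
}

#' Load a plate schema from a YAML config
#'
#' Reads a structured config with optional keys `columns` (map),
#' `control_aliases` (list), `time_multiplier` and
#' `concentration_multiplier`.
#'
#' @param path YAML file path.
#' @return A `plate_schema` (see [plateSchema()]).
#' @export
readSchema <- function(path) {
    cfg <- yaml::read_yaml(path)
    do.call(plateSchema, c(
        list(columns = if (is.null(cfg$columns)) list() else cfg$columns),
        cfg[intersect(names(cfg),
                      c("control_aliases", "time_multiplier",
                        "concentration_multiplier"))]))
}

#' Read a long-format plate CSV
#'
#' Parses a plate-reader export in long (tidy) layout — one row per well and
#' timepoint — into a [LumPlate-class], applying the schema's column mapping
#' and unit conversions and validating the result (monotone times per well,
#' nonnegative RLU, unique condition keys).
#'
#' @param path CSV file with a header row.
#' @param schema a [plateSchema()]; the default assumes canonical column
#'   names, hours and molar.
#' @param metadata free-form plate metadata list, stored on the object.
#' @return A validated [LumPlate-class].
#' @export
readPlate <- function(path, schema = plateSchema(), metadata = list()) {
    stopifnot(inherits(schema, "plate_schema"))
    raw <- utils::read.csv(path, check.names = FALSE)
    cols <- schema$columns
    need <- setdiff(unlist(cols[c("cell_line", "drug", "concentration_M",
                                  "replicate", "time_h", "rlu")]),
                    colnames(raw))
    if (length(need))
        stop("schema error: missing column(s) ",
             paste(sQuote(need), collapse = ", "), " in ", path)
    df <- data.frame(cell_line = as.character(raw[[cols$cell_line]]),
                     drug = as.character(raw[[cols$drug]]),
                     concentration_M = as.numeric(raw[[cols$concentration_M]]) *
                         schema$concentration_multiplier,
                     replicate = as.numeric(raw[[cols$replicate]]),
                     time_h = as.numeric(raw[[cols$time_h]]) *
                         schema$time_multiplier,
                     rlu = as.numeric(raw[[cols$rlu]]))
    if (cols$count %in% colnames(raw))
        df$count <- as.numeric(raw[[cols$count]])
    ctrl <- tolower(df$drug) %in% schema$control_aliases
    df$concentration_M[ctrl] <- 0
    LumPlate(df, metadata = metadata)
}

#' Write a LumPlate as a long-format CSV
#'
#' @param x A [LumPlate-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [readPlate()]; `readPlate(writePlate(x, f))` reproduces `x`'s
#'   wells field-for-field.
#' @export
writePlate <- function(x, path) {
    utils::write.csv(asLongTable(x), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.result_table_cols <- c("cell_line", "drug", "data_type", "hill_coef",
                        "max_resp", "ec50_M", "residuals")

.validateResultTable <- function(table) {
    miss <- setdiff(.result_table_cols, colnames(table))
    if (length(miss))
        stop("result table missing column(s): ",
             paste(miss, collapse = ", "))
    key <- paste(table$cell_line, table$drug, table$data_type)
    if (anyDuplicated(key))
        stop("duplicate (cell_line, drug, data_type) row(s): ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    invisible(table)
}

#' Write a dose-response parameter table
#'
#' Serializes the per-condition fit parameters (Hill coefficient, maximal
#' response, EC50 in molar, residual sum of squares) with one row per
#' (cell line, drug, data type) and full numeric precision.
#'
#' @param table `data.frame` with columns `cell_line`, `drug`, `data_type`
#'   (`"Lum"` or `"Direct"`), `hill_coef`, `max_resp`, `ec50_M`, `residuals`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(table, path) {
    .validateResultTable(table)
    out <- table[, .result_table_cols]
    for (col in c("hill_coef", "max_resp", "ec50_M", "residuals"))
        out[[col]] <- format(out[[col]], digits = 15, trim = TRUE,
                             scientific = NA)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a dose-response parameter table written by [writeResultTable()]
#'
#' @param path CSV path.
#' @return `data.frame` with the canonical result-table columns.
#' @export
readResultTable <- function(path) {
    tab <- utils::read.csv(path, colClasses = c(
        cell_line = "character", drug = "character",
        data_type = "character", hill_coef = "numeric",
        max_resp = "numeric", ec50_M = "numeric", residuals = "numeric"))
    .validateResultTable(tab)
    tab
}

#' Write / read a per-condition rates table
#'
#' The rates CSV records, per condition, the extracted rate with its
#' provenance: the full-window R squared of the winning slice, the slice's
#' time bounds and point count.
#'
#' @param rates `data.frame` as produced by [plateRates()], with columns
#'   `cell_line`, `drug`, `concentration_M`, `replicate`, `rate`, `r2`,
#'   `slice_start_h`, `slice_end_h`, `n_points`.
#' @param path CSV path.
#' @return `path` (write) or the `data.frame` (read), invisibly for write.
#' @export
writeRates <- function(rates, path) {
    need <- c("cell_line", "drug", "concentration_M", "replicate", "rate",
              "r2", "slice_start_h", "slice_end_h", "n_points")
    miss <- setdiff(need, colnames(rates))
    if (length(miss))
        stop("rates table missing column(s): ", paste(miss, collapse = ", "))
    out <- rates[, need]
    for (col in c("concentration_M", "rate", "r2"))
        out[[col]] <- format(out[[col]], digits = 15, trim = TRUE,
                             scientific = NA)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeRates
#' @export
readRates <- function(path) {
    utils::read.csv(path, colClasses = c(
        cell_line = "character", drug = "character",
        concentration_M = "numeric", replicate = "numeric",
        rate = "numeric", r2 = "numeric", slice_start_h = "numeric",
        slice_end_h = "numeric", n_points = "integer"))
}

#' Reference two-channel SCLC screen parameters
#'
#' Best-fit dose-response parameters from a small-cell lung cancer drug
#' screen in which two cell lines (H1048, H841) were profiled against six
#' kinase and survivin inhibitors with response measured simultaneously by
#' continuous luminescence (`data_type == "Lum"`) and by direct cell counting
#' (`data_type == "Direct"`), plus luminescence-only rows for six further
#' lines. Shipped as a plain-text fixture; used as the worked example for the
#' cross-channel comparison functions ([wilcoxonExact()],
#' [mechanismConcordance()]).
#'
#' @return `data.frame` in the result-table layout of [readResultTable()].
#' @examples
#' panel <- sclcPanel()
#' table(panel$data_type)
#' @export
sclcPanel <- function() {
    readResultTable(system.file("extdata", "sclc_screen_params.csv",
                                package = "luminrate", mustWork = TRUE))
}
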