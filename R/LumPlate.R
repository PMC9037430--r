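#' Construct a LumPlate from long-format well data
#'
#' Builds the plate container from a long table with one row per well and
#' timepoint. Wells are aligned on the union of observed times; timepoints a
#' well was not read at become `NA`.
#'
#' @param x `data.frame` with columns `cell_line`, `drug`, `concentration_M`,
#'   `replicate`, `time_h`, `rlu` and optionally `count`.
#' @param metadata named list of free-form plate metadata (instrument,
#'   sampling interval, simulation seed, ...). Set `control_free = TRUE` here
#'   to allow a plate without zero-concentration wells.
#' @return A [LumPlate-class] object.
#' @examples
#' df <- data.frame(cell_line = "A", drug = "control", concentration_M = 0,
#'                  replicate = 1, time_h = c(0, 4, 8), rlu = c(10, 20, 40))
#' LumPlate(df)
#' @export
LumPlate <- function(x, metadata = list()) {
    need <- c("cell_line", "drug", "concentration_M", "replicate",
              "time_h", "rlu")
    miss <- setdiff(need, colnames(x))
    if (length(miss))
        stop("missing column(s): ", paste(miss, collapse = ", "))
    for (col in c("concentration_M", "replicate", "time_h", "rlu"))
        if (!is.numeric(x[[col]]))
            stop("column '", col, "' must be numeric")
    key <- paste(x$cell_line, x$drug,
                 format(x$concentration_M, digits = 15), x$replicate,
                 sep = "\r")
    dup <- duplicated(cbind(key, x$time_h))
    if (any(dup))
        stop("duplicated (well, time) row(s) for well(s): ",
             paste(unique(gsub("\r", "/", key[dup])), collapse = "; "))
    if (any(!is.finite(x$rlu) | x$rlu < 0))
        stop("RLU values must be finite and nonnegative")
    times <- sort(unique(x$time_h))
    wells <- !duplicated(key)
    ukey <- key[wells]
    nr <- length(ukey); nc <- length(times)
    ridx <- match(key, ukey)
    cidx <- match(x$time_h, times)
    rlu <- matrix(NA_real_, nr, nc)
    rlu[cbind(ridx, cidx)] <- x$rlu
    assays <- list(rlu = rlu)
    if ("count" %in% colnames(x) && !all(is.na(x$count))) {
        ct <- matrix(NA_real_, nr, nc)
        ct[cbind(ridx, cidx)] <- x$count
        assays$count <- ct
    }
    rd <- DataFrame(cell_line = as.character(x$cell_line[wells]),
                    drug = as.character(x$drug[wells]),
                    concentration_M = x$concentration_M[wells],
                    replicate = x$replicate[wells])
    rownames(rd) <- sprintf("%s.%s.%g.r%d", rd$cell_line, rd$drug,
                            rd$concentration_M, as.integer(rd$replicate))
    se <- SummarizedExperiment(
        assays = assays, rowData = rd,
        colData = DataFrame(time_h = times,
                            row.names = sprintf("t%g", times)),
        metadata = metadata)
    new("LumPlate", se)
}

#' @describeIn LumPlate Well metadata (cell line, drug, concentration,
#'   replicate) as a plain `data.frame`.
#' @param object,x A `LumPlate`.
#' @export
wellInfo <- function(x) as.data.frame(rowData(x))

#' @describeIn LumPlate Plate-reader timepoints in hours.
#' @export
assayTimes <- function(x) colData(x)$time_h

#' One well's measured time course
#'
#' Extracts the (time, value) series of a single well on one channel,
#' dropping timepoints at which the well was not measured.
#'
#' @param x A [LumPlate-class].
#' @param well Row index or row name of the well.
#' @param channel `"lum"` (RLU) or `"count"` (direct cell counts).
#' @return `data.frame` with columns `time_h` and `value`, ordered by time.
#' @export
wellSeries <- function(x, well, channel = c("lum", "count")) {
    channel <- match.arg(channel)
    aname <- if (channel == "lum") "rlu" else "count"
    if (!aname %in% assayNames(x))
        stop("plate has no '", aname, "' assay")
    v <- assay(x, aname)[well, ]
    keep <- !is.na(v)
    if (sum(keep) < 2L)
        stop("well '", well, "' has fewer than 2 measured points on channel '",
             channel, "'")
    data.frame(time_h = assayTimes(x)[keep], value = unname(v[keep]))
}

#' Flatten a LumPlate back to long format
#'
#' Inverse of [LumPlate()]: one row per (well, measured timepoint), ordered by
#' well then time. Used by [writePlate()] and in round-trip tests.
#'
#' @param x A [LumPlate-class].
#' @return Long `data.frame` with the constructor's column set.
#' @export
asLongTable <- function(x) {
    rd <- wellInfo(x)
    tt <- assayTimes(x)
    rlu <- assay(x, "rlu")
    has_ct <- "count" %in% assayNames(x)
    ct <- if (has_ct) assay(x, "count")
    out <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
        keep <- !is.na(rlu[i, ])
        d <- data.frame(cell_line = rd$cell_line[i], drug = rd$drug[i],
                        concentration_M = rd$concentration_M[i],
                        replicate = rd$replicate[i],
                        time_h = tt[keep], rlu = unname(rlu[i, keep]))
        if (has_ct) d$count <- unname(ct[i, keep])
        d
    }))
    rownames(out) <- NULL
    out
}

setMethod("show", "LumPlate", function(object) {
    rd <- rowData(object)
    cat(sprintf("LumPlate: %d wells x %d timepoints (%g-%g h)\n",
                nrow(object), ncol(object),
                min(colData(object)$time_h), max(colData(object)$time_h)))
    cat(sprintf("  cell lines: %s\n",
                paste(unique(rd$cell_line), collapse = ", ")))
    cat(sprintf("  drugs: %s\n", paste(unique(rd$drug), collapse = ", ")))
    cat(sprintf("  assays: %s\n", paste(assayNames(object), collapse = ", ")))
})

setMethod("show", "SliceFit", function(object) {
    cat(sprintf("SliceFit [%d..%d] n=%d slope=%.4g r2=%.4f\n",
                object@startIndex, object@endIndex, object@nPoints,
                object@slope, object@r2))
})

setMethod("show", "RateResult", function(object) {
    cat(sprintf("RateResult %s/%s @ %g M (rep %s, %s): rate = %.5g / h\n",
                object@cellLine, object@drug, object@concentrationM,
                ifelse(is.na(object@replicate), "pooled",
                       format(object@replicate)),
                object@channel, object@rate))
    cat(sprintf("  window [%g, %g] h, slice n=%d, r2=%.4f\n",
                object@window[1], object@window[2],
                object@slice@nPoints, object@slice@r2))
    if (length(object@warnings))
        cat("  warnings:", paste(object@warnings, collapse = ", "), "\n")
})

setMethod("show", "DoseResponseFit", function(object) {
    cat(sprintf(
        "DoseResponseFit: E0=%.3f Emax=%.3f EC50=%.3g M Hill=%.3f SSE=%.4g\n",
        object@e0, object@emax, object@ec50M, object@hill, object@residuals))
    cat(sprintf("  effect: %s%s%s\n", object@effectClass,
                if (object@converged) "" else " [not converged]",
                if (length(object@boundsHit))
                    paste0(" [at bound: ",
                           paste(object@boundsHit, collapse = ","), "]")
                else ""))
})

setMethod("show", "WilcoxonResult", function(object) {
    cat(sprintf(
        "Wilcoxon signed-rank (%s): W = %g (W+ = %g, W- = %g), n = %d, two-sided p = %.7g\n",
        object@method, object@w, object@wPlus, object@wMinus,
        object@nUsed, object@pTwoSided))
})
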