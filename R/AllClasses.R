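#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' Plate container for continuous luminescence time courses
#'
#' `LumPlate` extends [SummarizedExperiment::SummarizedExperiment] to hold one
#' plate's worth of well time courses. Rows are wells (conditions), columns are
#' the plate-reader timepoints shared by the plate, and the `"rlu"` assay holds
#' relative luminescence units. An optional `"count"` assay carries direct
#' cell counts acquired on the same wells. Wells that were not read at a given
#' timepoint hold `NA`; every well must retain at least two measured points.
#'
#' Row metadata must provide `cell_line`, `drug`, `concentration_M` (molar;
#' `0` denotes the vehicle control) and `replicate`; column metadata provides
#' `time_h`, strictly increasing hours since assay start. The combination
#' (cell_line, drug, concentration_M, replicate) must be unique. Unless
#' `metadata(x)$control_free` is `TRUE`, every cell line on the plate must have
#' at least one control (zero-concentration) well, since downstream
#' normalization divides by the control ("basal") rate.
#'
#' @seealso [readPlate()], [simulatePlate()], [plateRates()]
#' @export
setClass("LumPlate", contains = "SummarizedExperiment")

.validLumPlate <- function(object) {
    msg <- character()
    rd <- rowData(object)
    need <- c("cell_line", "drug", "concentration_M", "replicate")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        return(sprintf("missing rowData column(s): %s",
                       paste(miss, collapse = ", ")))
    if (!"rlu" %in% assayNames(object))
        return("assay 'rlu' is required")
    if (!"time_h" %in% colnames(colData(object)))
        return("missing colData column 'time_h'")
    tt <- colData(object)$time_h
    if (anyNA(tt) || any(!is.finite(tt)))
        msg <- c(msg, "time_h must be finite")
    else if (length(tt) > 1L && any(diff(tt) <= 0))
        msg <- c(msg, "time_h must be strictly increasing")
    conc <- rd$concentration_M
    if (anyNA(conc) || any(!is.finite(conc)) || any(conc < 0))
        msg <- c(msg, "concentration_M must be finite and >= 0")
    rep_ <- rd$replicate
    if (anyNA(rep_) || any(rep_ < 1) || any(rep_ != round(rep_)))
        msg <- c(msg, "replicate must be an integer >= 1")
    key <- paste(rd$cell_line, rd$drug, rd$concentration_M, rd$replicate,
                 sep = "\r")
    if (anyDuplicated(key))
        msg <- c(msg, sprintf(
            "duplicated condition key(s): %s",
            paste(unique(gsub("\r", "/", key[duplicated(key)])),
                  collapse = "; ")))
    rlu <- assay(object, "rlu")
    if (any(rlu < 0, na.rm = TRUE))
        msg <- c(msg, "negative RLU values present")
    npts <- rowSums(!is.na(rlu))
    if (nrow(rlu) && any(npts < 2L))
        msg <- c(msg, sprintf(
            "well(s) with fewer than 2 measured timepoints: %s",
            paste(rownames(object)[npts < 2L], collapse = ", ")))
    if ("count" %in% assayNames(object)) {
        ct <- assay(object, "count")
        if (any(ct < 0, na.rm = TRUE))
            msg <- c(msg, "negative cell counts present")
    }
    if (!isTRUE(metadata(object)$control_free)) {
        has_ctrl <- tapply(conc == 0, rd$cell_line, any)
        if (any(!has_ctrl))
            msg <- c(msg, sprintf(
                "cell line(s) without a concentration == 0 control: %s (set metadata control_free = TRUE to allow)",
                paste(names(has_ctrl)[!has_ctrl], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
}
setValidity("LumPlate", .validLumPlate)

#' Linear fit over a trailing slice of timepoints
#'
#' Holds the ordinary-least-squares result for one contiguous run of
#' timepoints ending at the analysis window's final timepoint. Indices are
#' 1-based positions into the series the slice was cut from, inclusive on both
#' ends. `r2` is the coefficient of determination of the simple linear
#' regression of signal on time, defined as 0 when the signal has zero
#' variance over the slice.
#'
#' @slot startIndex,endIndex integer positions of the slice within its series.
#' @slot slope,intercept regression coefficients (signal units per hour,
#'   signal units).
#' @slot r2 coefficient of determination in \[0, 1\].
#' @slot nPoints number of timepoints in the slice.
#' @seealso [enumerateTrailingSlices()], [selectBestSlice()]
#' @export
setClass("SliceFit", representation(
    startIndex = "integer", endIndex = "integer",
    slope = "numeric", intercept = "numeric",
    r2 = "numeric", nPoints = "integer"))

setValidity("SliceFit", function(object) {
    msg <- character()
    if (object@nPoints != object@endIndex - object@startIndex + 1L)
        msg <- c(msg, "nPoints must equal endIndex - startIndex + 1")
    if (object@nPoints < 2L)
        msg <- c(msg, "a slice needs at least 2 points")
    if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
        msg <- c(msg, "r2 must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Extracted rate for one assay condition
#'
#' The slope of the best-R-squared trailing slice for one
#' (cell line, drug, concentration, replicate) condition and channel, with
#' provenance: the winning [SliceFit-class], the time window that was
#' searched, and any warnings raised along the way (`"short_window_fallback"`,
#' `"negative_control_rate"`, `"sub_threshold_linearity"`).
#'
#' Units are RLU per hour for the luminescence channel and log2(cells) per
#' hour (doublings per hour) for the count channel.
#'
#' @seealso [extractRate()], [plateRates()], [countRate()]
#' @export
setClass("RateResult", representation(
    cellLine = "character", drug = "character",
    concentrationM = "numeric", replicate = "numeric",
    channel = "character", rate = "numeric",
    slice = "SliceFit", window = "numeric",
    r2Full = "numeric", warnings = "character"))

setValidity("RateResult", function(object) {
    msg <- character()
    if (!object@channel %in% c("lum", "count"))
        msg <- c(msg, "channel must be 'lum' or 'count'")
    if (length(object@window) != 2L || diff(object@window) < 0)
        msg <- c(msg, "window must be c(t_start, t_end) with t_start <= t_end")
    if (length(msg)) msg else TRUE
})

#' Four-parameter log-logistic dose-response fit
#'
#' Parameters of the sigmoid
#' \deqn{y(c) = E_{max} + \frac{E_0 - E_{max}}{1 + (c/EC_{50})^{h}}}
#' fitted by bounded least squares to normalized-rate versus concentration
#' data. `e0` is the upper asymptote (response at zero drug, ~1 by
#' construction of the normalization), `emax` the lower asymptote whose sign
#' encodes the drug-effect mechanism, `ec50M` the half-maximal concentration
#' in molar, and `hill` the Hill slope. `residuals` is the sum of squared
#' errors of the fit; `boundsHit` names any parameter whose estimate landed on
#' a configured bound.
#'
#' @seealso [fit4PL()], [classifyEffect()], [predict4PL()]
#' @export
setClass("DoseResponseFit", representation(
    e0 = "numeric", emax = "numeric", ec50M = "numeric", hill = "numeric",
    residuals = "numeric", effectClass = "character",
    converged = "logical", boundsHit = "character",
    points = "data.frame"))

setValidity("DoseResponseFit", function(object) {
    msg <- character()
    if (!is.na(object@residuals) && object@residuals < 0)
        msg <- c(msg, "residuals (sum of squared errors) must be >= 0")
    if (!is.na(object@hill) && object@hill <= 0)
        msg <- c(msg, "hill must be > 0")
    if (length(msg)) msg else TRUE
})

#' Exact Wilcoxon signed-rank test result
#'
#' Paired-test result with the convention used for critical-value tables:
#' the reported statistic `w` is the smaller of the positive and negative
#' rank sums. `pTwoSided` is exact (full enumeration of sign assignments)
#' for up to 25 informative pairs, and a continuity-corrected normal
#' approximation beyond.
#'
#' @seealso [wilcoxonExact()], [wilcoxonCriticalValue()]
#' @export
setClass("WilcoxonResult", representation(
    nUsed = "integer", wPlus = "numeric", wMinus = "numeric",
    w = "numeric", pTwoSided = "numeric", method = "character"))

setValidity("WilcoxonResult", function(object) {
    msg <- character()
    n <- object@nUsed
    if (abs(object@wPlus + object@wMinus - n * (n + 1) / 2) > 1e-8)
        msg <- c(msg, "rank sums must total n(n+1)/2")
    if (object@pTwoSided < 0 || object@pTwoSided > 1)
        msg <- c(msg, "pTwoSided must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Mechanistic plate-simulation settings
#'
#' Settings for [simulatePlate()]. Cells grow exponentially at a rate that is
#' a four-parameter log-logistic function of drug concentration; luminescence
#' is proportional to live-cell number times the remaining assay reagent,
#' which is consumed at `gamma` per cell per hour (giving the characteristic
#' rise-peak-decline trace); measurements carry multiplicative Gaussian noise
#' of coefficient of variation `cv`; the count channel images a binomial
#' `imagedFraction` of each well.
#'
#' @seealso [simulationConfig()] for construction with defaults.
#' @export
setClass("SimulationConfig", representation(
    n0 = "numeric", doublingTimeH = "numeric",
    drugParams = "data.frame", concentrationsM = "numeric",
    gamma = "numeric", aScale = "numeric", cv = "numeric",
    imagedFraction = "numeric", sampleIntervalH = "numeric",
    durationH = "numeric", nReplicates = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@n0 <= 0) msg <- c(msg, "n0 must be > 0")
    if (object@doublingTimeH <= 0) msg <- c(msg, "doublingTimeH must be > 0")
    if (object@imagedFraction <= 0 || object@imagedFraction > 1)
        msg <- c(msg, "imagedFraction must lie in (0, 1]")
    if (object@cv < 0) msg <- c(msg, "cv must be >= 0")
    if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
    if (object@sampleIntervalH <= 0 || object@durationH <= 0)
        msg <- c(msg, "sampleIntervalH and durationH must be > 0")
    if (object@durationH < 2 * object@sampleIntervalH)
        msg <- c(msg, "durationH must span at least two sampling intervals")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (any(object@concentrationsM <= 0))
        msg <- c(msg, "concentrationsM must be > 0 (the control is added automatically)")
    need <- c("cell_line", "drug", "emax", "ec50_M", "hill")
    miss <- setdiff(need, colnames(object@drugParams))
    if (length(miss))
        msg <- c(msg, sprintf("drugParams missing column(s): %s",
                              paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})
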