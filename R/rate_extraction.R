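#' Time of peak signal
#'
#' Returns the time at which a well's signal is maximal. The control well's
#' peak defines the effective end of the assay (reagent depletion makes the
#' trace decline afterwards, so later points carry no growth information);
#' a drugged well's own peak defines the start of its analysis window. Ties
#' are broken by the earliest such time, so that a post-peak decline is
#' captured in full.
#'
#' @param series `data.frame` with columns `time_h` and `value`, as returned
#'   by [wellSeries()].
#' @return Peak time in hours.
#' @export
peakTime <- function(series) {
    .checkSeries(series)
    series$time_h[which.max(series$value)]
}

.checkSeries <- function(series) {
    if (!is.data.frame(series) ||
        !all(c("time_h", "value") %in% colnames(series)))
        stop("series must be a data.frame with columns time_h and value")
    if (nrow(series) < 2L)
        stop("series must hold at least 2 points")
    if (any(diff(series$time_h) <= 0))
        stop("series times must be strictly increasing")
    invisible(series)
}

#' Enumerate trailing slices of a window and fit each by least squares
#'
#' The rate-extraction algorithm considers every contiguous run of timepoints
#' that ends at the analysis window's final timepoint ("trailing slices"),
#' from `minPoints` points up to the whole window, and fits each by ordinary
#' least squares. Interior slices are deliberately not searched.
#'
#' @param series `data.frame` with `time_h`, `value`.
#' @param window numeric `c(t_start, t_end)` in hours; only points with
#'   `t_start <= time_h <= t_end` are considered. Defaults to the whole
#'   series.
#' @param minPoints smallest slice size (default 5, i.e. more than four
#'   points; some descriptions of the procedure say "at least four" — set
#'   `minPoints = 4` for that reading).
#' @return List of [SliceFit-class], ordered by increasing slice length.
#'   Slice indices refer to positions in `series`.
#' @export
enumerateTrailingSlices <- function(series, window = NULL, minPoints = 5L) {
    .checkSeries(series)
    if (is.null(window)) window <- range(series$time_h)
    idx <- which(series$time_h >= window[1] & series$time_h <= window[2])
    n <- length(idx)
    if (n < minPoints)
        stop(sprintf(
            "window [%g, %g] h holds %d point(s); at least %d required",
            window[1], window[2], n, minPoints))
    endI <- idx[n]
    lapply(minPoints:n, function(L) {
        startI <- idx[n - L + 1L]
        sel <- idx[(n - L + 1L):n]
        f <- .ols(series$time_h[sel], series$value[sel])
        .sliceFit(startI, endI, f$slope, f$intercept, f$r2)
    })
}

#' Pick the slice whose regression maximizes R squared
#'
#' @param slices nonempty list of [SliceFit-class].
#' @return The slice with maximal `r2`; ties go to the slice with the most
#'   points (longer slices give statistically steadier slopes).
#' @export
selectBestSlice <- function(slices) {
    if (!length(slices)) stop("no slices to select from")
    r2 <- vapply(slices, function(s) s@r2, numeric(1))
    np <- vapply(slices, function(s) s@nPoints, integer(1))
    slices[[order(-r2, -np)[1L]]]
}

#' Extract a condition's luminescence rate
#'
#' Implements the windowed trailing-slice procedure. For the undrugged
#' control the window runs from the first timepoint to `controlPeak` (the
#' end of the assay); for a drugged well it runs from the well's own peak to
#' `controlPeak`, so that a drug-induced early peak followed by decline
#' contributes its decline slope. Trailing slices are enumerated within the
#' window and the best-R-squared slice's slope becomes the rate.
#'
#' If the window holds fewer than `minPoints` samples (a drugged well whose
#' own peak sits at or just before the end of the assay, i.e. no real decline
#' phase), the peak constraint is dropped: the full window from the first
#' timepoint to `controlPeak` is searched instead, and the result carries a
#' `"short_window_fallback"` warning flag. A well indistinguishable from the
#' control is thereby treated exactly like the control, so its normalized
#' rate lands at 1.
#' A control whose rate comes out negative is flagged
#' `"negative_control_rate"`; a series whose full-trace linear fit falls at
#' or below `linearityThreshold` is flagged `"sub_threshold_linearity"`.
#'
#' @param series `data.frame` with `time_h`, `value` (RLU).
#' @param controlPeak end-of-assay time in hours, from [peakTime()] on the
#'   control condition.
#' @param minPoints smallest slice size (default 5).
#' @param isControl `TRUE` for the undrugged (basal) condition.
#' @param linearityThreshold R-squared gate for the linearity flag
#'   (default 0.90).
#' @param info optional named list giving `cellLine`, `drug`,
#'   `concentrationM`, `replicate` provenance for the result.
#' @return A [RateResult-class].
#' @export
extractRate <- function(series, controlPeak, minPoints = 5L,
                        isControl = FALSE, linearityThreshold = 0.9,
                        info = list()) {
    .checkSeries(series)
    if (controlPeak < series$time_h[1] ||
        controlPeak > series$time_h[nrow(series)])
        stop("controlPeak lies outside the sampled time range")
    if (sum(series$time_h <= controlPeak) < minPoints)
        stop(sprintf("series holds fewer than %d points up to controlPeak",
                     minPoints))
    warnings <- character()
    t0 <- if (isControl) series$time_h[1] else peakTime(series)
    window <- c(t0, controlPeak)
    nwin <- sum(series$time_h >= window[1] & series$time_h <= window[2])
    if (nwin < minPoints) {
        # A well that peaks at (or after) the end of the assay has no
        # post-peak decline to isolate, so the peak constraint is dropped and
        # the control's full window is searched instead of failing the curve.
        window <- c(series$time_h[1], controlPeak)
        warnings <- c(warnings, "short_window_fallback")
    }
    best <- selectBestSlice(
        enumerateTrailingSlices(series, window, minPoints))
    lin <- linearityCheck(series, linearityThreshold)
    if (!lin$passes)
        warnings <- c(warnings, "sub_threshold_linearity")
    if (isControl && best@slope < 0)
        warnings <- c(warnings, "negative_control_rate")
    new("RateResult",
        cellLine = as.character(info$cellLine %||% NA_character_),
        drug = as.character(info$drug %||% NA_character_),
        concentrationM = as.numeric(info$concentrationM %||% NA_real_),
        replicate = as.numeric(info$replicate %||% NA_real_),
        channel = "lum", rate = best@slope, slice = best,
        window = window, r2Full = lin$r2, warnings = warnings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proliferation rate from direct cell counts
#'
#' Direct-count proliferation rates are taken as the ordinary-least-squares
#' slope of log2(count) against time over the full series — log2 because
#' exponential growth is then a straight line whose slope is in doublings per
#' hour.
#'
#' @param series `data.frame` with `time_h` and `value` (cell counts, all
#'   strictly positive).
#' @param info provenance list as in [extractRate()].
#' @return A [RateResult-class] with `channel == "count"`.
#' @export
countRate <- function(series, info = list()) {
    .checkSeries(series)
    bad <- which(series$value <= 0)
    if (length(bad))
        stop("nonpositive count at timepoint ",
             paste(series$time_h[bad], collapse = ", "), " h")
    f <- .ols(series$time_h, log2(series$value))
    n <- nrow(series)
    new("RateResult",
        cellLine = as.character(info$cellLine %||% NA_character_),
        drug = as.character(info$drug %||% NA_character_),
        concentrationM = as.numeric(info$concentrationM %||% NA_real_),
        replicate = as.numeric(info$replicate %||% NA_real_),
        channel = "count", rate = f$slope,
        slice = .sliceFit(1L, n, f$slope, f$intercept, f$r2),
        window = range(series$time_h), r2Full = f$r2,
        warnings = character())
}

#' Linearity quality gate
#'
#' A cell line is usable for slope-based analysis only if its undrugged
#' signal stays linear for the duration of the assay. The gate fits the full
#' series by least squares and passes iff R squared strictly exceeds the
#' threshold.
#'
#' @param series `data.frame` with `time_h`, `value`.
#' @param threshold R-squared cutoff, default 0.90; the comparison is strict
#'   (`r2 > threshold`).
#' @return `list(r2 =, passes =)`.
#' @export
linearityCheck <- function(series, threshold = 0.9) {
    .checkSeries(series)
    r2 <- .ols(series$time_h, series$value)$r2
    list(r2 = r2, passes = r2 > threshold)
}

#' Static luminescence-versus-cell-number regression
#'
#' Single-timepoint calibration: regress RLU on seeded cell number across a
#' dilution series to confirm signal is proportional to live-cell number.
#'
#' @param cells numeric vector of cell numbers (not all equal).
#' @param rlu numeric vector of luminescence readings, same length,
#'   `n >= 3`.
#' @return `list(slope =, intercept =, r2 =)`.
#' @export
staticRegression <- function(cells, rlu) {
    if (length(cells) != length(rlu))
        stop("cells and rlu must have equal length")
    if (length(cells) < 3L)
        stop("at least 3 points are required")
    if (diff(range(cells)) == 0)
        stop("degenerate cell numbers: all values equal")
    f <- .ols(cells, rlu)
    list(slope = f$slope, intercept = f$intercept, r2 = f$r2)
}

#' Extract rates for every condition on a plate
#'
#' Applies the trailing-slice procedure across a whole [LumPlate-class]. Per
#' cell line, the control (zero-concentration) wells are averaged timepoint-
#' wise and their peak defines the end of the assay; each condition is then
#' rate-extracted against that end time. By default replicate wells are
#' averaged per timepoint before slicing; with `perReplicate = TRUE` each
#' replicate is sliced on its own.
#'
#' For `channel = "count"` rates are full-series log2-count slopes
#' ([countRate()]) and the window/peak machinery does not apply.
#'
#' @param plate A [LumPlate-class].
#' @param channel `"lum"` or `"count"`.
#' @param minPoints,linearityThreshold see [extractRate()].
#' @param perReplicate slice each replicate separately instead of averaging.
#' @return `data.frame` with columns `cell_line`, `drug`, `concentration_M`,
#'   `replicate` (`NA` when averaged), `rate`, `r2` (winning-slice R squared),
#'   `slice_start_h`, `slice_end_h`, `n_points`, `warnings`
#'   (semicolon-joined flags). The control rows (`concentration_M == 0`) are
#'   included; they are the normalization denominators downstream.
#' @export
plateRates <- function(plate, channel = c("lum", "count"), minPoints = 5L,
                       perReplicate = FALSE, linearityThreshold = 0.9) {
    channel <- match.arg(channel)
    stopifnot(is(plate, "LumPlate"))
    aname <- if (channel == "lum") "rlu" else "count"
    if (!aname %in% assayNames(plate))
        stop("plate has no '", aname, "' assay")
    rd <- wellInfo(plate)
    tt <- assayTimes(plate)
    mat <- assay(plate, aname)

    groupSeries <- function(rows) {
        v <- if (length(rows) > 1L) colMeans(mat[rows, , drop = FALSE],
                                             na.rm = TRUE)
             else mat[rows, ]
        keep <- is.finite(v)
        data.frame(time_h = tt[keep], value = unname(v[keep]))
    }

    res <- list()
    for (cl in unique(rd$cell_line)) {
        ctrl_rows <- which(rd$cell_line == cl & rd$concentration_M == 0)
        if (channel == "lum") {
            if (!length(ctrl_rows))
                stop("cell line '", cl, "' has no control wells; ",
                     "cannot define the end of the assay")
            controlPeak <- peakTime(groupSeries(ctrl_rows))
        }
        sub <- rd[rd$cell_line == cl, , drop = FALSE]
        conds <- unique(sub[, c("drug", "concentration_M")])
        for (j in seq_len(nrow(conds))) {
            rows <- which(rd$cell_line == cl &
                          rd$drug == conds$drug[j] &
                          rd$concentration_M == conds$concentration_M[j])
            reps <- if (perReplicate) as.list(rows) else list(rows)
            for (rr in reps) {
                info <- list(cellLine = cl, drug = conds$drug[j],
                             concentrationM = conds$concentration_M[j],
                             replicate = if (perReplicate)
                                 rd$replicate[rr] else NA_real_)
                series <- groupSeries(rr)
                r <- if (channel == "lum")
                    extractRate(series, controlPeak, minPoints = minPoints,
                                isControl = conds$concentration_M[j] == 0,
                                linearityThreshold = linearityThreshold,
                                info = info)
                else countRate(series, info = info)
                res[[length(res) + 1L]] <- data.frame(
                    cell_line = r@cellLine, drug = r@drug,
                    concentration_M = r@concentrationM,
                    replicate = r@replicate,
                    rate = r@rate, r2 = r@slice@r2,
                    slice_start_h = series$time_h[r@slice@startIndex],
                    slice_end_h = series$time_h[r@slice@endIndex],
                    n_points = r@slice@nPoints,
                    warnings = paste(r@warnings, collapse = ";"))
            }
        }
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
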