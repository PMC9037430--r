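#' Normalize drugged rates to the basal rate
#'
#' Each drugged condition's rate is divided by the undrugged control's
#' ("basal") rate for the same cell line, making responses dimensionless:
#' 1 means no drug effect, 0 a static population, negative values a shrinking
#' one. The control itself maps to exactly 1 by construction and enters the
#' dose-response fit only as the anchor of the upper asymptote, not as a
#' point.
#'
#' @param rates `data.frame` with columns `concentration_M` (> 0) and `rate`,
#'   one row per drugged condition of a single cell line / drug pairing.
#' @param basal the control rate: a number or a [RateResult-class].
#' @return `data.frame` with columns `concentration_M` and `normalized_rate`.
#' @export
normalizeRates <- function(rates, basal) {
    if (is(basal, "RateResult")) basal <- basal@rate
    if (!is.numeric(basal) || length(basal) != 1L || is.na(basal))
        stop("basal must be a single rate")
    if (basal == 0)
        stop("basal rate is exactly 0; normalization is undefined")
    if (any(rates$concentration_M <= 0))
        stop("normalizeRates expects drugged conditions only (concentration > 0)")
    data.frame(concentration_M = rates$concentration_M,
               normalized_rate = rates$rate / basal)
}

#' Fitting settings for the four-parameter log-logistic model
#'
#' Bounds keep pathological fits identifiable: very strong responses pin the
#' lower asymptote at `emaxFloor`, near-vertical transitions pin the Hill
#' slope at `hillMax`, and EC50s escaping the tested range pin at the
#' `ec50Bounds`. Estimates landing on a bound are reported in the fit's
#' `boundsHit` slot.
#'
#' @param emaxFloor,emaxCeiling bounds on both asymptotes (default -5, 1.5).
#' @param hillMax upper bound on the Hill coefficient (default 15).
#' @param ec50Bounds molar `c(lower, upper)` for EC50 (default 1e-12, 1e3).
#' @param hillStarts,ec50QuartileStarts multi-start grid: Hill starting
#'   values, and whether to seed EC50 at the data's concentration quartiles.
#' @return list of class `fit4pl_config`.
#' @export
fit4plConfig <- function(emaxFloor = -5, emaxCeiling = 1.5, hillMax = 15,
                         ec50Bounds = c(1e-12, 1e3),
                         hillStarts = c(0.5, 1, 3, 8),
                         ec50QuartileStarts = TRUE) {
    stopifnot(emaxFloor < emaxCeiling, hillMax > 0,
              length(ec50Bounds) == 2L, all(ec50Bounds > 0),
              ec50Bounds[1] < ec50Bounds[2])
    structure(list(emaxFloor = emaxFloor, emaxCeiling = emaxCeiling,
                   hillMax = hillMax, ec50Bounds = ec50Bounds,
                   hillStarts = hillStarts,
                   ec50QuartileStarts = ec50QuartileStarts),
              class = "fit4pl_config")
}

# 4PL response at concentration c, parameterized by log10(EC50)
.fourPL <- function(lc, e0, emax, p, h) {
    emax + (e0 - emax) / (1 + 10^(h * (lc - p)))
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{y(c) = E_{max} + (E_0 - E_{max}) / (1 + (c/EC_{50})^{h})}
#' to normalized rate versus concentration, performed against log10
#' concentration. Steep-Hill sigmoids are riddled with local minima, so the
#' optimization is multi-started over a grid of Hill values and EC50 seeds at
#' the concentration quartiles; each start runs bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM]) with an L-BFGS-B fallback, and the lowest
#' sum-of-squares solution wins. The upper asymptote `e0` is a free
#' parameter initialized at 1 (the normalization anchors the true curve
#' there, but it is estimated, not pinned).
#'
#' @param points `data.frame` with `concentration_M` (> 0) and
#'   `normalized_rate`; at least 4 points over at least 3 distinct
#'   concentrations.
#' @param config a [fit4plConfig()].
#' @param tolZero,tolOne classification tolerances passed to
#'   [classifyEffect()].
#' @return A [DoseResponseFit-class]; `converged` is `FALSE` when no start
#'   converged (the best attempt's parameters are still reported).
#' @examples
#' conc <- 10^seq(-10, -6, by = 0.5)
#' y <- 1 + (-0.5 - 1) * (1 / (1 + (1e-8 / conc)))  # e0=1 emax=-0.5 hill=1
#' fit4PL(data.frame(concentration_M = conc, normalized_rate = y))
#' @export
fit4PL <- function(points, config = fit4plConfig(), tolZero = 0.1,
                   tolOne = 0.1) {
    stopifnot(inherits(config, "fit4pl_config"))
    if (!all(c("concentration_M", "normalized_rate") %in% colnames(points)))
        stop("points must have columns concentration_M and normalized_rate")
    if (any(points$concentration_M <= 0))
        stop("concentrations must be > 0")
    if (nrow(points) < 4L)
        stop("at least 4 points are required")
    if (length(unique(points$concentration_M)) < 3L)
        stop("at least 3 distinct concentrations are required")

    lc <- log10(points$concentration_M)
    y <- points$normalized_rate
    lower <- c(e0 = config$emaxFloor, emax = config$emaxFloor,
               p = log10(config$ec50Bounds[1]), h = 1e-3)
    upper <- c(e0 = config$emaxCeiling, emax = config$emaxCeiling,
               p = log10(config$ec50Bounds[2]), h = config$hillMax)
    clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
    emax0 <- clamp(min(y), config$emaxFloor, config$emaxCeiling)
    pstarts <- if (config$ec50QuartileStarts)
        unique(stats::quantile(lc, c(0.25, 0.5, 0.75), names = FALSE))
    else stats::median(lc)
    pstarts <- clamp(pstarts, lower["p"], upper["p"])

    sse <- function(par) {
        r <- y - .fourPL(lc, par[1], par[2], par[3], par[4])
        sum(r * r)
    }
    best <- NULL
    anyConv <- FALSE
    df <- data.frame(lc = lc, y = y)
    for (h0 in config$hillStarts) for (p0 in pstarts) {
        start <- c(e0 = clamp(1, lower["e0"], upper["e0"]), emax = emax0,
                   p = unname(p0), h = clamp(h0, lower["h"], upper["h"]))
        names(start) <- c("e0", "emax", "p", "h")
        fit <- tryCatch({
            m <- minpack.lm::nlsLM(
                y ~ emax + (e0 - emax) / (1 + 10^(h * (lc - p))),
                data = df, start = as.list(start),
                lower = lower, upper = upper,
                control = minpack.lm::nls.lm.control(maxiter = 200))
            list(par = stats::coef(m)[c("e0", "emax", "p", "h")],
                 value = sum(stats::resid(m)^2), conv = TRUE)
        }, error = function(e) NULL)
        if (is.null(fit)) {
            o <- tryCatch(
                stats::optim(start, sse, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(maxit = 500)),
                error = function(e) NULL)
            if (!is.null(o))
                fit <- list(par = o$par, value = o$value,
                            conv = o$convergence == 0)
        }
        if (!is.null(fit)) {
            anyConv <- anyConv || fit$conv
            if (is.null(best) || fit$value < best$value) best <- fit
        }
    }
    if (is.null(best))
        stop("dose-response optimization failed from every start")

    par <- best$par
    tol <- 1e-6
    hit <- names(lower)[abs(par - lower) < tol | abs(par - upper) < tol]
    hit <- sub("^p$", "ec50", hit)
    fit <- new("DoseResponseFit",
               e0 = unname(par["e0"]), emax = unname(par["emax"]),
               ec50M = unname(10^par["p"]), hill = unname(par["h"]),
               residuals = best$value, effectClass = "unclassified",
               converged = anyConv, boundsHit = hit,
               points = points[, c("concentration_M", "normalized_rate")])
    fit@effectClass <- classifyEffect(fit, tolZero = tolZero,
                                      tolOne = tolOne)
    fit
}

#' Evaluate a fitted dose-response curve
#'
#' @param fit A [DoseResponseFit-class].
#' @param concentration molar concentrations (> 0).
#' @return Predicted normalized rates.
#' @export
predict4PL <- function(fit, concentration) {
    stopifnot(is(fit, "DoseResponseFit"), all(concentration > 0))
    .fourPL(log10(concentration), fit@e0, fit@emax, log10(fit@ec50M),
            fit@hill)
}

#' Classify the drug-effect mechanism from the maximal response
#'
#' The fitted lower asymptote (Emax, "maximal response") encodes what the
#' drug does to the population at saturating dose: a rate indistinguishable
#' from the basal rate (Emax near 1) means no effect; a fractional positive
#' rate means the population still grows, only slower (anti-proliferative); a
#' rate near zero means a static population (cytostatic); a negative rate
#' means the population shrinks (cytotoxic).
#'
#' @param fit A [DoseResponseFit-class], or a bare Emax value.
#' @param tolZero half-width of the "rate of ~0" band around Emax = 0
#'   (default 0.1).
#' @param tolOne half-width of the no-effect band around Emax = 1
#'   (default 0.1).
#' @return One of `"no_effect"`, `"anti_proliferative"`, `"cytostatic"`,
#'   `"cytotoxic"`.
#' @export
classifyEffect <- function(fit, tolZero = 0.1, tolOne = 0.1) {
    emax <- if (is(fit, "DoseResponseFit")) fit@emax else fit
    stopifnot(is.numeric(emax), length(emax) == 1L, is.finite(emax))
    if (emax >= 1 - tolOne) "no_effect"
    else if (abs(emax) <= tolZero) "cytostatic"
    else if (emax < 0) "cytotoxic"
    else "anti_proliferative"
}

#' Coarse mechanism group used for cross-channel concordance
#'
#' Collapses [classifyEffect()]'s four classes to the three groups used when
#' comparing measurement channels: negative maximal response (cytotoxic),
#' non-negative below the no-effect band (anti-proliferative/cytostatic,
#' which both denote a non-shrinking, non-expanding-at-basal population), or
#' no effect.
#'
#' @inheritParams classifyEffect
#' @return One of `"cytotoxic"`, `"anti_proliferative/cytostatic"`,
#'   `"no_effect"`.
#' @export
mechanismGroup <- function(fit, tolOne = 0.1) {
    emax <- if (is(fit, "DoseResponseFit")) fit@emax else fit
    stopifnot(is.numeric(emax), length(emax) == 1L, is.finite(emax))
    if (emax >= 1 - tolOne) "no_effect"
    else if (emax < 0) "cytotoxic"
    else "anti_proliferative/cytostatic"
}

#' Assemble fits into the canonical result table
#'
#' @param fits list of [DoseResponseFit-class].
#' @param keys `data.frame` with columns `cell_line`, `drug`, `data_type`
#'   (one row per fit; keys must be unique).
#' @return `data.frame` in the layout of [writeResultTable()].
#' @export
buildResultTable <- function(fits, keys) {
    stopifnot(length(fits) == nrow(keys),
              all(c("cell_line", "drug", "data_type") %in% colnames(keys)))
    key <- paste(keys$cell_line, keys$drug, keys$data_type)
    if (anyDuplicated(key))
        stop("duplicate (cell_line, drug, data_type) key(s): ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    tab <- data.frame(
        cell_line = keys$cell_line, drug = keys$drug,
        data_type = keys$data_type,
        hill_coef = vapply(fits, function(f) f@hill, numeric(1)),
        max_resp = vapply(fits, function(f) f@emax, numeric(1)),
        ec50_M = vapply(fits, function(f) f@ec50M, numeric(1)),
        residuals = vapply(fits, function(f) f@residuals, numeric(1)))
    .validateResultTable(tab)
}

#' Fit dose-response curves for every cell line / drug pairing of a plate
#'
#' High-level wrapper: from a rates table (see [plateRates()]) it takes, per
#' cell line, the control row as the basal rate, normalizes each drug's
#' concentration series, fits the four-parameter log-logistic model and
#' classifies the effect.
#'
#' @param rates rates `data.frame` including control rows
#'   (`concentration_M == 0`). Per-replicate rates are averaged per
#'   concentration first.
#' @param dataType label for the result table's `data_type` column
#'   (`"Lum"` or `"Direct"`).
#' @param config,tolZero,tolOne see [fit4PL()].
#' @return list with `fits` (named `"cell_line/drug"` list of
#'   [DoseResponseFit-class]) and `table` (result `data.frame`).
#' @export
fitDoseResponse <- function(rates, dataType = "Lum",
                            config = fit4plConfig(), tolZero = 0.1,
                            tolOne = 0.1) {
    # collapse per-replicate rows to one rate per condition
    agg <- stats::aggregate(
        rate ~ cell_line + drug + concentration_M, data = rates, FUN = mean)
    fits <- list(); keys <- NULL
    for (cl in unique(agg$cell_line)) {
        ctrl <- agg[agg$cell_line == cl & agg$concentration_M == 0, ]
        if (!nrow(ctrl))
            stop("cell line '", cl, "' has no control rate")
        basal <- mean(ctrl$rate)
        drugged <- agg[agg$cell_line == cl & agg$concentration_M > 0, ]
        for (dr in unique(drugged$drug)) {
            sub <- drugged[drugged$drug == dr, ]
            pts <- normalizeRates(sub, basal)
            fit <- fit4PL(pts, config = config, tolZero = tolZero,
                          tolOne = tolOne)
            fits[[paste(cl, dr, sep = "/")]] <- fit
            keys <- rbind(keys, data.frame(cell_line = cl, drug = dr,
                                           data_type = dataType))
        }
    }
    list(fits = fits, table = buildResultTable(unname(fits), keys))
}
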