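# Exact null distribution of the positive rank sum. ranks2 holds the
# doubled (mid)ranks as integers; the generating function over all 2^n sign
# assignments is built by convolution, which enumerates every assignment's
# sum exactly. Returns counts over sums 0..sum(ranks2) (index = sum + 1).
.signedRankCounts <- function(ranks2) {
    total <- sum(ranks2)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (r in ranks2) {
        shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
        counts <- counts + shifted
    }
    counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired nonparametric test on `a - b`. Zero differences are dropped
#' (Wilcoxon's original treatment); tied absolute differences receive
#' midranks. The reported statistic is `W = min(W+, W-)`, the convention
#' under which published critical-value tables are lower-tail (reject when
#' `W` is at or below the critical value). For up to `exactMax` informative
#' pairs the two-sided p-value is exact, obtained by enumerating all
#' `2^n` sign assignments of the (mid)ranks; beyond that a normal
#' approximation with continuity and tie correction is used.
#'
#' @param a,b paired numeric vectors (e.g. log EC50 from two measurement
#'   channels), equal length, all finite.
#' @param exactMax largest `n` for which the exact enumeration is used
#'   (default 25).
#' @return A [WilcoxonResult-class].
#' @examples
#' wilcoxonExact(c(2, 4, 7), c(1, 2, 4))  # W = 0, exact p = 0.25
#' @export
wilcoxonExact <- function(a, b, exactMax = 25L) {
    stopifnot(length(a) == length(b), length(a) >= 1L)
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("all paired values must be finite")
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
        stop("all differences are zero; the test is undefined")
    r <- rank(abs(d))
    wPlus <- sum(r[d > 0])
    wMinus <- sum(r[d < 0])
    w <- min(wPlus, wMinus)
    total <- n * (n + 1) / 2
    if (n <= exactMax) {
        counts <- .signedRankCounts(as.integer(round(2 * r)))
        # P(W+ <= w): doubled scale; symmetric null, so two-sided p doubles
        # the smaller tail, clamped at 1 when w sits at the center
        pLow <- sum(counts[seq_len(floor(2 * w) + 1L)]) / 2^n
        p <- min(1, 2 * pLow)
        method <- "exact_enumeration"
    } else {
        tie <- table(r)
        sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(tie^3 - tie) / 48
        z <- (w - total / 4 + 0.5) / sqrt(sigma2)
        p <- min(1, 2 * stats::pnorm(z))
        method <- "normal_approx"
    }
    new("WilcoxonResult", nUsed = n, wPlus = wPlus, wMinus = wMinus,
        w = w, pTwoSided = p, method = method)
}

#' Exact two-sided critical value for the signed-rank statistic
#'
#' Largest integer `c` such that `2 * P(W+ <= c) <= alpha` under the exact
#' tie-free null distribution over ranks `1..n`, i.e. the usual two-tailed
#' table value: reject when the min rank sum is `<= c`.
#'
#' @param n number of informative pairs, between 5 and 25.
#' @param alpha two-sided level (default 0.05).
#' @return The critical value, or `-1` when no rejection region exists at
#'   that level.
#' @examples
#' wilcoxonCriticalValue(12, 0.05)  # 13
#' @export
wilcoxonCriticalValue <- function(n, alpha = 0.05) {
    if (n < 5L || n > 25L)
        stop("n must lie in 5..25")
    stopifnot(alpha >= 0, alpha <= 1)
    counts <- .signedRankCounts(2L * seq_len(n))
    # cumulative over integer W values 0..n(n+1)/2 (doubled-scale indices)
    total <- n * (n + 1) / 2
    cdf <- cumsum(counts)[2 * (0:total) + 1L] / 2^n
    ok <- which(2 * cdf <= alpha)
    if (!length(ok)) -1L else as.integer(max(ok) - 1L)
}

#' Cross-channel agreement on drug-effect mechanism
#'
#' Pairs the fits (or maximal-response values) of two measurement channels by
#' (cell line, drug) key and counts the pairs whose mechanism calls agree.
#' By default agreement is judged at the coarse [mechanismGroup()] level —
#' negative vs non-negative-below-one vs no-effect — because that is the
#' screening-relevant distinction (is the lead compound killing cells or
#' merely slowing them?); `granularity = "class"` demands the full
#' four-class [classifyEffect()] call to match instead.
#'
#' @param a,b `data.frame`s with columns `cell_line`, `drug`, `max_resp`
#'   (one channel each); their key sets must coincide.
#' @param tolZero,tolOne classification tolerances.
#' @param granularity `"mechanism"` (default) or `"class"`.
#' @return list with `n_pairs`, `n_concordant`, `discordant_keys`
#'   (`data.frame` of cell_line/drug), and `classes` (per-pair calls).
#' @export
mechanismConcordance <- function(a, b, tolZero = 0.1, tolOne = 0.1,
                                 granularity = c("mechanism", "class")) {
    granularity <- match.arg(granularity)
    need <- c("cell_line", "drug", "max_resp")
    stopifnot(all(need %in% colnames(a)), all(need %in% colnames(b)))
    keyA <- paste(a$cell_line, a$drug, sep = "/")
    keyB <- paste(b$cell_line, b$drug, sep = "/")
    if (anyDuplicated(keyA) || anyDuplicated(keyB))
        stop("duplicate (cell_line, drug) keys within a channel")
    onlyA <- setdiff(keyA, keyB); onlyB <- setdiff(keyB, keyA)
    if (length(onlyA) || length(onlyB))
        stop("key sets differ between channels; missing: ",
             paste(c(onlyA, onlyB), collapse = ", "))
    b <- b[match(keyA, keyB), ]
    cls <- function(e) if (granularity == "mechanism")
        mechanismGroup(e, tolOne = tolOne)
    else classifyEffect(e, tolZero = tolZero, tolOne = tolOne)
    clsA <- vapply(a$max_resp, cls, character(1))
    clsB <- vapply(b$max_resp, cls, character(1))
    conc <- clsA == clsB
    list(n_pairs = length(conc),
         n_concordant = sum(conc),
         discordant_keys = data.frame(cell_line = a$cell_line[!conc],
                                      drug = a$drug[!conc]),
         classes = data.frame(cell_line = a$cell_line, drug = a$drug,
                              class_a = clsA, class_b = clsB,
                              concordant = conc))
}

#' Full two-channel comparison report
#'
#' From a result table holding both `data_type` channels (or two separate
#' tables), pairs conditions measured by both, runs the exact Wilcoxon
#' signed-rank test on the natural-log EC50 differences, looks up the exact
#' critical value, and tabulates mechanism concordance. Pairs whose EC50
#' equals a fitting bound are flagged (`bound_flagged`) and, by default,
#' retained; set `excludeBound = TRUE` to drop them from the Wilcoxon input.
#'
#' @param table result `data.frame` (layout of [readResultTable()]) with both
#'   channels present, or the channel-A table if `tableB` is given.
#' @param tableB optional channel-B table.
#' @param channelA,channelB `data_type` labels to pair (default `"Lum"` vs
#'   `"Direct"`).
#' @param alpha two-sided level for the critical value.
#' @param ec50Bounds molar bounds used to flag clipped EC50s.
#' @param excludeBound drop bound-flagged pairs from the test.
#' @param tolZero,tolOne classification tolerances.
#' @return list with `wilcoxon` ([WilcoxonResult-class]), `w`, `p`, `n`,
#'   `critical_value`, `significant` (`w <= critical_value`), `concordance`
#'   (see [mechanismConcordance()]), `pairs` (the paired lnEC50 table) and
#'   `bound_flagged` keys.
#' @export
compareChannels <- function(table, tableB = NULL, channelA = "Lum",
                            channelB = "Direct", alpha = 0.05,
                            ec50Bounds = c(1e-12, 1e3),
                            excludeBound = FALSE,
                            tolZero = 0.1, tolOne = 0.1) {
    if (is.null(tableB)) {
        a <- table[table$data_type == channelA, ]
        b <- table[table$data_type == channelB, ]
    } else {
        a <- table; b <- tableB
    }
    keyA <- paste(a$cell_line, a$drug, sep = "/")
    keyB <- paste(b$cell_line, b$drug, sep = "/")
    shared <- intersect(keyA, keyB)
    if (!length(shared))
        stop("no (cell_line, drug) pairing is present in both channels")
    a <- a[match(shared, keyA), ]
    b <- b[match(shared, keyB), ]
    onBound <- function(x) x <= ec50Bounds[1] * (1 + 1e-6) |
        x >= ec50Bounds[2] * (1 - 1e-6)
    flagged <- onBound(a$ec50_M) | onBound(b$ec50_M)
    pairs <- data.frame(cell_line = a$cell_line, drug = a$drug,
                        ln_ec50_a = log(a$ec50_M), ln_ec50_b = log(b$ec50_M),
                        bound_flagged = flagged)
    use <- if (excludeBound) !flagged else rep(TRUE, nrow(pairs))
    wt <- wilcoxonExact(pairs$ln_ec50_a[use], pairs$ln_ec50_b[use])
    crit <- if (wt@nUsed >= 5L && wt@nUsed <= 25L)
        wilcoxonCriticalValue(wt@nUsed, alpha) else NA_integer_
    conc <- mechanismConcordance(
        a[, c("cell_line", "drug", "max_resp")],
        b[, c("cell_line", "drug", "max_resp")],
        tolZero = tolZero, tolOne = tolOne)
    list(wilcoxon = wt, w = wt@w, p = wt@pTwoSided, n = wt@nUsed,
         critical_value = crit,
         significant = !is.na(crit) && wt@w <= crit,
         concordance = conc, pairs = pairs,
         bound_flagged = pairs[flagged, c("cell_line", "drug")])
}
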