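# Shared fixture builders; everything is generated in code.

mkSeries <- function(time_h, value) data.frame(time_h = time_h, value = value)

# A tiny one-cell-line long table suitable for LumPlate()
mkLongTable <- function(times = c(0, 4, 8, 12, 16, 20, 24),
                        nConc = 3, nRep = 2) {
    conc <- c(0, 10^seq(-9, -9 + 0.5 * (nConc - 1), by = 0.5))
    do.call(rbind, lapply(conc, function(cc)
        do.call(rbind, lapply(seq_len(nRep), function(r)
            data.frame(cell_line = "A",
                       drug = if (cc == 0) "control" else "drugX",
                       concentration_M = cc, replicate = r,
                       time_h = times,
                       rlu = 100 + 10 * times + r)))))
}

# Independent brute-force oracle: regress every trailing suffix with lm()
bruteForceSlices <- function(series, window, minPoints) {
    idx <- which(series$time_h >= window[1] & series$time_h <= window[2])
    n <- length(idx)
    lapply(minPoints:n, function(L) {
        sel <- idx[(n - L + 1L):n]
        m <- stats::lm(value ~ time_h, data = series[sel, ])
        list(start = sel[1L], end = sel[L],
             slope = unname(stats::coef(m)[2]),
             intercept = unname(stats::coef(m)[1]),
             r2 = suppressWarnings(summary(m)$r.squared), n = L)
    })
}

# Independent brute-force exact Wilcoxon: enumerate every sign assignment
bruteForceWilcoxon <- function(a, b) {
    d <- (a - b)[a != b]
    n <- length(d)
    r <- rank(abs(d))
    wPlus <- sum(r[d > 0])
    w <- min(wPlus, sum(r) - wPlus)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wp <- as.vector(signs %*% r)
    wdist <- pmin(wp, sum(r) - wp)
    list(w = w, p = min(1, 2 * mean(wp <= w)), dist = wp)
}

# Generate 4PL points y(c) from the model directly
points4PL <- function(e0, emax, ec50, hill,
                      conc = 10^seq(-10, -6, by = 0.5)) {
    data.frame(concentration_M = conc,
               normalized_rate = emax + (e0 - emax) /
                   (1 + (conc / ec50)^hill))
}

# The 12 two-channel pairings of the bundled screen panel, aligned by key
panelPairs <- function() {
    panel <- sclcPanel()
    a <- panel[panel$data_type == "Lum" &
               panel$cell_line %in% c("H1048", "H841"), ]
    b <- panel[panel$data_type == "Direct", ]
    a <- a[paste(a$cell_line, a$drug) %in% paste(b$cell_line, b$drug), ]
    b <- b[match(paste(a$cell_line, a$drug),
                 paste(b$cell_line, b$drug)), ]
    list(a = a, b = b)
}
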