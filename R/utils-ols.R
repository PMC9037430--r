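# Closed-form simple linear regression used in the slice scan. Returns the
# OLS slope, intercept and coefficient of determination of y on x. r2 is
# defined as 0 when y has zero variance (no linear signal to explain) and is
# clamped to [0, 1] against floating-point drift.
.ols <- function(x, y) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    dx <- x - mx; dy <- y - my
    sxx <- sum(dx * dx)
    syy <- sum(dy * dy)
    sxy <- sum(dx * dy)
    slope <- sxy / sxx
    r2 <- if (syy <= 0) 0 else min(max(sxy * sxy / (sxx * syy), 0), 1)
    list(slope = slope, intercept = my - slope * mx, r2 = r2, n = n)
}

.sliceFit <- function(startIndex, endIndex, slope, intercept, r2) {
    new("SliceFit", startIndex = as.integer(startIndex),
        endIndex = as.integer(endIndex), slope = slope,
        intercept = intercept, r2 = r2,
        nPoints = as.integer(endIndex - startIndex + 1L))
}
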