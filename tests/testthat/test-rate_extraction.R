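test_that("peak time is the earliest maximum", {
    s <- mkSeries(seq(0, 96, by = 4), seq_len(25))
    expect_equal(peakTime(s), 96)
    expect_equal(peakTime(mkSeries(c(0, 12, 24, 36), c(1, 5, 5, 2))), 12)
})

test_that("trailing-slice enumeration matches a brute-force lm() scan", {
    set.seed(42)
    for (rep in 1:25) {
        n <- sample(8:15, 1)
        s <- mkSeries(cumsum(runif(n, 1, 5)), rnorm(n, 50, 10))
        w <- range(s$time_h)
        mine <- enumerateTrailingSlices(s, w, minPoints = 5)
        oracle <- bruteForceSlices(s, w, 5)
        expect_length(mine, length(oracle))
        for (i in seq_along(mine)) {
            expect_equal(mine[[i]]@startIndex, oracle[[i]]$start)
            expect_equal(mine[[i]]@endIndex, oracle[[i]]$end)
            expect_equal(mine[[i]]@slope, oracle[[i]]$slope)
            expect_equal(mine[[i]]@intercept, oracle[[i]]$intercept)
            expect_equal(mine[[i]]@r2, oracle[[i]]$r2)
        }
    }
})

test_that("slice bookkeeping: counts, exact lines, and window errors", {
    s <- mkSeries(0:9, 2 * (0:9) + 1)
    slices <- enumerateTrailingSlices(s, c(0, 9), minPoints = 5)
    expect_length(slices, 6)
    expect_equal(vapply(slices, function(x) x@nPoints, integer(1)), 5:10)
    for (sl in slices) {
        expect_equal(sl@endIndex, 10L)
        expect_equal(sl@slope, 2)
        expect_equal(sl@intercept, 1)
        expect_equal(sl@r2, 1)
    }
    expect_error(enumerateTrailingSlices(s, c(7, 9), minPoints = 5),
                 "at least 5")
})

test_that("best-slice selection maximizes r2 with longest-slice ties", {
    mk <- function(r2, n) new("SliceFit", startIndex = 1L,
                              endIndex = as.integer(n), slope = 1,
                              intercept = 0, r2 = r2,
                              nPoints = as.integer(n))
    expect_equal(selectBestSlice(list(mk(0.91, 5), mk(0.99, 6),
                                      mk(0.95, 7)))@r2, 0.99)
    expect_equal(selectBestSlice(list(mk(0.95, 5), mk(0.95, 9)))@nPoints, 9L)
    expect_error(selectBestSlice(list()), "no slices")

    # curvature before an exact 7-point line: the line slice must win whole
    t <- 0:11
    y <- c(5 - (4:0)^2, 3 * (5:11) + 2)   # last 7 points: y = 3t + 2
    s <- mkSeries(t, y)
    best <- selectBestSlice(enumerateTrailingSlices(s, c(0, 11), 5))
    oracle <- bruteForceSlices(s, c(0, 11), 5)
    or2 <- vapply(oracle, function(o) o$r2, numeric(1))
    on <- vapply(oracle, function(o) o$n, numeric(1))
    expect_equal(best@nPoints, 7L)
    expect_equal(best@nPoints, as.integer(on[order(-or2, -on)[1]]))
    expect_equal(best@slope, 3)
})

test_that("rate extraction windows controls and drugged wells differently", {
    t <- seq(0, 96, by = 4)
    # control: exact line over the whole assay, peak at the end
    ctrl <- mkSeries(t, 100 + 50 * t)
    rc <- extractRate(ctrl, controlPeak = 96, isControl = TRUE)
    expect_equal(rc@rate, 50)
    expect_equal(rc@window, c(0, 96))
    expect_length(rc@warnings, 0)

    # drugged: rise to a peak at 24 h, then linear decline at -30 RLU/h
    y <- ifelse(t <= 24, 100 + 100 * t, 2500 - 30 * (t - 24))
    dr <- extractRate(mkSeries(t, y), controlPeak = 96)
    expect_equal(dr@window, c(24, 96))
    expect_equal(dr@rate, -30)

    # peak 4 h before control peak with 4 h sampling: fallback, flagged
    y2 <- ifelse(t <= 92, 10 + 5 * t, 470 - 5 * (t - 92))
    fb <- extractRate(mkSeries(t, y2), controlPeak = 96)
    expect_true("short_window_fallback" %in% fb@warnings)
    expect_equal(fb@window, c(0, 96))

    # a negative control slope is flagged, not hidden
    neg <- extractRate(mkSeries(t, 1000 - 2 * t), controlPeak = 96,
                       isControl = TRUE)
    expect_equal(neg@rate, -2)
    expect_true("negative_control_rate" %in% neg@warnings)

    expect_error(extractRate(mkSeries(c(0, 4, 8), c(1, 2, 3)),
                             controlPeak = 8), "fewer than 5")
    expect_error(extractRate(ctrl, controlPeak = 200), "outside")
})

test_that("noise-free control rate matches the analytic slope at the slice", {
    # slow growth, no depletion: the trace's end region is genuinely linear,
    # so the winning slice's OLS slope must sit on the local derivative
    cfg <- simulationConfig(cv = 0, nReplicates = 1, gamma = 0,
                            doublingTimeH = 200, durationH = 40)
    sim <- simulatePlate(cfg)
    r <- plateRates(sim$plate)
    ctrl <- r[r$concentration_M == 0, ]
    k0 <- log(2) / 200
    mid <- (ctrl$slice_start_h + ctrl$slice_end_h) / 2
    eps <- 1e-4
    dLdt <- (luminescenceCurve(mid + eps, k0, gamma = 0) -
             luminescenceCurve(mid - eps, k0, gamma = 0)) / (2 * eps)
    expect_equal(ctrl$rate, dLdt, tolerance = 0.02)
})

test_that("count rates are exact on geometric series and robust to noise", {
    t <- seq(0, 96, by = 12)
    doubling <- mkSeries(t, 300 * 2^(t / 24))
    rr <- countRate(doubling)
    expect_equal(rr@rate, 1 / 24)
    expect_equal(rr@slice@r2, 1)

    flat <- countRate(mkSeries(t, rep(500, length(t))))
    expect_equal(flat@rate, 0)

    z <- mkSeries(c(0, 12, 24), c(10, 0, 40))
    expect_error(countRate(z), "12")

    # binomial imaging noise, 26 timepoints: slope within 10% of programmed
    tt <- seq(0, 100, by = 4)
    k <- log(2) / 24
    set.seed(7)
    errs <- replicate(100, {
        n <- round(300 * exp(k * tt))
        obs <- rbinom(length(tt), n, 0.1) / 0.1
        countRate(mkSeries(tt, pmax(obs, 1)))@rate
    })
    target <- k / log(2)
    expect_gte(sum(abs(errs - target) / target < 0.10), 95)
    expect_lt(median(abs(errs - target) / target), 0.10)
})

test_that("linearity gate is strict at the threshold", {
    t <- 0:20
    exact <- linearityCheck(mkSeries(t, 3 * t + 7))
    expect_equal(exact$r2, 1)
    expect_true(exact$passes)

    saw <- linearityCheck(mkSeries(0:19, rep(c(10, 20), 10)))
    expect_lt(saw$r2, 0.05)
    expect_false(saw$passes)

    # construct r2 == 0.90 exactly: add a residual component orthogonal to
    # both the time axis and the intercept, scaled to leave 10% unexplained
    x <- as.numeric(1:12)
    v <- x^2 - mean(x^2) -
        (x - mean(x)) * sum((x^2 - mean(x^2)) * (x - mean(x))) /
            sum((x - mean(x))^2)
    sxx <- sum((x - mean(x))^2)
    cc <- sqrt(sxx / (9 * sum(v^2)))
    s <- mkSeries(x, x + cc * v)
    gate <- linearityCheck(s, threshold = 0.9)
    expect_equal(gate$r2, 0.9, tolerance = 1e-12)
    # strictness: a threshold equal to the attained r2 must fail (">"), and
    # nudging the residual component up puts r2 under 0.90 and fails there
    expect_false(linearityCheck(s, threshold = gate$r2)$passes)
    under <- linearityCheck(mkSeries(x, x + cc * (1 + 1e-6) * v),
                            threshold = 0.9)
    expect_false(under$passes)
})

test_that("static RLU-vs-cells calibration behaves like the assay validation", {
    x <- c(100, 200, 400, 800)
    fit <- staticRegression(x, 10 * x)
    expect_equal(fit$slope, 10)
    expect_equal(fit$r2, 1)

    expect_error(staticRegression(c(1, 2), c(1, 2)), "at least 3")
    expect_error(staticRegression(rep(5, 4), 1:4), "degenerate")

    # 2-fold dilution from 10,000 cells over 10 wells, 5% proportional noise
    cells <- 10000 / 2^(0:9)
    set.seed(11)
    ok <- replicate(100, {
        y <- 12 * cells * (1 + rnorm(10, 0, 0.05))
        staticRegression(cells, y)$r2 > 0.92
    })
    expect_gte(sum(ok), 95)
})

test_that("slice choice is invariant to shifting and scaling the signal", {
    set.seed(99)
    for (i in 1:10) {
        t <- seq(0, 80, by = 4)
        y <- 500 * exp(0.02 * t) * (1 + rnorm(length(t), 0, 0.05))
        s <- mkSeries(t, y)
        base <- selectBestSlice(enumerateTrailingSlices(s, minPoints = 5))
        shift <- selectBestSlice(enumerateTrailingSlices(
            mkSeries(t, y + 1234), minPoints = 5))
        expect_equal(shift@startIndex, base@startIndex)
        expect_equal(shift@slope, base@slope)
        expect_equal(shift@r2, base@r2)
        expect_equal(shift@intercept, base@intercept + 1234)
        scaled <- selectBestSlice(enumerateTrailingSlices(
            mkSeries(t, 3.5 * y), minPoints = 5))
        expect_equal(scaled@startIndex, base@startIndex)
        expect_equal(scaled@slope, 3.5 * base@slope)
        expect_equal(scaled@r2, base@r2)
    }
})

test_that("plate-level extraction averages replicates and honors flags", {
    df <- mkLongTable(times = seq(0, 40, by = 4), nConc = 2, nRep = 3)
    plate <- LumPlate(df)
    pooled <- plateRates(plate)
    expect_true(all(is.na(pooled$replicate)))
    # every condition appears exactly once
    expect_equal(nrow(pooled), 3)
    perRep <- plateRates(plate, perReplicate = TRUE)
    expect_equal(nrow(perRep), 9)
    expect_false(any(is.na(perRep$replicate)))
    # mkLongTable wells are exact lines: slope 10 everywhere
    expect_equal(pooled$rate, rep(10, 3))
})
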