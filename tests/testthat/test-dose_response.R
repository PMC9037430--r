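test_that("normalization divides by the basal rate and rejects a zero basal", {
    r <- data.frame(concentration_M = c(1e-9, 1e-8), rate = c(40, -20))
    pts <- normalizeRates(r, 40)
    expect_equal(pts$normalized_rate, c(1, -0.5))
    expect_error(normalizeRates(r, 0), "undefined")
    expect_error(
        normalizeRates(data.frame(concentration_M = 0, rate = 1), 40),
        "concentration > 0")
})

test_that("normalized points and fits are invariant to rescaling the signal", {
    r <- data.frame(concentration_M = 10^seq(-10.5, -7, by = 0.5),
                    rate = c(39, 38, 35, 28, 15, 2, -8, -12))
    for (c_ in c(0.01, 7)) {
        a <- normalizeRates(r, 40)
        b <- normalizeRates(transform(r, rate = c_ * rate), c_ * 40)
        expect_equal(b, a)
        expect_equal(fit4PL(b)@ec50M, fit4PL(a)@ec50M)
        expect_equal(fit4PL(b)@effectClass, fit4PL(a)@effectClass)
    }
})

test_that("noise-free 4PL parameters are recovered within 1%", {
    cases <- list(
        c(e0 = 1, emax = -0.5, ec50 = 1e-8, hill = 1),
        c(e0 = 1, emax = 0.2, ec50 = 3e-9, hill = 2.5),
        c(e0 = 0.95, emax = -1.2, ec50 = 8e-8, hill = 0.7))
    for (p in cases) {
        pts <- points4PL(p["e0"], p["emax"], p["ec50"], p["hill"],
                         conc = 10^seq(-10, -6, by = 0.5))
        fit <- fit4PL(pts)
        expect_true(fit@converged)
        expect_equal(fit@e0, unname(p["e0"]), tolerance = 0.01)
        expect_equal(fit@emax, unname(p["emax"]), tolerance = 0.01)
        expect_equal(fit@hill, unname(p["hill"]), tolerance = 0.01)
        expect_lt(abs(log10(fit@ec50M / p["ec50"])), 0.01)
        expect_lt(fit@residuals, 1e-6)
    }
})

test_that("flat response data yield a no-effect fit", {
    pts <- data.frame(concentration_M = 10^seq(-9, -6, by = 0.5),
                      normalized_rate = 1)
    fit <- fit4PL(pts)
    expect_equal(fit@emax, 1, tolerance = 0.05)
    expect_equal(fit@effectClass, "no_effect")
})

test_that("degenerate inputs to the fitter are refused", {
    pts <- points4PL(1, -0.5, 1e-8, 1)
    expect_error(fit4PL(pts[1:3, ]), "4 points")
    few <- data.frame(concentration_M = rep(c(1e-9, 1e-8), each = 2),
                      normalized_rate = c(1, 1, 0, 0))
    expect_error(fit4PL(few), "3 distinct")
    neg <- pts; neg$concentration_M[1] <- 0
    expect_error(fit4PL(neg), "> 0")
})

test_that("reported residuals equal an independent sum-of-squares recomputation", {
    set.seed(3)
    pts <- points4PL(1, -0.4, 2e-8, 1.5)
    pts$normalized_rate <- pts$normalized_rate + rnorm(nrow(pts), 0, 0.05)
    fit <- fit4PL(pts)
    sse <- sum((pts$normalized_rate -
                predict4PL(fit, pts$concentration_M))^2)
    expect_equal(fit@residuals, sse, tolerance = 1e-8)
})

test_that("the fitted curve is monotone between its asymptotes", {
    set.seed(8)
    pts <- points4PL(1, -0.6, 5e-9, 3)
    pts$normalized_rate <- pts$normalized_rate + rnorm(nrow(pts), 0, 0.03)
    fit <- fit4PL(pts)
    grid <- predict4PL(fit, 10^seq(-12, -4, length.out = 200))
    expect_true(all(diff(grid) <= 1e-10))
    expect_true(all(grid <= fit@e0 + 1e-8 & grid >= fit@emax - 1e-8))
})

test_that("estimates landing on configured bounds are reported", {
    # responses plunging to -8 cannot be reached with the -5 floor
    conc <- 10^seq(-10, -6, by = 0.5)
    y <- -8 + (1 + 8) / (1 + (conc / 1e-8))
    fit <- fit4PL(data.frame(concentration_M = conc, normalized_rate = y))
    expect_equal(fit@emax, -5)
    expect_true("emax" %in% fit@boundsHit)
})

test_that("effect classification follows the maximal-response bands", {
    expect_equal(classifyEffect(-0.480), "cytotoxic")
    expect_equal(classifyEffect(1.0), "no_effect")
    expect_equal(classifyEffect(0.0), "cytostatic")
    expect_equal(classifyEffect(0.5), "anti_proliferative")
    expect_equal(classifyEffect(0.09), "cytostatic")
    expect_equal(classifyEffect(-0.09), "cytostatic")
    expect_equal(classifyEffect(-0.11), "cytotoxic")
    expect_equal(classifyEffect(0.95), "no_effect")
    # tolerances are configurable
    expect_equal(classifyEffect(-0.09, tolZero = 0.05), "cytotoxic")
    # coarse grouping merges the two non-shrinking drugged classes
    expect_equal(mechanismGroup(0.05), "anti_proliferative/cytostatic")
    expect_equal(mechanismGroup(0.5), "anti_proliferative/cytostatic")
    expect_equal(mechanismGroup(-0.05), "cytotoxic")
    expect_equal(mechanismGroup(1), "no_effect")
})

test_that("result tables assemble one row per fit and round-trip", {
    pts <- points4PL(1, -0.5, 1e-8, 1)
    f1 <- fit4PL(pts)
    f2 <- fit4PL(points4PL(1, 0.3, 1e-7, 2))
    keys <- data.frame(cell_line = c("A", "A"), drug = c("d1", "d1"),
                       data_type = c("Lum", "Direct"))
    tab <- buildResultTable(list(f1, f2), keys)
    expect_equal(nrow(tab), 2)
    expect_equal(tab$max_resp, c(f1@emax, f2@emax))

    f <- withr::local_tempfile(fileext = ".csv")
    writeResultTable(tab, f)
    expect_equal(readResultTable(f), tab, ignore_attr = TRUE)

    bad <- keys; bad$data_type <- "Lum"
    expect_error(buildResultTable(list(f1, f2), bad), "duplicate")
})

test_that("plate-level dose-response fitting recovers the programmed truth", {
    sim <- simulatePlate(simulationConfig(seed = 21))
    rates <- plateRates(sim$plate, channel = "count")
    res <- fitDoseResponse(rates, dataType = "Direct")
    fit <- res$fits[["SIM1/drugA"]]
    expect_lt(abs(log10(fit@ec50M / 1e-8)), 0.15)
    expect_lt(abs(fit@emax - (-0.5)), 0.15)
    expect_equal(fit@effectClass, "cytotoxic")
    expect_equal(res$table$data_type, "Direct")
})
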