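test_that("a small long table builds a valid plate and round-trips", {
    df <- mkLongTable()
    plate <- LumPlate(df)
    expect_s4_class(plate, "LumPlate")
    expect_equal(nrow(plate), length(unique(
        paste(df$cell_line, df$drug, df$concentration_M, df$replicate))))
    expect_equal(assayTimes(plate), sort(unique(df$time_h)))

    one <- df[df$concentration_M == 0 & df$replicate == 1, ]
    s <- wellSeries(plate, 1)
    expect_equal(s$time_h, one$time_h)
    expect_equal(s$value, one$rlu)

    back <- asLongTable(plate)
    ord <- function(x) x[order(x$cell_line, x$drug, x$concentration_M,
                               x$replicate, x$time_h), ]
    expect_equal(ord(back), ord(df), ignore_attr = TRUE)
})

test_that("plate CSV write/read reproduces simulator output field by field", {
    for (seed in c(2, 11)) {
        sim <- simulatePlate(simulationConfig(
            seed = seed, durationH = 48, sampleIntervalH = 4,
            nReplicates = 2,
            concentrationsM = 10^seq(-9, -7.5, by = 0.5)))
        f <- withr::local_tempfile(fileext = ".csv")
        writePlate(sim$plate, f)
        back <- readPlate(f)
        expect_equal(wellInfo(back), wellInfo(sim$plate))
        expect_equal(assayTimes(back), assayTimes(sim$plate))
        expect_equal(assay(back, "rlu"), assay(sim$plate, "rlu"),
                     ignore_attr = TRUE)
        expect_equal(assay(back, "count"), assay(sim$plate, "count"),
                     ignore_attr = TRUE)
    }
})

test_that("schema maps foreign column names, units and control aliases", {
    raw <- data.frame(line = "A", compound = c("DMSO", "drugX", "drugX"),
                      conc_uM = c(1, 0.01, 0.01), rep = 1,
                      t_min = c(0, 0, 240), signal = c(5, 5, 9))
    raw <- rbind(raw, within(raw[1, ], t_min <- 240))
    f <- withr::local_tempfile(fileext = ".csv")
    write.csv(raw, f, row.names = FALSE)
    schema <- plateSchema(
        columns = list(cell_line = "line", drug = "compound",
                       concentration_M = "conc_uM", replicate = "rep",
                       time_h = "t_min", rlu = "signal"),
        control_aliases = c("dmso"),
        time_multiplier = 1 / 60, concentration_multiplier = 1e-6)
    plate <- readPlate(f, schema)
    info <- wellInfo(plate)
    expect_equal(sort(info$concentration_M), c(0, 1e-8))
    expect_equal(assayTimes(plate), c(0, 4))
    # YAML round-trip of the same schema
    y <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(
        columns = list(cell_line = "line", drug = "compound",
                       concentration_M = "conc_uM", replicate = "rep",
                       time_h = "t_min", rlu = "signal"),
        control_aliases = list("dmso"),
        time_multiplier = 1 / 60,
        concentration_multiplier = 1e-6), y)
    plate2 <- readPlate(f, readSchema(y))
    expect_equal(assay(plate2, "rlu"), assay(plate, "rlu"),
                 ignore_attr = TRUE)
})

test_that("malformed plate inputs are rejected with a named diagnosis", {
    df <- mkLongTable()
    f <- withr::local_tempfile(fileext = ".csv")
    write.csv(df[, setdiff(colnames(df), "rlu")], f, row.names = FALSE)
    expect_error(readPlate(f), "rlu")

    dup <- rbind(df, df[1, ])
    expect_error(LumPlate(dup), "duplicated.*control",
                 ignore.case = TRUE)

    neg <- df; neg$rlu[3] <- -1
    expect_error(LumPlate(neg), "nonnegative")

    # a cell line without any control condition fails validity unless flagged
    nc <- df[df$concentration_M > 0, ]
    expect_error(LumPlate(nc), "control")
    expect_s4_class(LumPlate(nc, metadata = list(control_free = TRUE)),
                    "LumPlate")
})

test_that("result table writes verbatim rows and round-trips", {
    panel <- sclcPanel()
    row <- panel[panel$cell_line == "DMS114" & panel$drug == "Barasertib", ]
    expect_equal(row$hill_coef, 8.754)
    expect_equal(row$max_resp, -0.079)
    expect_equal(row$ec50_M, 7.86e-9)
    expect_equal(row$residuals, 9.812)

    f <- withr::local_tempfile(fileext = ".csv")
    writeResultTable(row, f)
    txt <- readLines(f)
    expect_match(txt[1], "^cell_line,drug,data_type,hill_coef,max_resp,ec50_M,residuals$")
    expect_match(txt[2], "^DMS114,Barasertib,Lum,8.754,-0.079,7.86e-09,9.812$")

    writeResultTable(panel, f)
    expect_equal(readResultTable(f), panel, ignore_attr = TRUE)

    empty <- panel[0, ]
    writeResultTable(empty, f)
    expect_equal(length(readLines(f)), 1L)

    dup <- rbind(panel, panel[1, ])
    expect_error(writeResultTable(dup, f), "duplicate")
})

test_that("rates table round-trips through CSV", {
    sim <- simulatePlate(simulationConfig(
        seed = 5, durationH = 60, nReplicates = 1,
        concentrationsM = 10^seq(-9, -7.5, by = 0.5)))
    r <- suppressWarnings(plateRates(sim$plate))
    f <- withr::local_tempfile(fileext = ".csv")
    writeRates(r, f)
    back <- readRates(f)
    cols <- c("cell_line", "drug", "concentration_M", "replicate",
              "rate", "r2", "slice_start_h", "slice_end_h", "n_points")
    expect_equal(back[, cols], r[, cols], ignore_attr = TRUE)
})
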