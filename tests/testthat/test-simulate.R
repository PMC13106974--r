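test_that("the same seed reproduces a run exactly", {
    a <- simulateRun(SimParams(nCells = 15, seed = 9L))
    b <- simulateRun(SimParams(nCells = 15, seed = 9L))
    expect_identical(intensities(a$trace), intensities(b$trace))
    expect_identical(a$truth, b$truth)
    c <- simulateRun(SimParams(nCells = 15, seed = 10L))
    expect_false(identical(intensities(a$trace), intensities(c$trace)))
})

test_that("noiseless pulses conserve emitted counts exactly", {
    p <- SimParams(nCells = 3, massMean = 2, massSd = 0, sensitivity = 100,
                   baselineRate = 0, noise = FALSE, nBlanks = 2,
                   standardMasses = c(0, 173), standardReplicates = 1L,
                   seed = 1L)
    sim <- simulateRun(p)
    cells <- sim$truth[sim$truth$kind == "cell", ]
    expect_equal(cells$emitted_counts, rep(200, 3))
    # integrating the trace recovers those counts exactly
    cfg <- RunConfig(integrationUnits = "counts")
    thr <- suppressWarnings(
        computeBlankThreshold(sim$trace, sim$events, cfg))
    expect_equal(thresholdValue(thr), 0)
    m <- quantifyEvents(sim$trace, sim$events, thr, cfg)
    expect_equal(m$integrated_response, cells$emitted_counts)
})

test_that("a 5-sigma threshold silences a baseline-only run", {
    p <- SimParams(nCells = 0, nBlanks = 50, baselineRate = 100,
                   standardMasses = c(0, 173), standardReplicates = 1L,
                   seed = 77L)
    sim <- simulateRun(p)
    thr0 <- computeBlankThreshold(sim$trace, sim$events, RunConfig())
    # mean + 5 * per-sample SD (the blank noise band), as a Threshold
    thr <- Threshold(thr0@blankMean + 5 * thr0@blankPointSd)
    blanks <- sim$events[sim$events$kind == "blank", ]
    hits <- vapply(seq_len(nrow(blanks)), function(i) {
        idx <- which(times(sim$trace) >= blanks$t_start[i] &
                     times(sim$trace) < blanks$t_end[i])
        !is.null(detectPeak(intensities(sim$trace)[idx], thr))
    }, logical(1))
    expect_equal(sum(hits), 0L)
})

test_that("simulated calibration matches its declared sensitivity", {
    pn <- SimParams(sensitivity = 100, noise = FALSE, seed = 2L)
    stdn <- simulateCalibration(pn)
    expect_equal(stdn$integrated_response, 100 * stdn$nominal_mass_fg)
    expect_equal(nrow(stdn), 6L * 2L)

    # Poisson ladder: fitted slope within 3 SE of the true sensitivity,
    # with the SE from the exact Poisson sampling variance of the OLS
    # slope, var = sum(w_i^2 * sens * m_i), w_i = (m_i - mbar) / Sxx
    p <- SimParams(sensitivity = 100, standardReplicates = 4L, seed = 3L)
    std <- simulateCalibration(p)
    cv <- fitCalibration(std)
    m <- std$nominal_mass_fg
    w <- (m - mean(m)) / sum((m - mean(m))^2)
    se <- sqrt(sum(w^2 * 100 * m))
    expect_lt(abs(calSlope(cv) - 100), 3 * se)
})

test_that("cell masses follow the requested distribution", {
    p <- SimParams(nCells = 500, seed = 13L)
    sim <- simulateRun(p)
    m <- sim$truth$true_mass_fg[sim$truth$kind == "cell"]
    expect_true(all(m > 0))
    expect_lt(abs(mean(m) - 1.83), 3 * 0.27 / sqrt(500))
    pl <- SimParams(nCells = 500, massDistribution = "lognormal",
                    seed = 13L)
    ml <- simulateRun(pl)$truth
    ml <- ml$true_mass_fg[ml$kind == "cell"]
    expect_lt(abs(mean(ml) - 1.83), 4 * 0.27 / sqrt(500))
    expect_gt(mean((ml - mean(ml))^3), 0)   # right-skewed
})

test_that("true-zero cells end up flagged below the LOD", {
    # a baseline-only run whose second half of blanks is relabelled as
    # cells: every such "cell" holds no analyte at all
    p <- SimParams(nCells = 0, nBlanks = 60, seed = 19L)
    sim <- simulateRun(p)
    ev <- sim$events
    zero <- grepl("blank_0(3[1-9]|[4-6][0-9])", ev$spot_id)
    ev$kind[zero] <- "cell"
    ev$group[zero] <- "zero"
    run <- quantifyRun(sim$trace, ev, RunConfig(lodK = 3))
    flagged <- grepl("BELOW_LOD", run$measurements$flags, fixed = TRUE)
    expect_gte(mean(flagged), 0.99)
})

test_that("a too-wide pulse for its window is rejected", {
    expect_error(simulateRun(SimParams(pulseWidth = 3, windowTime = 4)),
                 "wider")
})

test_that("end-to-end pipeline recovers simulated masses", {
    sim <- simulateRun(SimParams(seed = 7L))      # defaults: 100 cells
    run <- quantifyRun(sim$trace, sim$events, RunConfig())
    tt <- merge(run$measurements,
                sim$truth[sim$truth$kind == "cell",
                          c("spot_id", "true_mass_fg")])
    relErr <- abs(mean(tt$mass_fg) - mean(tt$true_mass_fg)) /
        mean(tt$true_mass_fg)
    expect_lt(relErr, 0.05)
    rmse <- sqrt(mean((tt$mass_fg - tt$true_mass_fg)^2))
    expect_lt(rmse / mean(tt$true_mass_fg), 0.10)
    # essentially every true-zero event (blanks aside) would be flagged;
    # here: all cells clear the LOD instead
    expect_true(all(tt$mass_fg > run$lod))
})
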