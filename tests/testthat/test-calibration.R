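ladder <- c(0, 173, 351, 684, 1821, 3455)

test_that("exact linear standards give the exact line and r2 = 1", {
    std <- data.frame(nominal_mass_fg = ladder,
                      integrated_response = 100 * ladder + 500)
    cv <- fitCalibration(std)
    expect_equal(calSlope(cv), 100)
    expect_equal(calIntercept(cv), 500)
    expect_equal(calRSquared(cv), 1.0)

    two <- data.frame(nominal_mass_fg = c(0, 100),
                      integrated_response = c(0, 1000))
    cv2 <- fitCalibration(two)
    expect_equal(calSlope(cv2), 10)
    expect_equal(calIntercept(cv2), 0)

    same <- data.frame(nominal_mass_fg = c(100, 100),
                       integrated_response = c(1, 2))
    expect_error(fitCalibration(same), "identical")
    inv <- data.frame(nominal_mass_fg = c(0, 100),
                      integrated_response = c(1000, 0))
    expect_error(fitCalibration(inv), "inverted")
})

test_that("the fit equals the closed-form normal-equations solution", {
    set.seed(404)
    # the printed six-mass ladder with 1% multiplicative noise
    m <- ladder
    r <- 100 * m * (1 + rnorm(length(m), 0, 0.01))
    cv <- fitCalibration(data.frame(nominal_mass_fg = m,
                                    integrated_response = r))
    want <- oracleOls(m, r)
    expect_equal(calSlope(cv), want$slope, tolerance = 1e-9)
    expect_equal(calIntercept(cv), want$intercept, tolerance = 1e-9)
    expect_equal(calRSquared(cv), want$r2, tolerance = 1e-9)
    expect_equal(cv@residualSd, want$residualSd, tolerance = 1e-9)

    # property: arbitrary replicate tables, including duplicated masses
    for (i in 1:25) {
        n <- sample(3:30, 1)
        m <- sample(ladder, n, replace = TRUE)
        if (length(unique(m)) < 2) next
        r <- 50 * m + rnorm(n, 0, 200)
        if (stats::cov(m, r) <= 0) next
        cv <- fitCalibration(data.frame(nominal_mass_fg = m,
                                        integrated_response = r))
        want <- oracleOls(m, r)
        expect_equal(calSlope(cv), want$slope, tolerance = 1e-9)
        expect_equal(calIntercept(cv), want$intercept, tolerance = 1e-9)
        expect_equal(calRSquared(cv), want$r2, tolerance = 1e-9)
    }
})

test_that("responseToMass inverts the calibration line", {
    cv <- fitCalibration(data.frame(
        nominal_mass_fg = ladder, integrated_response = 100 * ladder + 500))
    cfg <- RunConfig()
    expect_equal(responseToMass(650, cv, cfg)$mass_fg, 1.5)
    # response at the intercept is 0 fg and sits below any positive LOD
    at0 <- responseToMass(500, cv, cfg, lod = 0.9, loq = 3)
    expect_equal(at0$mass_fg, 0)
    expect_identical(at0$flags, "BELOW_LOD;BELOW_LOQ")
    # negative masses clamp to 0 with BELOW_LOD unless allowed
    neg <- responseToMass(100, cv, cfg)
    expect_equal(neg$mass_fg, 0)
    expect_identical(neg$flags, "BELOW_LOD")
    raw <- responseToMass(100, cv, RunConfig(allowNegativeMass = TRUE))
    expect_equal(raw$mass_fg, -4)
    # slope-only replication mode ignores the intercept
    so <- responseToMass(650, cv, RunConfig(slopeOnly = TRUE))
    expect_equal(so$mass_fg, 6.5)

    # round trip: mass -> noiseless response -> mass
    mass <- c(0.37, 1.83, 12.5, 3455)
    resp <- calIntercept(cv) + calSlope(cv) * mass
    expect_equal(responseToMass(resp, cv, cfg)$mass_fg, mass,
                 tolerance = 1e-9)
})

test_that("LOD and LOQ follow the k-sigma convention on blank responses", {
    cv <- fitCalibration(data.frame(nominal_mass_fg = c(0, 100),
                                    integrated_response = c(0, 10000)))
    lims <- lodLoq(curve = cv, config = RunConfig(), sd = 30)
    expect_equal(unname(lims["lod"]), 0.9)
    expect_equal(unname(lims["loq"]), 3.0)
    expect_warning(z <- lodLoq(curve = cv, config = RunConfig(), sd = 0),
                   "zero")
    expect_equal(unname(z["lod"]), 0)
    expect_warning(u <- lodLoq(c(5), cv, RunConfig()), "undefined")
    expect_true(all(is.na(u)))
})

test_that("drift model anchors are response ratios at the reference mass", {
    std <- data.frame(nominal_mass_fg = c(3455, 3455),
                      t_mid = c(0, 100),
                      integrated_response = c(1000, 800))
    dm <- buildDriftModel(std)
    expect_equal(dm@anchorFactors, c(1.0, 0.8))
    expect_equal(dm@anchorTimes, c(0, 100))

    flat <- std; flat$integrated_response <- c(1000, 1000)
    expect_equal(buildDriftModel(flat)@anchorFactors, c(1, 1))

    three <- data.frame(nominal_mass_fg = 3455, t_mid = c(0, 50, 100),
                        integrated_response = c(1000, 900, 800))
    dm3 <- buildDriftModel(three)
    expect_equal(driftFactor(dm3, 25), 0.95)

    one <- std[1, ]
    expect_warning(id <- buildDriftModel(one), "identity")
    expect_equal(driftFactor(id, c(-5, 40)), c(1, 1))

    zero <- std; zero$integrated_response <- c(0, 800)
    expect_error(buildDriftModel(zero), "zero response")
})

test_that("drift correction divides by the interpolated factor", {
    dm <- buildDriftModel(data.frame(
        nominal_mass_fg = 3455, t_mid = c(0, 100),
        integrated_response = c(1000, 800)))
    expect_equal(correctDrift(900, 50, dm), 1000)       # factor 0.9
    expect_equal(correctDrift(123.4, 7, identityDriftModel()), 123.4)
    # clamped to the nearest anchor outside the anchor range
    expect_equal(driftFactor(dm, -10), 1.0)
    expect_equal(driftFactor(dm, 250), 0.8)
})

test_that("drift correction cancels simulated multiplicative drift", {
    # identical true masses under a 30% linear sensitivity decline
    pDrift <- SimParams(nCells = 40L, massMean = 2, massSd = 0,
                        sensitivity = 1e5, baselineRate = 1,
                        nBlanks = 6L, seed = 31L)
    Trun <- (40 + 6 + 2 * 6) * pDrift@windowTime
    pDrift@driftSlope <- -0.3 / Trun
    simD <- simulateRun(pDrift)
    runD <- quantifyRun(simD$trace, simD$events,
                        RunConfig(driftCorrection = "piecewise_linear"))
    pFlat <- pDrift; pFlat@driftSlope <- 0
    simF <- simulateRun(pFlat)
    runF <- quantifyRun(simF$trace, simF$events, RunConfig())
    cvD <- sd(runD$measurements$corrected_response) /
        mean(runD$measurements$corrected_response)
    cvF <- sd(runF$measurements$corrected_response) /
        mean(runF$measurements$corrected_response)
    # corrected responses are as tight as the no-drift Poisson spread
    expect_lt(cvD, cvF * 1.5)
    expect_equal(mean(runD$measurements$mass_fg), 2, tolerance = 0.02)

    # without correction the response trend matches the injected profile
    runU <- quantifyRun(simD$trace, simD$events, RunConfig())
    mU <- runU$measurements
    fit <- lm(integrated_response ~ t_mid, data = mU)
    expSlope <- pDrift@driftSlope * 2 * 1e5 / pDrift@dwellTime
    expect_equal(unname(coef(fit)[2]), expSlope, tolerance = 0.25)
})
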