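# helper: one trace whose windows hold prescribed CPS values
traceFromCps <- function(cps, dwell = 0.01) {
    TimeTrace(times = (seq_along(cps) - 1) * dwell, intensities = cps,
              dwellTime = dwell)
}

test_that("blank threshold averages per-blank means, unweighted", {
    # three blanks of different lengths with per-blank means 100, 120, 110
    cps <- c(90, 110,            # blank 1: mean 100
             120, 100, 140,      # blank 2: mean 120
             110, 110,           # blank 3: mean 110
             rep(0, 3))
    tr <- traceFromCps(cps)
    ev <- data.frame(
        spot_id = c("b1", "b2", "b3"), kind = "blank",
        t_start = c(0, 0.02, 0.05), t_end = c(0.02, 0.05, 0.07),
        nominal_mass_fg = NA, group = "")
    thr <- computeBlankThreshold(tr, ev, RunConfig())
    expect_equal(thresholdValue(thr), 110)
    expect_equal(thr@blankMean, 110)
    expect_equal(thr@blankSd, 10)
    expect_equal(thr@nBlanks, 3L)

    # k-sigma method shifts by kSigma * sd of per-blank means
    thr3 <- computeBlankThreshold(tr, ev,
        RunConfig(thresholdMethod = "blank_mean_plus_k_sigma", kSigma = 3))
    expect_equal(thresholdValue(thr3), 110 + 30)

    # single blank: sd degenerates to 0, so +k*sigma equals the mean
    thr1 <- computeBlankThreshold(tr, ev[1, ],
        RunConfig(thresholdMethod = "blank_mean_plus_k_sigma", kSigma = 3))
    expect_equal(thresholdValue(thr1), 100)
    expect_equal(thr1@blankSd, 0)

    expect_error(computeBlankThreshold(tr, ev[0, ], RunConfig()),
                 "no blank measurements")
    z <- data.frame(spot_id = "b", kind = "blank", t_start = 0.07,
                    t_end = 0.1, nominal_mass_fg = NA, group = "")
    expect_warning(computeBlankThreshold(tr, z, RunConfig()), "zero")
})

test_that("blank threshold tracks the Poisson baseline mean", {
    set.seed(202)
    lambda <- 100; dwell <- 0.01; nper <- 200
    cps <- rpois(20 * nper, lambda) / dwell
    tr <- traceFromCps(cps, dwell)
    ev <- data.frame(spot_id = sprintf("b%02d", 1:20), kind = "blank",
                     t_start = (0:19) * nper * dwell,
                     t_end = (1:20) * nper * dwell,
                     nominal_mass_fg = NA, group = "")
    thr <- computeBlankThreshold(tr, ev, RunConfig())
    se <- sqrt(lambda / (20 * nper)) / dwell
    expect_lt(abs(thresholdValue(thr) - lambda / dwell), 3 * se)
})

test_that("peak boundaries follow the first sub-threshold local minimum", {
    thr <- Threshold(10)
    pk <- detectPeak(c(5, 4, 6, 50, 200, 120, 30, 4, 5), thr)
    expect_equal(pk@iLeft, 2L)     # CPS value 4, first downward dip left
    expect_equal(pk@iRight, 8L)
    expect_equal(pk@iApex, 5L)
    expect_equal(pk@integratedResponse, 414)
    expect_false(pk@edgeTruncated)

    expect_null(detectPeak(c(1, 2, 1), thr))
    pe <- detectPeak(c(200, 120, 5), thr)
    expect_equal(pe@iLeft, 1L)
    expect_true(pe@edgeTruncated)
    expect_error(detectPeak(numeric(), thr), "empty segment")

    # first_at_or_below stops at the nearest sub-threshold sample even if
    # it is not a local minimum
    cfg <- RunConfig(boundaryRule = "first_at_or_below")
    pf <- detectPeak(c(5, 4, 6, 50, 200, 120, 30, 4, 5), thr, cfg)
    expect_equal(pf@iLeft, 3L)
    expect_equal(pf@iRight, 8L)
    expect_equal(pf@integratedResponse, sum(c(6, 50, 200, 120, 30, 4)))

    # counts mode multiplies the summed CPS by the dwell time
    cc <- RunConfig(integrationUnits = "counts")
    pc <- detectPeak(c(5, 4, 6, 50, 200, 120, 30, 4, 5), thr, cc,
                     dwellTime = 0.01)
    expect_equal(pc@integratedResponse, 4.14)

    # apex ties resolve to the earliest index
    pt <- detectPeak(c(0, 50, 50, 0), thr)
    expect_equal(pt@iApex, 2L)
})

test_that("detected window matches the brute-force boundary oracle", {
    set.seed(303)
    for (rule in c("local_min_at_or_below", "first_at_or_below")) {
        cfg <- RunConfig(boundaryRule = rule)
        for (rep in 1:200) {
            n <- sample(5:200, 1)
            lambda <- runif(1, 2, 30)
            y <- rpois(n, lambda)
            k <- sample(n, 1)
            amp <- rpois(1, runif(1, 0, 8 * lambda))
            y[k] <- y[k] + amp
            thr <- Threshold(lambda)
            got <- detectPeak(y, thr, cfg)
            want <- oraclePeak(y, lambda, rule)
            if (is.null(want)) {
                expect_null(got)
            } else {
                expect_equal(got@iLeft, want$iLeft)
                expect_equal(got@iRight, want$iRight)
                expect_equal(got@iApex, want$iApex)
                expect_equal(got@integratedResponse, want$response)
                expect_identical(got@edgeTruncated, want$edgeTruncated)
            }
        }
    }
})

test_that("integration is linear in offsets and scale", {
    # adding c > 0 to every in-window sample adds exactly c * width, on a
    # segment whose boundaries cannot move (all samples super-threshold,
    # window pinned to the segment edges)
    y <- c(50, 200, 120, 30)
    pk <- detectPeak(y, Threshold(10))
    expect_equal(c(pk@iLeft, pk@iRight), c(1L, 4L))
    width <- pk@iRight - pk@iLeft + 1L
    pk2 <- detectPeak(y + 7, Threshold(10))
    expect_equal(pk2@integratedResponse,
                 pk@integratedResponse + 7 * width)
    # scaling intensities and threshold together scales the response
    y <- c(5, 4, 6, 50, 200, 120, 30, 4, 5)
    pk <- detectPeak(y, Threshold(10))
    pk3 <- detectPeak(y * 3.5, Threshold(35))
    expect_equal(pk3@iLeft, pk@iLeft)
    expect_equal(pk3@iRight, pk@iRight)
    expect_equal(pk3@integratedResponse, 3.5 * pk@integratedResponse)
})

test_that("quantifyEvents reports every cell, in order, with flags", {
    toy <- c(5, 4, 6, 50, 200, 120, 30, 4, 5)
    cps <- c(toy, rep(2, 9), toy, toy)
    tr <- traceFromCps(cps)
    win <- 9 * 0.01
    ev <- data.frame(
        spot_id = c("c1", "flat", "c2", "c3"), kind = "cell",
        t_start = (0:3) * win, t_end = (1:4) * win,
        nominal_mass_fg = NA,
        group = "donor1")
    m <- quantifyEvents(tr, ev, Threshold(10), RunConfig())
    expect_equal(m$spot_id, c("c1", "flat", "c2", "c3"))
    expect_equal(m$integrated_response[c(1, 3, 4)], rep(414, 3))
    # undetected cell is kept, with response 0 and BELOW_LOD
    expect_equal(m$integrated_response[2], 0)
    expect_identical(m$flags[2], "BELOW_LOD")
    # window outside the trace names the spot
    bad <- data.frame(spot_id = "ghost", kind = "cell", t_start = 99,
                      t_end = 100, nominal_mass_fg = NA, group = "")
    expect_error(quantifyEvents(tr, bad, Threshold(10), RunConfig()),
                 "ghost")
})

test_that("spot identities survive a full simulated run", {
    sim <- smallSim(seed = 21L, nCells = 30L)
    thr <- computeBlankThreshold(sim$trace, sim$events, RunConfig())
    m <- quantifyEvents(sim$trace, sim$events, thr, RunConfig())
    cells <- sim$events$spot_id[sim$events$kind == "cell"]
    expect_equal(nrow(m), length(cells))
    expect_setequal(m$spot_id, cells)
})
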