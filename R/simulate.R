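.GAUSS_FWHM <- 2 * sqrt(2 * log(2))   # FWHM = 2.3548 sigma

# complementary error function via the normal CDF
.erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

# exponentially modified gaussian density (tailing washout), tau = sigma
.emgDensity <- function(t, mu, sigma, tau) {
    z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
    (1 / (2 * tau)) * exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) *
        .erfc(z)
}

.pulseWeights <- function(t, center, params) {
    sigma <- params@pulseWidth / .GAUSS_FWHM
    w <- switch(params@pulseShape,
        gaussian = stats::dnorm(t, mean = center, sd = sigma),
        exp_modified_gaussian = .emgDensity(t, mu = center - sigma,
                                            sigma = sigma, tau = sigma))
    w / sum(w)   # all emitted counts land inside the event window
}

.drawMasses <- function(n, params) {
    if (n == 0L) return(numeric())
    if (params@massSd == 0) return(rep(params@massMean, n))
    if (params@massDistribution == "normal_truncated_at_zero") {
        out <- numeric(0)
        while (length(out) < n) {
            x <- stats::rnorm(n, params@massMean, params@massSd)
            out <- c(out, x[x > 0])
        }
        out[seq_len(n)]
    } else {
        s2 <- log(1 + (params@massSd / params@massMean)^2)
        stats::rlnorm(n, meanlog = log(params@massMean) - s2 / 2,
                      sdlog = sqrt(s2))
    }
}

# event sequence: ladder blocks spread over the run, blanks split between
# the start (after the first ladder) and the end, cells chunked between
# consecutive ladder blocks
.eventPlan <- function(params) {
    R <- params@standardReplicates
    ladder <- function(rep) {
        k <- order(params@standardMasses)
        # bracketing: the first block runs the ladder downward and the last
        # upward, so the highest mass (the drift anchor) is ablated at the
        # very start and very end of the run and every other event sits
        # between the anchors, where interpolated drift factors apply
        if (rep < R || R == 1L) k <- rev(k)
        data.frame(
            spot_id = sprintf("std_%d_%02d", rep, k),
            kind = "standard",
            nominal_mass_fg = params@standardMasses[k],
            group = "cal")
    }
    blanks <- function(idx) {
        if (length(idx) == 0L) return(NULL)
        data.frame(spot_id = sprintf("blank_%03d", idx), kind = "blank",
                   nominal_mass_fg = NA_real_, group = "")
    }
    cells <- function(idx) {
        if (length(idx) == 0L) return(NULL)
        data.frame(spot_id = sprintf("cell_%03d", idx), kind = "cell",
                   nominal_mass_fg = NA_real_, group = "sim")
    }
    nb1 <- ceiling(params@nBlanks / 2)
    blankA <- blanks(seq_len(nb1))
    blankB <- blanks(seq_len(params@nBlanks - nb1) + nb1)
    if (R == 1L) {
        plan <- rbind(ladder(1L), blankA, cells(seq_len(params@nCells)),
                      blankB)
    } else {
        nChunk <- R - 1L
        split <- floor(params@nCells * seq(0, nChunk) / nChunk)
        pieces <- list(ladder(1L), blankA)
        for (k in seq_len(nChunk)) {
            idx <- seq.int(split[k] + 1L, length.out = split[k + 1L] -
                               split[k])
            pieces <- c(pieces, list(cells(idx)))
            if (k < nChunk) pieces <- c(pieces, list(ladder(k + 1L)))
        }
        pieces <- c(pieces, list(blankB, ladder(R)))
        plan <- do.call(rbind, pieces)
    }
    plan$t_start <- (seq_len(nrow(plan)) - 1L) * params@windowTime
    plan$t_end <- plan$t_start + params@windowTime
    rownames(plan) <- NULL
    plan[c("spot_id", "kind", "t_start", "t_end", "nominal_mass_fg",
           "group")]
}

#' Simulate a full LA-ICP-MS acquisition with ground truth
#'
#' Generates one continuous trace of consecutive ablation spots: a Poisson
#' baseline everywhere, plus one short super-threshold pulse per cell and
#' per standard whose expected total counts are
#' `mass * sensitivity * driftFactor(t)`. Blanks are baseline-only windows.
#' The per-sample count is Poisson around baseline-plus-pulse expectation
#' (or exactly the expectation when `noise = FALSE`), divided by the dwell
#' time to give CPS. The event log uses the on-disk schema of
#' [readEvents()]; the truth table records each spot's true mass, realised
#' signal counts, window and drift factor. The same seed reproduces the run
#' exactly.
#'
#' @param params a [SimParams-class].
#' @return list with elements `trace` ([TimeTrace-class]), `events`
#'   (data.frame), `truth` (data.frame with `spot_id`, `kind`,
#'   `true_mass_fg`, `emitted_counts`, `t_start`, `t_end`,
#'   `drift_factor`) and `params`.
#' @export
simulateRun <- function(params = SimParams()) {
    validObject(params)
    sigma <- params@pulseWidth / .GAUSS_FWHM
    support <- if (params@pulseShape == "gaussian") 6 * sigma
               else 6 * sigma + 6 * sigma   # gaussian core + exponential tail
    if (support > params@windowTime)
        stop("pulse (FWHM ", params@pulseWidth,
             " s) is wider than its event window (", params@windowTime,
             " s)")
    set.seed(params@seed)
    plan <- .eventPlan(params)
    nEvents <- nrow(plan)
    n <- as.integer(round(nEvents * params@windowTime / params@dwellTime))
    t <- (seq_len(n) - 1L) * params@dwellTime

    masses <- numeric(nEvents)
    masses[plan$kind == "standard"] <-
        plan$nominal_mass_fg[plan$kind == "standard"]
    masses[plan$kind == "cell"] <-
        .drawMasses(sum(plan$kind == "cell"), params)

    counts <- if (params@noise) stats::rpois(n, params@baselineRate)
              else rep(params@baselineRate, n)
    emitted <- numeric(nEvents)
    driftAt <- numeric(nEvents)
    for (i in seq_len(nEvents)) {
        center <- (plan$t_start[i] + plan$t_end[i]) / 2
        d <- 1 + params@driftSlope * center
        if (d <= 0)
            stop("drift factor is non-positive at t = ", center, " s")
        driftAt[i] <- d
        if (plan$kind[i] == "blank" || masses[i] == 0)
            next
        idx <- which(t >= plan$t_start[i] & t < plan$t_end[i])
        w <- .pulseWeights(t[idx], center, params)
        lam <- masses[i] * params@sensitivity * d * w
        sig <- if (params@noise) stats::rpois(length(lam), lam) else lam
        counts[idx] <- counts[idx] + sig
        emitted[i] <- sum(sig)
    }

    trace <- TimeTrace(times = t, intensities = counts / params@dwellTime,
                       analyte = "56Fe",
                       acquisitionId = sprintf("sim_seed%d", params@seed),
                       dwellTime = params@dwellTime)
    truth <- data.frame(spot_id = plan$spot_id, kind = plan$kind,
                        true_mass_fg = ifelse(plan$kind == "blank", 0,
                                              masses),
                        emitted_counts = emitted,
                        t_start = plan$t_start, t_end = plan$t_end,
                        drift_factor = driftAt)
    list(trace = trace, events = plan, truth = truth, params = params)
}

#' Simulate integrated calibration standards directly
#'
#' Shortcut past the trace: each replicate of each ladder mass yields an
#' integrated response in counts, Poisson-distributed around
#' `mass * sensitivity` (exact when `noise = FALSE`), at acquisition times
#' one window apart.
#'
#' @param params a [SimParams-class]; `standardMasses`,
#'   `standardReplicates`, `sensitivity`, `noise` and `seed` are used.
#' @return data.frame with columns `spot_id`, `nominal_mass_fg`, `t_mid`,
#'   `integrated_response` (counts) and `true_counts`.
#' @export
simulateCalibration <- function(params = SimParams()) {
    validObject(params)
    if (length(params@standardMasses) < 2L)
        stop("need at least 2 standard masses")
    set.seed(params@seed)
    m <- rep(params@standardMasses, times = params@standardReplicates)
    rep_id <- rep(seq_len(params@standardReplicates),
                  each = length(params@standardMasses))
    lam <- m * params@sensitivity
    resp <- if (params@noise) stats::rpois(length(lam), lam) else lam
    data.frame(
        spot_id = sprintf("std_%d_%02d", rep_id,
                          rep(seq_along(params@standardMasses),
                              times = params@standardReplicates)),
        nominal_mass_fg = m,
        t_mid = (seq_along(m) - 0.5) * params@windowTime,
        integrated_response = as.numeric(resp),
        true_counts = lam)
}

#' Write a simulated run to disk
#'
#' Emits `trace.csv`, `events.csv` and `truth.csv` in the trace_io dialects.
#'
#' @param sim result of [simulateRun()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedRun <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeTrace(sim$trace, file.path(dir, "trace.csv"))
    writeEvents(sim$events, file.path(dir, "events.csv"))
    tr <- sim$truth[c("spot_id", "true_mass_fg", "emitted_counts")]
    write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE,
              quote = FALSE)
    invisible(dir)
}
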