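.canonFlags <- function(...) {
    toks <- unlist(strsplit(c(...), ";", fixed = TRUE))
    toks <- unique(toks[nzchar(toks)])
    paste(.FLAGS[.FLAGS %in% toks], collapse = ";")
}

#' Run the full single-cell quantification pipeline on one acquisition
#'
#' In order: (1) the background threshold from the run's blanks; (2) peak
#' integration of every standard and every cell event with the same
#' boundary rule; (3) a piecewise-linear drift model from the repeated
#' highest-mass standards (when `driftCorrection = "piecewise_linear"`),
#' applied to standards, blanks and cells alike; (4) the OLS calibration
#' curve on the (corrected) standards; (5) LOD/LOQ from the blank response
#' spread; (6) conversion of each cell's response to fg with QC flags.
#'
#' @param trace a [TimeTrace-class].
#' @param events events data.frame covering blanks, standards and cells.
#' @param config a [RunConfig-class].
#' @param curve optional pre-fitted [CalibrationCurve-class] (e.g. restored
#'   with [readCurve()] from another chamber); when given, this run's
#'   standards are not required.
#' @return list with `threshold` ([Threshold-class]), `standards`
#'   (integrated standards with a `corrected_response` column), `drift`
#'   ([DriftModel-class]), `curve` ([CalibrationCurve-class]), `lod`/`loq`
#'   (fg) and `measurements` (data.frame: `spot_id`, `group`, `t_mid`,
#'   `integrated_response`, `corrected_response`, `mass_fg`, `flags`).
#' @examples
#' sim <- simulateRun(SimParams(nCells = 20, seed = 42))
#' run <- quantifyRun(sim$trace, sim$events, RunConfig())
#' head(run$measurements)
#' @export
quantifyRun <- function(trace, events, config = RunConfig(), curve = NULL) {
    events <- .validateEvents(events, warnOverlap = FALSE)
    threshold <- computeBlankThreshold(trace, events, config)
    standards <- integrateStandards(trace, events, threshold, config)

    drift <- identityDriftModel()
    if (config@driftCorrection == "piecewise_linear" &&
        nrow(standards) > 0L)
        drift <- buildDriftModel(standards)
    standards$corrected_response <-
        correctDrift(standards$integrated_response, standards$t_mid, drift)

    if (is.null(curve)) {
        if (nrow(standards) < 2L)
            stop("no calibration standards in the event log and no curve ",
                 "supplied")
        fitIn <- standards
        fitIn$integrated_response <- fitIn$corrected_response
        curve <- fitCalibration(fitIn)
    }

    blanks <- blankResponses(trace, events, config)
    blankEv <- events[events$kind == "blank", , drop = FALSE]
    blanksCorr <- correctDrift(blanks,
                               (blankEv$t_start + blankEv$t_end) / 2, drift)
    lims <- lodLoq(blanksCorr, curve, config)

    meas <- quantifyEvents(trace, events, threshold, config)
    meas$corrected_response <-
        correctDrift(meas$integrated_response, meas$t_mid, drift)
    conv <- responseToMass(meas$corrected_response, curve, config,
                           lod = lims[["lod"]], loq = lims[["loq"]])
    meas$mass_fg <- conv$mass_fg
    meas$flags <- mapply(.canonFlags, meas$flags, conv$flags,
                         USE.NAMES = FALSE)
    list(threshold = threshold, standards = standards, drift = drift,
         curve = curve, lod = lims[["lod"]], loq = lims[["loq"]],
         measurements = meas)
}
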