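#' @import methods
NULL

.TOL_SPACING <- 1e-6   # relative tolerance on uniform sample spacing
.TOL_DWELL   <- 0.01   # dwell must match median spacing within 1%

#' TimeTrace: a uniformly sampled single-analyte intensity series
#'
#' One acquisition channel of a laser-ablation ICP-MS run: intensity in
#' counts per second (CPS) against time in seconds, read at a fixed detector
#' dwell time. Validity enforces strictly increasing, uniformly spaced times
#' (relative tolerance 1e-6), non-negative intensities, and a dwell time
#' equal to the median sample spacing within 1%.
#'
#' @slot acquisitionId character(1), identifier of the acquisition.
#' @slot analyte character(1), analyte channel label, e.g. "56Fe".
#' @slot times numeric, sample times in seconds.
#' @slot intensities numeric, intensities in CPS.
#' @slot dwellTime numeric(1), detector dwell time in seconds.
#' @export
setClass("TimeTrace",
    representation(
        acquisitionId = "character",
        analyte       = "character",
        times         = "numeric",
        intensities   = "numeric",
        dwellTime     = "numeric"
    )
)

setValidity("TimeTrace", function(object) {
    t <- object@times
    y <- object@intensities
    if (length(t) != length(y))
        return("times and intensities differ in length")
    if (length(t) < 2L)
        return("a TimeTrace needs at least two samples")
    dt <- diff(t)
    if (any(dt <= 0)) {
        i <- which(dt <= 0)[1L]
        return(sprintf("times not strictly increasing at row %d", i + 1L))
    }
    med <- stats::median(dt)
    if (any(abs(dt - med) > .TOL_SPACING * med))
        return("sample spacing is not uniform (relative tolerance 1e-6)")
    if (any(y < 0))
        return("intensities must be non-negative")
    dw <- object@dwellTime
    if (length(dw) != 1L || !is.finite(dw) || dw <= 0)
        return("dwellTime must be a single positive number")
    if (abs(dw - med) > .TOL_DWELL * med)
        return("dwellTime does not match the median sample spacing within 1%")
    TRUE
})

#' Construct a TimeTrace
#'
#' @param times numeric vector of sample times (seconds), strictly
#'   increasing and uniformly spaced.
#' @param intensities numeric vector of intensities (CPS), same length.
#' @param analyte analyte channel label.
#' @param acquisitionId acquisition identifier.
#' @param dwellTime detector dwell time in seconds; inferred from the median
#'   sample spacing when `NULL`.
#' @return A validated [TimeTrace-class] object.
#' @examples
#' tr <- TimeTrace(times = seq(0, 0.02, by = 0.01), intensities = c(10, 20, 30))
#' dwellTime(tr)
#' @export
TimeTrace <- function(times, intensities, analyte = "56Fe",
                      acquisitionId = "acq", dwellTime = NULL) {
    if (is.null(dwellTime))
        dwellTime <- stats::median(diff(times))
    new("TimeTrace",
        acquisitionId = as.character(acquisitionId),
        analyte = as.character(analyte),
        times = as.numeric(times),
        intensities = as.numeric(intensities),
        dwellTime = as.numeric(dwellTime))
}

setMethod("show", "TimeTrace", function(object) {
    cat(sprintf("TimeTrace '%s' [%s]: %d samples, %.4g-%.4g s, dwell %.4g s\n",
        object@acquisitionId, object@analyte, length(object@times),
        object@times[1L], object@times[length(object@times)],
        object@dwellTime))
})

#' RunConfig: analysis settings for one quantification run
#'
#' Bundles the tunable rules of the pipeline: how the background threshold is
#' derived from blanks, how peak boundaries are located, whether and how
#' instrumental drift is corrected, the integration units, and the k-factors
#' of the limits of detection and quantification.
#'
#' @slot thresholdMethod "blank_mean" (the mean of per-blank mean CPS) or
#'   "blank_mean_plus_k_sigma" (adds kSigma times the SD of per-blank means).
#' @slot kSigma non-negative multiplier for the sigma-based threshold.
#' @slot boundaryRule "local_min_at_or_below" (nearest sub-threshold local
#'   minimum on each side) or "first_at_or_below" (nearest sub-threshold
#'   sample).
#' @slot driftCorrection "none" or "piecewise_linear".
#' @slot integrationUnits "summed_cps" (sum of in-window CPS) or "counts"
#'   (summed CPS times dwell time).
#' @slot lodK,loqK k-factors of LOD and LOQ (defaults 3 and 10); lodK < loqK.
#' @slot seed integer RNG seed recorded with the run.
#' @slot allowNegativeMass report raw negative masses instead of clamping
#'   to 0 fg.
#' @slot slopeOnly convert response to mass as response/slope, ignoring the
#'   calibration intercept (strict replication mode).
#' @slot includeBelowLod include below-LOD cells in group summaries.
#' @export
setClass("RunConfig",
    representation(
        thresholdMethod   = "character",
        kSigma            = "numeric",
        boundaryRule      = "character",
        driftCorrection   = "character",
        integrationUnits  = "character",
        lodK              = "numeric",
        loqK              = "numeric",
        seed              = "integer",
        allowNegativeMass = "logical",
        slopeOnly         = "logical",
        includeBelowLod   = "logical"
    )
)

setValidity("RunConfig", function(object) {
    chk <- function(x, allowed, what) {
        if (length(x) != 1L || !x %in% allowed)
            sprintf("%s must be one of: %s", what,
                    paste(allowed, collapse = ", "))
        else NULL
    }
    msgs <- c(
        chk(object@thresholdMethod,
            c("blank_mean", "blank_mean_plus_k_sigma"), "thresholdMethod"),
        chk(object@boundaryRule,
            c("local_min_at_or_below", "first_at_or_below"), "boundaryRule"),
        chk(object@driftCorrection, c("none", "piecewise_linear"),
            "driftCorrection"),
        chk(object@integrationUnits, c("summed_cps", "counts"),
            "integrationUnits"))
    if (object@kSigma < 0) msgs <- c(msgs, "kSigma must be >= 0")
    if (!(object@lodK < object@loqK))
        msgs <- c(msgs, "lodK must be strictly less than loqK")
    if (length(msgs)) msgs else TRUE
})

#' Construct a RunConfig
#'
#' @param thresholdMethod,kSigma,boundaryRule,driftCorrection,integrationUnits
#'   see [RunConfig-class].
#' @param lodK,loqK limit-of-detection / -quantification k-factors.
#' @param seed integer seed recorded with the run.
#' @param allowNegativeMass,slopeOnly,includeBelowLod logical switches, see
#'   [RunConfig-class].
#' @return A validated [RunConfig-class] object.
#' @export
RunConfig <- function(thresholdMethod = c("blank_mean",
                                          "blank_mean_plus_k_sigma"),
                      kSigma = 0,
                      boundaryRule = c("local_min_at_or_below",
                                       "first_at_or_below"),
                      driftCorrection = c("none", "piecewise_linear"),
                      integrationUnits = c("summed_cps", "counts"),
                      lodK = 3, loqK = 10, seed = 1L,
                      allowNegativeMass = FALSE, slopeOnly = FALSE,
                      includeBelowLod = TRUE) {
    new("RunConfig",
        thresholdMethod = match.arg(thresholdMethod),
        kSigma = as.numeric(kSigma),
        boundaryRule = match.arg(boundaryRule),
        driftCorrection = match.arg(driftCorrection),
        integrationUnits = match.arg(integrationUnits),
        lodK = as.numeric(lodK), loqK = as.numeric(loqK),
        seed = as.integer(seed),
        allowNegativeMass = isTRUE(allowNegativeMass),
        slopeOnly = isTRUE(slopeOnly),
        includeBelowLod = isTRUE(includeBelowLod))
}

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig\n")
    cat(sprintf("  threshold: %s (kSigma=%g)\n",
        object@thresholdMethod, object@kSigma))
    cat(sprintf("  boundary rule: %s\n", object@boundaryRule))
    cat(sprintf("  drift: %s; units: %s; lodK/loqK: %g/%g; seed: %d\n",
        object@driftCorrection, object@integrationUnits,
        object@lodK, object@loqK, object@seed))
})

#' Threshold: blank-derived background level
#'
#' The background threshold against which ablation peaks are called. Per
#' blank spot the mean CPS is taken; the threshold is the unweighted average
#' of those per-blank means (optionally plus kSigma times their SD).
#'
#' @slot value threshold in CPS.
#' @slot method threshold method used.
#' @slot nBlanks number of blank spots.
#' @slot blankMean mean of per-blank mean CPS.
#' @slot blankSd SD of per-blank mean CPS (0 for a single blank).
#' @slot blankPointSd pooled per-sample SD of blank CPS (QC diagnostic).
#' @slot perBlankMeans named per-blank mean CPS, in acquisition order, so
#'   interleaved blank-collection schemes can be checked for time trends.
#' @slot perBlankTimes window midpoints (s) of the blanks.
#' @export
setClass("Threshold",
    representation(
        value         = "numeric",
        method        = "character",
        nBlanks       = "integer",
        blankMean     = "numeric",
        blankSd       = "numeric",
        blankPointSd  = "numeric",
        perBlankMeans = "numeric",
        perBlankTimes = "numeric"
    ),
    prototype(perBlankMeans = numeric(), perBlankTimes = numeric())
)

setValidity("Threshold", function(object) {
    if (object@value < 0) return("threshold value must be >= 0")
    if (object@method == "blank_mean" &&
        !isTRUE(all.equal(object@value, object@blankMean)))
        return("with method blank_mean, value must equal blankMean")
    TRUE
})

#' Construct a Threshold directly
#'
#' Usually produced by [computeBlankThreshold()]; a direct constructor is
#' provided so externally derived thresholds can be fed to [detectPeak()].
#'
#' @param value threshold in CPS.
#' @param method label for the derivation method.
#' @param nBlanks,blankMean,blankSd,blankPointSd see [Threshold-class].
#' @return A [Threshold-class] object.
#' @export
Threshold <- function(value, method = "blank_mean_plus_k_sigma",
                      nBlanks = 0L, blankMean = value, blankSd = 0,
                      blankPointSd = 0) {
    new("Threshold", value = as.numeric(value), method = method,
        nBlanks = as.integer(nBlanks), blankMean = as.numeric(blankMean),
        blankSd = as.numeric(blankSd),
        blankPointSd = as.numeric(blankPointSd))
}

setMethod("show", "Threshold", function(object) {
    cat(sprintf(
        "Threshold: %.6g CPS (%s; %d blanks; mean %.6g, sd %.4g CPS)\n",
        object@value, object@method, object@nBlanks, object@blankMean,
        object@blankSd))
})

#' Peak: one integrated ablation transient
#'
#' Boundary indices are 1-based inclusive sample indices into the segment
#' the peak was detected in.
#'
#' @slot spotId spot identifier.
#' @slot iLeft,iRight,iApex 1-based boundary and apex indices.
#' @slot integratedResponse summed in-window CPS (or counts, per config).
#' @slot edgeTruncated TRUE when a boundary search hit the segment edge
#'   before finding a qualifying boundary.
#' @slot extraRuns TRUE when further super-threshold runs exist outside the
#'   integration window (the measurement is flagged MERGED_SUSPECT).
#' @export
setClass("Peak",
    representation(
        spotId             = "character",
        iLeft              = "integer",
        iRight             = "integer",
        iApex              = "integer",
        integratedResponse = "numeric",
        edgeTruncated      = "logical",
        extraRuns          = "logical"
    )
)

setValidity("Peak", function(object) {
    if (!(object@iLeft <= object@iApex && object@iApex <= object@iRight))
        return("need iLeft <= iApex <= iRight")
    TRUE
})

setMethod("show", "Peak", function(object) {
    cat(sprintf(
        "Peak '%s': samples %d..%d (apex %d), response %.6g%s%s\n",
        object@spotId, object@iLeft, object@iRight, object@iApex,
        object@integratedResponse,
        if (object@edgeTruncated) ", edge-truncated" else "",
        if (object@extraRuns) ", extra runs outside window" else ""))
})

#' CalibrationCurve: response-vs-mass regression of the standards
#'
#' Ordinary least-squares line of integrated response on nominal analyte
#' mass (fg), with intercept. r-squared is the squared Pearson correlation
#' of response and mass.
#'
#' @slot slope response units per fg (must be positive).
#' @slot intercept response units.
#' @slot rSquared squared Pearson correlation, in [0, 1].
#' @slot residualSd residual SD of the fit (df = n - 2).
#' @slot nPoints number of standards in the fit.
#' @export
setClass("CalibrationCurve",
    representation(
        slope      = "numeric",
        intercept  = "numeric",
        rSquared   = "numeric",
        residualSd = "numeric",
        nPoints    = "integer"
    )
)

setValidity("CalibrationCurve", function(object) {
    if (object@slope <= 0) return("calibration slope must be positive")
    if (object@nPoints < 2L) return("need at least 2 calibration points")
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
        return("rSquared must lie in [0, 1]")
    TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf(
        "CalibrationCurve: response = %.6g * mass_fg + %.6g (n=%d, r2=%.4f, residual sd %.4g)\n",
        object@slope, object@intercept, object@nPoints, object@rSquared,
        object@residualSd))
})

#' DriftModel: piecewise-linear relative sensitivity over a run
#'
#' Relative sensitivity factors anchored at the acquisition times of repeated
#' standards of one reference mass; the first anchor is 1 by construction.
#' Between anchors the factor is linearly interpolated; outside the anchor
#' range it is clamped to the nearest anchor.
#'
#' @slot anchorTimes seconds, strictly increasing.
#' @slot anchorFactors positive relative sensitivities, first equal to 1.
#' @slot referenceMass fg of the anchoring standard (NA for identity models).
#' @export
setClass("DriftModel",
    representation(
        anchorTimes   = "numeric",
        anchorFactors = "numeric",
        referenceMass = "numeric"
    )
)

setValidity("DriftModel", function(object) {
    if (length(object@anchorTimes) != length(object@anchorFactors))
        return("anchorTimes and anchorFactors differ in length")
    if (length(object@anchorTimes) == 0L)
        return("a DriftModel needs at least one anchor")
    if (any(diff(object@anchorTimes) <= 0))
        return("anchorTimes must be strictly increasing")
    if (any(object@anchorFactors <= 0))
        return("anchorFactors must be positive")
    if (abs(object@anchorFactors[1L] - 1) > 1e-12)
        return("first anchor factor must be 1")
    TRUE
})

setMethod("show", "DriftModel", function(object) {
    if (length(object@anchorTimes) == 1L) {
        cat("DriftModel: identity (no correction)\n")
    } else {
        cat(sprintf(
            "DriftModel: %d anchors over %.4g-%.4g s, factors %.4g-%.4g (reference mass %g fg)\n",
            length(object@anchorTimes), min(object@anchorTimes),
            max(object@anchorTimes), min(object@anchorFactors),
            max(object@anchorFactors), object@referenceMass))
    }
})

#' Identity drift model
#'
#' @return A [DriftModel-class] whose factor is 1 everywhere.
#' @export
identityDriftModel <- function() {
    new("DriftModel", anchorTimes = 0, anchorFactors = 1,
        referenceMass = NA_real_)
}

#' SimParams: settings of the synthetic-run generator
#'
#' Defaults reproduce the study conditions the toolkit is validated under: a
#' resting human T-cell population (zero-truncated normal, mean 1.83 fg iron,
#' SD 0.27 fg), an instrument sensitivity of 1e4 counts per fg, a Poisson
#' baseline of 100 counts per dwell, 20 blank spots, and the six-mass gelatin
#' ladder 0, 173, 351, 684, 1821, 3455 fg ablated in duplicate at the start
#' and end of the run.
#'
#' @slot nCells number of cell ablation events.
#' @slot massMean,massSd fg; parameters of the per-cell mass distribution.
#' @slot massDistribution "normal_truncated_at_zero" or "lognormal" (moments
#'   matched to massMean/massSd).
#' @slot sensitivity detector counts per fg of analyte.
#' @slot baselineRate background counts per dwell interval.
#' @slot dwellTime detector dwell time, seconds.
#' @slot pulseShape "gaussian" or "exp_modified_gaussian" (tailing washout).
#' @slot pulseWidth full width at half maximum of the ablation pulse,
#'   seconds.
#' @slot windowTime seconds allotted to each ablation spot.
#' @slot driftSlope fractional sensitivity change per second (0 = no drift).
#' @slot nBlanks number of blank spots.
#' @slot standardMasses fg; the calibration ladder.
#' @slot standardReplicates ladder repeats, spread evenly over the run.
#' @slot noise draw Poisson counts (TRUE) or emit expected counts (FALSE).
#' @slot seed integer RNG seed; a fixed seed gives byte-identical output.
#' @export
setClass("SimParams",
    representation(
        nCells             = "integer",
        massMean           = "numeric",
        massSd             = "numeric",
        massDistribution   = "character",
        sensitivity        = "numeric",
        baselineRate       = "numeric",
        dwellTime          = "numeric",
        pulseShape         = "character",
        pulseWidth         = "numeric",
        windowTime         = "numeric",
        driftSlope         = "numeric",
        nBlanks            = "integer",
        standardMasses     = "numeric",
        standardReplicates = "integer",
        noise              = "logical",
        seed               = "integer"
    )
)

setValidity("SimParams", function(object) {
    if (object@nCells < 0L) return("nCells must be >= 0")
    if (object@massMean <= 0) return("massMean must be positive")
    if (object@massSd < 0) return("massSd must be >= 0")
    if (!object@massDistribution %in%
        c("normal_truncated_at_zero", "lognormal"))
        return("unknown massDistribution")
    if (object@sensitivity <= 0) return("sensitivity must be positive")
    if (object@baselineRate < 0) return("baselineRate must be >= 0")
    if (object@dwellTime <= 0) return("dwellTime must be positive")
    if (!object@pulseShape %in% c("gaussian", "exp_modified_gaussian"))
        return("unknown pulseShape")
    if (object@pulseWidth <= 0) return("pulseWidth must be positive")
    if (object@windowTime <= 0) return("windowTime must be positive")
    if (object@nBlanks < 0L) return("nBlanks must be >= 0")
    if (any(object@standardMasses < 0))
        return("standardMasses must be >= 0")
    if (object@standardReplicates < 1L)
        return("standardReplicates must be >= 1")
    TRUE
})

#' Construct simulator parameters
#'
#' @param nCells,massMean,massSd,massDistribution,sensitivity,baselineRate
#'   see [SimParams-class].
#' @param dwellTime,pulseShape,pulseWidth,windowTime,driftSlope,nBlanks see
#'   [SimParams-class].
#' @param standardMasses,standardReplicates,noise,seed see
#'   [SimParams-class].
#' @return A validated [SimParams-class] object.
#' @examples
#' p <- SimParams(nCells = 10, seed = 1)
#' sim <- simulateRun(p)
#' head(sim$truth)
#' @export
SimParams <- function(nCells = 100L, massMean = 1.83, massSd = 0.27,
                      massDistribution = c("normal_truncated_at_zero",
                                           "lognormal"),
                      sensitivity = 1e4, baselineRate = 100,
                      dwellTime = 0.01,
                      pulseShape = c("gaussian", "exp_modified_gaussian"),
                      pulseWidth = 0.25, windowTime = 4,
                      driftSlope = 0, nBlanks = 20L,
                      standardMasses = c(0, 173, 351, 684, 1821, 3455),
                      standardReplicates = 2L, noise = TRUE, seed = 1L) {
    new("SimParams",
        nCells = as.integer(nCells), massMean = as.numeric(massMean),
        massSd = as.numeric(massSd),
        massDistribution = match.arg(massDistribution),
        sensitivity = as.numeric(sensitivity),
        baselineRate = as.numeric(baselineRate),
        dwellTime = as.numeric(dwellTime),
        pulseShape = match.arg(pulseShape),
        pulseWidth = as.numeric(pulseWidth),
        windowTime = as.numeric(windowTime),
        driftSlope = as.numeric(driftSlope),
        nBlanks = as.integer(nBlanks),
        standardMasses = as.numeric(standardMasses),
        standardReplicates = as.integer(standardReplicates),
        noise = isTRUE(noise), seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
    cat(sprintf(
        "SimParams: %d cells (%s, mean %.3g fg, sd %.3g), %d blanks, %d x %d-mass ladder\n",
        object@nCells, object@massDistribution, object@massMean,
        object@massSd, object@nBlanks, object@standardReplicates,
        length(object@standardMasses)))
    cat(sprintf(
        "  sensitivity %.4g counts/fg, baseline %.4g counts/dwell, dwell %.4g s, pulse %s FWHM %.3g s, drift %.3g /s, seed %d\n",
        object@sensitivity, object@baselineRate, object@dwellTime,
        object@pulseShape, object@pulseWidth, object@driftSlope,
        object@seed))
})
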