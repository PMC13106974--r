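#' Fit the external calibration curve
#'
#' Ordinary least-squares regression of integrated response on nominal
#' analyte mass (fg), with intercept. Replicate standards at the same mass
#' all enter the fit individually (their spread feeds the residual SD);
#' r-squared is the squared Pearson correlation of response and mass.
#'
#' @param standards data.frame with columns `nominal_mass_fg` and
#'   `integrated_response` (as from [integrateStandards()] or
#'   [simulateCalibration()]).
#' @return A [CalibrationCurve-class]. Errors when fewer than two distinct
#'   masses are present or the fitted slope is not positive ("inverted
#'   calibration").
#' @examples
#' std <- data.frame(nominal_mass_fg = c(0, 173, 351, 684, 1821, 3455))
#' std$integrated_response <- 100 * std$nominal_mass_fg + 500
#' fitCalibration(std)
#' @export
fitCalibration <- function(standards) {
    m <- as.numeric(standards$nominal_mass_fg)
    r <- as.numeric(standards$integrated_response)
    if (length(m) < 2L)
        stop("need at least 2 calibration standards")
    if (length(unique(m)) < 2L)
        stop("all standard masses identical; cannot fit a calibration line")
    fit <- stats::lm(r ~ m)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    if (!is.finite(slope) || slope <= 0)
        stop("inverted calibration: fitted slope is not positive")
    r2 <- stats::cor(m, r)^2
    rsd <- if (length(m) > 2L)
        sqrt(sum(stats::residuals(fit)^2) / (length(m) - 2)) else 0
    new("CalibrationCurve", slope = slope, intercept = intercept,
        rSquared = r2, residualSd = rsd, nPoints = length(m))
}

#' Convert integrated responses to analyte mass
#'
#' Inverts the calibration line: `mass = (response - intercept) / slope`
#' (or `response / slope` in `slopeOnly` mode, which replicates a
#' slope-only conversion). Masses below the LOD are flagged BELOW_LOD,
#' below the LOQ BELOW_LOQ. Negative masses are clamped to 0 fg and flagged
#' BELOW_LOD unless `allowNegativeMass` is set.
#'
#' @param response numeric vector of (drift-corrected) integrated responses.
#' @param curve a [CalibrationCurve-class].
#' @param config a [RunConfig-class].
#' @param lod,loq mass limits in fg, from [lodLoq()]; `NA` suppresses the
#'   corresponding flag.
#' @return data.frame with columns `mass_fg` and `flags`.
#' @export
responseToMass <- function(response, curve, config = RunConfig(),
                           lod = NA_real_, loq = NA_real_) {
    mass <- if (config@slopeOnly) response / curve@slope
            else (response - curve@intercept) / curve@slope
    flags <- character(length(mass))
    neg <- mass < 0
    if (any(neg) && !config@allowNegativeMass) {
        mass[neg] <- 0
        flags[neg] <- "BELOW_LOD"
    }
    if (is.finite(lod))
        flags[mass < lod] <- "BELOW_LOD"
    if (is.finite(loq)) {
        low <- mass < loq
        flags[low] <- vapply(flags[low], function(f)
            .joinFlags(f, "BELOW_LOQ"), "")
        flags[low] <- sub("BELOW_LOQ;BELOW_LOD", "BELOW_LOD;BELOW_LOQ",
                          flags[low], fixed = TRUE)
    }
    data.frame(mass_fg = mass, flags = flags)
}

#' Limits of detection and quantification
#'
#' The 3-sigma / 10-sigma convention on the blank response spread:
#' `LOD = lodK * sd(blank responses) / slope` and
#' `LOQ = loqK * sd(blank responses) / slope`, both in fg.
#'
#' @param blankResponses numeric vector of integrated blank-window
#'   responses (see [blankResponses()]), or a single pre-computed SD via
#'   `sd = `.
#' @param curve a [CalibrationCurve-class].
#' @param config a [RunConfig-class] supplying `lodK` and `loqK`.
#' @param sd optional blank response SD overriding `blankResponses`.
#' @return Named numeric vector `c(lod = , loq = )` in fg. A zero SD gives
#'   a zero LOD/LOQ with a warning; fewer than two blank responses (and no
#'   `sd`) gives `NA` limits with a warning, which suppresses flagging.
#' @export
lodLoq <- function(blankResponses = NULL, curve, config = RunConfig(),
                   sd = NULL) {
    if (curve@slope <= 0)
        stop("calibration slope must be positive")
    if (is.null(sd)) {
        if (is.null(blankResponses) || length(blankResponses) < 2L) {
            warning("blank response SD unavailable; LOD/LOQ undefined",
                    call. = FALSE)
            return(c(lod = NA_real_, loq = NA_real_))
        }
        sd <- stats::sd(blankResponses)
    }
    if (sd == 0)
        warning("blank response SD is zero; LOD/LOQ are 0 fg",
                call. = FALSE)
    c(lod = config@lodK * sd / curve@slope,
      loq = config@loqK * sd / curve@slope)
}
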