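#' Build a piecewise-linear instrumental drift model
#'
#' Repeated standards of one reference mass (by default the highest mass in
#' the table) anchor the relative sensitivity over the run:
#' `factor(t_k) = response(t_k) / response(t_first)`, linearly interpolated
#' between anchors and clamped to the nearest anchor outside their range.
#'
#' @param standards integrated standards data.frame (columns
#'   `nominal_mass_fg`, `t_mid`, `integrated_response`).
#' @param referenceMass fg of the anchoring standard; default: the largest
#'   mass present.
#' @return A [DriftModel-class]. With fewer than two reference-mass
#'   standards at distinct times, the identity model is returned with a
#'   warning. A zero response at any anchor is an error.
#' @export
buildDriftModel <- function(standards, referenceMass = NULL) {
    if (is.null(referenceMass))
        referenceMass <- max(standards$nominal_mass_fg)
    sel <- standards[standards$nominal_mass_fg == referenceMass, ,
                     drop = FALSE]
    sel <- sel[order(sel$t_mid), , drop = FALSE]
    sel <- sel[!duplicated(sel$t_mid), , drop = FALSE]
    if (nrow(sel) < 2L) {
        warning("fewer than 2 reference-mass standards at distinct times; ",
                "returning identity drift model", call. = FALSE)
        return(identityDriftModel())
    }
    if (any(sel$integrated_response == 0))
        stop("zero response at a drift anchor (reference mass ",
             referenceMass, " fg)")
    new("DriftModel", anchorTimes = sel$t_mid,
        anchorFactors = sel$integrated_response /
            sel$integrated_response[1L],
        referenceMass = as.numeric(referenceMass))
}

#' Relative sensitivity factor at a time point
#'
#' @param model a [DriftModel-class].
#' @param t numeric vector of times (seconds).
#' @return Interpolated (clamped outside the anchor range) drift factors.
#' @export
driftFactor <- function(model, t) {
    if (length(model@anchorTimes) == 1L)
        return(rep(model@anchorFactors, length(t)))
    stats::approx(model@anchorTimes, model@anchorFactors, xout = t,
                  rule = 2)$y
}

#' Correct a response for instrumental drift
#'
#' `corrected = raw / factor(tMid)`; the identity model passes responses
#' through unchanged.
#'
#' @param response numeric vector of raw integrated responses.
#' @param tMid times (seconds) the responses were acquired at.
#' @param model a [DriftModel-class].
#' @return Drift-corrected responses.
#' @export
correctDrift <- function(response, tMid, model) {
    response / driftFactor(model, tMid)
}
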