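# A sub-threshold local minimum: value <= threshold, and <= both neighbours
# (a segment edge counts as a neighbourless side).
.isBoundary <- function(y, i, thr) {
    n <- length(y)
    y[i] <= thr &&
        (i == 1L || y[i] <= y[i - 1L]) &&
        (i == n  || y[i] <= y[i + 1L])
}

#' Detect and integrate the ablation peak of one trace segment
#'
#' A peak exists when at least one sample exceeds the background threshold.
#' The core region is the maximal contiguous run of super-threshold samples
#' containing the global maximum (ties at the apex resolve to the earliest
#' index). Boundaries are then searched outward from the core:
#' with `boundaryRule = "local_min_at_or_below"` (default) each boundary is
#' the nearest sample at or below the threshold that is also a local minimum
#' (at or below both neighbours; a segment edge qualifies), i.e. the first
#' downward excursion at or below the background on either side of the peak;
#' with `"first_at_or_below"` it is simply the nearest sub-threshold sample.
#' A search that reaches the segment edge without finding a qualifying
#' boundary stops at the edge and marks the peak `edgeTruncated`. All samples
#' between the boundaries are summed — further super-threshold runs inside
#' the window are absorbed; runs outside it set `extraRuns` (reported as
#' MERGED_SUSPECT on the measurement).
#'
#' @param intensities numeric vector of segment intensities (CPS), or a
#'   [TimeTrace-class] whose full series is used.
#' @param threshold a [Threshold-class] (or a single CPS value).
#' @param config a [RunConfig-class]; `boundaryRule` and `integrationUnits`
#'   are honoured (`"counts"` multiplies the summed CPS by `dwellTime`).
#' @param spotId identifier stored on the returned peak.
#' @param dwellTime dwell time used for `integrationUnits = "counts"` when
#'   `intensities` is a bare vector.
#' @return A [Peak-class], or `NULL` when no sample exceeds the threshold.
#' @examples
#' thr <- Threshold(10)
#' detectPeak(c(5, 4, 6, 50, 200, 120, 30, 4, 5), thr)
#' @export
detectPeak <- function(intensities, threshold, config = RunConfig(),
                       spotId = "segment", dwellTime = NA_real_) {
    if (is(intensities, "TimeTrace")) {
        dwellTime <- intensities@dwellTime
        intensities <- intensities@intensities
    }
    y <- as.numeric(intensities)
    if (length(y) == 0L)
        stop("empty segment for spot '", spotId, "'")
    thr <- if (is(threshold, "Threshold")) threshold@value
           else as.numeric(threshold)
    above <- y > thr
    if (!any(above))
        return(NULL)
    n <- length(y)
    iApex <- which.max(y)              # earliest index on ties
    cs <- iApex
    while (cs > 1L && above[cs - 1L]) cs <- cs - 1L
    ce <- iApex
    while (ce < n && above[ce + 1L]) ce <- ce + 1L

    localMin <- config@boundaryRule == "local_min_at_or_below"
    iLeft <- NA_integer_
    i <- cs - 1L
    while (i >= 1L) {
        ok <- if (localMin) .isBoundary(y, i, thr) else y[i] <= thr
        if (ok) { iLeft <- i; break }
        i <- i - 1L
    }
    edgeL <- is.na(iLeft)
    if (edgeL) iLeft <- 1L
    iRight <- NA_integer_
    i <- ce + 1L
    while (i <= n) {
        ok <- if (localMin) .isBoundary(y, i, thr) else y[i] <= thr
        if (ok) { iRight <- i; break }
        i <- i + 1L
    }
    edgeR <- is.na(iRight)
    if (edgeR) iRight <- n

    resp <- sum(y[iLeft:iRight])
    if (config@integrationUnits == "counts") {
        if (!is.finite(dwellTime))
            stop("integrationUnits = 'counts' needs a dwell time")
        resp <- resp * dwellTime
    }
    outside <- above
    outside[iLeft:iRight] <- FALSE
    new("Peak", spotId = as.character(spotId),
        iLeft = iLeft, iRight = iRight, iApex = iApex,
        integratedResponse = resp,
        edgeTruncated = edgeL || edgeR,
        extraRuns = any(outside))
}
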