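# indices of samples in the half-open window [tStart, tEnd)
.windowIdx <- function(trace, tStart, tEnd) {
    t <- trace@times
    which(t >= tStart & t < tEnd)
}

.segment <- function(trace, event) {
    idx <- .windowIdx(trace, event$t_start, event$t_end)
    if (length(idx) == 0L)
        stop("event window of '", event$spot_id,
             "' contains no trace samples (outside trace?)")
    list(times = trace@times[idx], intensities = trace@intensities[idx])
}

#' Blank-derived background threshold
#'
#' For every blank spot in the event log, the mean CPS over its window is
#' taken; the per-blank means are then averaged together (unweighted) to
#' give the background threshold. With
#' `thresholdMethod = "blank_mean_plus_k_sigma"` the threshold is raised by
#' `kSigma` times the SD of the per-blank means (0 when only one blank was
#' collected).
#'
#' @param trace a [TimeTrace-class].
#' @param events events data.frame; only rows with kind "blank" are used.
#' @param config a [RunConfig-class].
#' @return A [Threshold-class]. Errors when the event log holds no blanks;
#'   warns (and returns a zero threshold) when every blank sample is zero.
#' @export
computeBlankThreshold <- function(trace, events, config = RunConfig()) {
    blanks <- events[events$kind == "blank", , drop = FALSE]
    if (nrow(blanks) == 0L)
        stop("no blank measurements in the event log")
    segs <- lapply(seq_len(nrow(blanks)),
                   function(i) .segment(trace, blanks[i, ]))
    perBlankMean <- vapply(segs, function(s) mean(s$intensities), 0)
    allSamples <- unlist(lapply(segs, `[[`, "intensities"))
    blankMean <- mean(perBlankMean)
    blankSd <- if (length(perBlankMean) > 1L) stats::sd(perBlankMean) else 0
    pointSd <- if (length(allSamples) > 1L) stats::sd(allSamples) else 0
    value <- switch(config@thresholdMethod,
        blank_mean = blankMean,
        blank_mean_plus_k_sigma = blankMean + config@kSigma * blankSd)
    if (all(allSamples == 0))
        warning("all blank samples are zero; background threshold is 0 CPS",
                call. = FALSE)
    new("Threshold", value = value, method = config@thresholdMethod,
        nBlanks = nrow(blanks), blankMean = blankMean, blankSd = blankSd,
        blankPointSd = pointSd,
        perBlankMeans = stats::setNames(perBlankMean, blanks$spot_id),
        perBlankTimes = (blanks$t_start + blanks$t_end) / 2)
}

#' Integrated responses of the blank windows
#'
#' Each blank window is integrated over all of its samples (summed CPS, or
#' counts when `integrationUnits = "counts"`). The SD of these responses is
#' the blank response spread that [lodLoq()] converts to mass limits.
#'
#' @inheritParams computeBlankThreshold
#' @return Named numeric vector of per-blank integrated responses.
#' @export
blankResponses <- function(trace, events, config = RunConfig()) {
    blanks <- events[events$kind == "blank", , drop = FALSE]
    if (nrow(blanks) == 0L)
        stop("no blank measurements in the event log")
    r <- vapply(seq_len(nrow(blanks)), function(i) {
        s <- .segment(trace, blanks[i, ])
        sum(s$intensities)
    }, 0)
    if (config@integrationUnits == "counts")
        r <- r * trace@dwellTime
    stats::setNames(r, blanks$spot_id)
}
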