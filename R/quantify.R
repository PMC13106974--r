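.joinFlags <- function(...) {
    f <- c(...)
    paste(f[nzchar(f)], collapse = ";")
}

.eventResponse <- function(trace, event, threshold, config) {
    seg <- .segment(trace, event)
    pk <- detectPeak(seg$intensities, threshold, config,
                     spotId = event$spot_id, dwellTime = trace@dwellTime)
    if (is.null(pk)) {
        list(response = 0, tMid = (event$t_start + event$t_end) / 2,
             flags = "BELOW_LOD", detected = FALSE)
    } else {
        flags <- c(if (pk@edgeTruncated) "EDGE_TRUNCATED" else "",
                   if (pk@extraRuns) "MERGED_SUSPECT" else "")
        list(response = pk@integratedResponse,
             tMid = mean(seg$times[c(pk@iLeft, pk@iRight)]),
             flags = .joinFlags(flags), detected = TRUE)
    }
}

#' Integrate every cell ablation event of a run
#'
#' Applies [detectPeak()] to each event of kind "cell", individually. Cells
#' without any super-threshold sample are still reported, with integrated
#' response 0 and flag BELOW_LOD. Blanks are excluded; standards belong to
#' the calibration path ([integrateStandards()]).
#'
#' @param trace a [TimeTrace-class].
#' @param events events data.frame (see [readEvents()]).
#' @param threshold a [Threshold-class] computed from the same run's blanks.
#' @param config a [RunConfig-class].
#' @return A measurements data.frame with columns `spot_id`, `group`,
#'   `t_mid` (midpoint of the integrated window, for drift correction),
#'   `integrated_response` and `flags`, one row per cell event, ordered by
#'   event start time.
#' @export
quantifyEvents <- function(trace, events, threshold, config = RunConfig()) {
    ev <- .validateEvents(events, warnOverlap = FALSE)
    cells <- ev[ev$kind == "cell", , drop = FALSE]
    out <- lapply(seq_len(nrow(cells)), function(i) {
        r <- .eventResponse(trace, cells[i, ], threshold, config)
        data.frame(spot_id = cells$spot_id[i], group = cells$group[i],
                   t_mid = r$tMid, integrated_response = r$response,
                   flags = r$flags)
    })
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    if (is.null(res))
        res <- data.frame(spot_id = character(), group = character(),
                          t_mid = numeric(), integrated_response = numeric(),
                          flags = character())
    res
}

#' Integrate the standard (gelatin micro-droplet) events of a run
#'
#' Standards are integrated with exactly the same threshold and boundary
#' rule as the cells, so that the calibration intercept absorbs the
#' background contribution common to both. A standard without any
#' super-threshold sample (typically the 0 fg droplet) enters with
#' response 0.
#'
#' @inheritParams quantifyEvents
#' @return A data.frame with columns `spot_id`, `nominal_mass_fg`, `t_mid`
#'   and `integrated_response`, ordered by event start time.
#' @export
integrateStandards <- function(trace, events, threshold,
                               config = RunConfig()) {
    ev <- .validateEvents(events, warnOverlap = FALSE)
    std <- ev[ev$kind == "standard", , drop = FALSE]
    out <- lapply(seq_len(nrow(std)), function(i) {
        r <- .eventResponse(trace, std[i, ], threshold, config)
        data.frame(spot_id = std$spot_id[i],
                   nominal_mass_fg = std$nominal_mass_fg[i],
                   t_mid = r$tMid, integrated_response = r$response)
    })
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    if (is.null(res))
        res <- data.frame(spot_id = character(),
                          nominal_mass_fg = numeric(), t_mid = numeric(),
                          integrated_response = numeric())
    res
}
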