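#' @importFrom utils read.csv write.csv
NULL

# QC flag tokens used in results files
.FLAGS <- c("EDGE_TRUNCATED", "BELOW_LOD", "BELOW_LOQ", "MERGED_SUSPECT")

#' Read a time-resolved intensity trace
#'
#' Traces are plain CSV with a header `time_s,<analyte>_cps` (one analyte
#' per column; extra analyte columns are ignored). Times are seconds,
#' intensities counts per second.
#'
#' @param path path to the trace CSV.
#' @param analyte analyte channel to read, e.g. "56Fe"; its column must be
#'   named `<analyte>_cps`.
#' @param acquisitionId identifier stored on the returned trace; defaults to
#'   the file name without extension.
#' @return A validated [TimeTrace-class]; the dwell time is inferred from
#'   the median sample spacing.
#' @export
readTrace <- function(path, analyte = "56Fe", acquisitionId = NULL) {
    if (!file.exists(path))
        stop("trace file not found: ", path)
    d <- read.csv(path, check.names = FALSE)
    col <- paste0(analyte, "_cps")
    if (!"time_s" %in% names(d))
        stop("trace file ", path, " has no 'time_s' column")
    if (!col %in% names(d))
        stop("trace file ", path, " has no '", col,
             "' column for analyte ", analyte)
    t <- as.numeric(d[["time_s"]])
    dt <- diff(t)
    if (any(dt <= 0)) {
        i <- which(dt <= 0)[1L]
        stop("times not strictly increasing at data row ", i + 1L,
             " of ", path)
    }
    if (is.null(acquisitionId))
        acquisitionId <- sub("\\.[^.]*$", "", basename(path))
    TimeTrace(times = t, intensities = as.numeric(d[[col]]),
              analyte = analyte, acquisitionId = acquisitionId)
}

#' Write a trace to CSV
#'
#' @param trace a [TimeTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
    d <- data.frame(time_s = times(trace), cps = intensities(trace))
    names(d)[2L] <- paste0(analyte(trace), "_cps")
    write.csv(d, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.EVENT_KINDS <- c("cell", "blank", "standard")

.validateEvents <- function(ev, warnOverlap = TRUE) {
    need <- c("spot_id", "kind", "t_start", "t_end")
    miss <- setdiff(need, names(ev))
    if (length(miss))
        stop("event log missing column(s): ", paste(miss, collapse = ", "))
    if (!"nominal_mass_fg" %in% names(ev)) ev$nominal_mass_fg <- NA_real_
    if (!"group" %in% names(ev)) ev$group <- ""
    ev$spot_id <- as.character(ev$spot_id)
    ev$kind <- as.character(ev$kind)
    ev$t_start <- as.numeric(ev$t_start)
    ev$t_end <- as.numeric(ev$t_end)
    ev$nominal_mass_fg <- suppressWarnings(as.numeric(ev$nominal_mass_fg))
    ev$group <- as.character(ev$group)
    bad <- setdiff(unique(ev$kind), .EVENT_KINDS)
    if (length(bad))
        stop("unknown event kind(s): ", paste(bad, collapse = ", "))
    if (any(ev$t_start >= ev$t_end)) {
        i <- which(ev$t_start >= ev$t_end)[1L]
        stop("event '", ev$spot_id[i], "' has t_start >= t_end")
    }
    noMass <- ev$kind == "standard" & !is.finite(ev$nominal_mass_fg)
    if (any(noMass))
        stop("standard event(s) without nominal_mass_fg: ",
             paste(ev$spot_id[noMass], collapse = ", "))
    if (any(ev$nominal_mass_fg < 0, na.rm = TRUE))
        stop("nominal_mass_fg must be >= 0")
    ev <- ev[order(ev$t_start, ev$spot_id), , drop = FALSE]
    rownames(ev) <- NULL
    if (warnOverlap && nrow(ev) > 1L) {
        ov <- which(ev$t_start[-1L] < ev$t_end[-nrow(ev)])
        for (i in ov)
            warning("event windows overlap: '", ev$spot_id[i], "' and '",
                    ev$spot_id[i + 1L], "'", call. = FALSE)
    }
    ev[c("spot_id", "kind", "t_start", "t_end", "nominal_mass_fg", "group")]
}

#' Read an ablation event log
#'
#' The event log assigns trace segments to labeled spots. CSV columns:
#' `spot_id,kind,t_start,t_end,nominal_mass_fg,group`, with kind one of
#' cell/blank/standard. `nominal_mass_fg` is required for standards. Windows
#' are half-open `[t_start, t_end)` seconds: a sample at time t belongs to a
#' window iff `t_start <= t < t_end`. Rows are returned ordered by
#' `t_start`; overlapping windows raise a warning naming both spots.
#'
#' @param path path to the events CSV.
#' @return A data.frame of validated events.
#' @export
readEvents <- function(path) {
    if (!file.exists(path))
        stop("event file not found: ", path)
    .validateEvents(read.csv(path, stringsAsFactors = FALSE))
}

#' Write an event log to CSV
#'
#' @param events events data.frame as returned by [readEvents()] or
#'   [simulateRun()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path) {
    ev <- .validateEvents(events, warnOverlap = FALSE)
    write.csv(ev, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' Write per-cell measurements to CSV
#'
#' Columns `spot_id,group,integrated_response,mass_fg,flags`; one row per
#' cell, ordered by `spot_id`; flags are semicolon-joined QC tokens
#' (EDGE_TRUNCATED, BELOW_LOD, BELOW_LOQ, MERGED_SUSPECT).
#'
#' @param measurements measurements data.frame (from [quantifyRun()] or
#'   [quantifyEvents()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(measurements, path) {
    cols <- c("spot_id", "group", "integrated_response", "mass_fg", "flags")
    m <- measurements
    if (nrow(m) == 0L) {
        m <- data.frame(spot_id = character(), group = character(),
                        integrated_response = numeric(),
                        mass_fg = numeric(), flags = character())
    } else {
        if (!"mass_fg" %in% names(m)) m$mass_fg <- NA_real_
        if (!"flags" %in% names(m)) m$flags <- ""
        m <- m[order(m$spot_id), cols, drop = FALSE]
    }
    # full precision so that results round-trip exactly
    m$integrated_response <- formatC(m$integrated_response, digits = 17,
                                     format = "g")
    m$mass_fg <- ifelse(is.na(m$mass_fg), "",
                        formatC(m$mass_fg, digits = 17, format = "g"))
    write.csv(m[cols], path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' Read a per-cell results file written by [writeResults()]
#'
#' @param path path to the results CSV.
#' @return A measurements data.frame.
#' @export
readResults <- function(path) {
    if (!file.exists(path))
        stop("results file not found: ", path)
    d <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(spot_id = "character", group = "character",
                                 flags = "character"))
    d$integrated_response <- as.numeric(d$integrated_response)
    d$mass_fg <- suppressWarnings(as.numeric(d$mass_fg))
    d$flags[is.na(d$flags)] <- ""
    d
}

# ---- flat key:value files (configs, persisted calibration curves) --------

.readKeyValue <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    hit <- regexpr(":", lines, fixed = TRUE)
    if (any(hit < 0))
        stop("malformed line in ", path, ": ", lines[which(hit < 0)[1L]])
    keys <- trimws(substr(lines, 1L, hit - 1L))
    vals <- trimws(substring(lines, hit + 1L))
    if (anyDuplicated(keys))
        stop("duplicate key in ", path, ": ", keys[duplicated(keys)][1L])
    stats::setNames(as.list(vals), keys)
}

.writeKeyValue <- function(x, path) {
    writeLines(paste0(names(x), ": ", vapply(x, as.character, "")), path)
    invisible(path)
}

#' Persist / restore a calibration curve
#'
#' Curves are stored as a flat `key: value` text file so one chamber's
#' calibration can be reused on another.
#'
#' @param curve a [CalibrationCurve-class].
#' @param path file path.
#' @return `writeCurve` returns `path` invisibly; `readCurve` the restored
#'   [CalibrationCurve-class].
#' @export
writeCurve <- function(curve, path) {
    .writeKeyValue(list(
        slope = formatC(curve@slope, digits = 17, format = "g"),
        intercept = formatC(curve@intercept, digits = 17, format = "g"),
        r_squared = formatC(curve@rSquared, digits = 17, format = "g"),
        residual_sd = formatC(curve@residualSd, digits = 17, format = "g"),
        n_points = curve@nPoints), path)
}

#' @rdname writeCurve
#' @export
readCurve <- function(path) {
    kv <- .readKeyValue(path)
    need <- c("slope", "intercept", "r_squared", "residual_sd", "n_points")
    miss <- setdiff(need, names(kv))
    if (length(miss))
        stop("curve file missing key(s): ", paste(miss, collapse = ", "))
    new("CalibrationCurve",
        slope = as.numeric(kv$slope), intercept = as.numeric(kv$intercept),
        rSquared = as.numeric(kv$r_squared),
        residualSd = as.numeric(kv$residual_sd),
        nPoints = as.integer(kv$n_points))
}
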