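#' Convert a bulk ICP-MS digest concentration to per-cell mass
#'
#' The bulk path digests a counted cell aliquot and reports an element
#' concentration in µg/L. With the replicate's digest volume and cell count,
#' `total_pg = concentration * volume_L * 1e6`,
#' `pg_per_million_cells = total_pg / (cells / 1e6)` and
#' `fg_per_cell = pg_per_million_cells / 1000` (1 pg = 1000 fg, so
#' 1000 pg per million cells is exactly 1 fg per cell). Replicates flagged
#' below the limit of quantification (BLQ) yield `NA` and are excluded from
#' replicate means.
#'
#' @param concentration_ug_L measured concentration, µg/L (vectorised).
#' @param volume_L digest volume per replicate, litres.
#' @param cells_in_replicate cells in the replicate.
#' @param blq logical; TRUE marks a below-LOQ replicate.
#' @return data.frame with columns `pg_per_million_cells`, `fg_per_cell`
#'   and `blq`.
#' @examples
#' bulkToPerCell(1, 0.003, 1333333)   # 3000 pg over 1.33M cells
#' @export
bulkToPerCell <- function(concentration_ug_L, volume_L, cells_in_replicate,
                          blq = FALSE) {
    n <- max(length(concentration_ug_L), length(volume_L),
             length(cells_in_replicate), length(blq))
    conc <- rep_len(as.numeric(concentration_ug_L), n)
    vol <- rep_len(as.numeric(volume_L), n)
    cells <- rep_len(as.numeric(cells_in_replicate), n)
    blq <- rep_len(as.logical(blq), n)
    if (any(vol <= 0)) stop("replicate_volume must be positive")
    if (any(cells <= 0)) stop("cells_in_replicate must be positive")
    if (any(conc < 0 & !blq)) stop("concentration must be >= 0 unless BLQ")
    totalPg <- conc * vol * 1e6          # µg/L * L * 1e6 pg/µg
    pgPerMillion <- totalPg / (cells / 1e6)
    fgPerCell <- pgPerMillion * 1e-3     # 1000 pg/1e6 cells == 1 fg/cell
    pgPerMillion[blq] <- NA_real_
    fgPerCell[blq] <- NA_real_
    data.frame(pg_per_million_cells = pgPerMillion,
               fg_per_cell = fgPerCell, blq = blq)
}

#' Average technical replicates of a bulk measurement
#'
#' BLQ replicates are excluded (not zero-imputed); a sample whose
#' replicates are all BLQ is reported BLQ as a whole.
#'
#' @param values per-replicate values (e.g. fg per cell); `NA` allowed for
#'   BLQ replicates.
#' @param blq logical per replicate; defaults to `is.na(values)`.
#' @return list with `mean`, `sd`, `n_used`, `n_blq` and `blq` (TRUE when
#'   the whole sample is below the limit of quantification).
#' @export
averageReplicates <- function(values, blq = is.na(values)) {
    stopifnot(length(values) >= 1L)
    blq <- rep_len(as.logical(blq), length(values))
    use <- values[!blq]
    if (length(use) == 0L)
        return(list(mean = NA_real_, sd = NA_real_, n_used = 0L,
                    n_blq = sum(blq), blq = TRUE))
    list(mean = mean(use),
         sd = if (length(use) > 1L) stats::sd(use) else 0,
         n_used = length(use), n_blq = sum(blq), blq = FALSE)
}

#' Read a bulk ICP-MS table
#'
#' CSV columns: `sample_id,element,concentration_ug_L,volume_mL,
#' cells_in_replicate,blq` (volume in millilitres, as pipetted).
#'
#' @param path path to the bulk CSV.
#' @return data.frame with the input columns plus `volume_L`.
#' @export
readBulk <- function(path) {
    if (!file.exists(path)) stop("bulk file not found: ", path)
    d <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "element", "concentration_ug_L", "volume_mL",
              "cells_in_replicate", "blq")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("bulk file missing column(s): ", paste(miss, collapse = ", "))
    d$blq <- as.logical(d$blq)
    d$volume_L <- d$volume_mL / 1000
    d
}

#' Per-sample bulk summary (pg per million cells and fg per cell)
#'
#' Converts every replicate with [bulkToPerCell()] and averages technical
#' replicates per sample and element with [averageReplicates()].
#'
#' @param bulk data.frame as returned by [readBulk()].
#' @return data.frame with one row per sample/element: replicate means and
#'   SDs of both units, `n_used`, `n_blq`, and a `blq` column for samples
#'   below the limit of quantification throughout.
#' @export
bulkSummary <- function(bulk) {
    per <- bulkToPerCell(bulk$concentration_ug_L, bulk$volume_L,
                         bulk$cells_in_replicate, bulk$blq)
    key <- interaction(bulk$sample_id, bulk$element, drop = TRUE)
    out <- lapply(levels(key), function(k) {
        i <- key == k
        fg <- averageReplicates(per$fg_per_cell[i])
        pg <- averageReplicates(per$pg_per_million_cells[i])
        data.frame(sample_id = bulk$sample_id[i][1L],
                   element = bulk$element[i][1L],
                   pg_per_million_cells = pg$mean, pg_sd = pg$sd,
                   fg_per_cell = fg$mean, fg_sd = fg$sd,
                   n_used = fg$n_used, n_blq = fg$n_blq, blq = fg$blq)
    })
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    res[order(res$sample_id, res$element), , drop = FALSE]
}
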