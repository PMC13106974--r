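.fmt <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

#' Write a plain-text run report
#'
#' One deterministic report per run: background threshold and blank QC,
#' calibration coefficients with r-squared, LOD/LOQ, drift anchors, group
#' summaries, all pairwise Mann-Whitney comparisons, and the per-cell
#' table. Re-running on the same inputs reproduces the file byte for byte.
#'
#' @param run result list of [quantifyRun()].
#' @param path output path of the report.
#' @param includeBelowLod passed to [summarizeGroups()] /
#'   [compareAllGroups()].
#' @return `path`, invisibly.
#' @export
renderReport <- function(run, path, includeBelowLod = TRUE) {
    thr <- run$threshold
    cv <- run$curve
    ln <- c(
        "== scmetal run report ==",
        "",
        "[threshold]",
        sprintf("value_cps: %s", .fmt(thr@value)),
        sprintf("method: %s", thr@method),
        sprintf("n_blanks: %d", thr@nBlanks),
        sprintf("blank_mean_cps: %s", .fmt(thr@blankMean)),
        sprintf("blank_sd_cps: %s", .fmt(thr@blankSd)),
        sprintf("blank_point_sd_cps: %s", .fmt(thr@blankPointSd)),
        "",
        "[blanks]",          # per-blank means in time order, for QC
        "spot_id,t_mid,mean_cps",
        sprintf("%s,%s,%s", names(thr@perBlankMeans),
                .fmt(thr@perBlankTimes, 6), .fmt(thr@perBlankMeans)),
        "",
        "[calibration]",
        sprintf("slope: %s", .fmt(cv@slope)),
        sprintf("intercept: %s", .fmt(cv@intercept)),
        sprintf("r_squared: %s", .fmt(cv@rSquared, 17)),
        sprintf("residual_sd: %s", .fmt(cv@residualSd)),
        sprintf("n_points: %d", cv@nPoints),
        sprintf("lod_fg: %s", .fmt(run$lod)),
        sprintf("loq_fg: %s", .fmt(run$loq)),
        "",
        "[drift]",
        sprintf("anchors: %s",
                paste(sprintf("%s@%ss", .fmt(run$drift@anchorFactors, 4),
                              .fmt(run$drift@anchorTimes, 4)),
                      collapse = " ")))
    sm <- summarizeGroups(run$measurements, includeBelowLod)
    ln <- c(ln, "", "[groups]",
            "group,n_cells,mean_fg,sd_fg,median_fg",
            sprintf("%s,%d,%s,%s,%s", sm$group, sm$n_cells,
                    .fmt(sm$mean_fg), .fmt(sm$sd_fg), .fmt(sm$median_fg)))
    cp <- compareAllGroups(run$measurements, includeBelowLod)
    if (nrow(cp) > 0L)
        ln <- c(ln, "", "[comparisons]",
                "group_a,group_b,n_a,n_b,U,p_value,fold_change_of_means",
                sprintf("%s,%s,%d,%d,%s,%s,%s", cp$group_a, cp$group_b,
                        cp$n_a, cp$n_b, .fmt(cp$U), .fmt(cp$p_value),
                        .fmt(cp$fold_change_of_means)))
    m <- run$measurements[order(run$measurements$spot_id), , drop = FALSE]
    ln <- c(ln, "", "[cells]",
            "spot_id,group,integrated_response,mass_fg,flags",
            sprintf("%s,%s,%s,%s,%s", m$spot_id, m$group,
                    .fmt(m$integrated_response, 10), .fmt(m$mass_fg, 10),
                    m$flags))
    writeLines(ln, path)
    invisible(path)
}
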