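.CONFIG_KEYS <- c(
    threshold_method    = "thresholdMethod",
    k_sigma             = "kSigma",
    boundary_rule       = "boundaryRule",
    drift_correction    = "driftCorrection",
    integration_units   = "integrationUnits",
    lod_k               = "lodK",
    loq_k               = "loqK",
    seed                = "seed",
    allow_negative_mass = "allowNegativeMass",
    slope_only          = "slopeOnly",
    include_below_lod   = "includeBelowLod")

#' Read / write a run configuration file
#'
#' Configs are flat `key: value` text (a YAML-compatible subset). Recognised
#' keys: threshold_method, k_sigma, boundary_rule, drift_correction,
#' integration_units, lod_k, loq_k, seed, allow_negative_mass, slope_only,
#' include_below_lod. Unknown keys are an error, not a warning; omitted keys
#' take the [RunConfig()] defaults.
#'
#' @param path path to the config file.
#' @return `readRunConfig` returns a validated [RunConfig-class];
#'   `writeRunConfig` returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
    kv <- .readKeyValue(path)
    unknown <- setdiff(names(kv), names(.CONFIG_KEYS))
    if (length(unknown))
        stop("unknown config key(s) in ", path, ": ",
             paste(unknown, collapse = ", "))
    args <- list()
    for (k in names(kv)) {
        arg <- .CONFIG_KEYS[[k]]
        v <- kv[[k]]
        args[[arg]] <- switch(arg,
            kSigma = , lodK = , loqK = as.numeric(v),
            seed = as.integer(v),
            allowNegativeMass = , slopeOnly = , includeBelowLod =
                tolower(v) %in% c("true", "yes", "1"),
            v)
    }
    do.call(RunConfig, args)
}

#' @param config a [RunConfig-class] to persist.
#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    .writeKeyValue(list(
        threshold_method = config@thresholdMethod,
        k_sigma = config@kSigma,
        boundary_rule = config@boundaryRule,
        drift_correction = config@driftCorrection,
        integration_units = config@integrationUnits,
        lod_k = config@lodK,
        loq_k = config@loqK,
        seed = config@seed,
        allow_negative_mass = tolower(config@allowNegativeMass),
        slope_only = tolower(config@slopeOnly),
        include_below_lod = tolower(config@includeBelowLod)), path)
}
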