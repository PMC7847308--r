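#' Default run configuration
#'
#' All pipeline thresholds at their standard values: 107 nm pixels, 32 ms
#' frames, 150 nm linking radius, 100-frame minimum observation, 500 nm
#' crosstalk exclusion, K = 3 states, 0.05 nm curve grid over
#' [2.5, 30] nm.
#'
#' @param seed Top-level seed recorded in the configuration.
#' @return A named list of class `"gietConfig"`.
#' @export
defaultConfig <- function(seed = 1L) {
  structure(list(
    stack = list(preset = "giet520"),
    fluorophore = "FAM",
    curve = list(d_min = 2.5, d_max = 30, step = 0.05),
    localization = list(psf_sigma_px = 1.3, detection_threshold = 5,
                        pixel_size_nm = 107),
    tracing = list(search_radius_nm = 150, min_frames = 100,
                   exclusion_nm = 500, frame_interval_s = 0.032),
    hmm = list(K = 3, max_iter = 1000, tol = 1e-6,
               training_fraction = 0.33),
    calibration = list(l_ml_nm = 2.5, n_boot = 200),
    seed = as.integer(seed),
    output_dir = "."
  ), class = "gietConfig")
}

.configSchema <- function() {
  cfg <- unclass(defaultConfig())
  lapply(cfg, function(x) if (is.list(x)) names(x) else NA)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unspecified fields from
#' [defaultConfig()], and rejects unknown fields naming their path.
#'
#' @param path YAML file path.
#' @return A validated `"gietConfig"`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  validateConfig(raw)
}

#' Validate a configuration list
#'
#' @param raw Named list, e.g. parsed from YAML.
#' @return A `"gietConfig"` with defaults filled in.
#' @export
validateConfig <- function(raw) {
  schema <- .configSchema()
  cfg <- unclass(defaultConfig())
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (top in names(raw)) {
    sub <- schema[[top]]
    if (all(is.na(sub))) {
      cfg[[top]] <- raw[[top]]
    } else {
      bad <- setdiff(names(raw[[top]]), sub)
      if (length(bad))
        stop("unknown config field(s): ",
             paste(paste0(top, ".", bad), collapse = ", "))
      for (f in names(raw[[top]])) cfg[[top]][[f]] <- raw[[top]][[f]]
    }
  }
  if (!is.numeric(cfg$seed)) stop("config field 'seed' must be numeric")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "gietConfig"
  cfg
}

#' Write a configuration to YAML
#'
#' @param config A `"gietConfig"`.
#' @param path Output path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive a stage-specific sub-seed from the top-level seed
#'
#' One explicit top-level seed drives every stochastic stage; stages get
#' decorrelated streams through a fixed integer hash of the stage name.
#' The result always fits a 32-bit integer.
#'
#' @param seed Top-level integer seed.
#' @param stage Stage name, e.g. `"bootstrap"`, `"simulate"`.
#' @return An integer sub-seed.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629)
}

#' Write an analysis report as structured JSON
#'
#' Embeds provenance (package version, R version, date, seed and the
#' configuration) with the results. Numbers are written unrounded.
#'
#' @param results Named list of results (data frames become records).
#' @param path Output `.json` path.
#' @param config Optional `"gietConfig"` to embed.
#' @param seed Seed to record.
#' @export
writeReport <- function(results, path, config = NULL, seed = NULL) {
  payload <- list(
    provenance = list(
      package = "gietr",
      version = as.character(utils::packageVersion("gietr")),
      r_version = R.version.string,
      date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      config = if (!is.null(config)) unclass(config) else NULL),
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Thin wrapper over the tiff package returning the `[row, col, frame]`
#' array consumed by [localizeSpots()].
#'
#' @param path TIFF file path.
#' @return 3D array of pixel values.
#' @export
readImageStack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
}
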