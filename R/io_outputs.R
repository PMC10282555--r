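#' Pipeline run configuration
#'
#' Collects every knob of a full UNRAVEL run — input paths, contribution
#' strategy, mean weighting, metrics, thresholds, seed, output directory — in
#' one validated object that round-trips losslessly through JSON.
#'
#' @param peaks,fractions paths to the fixel-field NIfTI volumes.
#' @param metrics named character vector mapping metric names to NIfTI paths.
#' @param tractogram path to a TRK/TCK tractogram.
#' @param strategy \code{"ang"}, \code{"cfo"} or \code{"vol"}.
#' @param weighting \code{"tsl"} or \code{"roi"}.
#' @param min_length roi-membership threshold in mm.
#' @param seed integer seed recorded in output manifests.
#' @param out_dir output directory.
#' @param log_level one of \code{"quiet"}, \code{"info"}, \code{"debug"}.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(peaks, fractions, metrics, tractogram,
                       strategy = "ang", weighting = "tsl", min_length = 0,
                       seed = 1L, out_dir = ".", log_level = "info") {
  strategy <- match_strategy(strategy)
  weighting <- match.arg(weighting, c("tsl", "roi"))
  log_level <- match.arg(log_level, c("quiet", "info", "debug"))
  if (is.null(names(metrics)) || any(names(metrics) == ""))
    stop("'metrics' must be a named vector: name = metric, value = NIfTI path")
  structure(list(
    peaks = peaks, fractions = fractions,
    metrics = as.list(metrics), tractogram = tractogram,
    strategy = strategy, weighting = weighting,
    min_length = min_length, seed = as.integer(seed),
    out_dir = out_dir, log_level = log_level
  ), class = "run_config")
}

#' @rdname run_config
#' @param path JSON file to read/write.
#' @param config a \code{"run_config"}.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(peaks = x$peaks, fractions = x$fractions,
             metrics = unlist(x$metrics), tractogram = x$tractogram,
             strategy = x$strategy, weighting = x$weighting,
             min_length = x$min_length, seed = x$seed,
             out_dir = x$out_dir, log_level = x$log_level)
}

#' Write the outputs of an UNRAVEL run
#'
#' Serializes maps (3D/4D NIfTI, 32-bit float, \code{NaN} marking undefined
#' voxels), tract-mean summaries and along-streamline profiles (CSV, \code{NA}
#' rendered as empty fields) and a JSON run manifest recording configuration,
#' seed and package version.
#'
#' @param maps named list of \code{"microstructure_map"} and/or
#'   \code{"weight_maps"} objects (names become file stems).
#' @param summaries data frame of tract means (e.g. rbind-ed
#'   \code{\link{summary.unravel}} rows), or \code{NULL}.
#' @param profiles data frame of \code{\link{streamline_profile}} rows, or
#'   \code{NULL}.
#' @param out_dir output directory (created if needed; must be writable).
#' @param config optional \code{\link{run_config}} echoed into the manifest.
#' @param seed seed recorded in the manifest.
#' @return Named list of written paths (the manifest of the run), invisibly.
#' @export
write_outputs <- function(maps = list(), summaries = NULL, profiles = NULL,
                          out_dir, config = NULL, seed = NA_integer_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  written <- list()
  for (nm in names(maps)) {
    m <- maps[[nm]]
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    if (inherits(m, "microstructure_map")) {
      write_vol(m$values, m$affine, p)
    } else if (inherits(m, "weight_maps")) {
      write_vol(m$fixel_weights, m$affine %||% diag(4), p)
      p2 <- file.path(out_dir, paste0(nm, "_total_length.nii.gz"))
      write_vol(m$total_length, m$affine %||% diag(4), p2)
      written[[paste0(nm, "_total_length")]] <- p2
    } else stop("unsupported map object '", nm, "'")
    written[[nm]] <- p
  }
  if (!is.null(summaries)) {
    p <- file.path(out_dir, "tract_means.csv")
    utils::write.csv(summaries, p, row.names = FALSE, na = "")
    written$tract_means <- p
  }
  if (!is.null(profiles)) {
    p <- file.path(out_dir, "streamline_profile.csv")
    utils::write.csv(profiles, p, row.names = FALSE, na = "")
    written$streamline_profile <- p
  }
  manifest <- list(
    package = "unravelr",
    version = as.character(utils::packageVersion("unravelr")),
    seed = seed,
    config = if (!is.null(config)) unclass(config) else NULL,
    files = written
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  written$manifest <- mp
  invisible(written)
}

#' Run the full pipeline from a configuration
#'
#' Reads the fixel field and tractogram named by a \code{\link{run_config}},
#' fits \code{\link{unravel}}, and writes maps, tract means, and the manifest
#' to the configured output directory.
#'
#' @param config a \code{\link{run_config}}.
#' @return The written-file manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$log_level != "quiet") message(...)
  say("reading fixel field")
  field <- read_fixel_field(config$peaks, config$fractions,
                            unlist(config$metrics))
  say("reading tractogram ", config$tractogram)
  tr <- read_tractogram(config$tractogram)
  say("fitting (strategy ", config$strategy, ")")
  fit <- unravel(field, tr, strategy = config$strategy)
  summaries <- summary(fit, weighting = config$weighting,
                       min_length = config$min_length)
  maps <- fit$maps
  names(maps) <- paste0("map_", names(maps), "_", config$strategy)
  write_outputs(maps, summaries = summaries, out_dir = config$out_dir,
                config = config, seed = config$seed)
}
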