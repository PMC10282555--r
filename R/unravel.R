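#' Assign multi-fixel microstructure to a tract
#'
#' The central entry point of the package: traces every streamline of a tract
#' through a fixel field, distributes each intra-voxel segment across the
#' voxel's fixels with the chosen contribution strategy, and aggregates the
#' result into fixel weight maps, a total-segment-length map, and one
#' tract-specific microstructure map per requested metric.
#'
#' @param field a \code{\link{fixel_field}}.
#' @param x a \code{\link{tract}} (streamlines in world mm on the same grid).
#' @param metrics character vector of metric names to map (default: all
#'   metrics of the field).
#' @param strategy fixel-contribution strategy: \code{"ang"} (angular
#'   weighting, the default), \code{"cfo"} (closest fixel only) or
#'   \code{"vol"} (relative volume fractions).
#' @return An object of class \code{"unravel"}: list with \code{subsegments},
#'   \code{weight_maps}, \code{maps} (named list of microstructure maps),
#'   \code{strategy}, \code{field_shape}, \code{affine}, \code{call}.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' fit <- unravel(ph$field, ph$tracts$T1, strategy = "ang")
#' summary(fit)
#' coef(fit)
#' @seealso \code{\link{tract_mean}}, \code{\link{streamline_profile}}
#' @export
unravel <- function(field, x, metrics = names(field$metrics),
                    strategy = c("ang", "cfo", "vol")) {
  stopifnot(inherits(field, "fixel_field"), inherits(x, "tract"))
  strategy <- match_strategy(strategy[1])
  missing_m <- setdiff(metrics, names(field$metrics))
  if (length(missing_m))
    stop("unknown metric(s) ", paste(missing_m, collapse = ", "),
         "; available: ", paste(names(field$metrics), collapse = ", "))
  subseg <- split_tract(x, grid_of(field))
  wm <- compute_weight_maps(subseg, field, strategy)
  maps <- lapply(metrics, function(m) compute_microstructure_map(wm, field, m))
  names(maps) <- metrics
  structure(list(
    subsegments = subseg,
    weight_maps = wm,
    maps = maps,
    strategy = strategy,
    field_shape = field$shape,
    affine = field$affine,
    call = match.call()
  ), class = "unravel")
}

#' @export
print.unravel <- function(x, ...) {
  cat("UNRAVEL tract-microstructure fit (strategy:", x$strategy, ")\n")
  cat("  subsegments:", nrow(x$subsegments), "in",
      sum(x$weight_maps$total_length > 0), "voxels; total length",
      sprintf("%.1f mm", sum(x$weight_maps$total_length)), "\n")
  cat("  metrics mapped:", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' Tract-wide means of an UNRAVEL fit
#'
#' Computes the tract-wide mean of every mapped metric under one or both voxel
#' weightings (total segment length \code{"tsl"}, region of interest
#' \code{"roi"}).
#'
#' @param object an \code{\link{unravel}} fit.
#' @param weighting weightings to report.
#' @param min_length roi-membership threshold in mm (see
#'   \code{\link{tract_mean}}).
#' @param ... unused.
#' @return An object of class \code{"summary.unravel"}: a data frame with one
#'   row per metric x weighting (columns \code{metric}, \code{strategy},
#'   \code{weighting}, \code{mean}, \code{n_voxels}, \code{total_length_mm}).
#' @export
summary.unravel <- function(object, weighting = c("tsl", "roi"),
                            min_length = 0, ...) {
  rows <- list()
  for (m in names(object$maps)) for (w in weighting) {
    s <- tract_mean(object$maps[[m]], object$weight_maps, w,
                    min_length = min_length)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, strategy = object$strategy, weighting = w, mean = s$mean,
      n_voxels = s$n_voxels, total_length_mm = s$total_length_mm)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("summary.unravel", "data.frame")
  out
}

#' @export
print.summary.unravel <- function(x, ...) {
  cat("Tract-wide means:\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @describeIn unravel tract-wide means under tsl weighting, as a named
#'   vector (one entry per metric).
#' @param object,... method arguments.
#' @export
coef.unravel <- function(object, ...) {
  s <- summary(object, weighting = "tsl")
  stats::setNames(s$mean, s$metric)
}

#' Image a map from an UNRAVEL fit
#'
#' Displays one axial slice of a tract-specific microstructure map (or of the
#' total-segment-length map) with \code{\link[graphics]{image}}.
#'
#' @param x an \code{\link{unravel}} fit.
#' @param metric metric name, or \code{"total_length"}.
#' @param slice 1-based slice index along z.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.unravel <- function(x, metric = names(x$maps)[1], slice = 1L, ...) {
  vol <- if (identical(metric, "total_length")) x$weight_maps$total_length
         else x$maps[[metric]]$values
  if (is.null(vol)) stop("no map for metric '", metric, "'")
  graphics::image(vol[, , slice], useRaster = TRUE, asp = 1,
                  main = paste0(metric, " (", x$strategy, "), slice ", slice),
                  ...)
  invisible(x)
}
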