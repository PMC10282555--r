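# Vectorized per-subsegment relative contributions.
# Returns list(alpha = n x k_max matrix (0 on absent slots), present, kv, lin)
# where lin is the 1-based linear voxel index of each subsegment.
subsegment_alphas <- function(subseg, field, strategy) {
  strategy <- match_strategy(strategy)
  n <- nrow(subseg)
  km <- field$k_max
  nvox <- prod(field$shape)
  lin <- (subseg$k - 1L) * field$shape[1] * field$shape[2] +
    (subseg$j - 1L) * field$shape[1] + subseg$i
  frv <- as.vector(field$fractions)
  fr <- matrix(0, n, km)
  for (kk in seq_len(km)) fr[, kk] <- frv[lin + (kk - 1L) * nvox]
  present <- fr > 0
  kv <- rowSums(present)
  alpha <- matrix(0, n, km)
  if (n == 0L) return(list(alpha = alpha, present = present, kv = kv, lin = lin))

  if (strategy == "vol") {
    tot <- rowSums(fr)
    nz <- tot > 0
    alpha[nz, ] <- fr[nz, , drop = FALSE] / tot[nz]
  } else {
    ov <- as.vector(field$orientations)
    dirs <- cbind(subseg$dir_x, subseg$dir_y, subseg$dir_z)
    theta <- matrix(0, n, km)
    for (kk in seq_len(km)) {
      dot <- numeric(n)
      for (ax in 1:3)
        dot <- dot + dirs[, ax] * ov[lin + ((kk - 1L) + (ax - 1L) * km) * nvox]
      theta[, kk] <- acos(pmin(1, abs(dot))) * 180 / pi
    }
    if (strategy == "cfo") {
      th <- theta
      th[!present] <- Inf
      rows <- which(kv > 0)
      pick <- max.col(-th[rows, , drop = FALSE], ties.method = "first")
      alpha[cbind(rows, pick)] <- 1
    } else {  # ang
      thp <- theta
      thp[!present] <- 0
      sumth <- rowSums(thp)
      phi <- pmin(90, sumth)
      den <- phi * kv - sumth
      multi <- kv > 1
      ok <- multi & den >= 1e-12
      if (any(ok))
        alpha[ok, ] <- (present[ok, , drop = FALSE] *
                          (phi[ok] - thp[ok, , drop = FALSE])) / den[ok]
      degen <- multi & den < 1e-12
      if (any(degen))
        alpha[degen, ] <- present[degen, , drop = FALSE] / kv[degen]
      single <- kv == 1
      alpha[single, ] <- present[single, , drop = FALSE]
    }
  }
  list(alpha = alpha, present = present, kv = kv, lin = lin)
}

#' Fixel weight maps and total segment length map of a tract
#'
#' Accumulates, per voxel and fixel, the segment-specific fixel weights
#' \eqn{w_{vsk} = \alpha_{vsk} l_{vs}} of all tract subsegments into a fixel
#' weight map \eqn{w_{vk} = \sum_s \alpha_{vsk} l_{vs}} (mm), together with the
#' total segment length map \eqn{w_v = \sum_s l_{vs}}, a tractography-only
#' tract presence measure independent of the weighting strategy.
#'
#' @param subsegments subsegment table from \code{\link{split_tract}} on the
#'   fixel field's grid.
#' @param field a \code{\link{fixel_field}}.
#' @param strategy one of \code{"ang"}, \code{"cfo"}, \code{"vol"}.
#' @return An object of class \code{"weight_maps"}: list with
#'   \code{fixel_weights} (array \code{c(shape, k_max)}), \code{total_length}
#'   (array of the grid shape), \code{strategy}.
#' @export
compute_weight_maps <- function(subsegments, field, strategy = c("ang", "cfo", "vol")) {
  stopifnot(inherits(field, "fixel_field"))
  strategy <- match_strategy(strategy[1])
  sg <- attr(subsegments, "grid")
  if (!is.null(sg) && !same_grid(sg, grid_of(field)))
    stop("subsegments were computed on a different grid than the fixel field ",
         "(shape/affine mismatch)")
  km <- field$k_max
  nvox <- prod(field$shape)
  fw <- matrix(0, nvox, km)
  tl <- numeric(nvox)
  if (nrow(subsegments)) {
    ba <- subsegment_alphas(subsegments, field, strategy)
    w <- ba$alpha * subsegments$length
    grp <- factor(ba$lin, levels = sort(unique(ba$lin)))
    lv <- as.integer(levels(grp))
    fw[lv, ] <- rowsum(w, grp, reorder = TRUE)
    tl[lv] <- rowsum(subsegments$length, grp, reorder = TRUE)[, 1]
  }
  structure(list(
    fixel_weights = array(fw, dim = c(field$shape, km)),
    total_length  = array(tl, dim = field$shape),
    strategy      = strategy,
    affine        = field$affine
  ), class = "weight_maps")
}

#' Tract-specific microstructure map
#'
#' Per-voxel weighted average of the fixel metric values by the fixel weight
#' map: \eqn{M_v = \sum_k w_{vk} M_{vk} / \sum_k w_{vk}}. Voxels the tract does
#' not traverse (or with no fixels) are undefined and carry \code{NaN}.
#'
#' @param weight_maps a \code{\link{compute_weight_maps}} result.
#' @param field the same \code{\link{fixel_field}}.
#' @param metric_name name of a metric present in \code{field$metrics}.
#' @return An object of class \code{"microstructure_map"}: list with
#'   \code{values} (array of the grid shape, \code{NaN} where undefined),
#'   \code{metric_name}, \code{strategy}, \code{affine}.
#' @export
compute_microstructure_map <- function(weight_maps, field, metric_name) {
  stopifnot(inherits(weight_maps, "weight_maps"), inherits(field, "fixel_field"))
  if (!metric_name %in% names(field$metrics))
    stop("unknown metric '", metric_name, "'; available: ",
         paste(names(field$metrics), collapse = ", "))
  nvox <- prod(field$shape)
  w <- matrix(weight_maps$fixel_weights, nvox, field$k_max)
  m <- matrix(field$metrics[[metric_name]], nvox, field$k_max)
  num <- rowSums(w * m)
  den <- rowSums(w)
  vals <- rep(NaN, nvox)
  nz <- den > 0
  vals[nz] <- num[nz] / den[nz]
  structure(list(
    values = array(vals, dim = field$shape),
    metric_name = metric_name,
    strategy = weight_maps$strategy,
    affine = field$affine
  ), class = "microstructure_map")
}

#' Segment-aggregated microstructure map
#'
#' Builds the tract microstructure map directly from per-segment metrics:
#' \eqn{M_v = \sum_s l_{vs} M_{vs} / \sum_s l_{vs}}, with \eqn{M_{vs}} the
#' contribution-weighted segment metric. Algebraically identical to
#' \code{\link{compute_microstructure_map}}; computed along an independent
#' code path (per-subsegment scalar evaluation) so the two serve as mutual
#' consistency oracles.
#'
#' @inheritParams compute_weight_maps
#' @inheritParams compute_microstructure_map
#' @return A \code{"microstructure_map"} object.
#' @export
segment_level_map <- function(subsegments, field, strategy = c("ang", "cfo", "vol"),
                              metric_name) {
  stopifnot(inherits(field, "fixel_field"))
  strategy <- match_strategy(strategy[1])
  if (!metric_name %in% names(field$metrics))
    stop("unknown metric '", metric_name, "'; available: ",
         paste(names(field$metrics), collapse = ", "))
  nvox <- prod(field$shape)
  num <- numeric(nvox); den <- numeric(nvox)
  for (r in seq_len(nrow(subsegments))) {
    i <- subsegments$i[r]; j <- subsegments$j[r]; k <- subsegments$k[r]
    vf <- voxel_fixels(field, i, j, k)
    if (length(vf$fractions) == 0L) next
    u <- c(subsegments$dir_x[r], subsegments$dir_y[r], subsegments$dir_z[r])
    a <- alpha_for(strategy, u, vf$orientations, vf$fractions)
    mvs <- segment_metric(a, vf$metrics[[metric_name]])
    lin <- (k - 1L) * field$shape[1] * field$shape[2] + (j - 1L) * field$shape[1] + i
    num[lin] <- num[lin] + subsegments$length[r] * mvs
    den[lin] <- den[lin] + subsegments$length[r]
  }
  vals <- rep(NaN, nvox)
  nz <- den > 0
  vals[nz] <- num[nz] / den[nz]
  structure(list(
    values = array(vals, dim = field$shape),
    metric_name = metric_name, strategy = strategy, affine = field$affine
  ), class = "microstructure_map")
}

#' Tract-wide mean of a microstructure map
#'
#' Scalar summary \eqn{\bar M = \sum_v \gamma_v M_v / \sum_v \gamma_v}. Under
#' total-segment-length weighting (\code{"tsl"}) \eqn{\gamma_v = w_v}, so
#' voxels occupied by more/longer streamline segments contribute more; under
#' region-of-interest weighting (\code{"roi"}) \eqn{\gamma_v = 1} for every
#' voxel the tract traverses. Undefined map voxels are excluded from both
#' numerator and denominator.
#'
#' @param map a \code{\link{compute_microstructure_map}} result.
#' @param weight_maps the matching \code{\link{compute_weight_maps}} result.
#' @param weighting \code{"tsl"} or \code{"roi"}.
#' @param min_length minimum total segment length (mm) for a voxel to count as
#'   tract-occupied under \code{"roi"} weighting; suppresses edge voxels
#'   traversed by only a sliver of streamline. Default 0 (any presence).
#' @return An object of class \code{"tract_summary"}: list with \code{mean},
#'   \code{weighting}, \code{strategy}, \code{metric_name}, \code{n_voxels},
#'   \code{total_length_mm}.
#' @export
tract_mean <- function(map, weight_maps, weighting = c("tsl", "roi"),
                       min_length = 0) {
  stopifnot(inherits(map, "microstructure_map"), inherits(weight_maps, "weight_maps"))
  weighting <- match.arg(weighting)
  if (!identical(dim(map$values), dim(weight_maps$total_length)))
    stop("map and weight maps are on different grids")
  mv <- as.vector(map$values)
  wv <- as.vector(weight_maps$total_length)
  defined <- is.finite(mv) & wv > 0
  gamma <- if (weighting == "tsl") wv else as.numeric(wv > min_length)
  gamma[!defined] <- 0
  if (sum(gamma) == 0)
    stop("tract_mean: no defined voxel (empty tract or all-undefined map)")
  structure(list(
    mean = sum(gamma * mv, na.rm = TRUE) / sum(gamma),
    weighting = weighting,
    strategy = map$strategy,
    metric_name = map$metric_name,
    n_voxels = sum(gamma > 0),
    total_length_mm = sum(wv)
  ), class = "tract_summary")
}

#' @export
print.tract_summary <- function(x, ...) {
  cat(sprintf("Tract mean %s (%s, %s): %.6f over %d voxels (total length %.1f mm)\n",
              x$metric_name, x$strategy, x$weighting, x$mean, x$n_voxels,
              x$total_length_mm))
  invisible(x)
}

#' Along-streamline microstructure profile
#'
#' Traces one streamline through the fixel field and reports, for every
#' in-volume intra-voxel subsegment in traversal order, its voxel, relative
#' fixel contributions, length and segment metric. This is how a streamline
#' exhibits non-constant microstructure along its course.
#'
#' @param streamline n x 3 matrix of world-mm points (or a \code{\link{tract}},
#'   whose \code{index}-th streamline is used).
#' @param field a \code{\link{fixel_field}}.
#' @param strategy contribution strategy (\code{"ang"}, \code{"cfo"},
#'   \code{"vol"}).
#' @param metric_name metric to evaluate along the streamline.
#' @param index streamline index when \code{streamline} is a tract.
#' @return Data frame, one row per subsegment: \code{segment}, \code{i, j, k},
#'   \code{alpha_1..alpha_k_max} (\code{NA} on absent fixel slots),
#'   \code{length}, \code{metric} (\eqn{M_{vs}}; \code{NA} in fixel-free
#'   voxels).
#' @export
streamline_profile <- function(streamline, field, strategy = c("ang", "cfo", "vol"),
                               metric_name, index = 1L) {
  stopifnot(inherits(field, "fixel_field"))
  strategy <- match_strategy(strategy[1])
  if (inherits(streamline, "tract")) streamline <- streamline$streamlines[[index]]
  tr <- tract(list(streamline))
  if (length(tr$streamlines) == 0L) stop("streamline has fewer than 2 distinct points")
  subseg <- split_tract(tr, grid_of(field))
  if (!nrow(subseg)) {
    message("streamline_profile: streamline lies entirely outside the grid")
  }
  km <- field$k_max
  am <- matrix(NA_real_, nrow(subseg), km)
  mvs <- rep(NA_real_, nrow(subseg))
  for (r in seq_len(nrow(subseg))) {
    vf <- voxel_fixels(field, subseg$i[r], subseg$j[r], subseg$k[r])
    kv <- length(vf$fractions)
    if (kv == 0L) next
    u <- c(subseg$dir_x[r], subseg$dir_y[r], subseg$dir_z[r])
    a <- alpha_for(strategy, u, vf$orientations, vf$fractions)
    am[r, seq_len(kv)] <- a
    mvs[r] <- segment_metric(a, vf$metrics[[metric_name]])
  }
  colnames(am) <- paste0("alpha_", seq_len(km))
  out <- cbind(subseg[, c("segment", "i", "j", "k")], as.data.frame(am),
               length = subseg$length, metric = mvs)
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy
  attr(out, "metric_name") <- metric_name
  out
}

#' Scan-rescan percentage-change summary
#'
#' Per-tract percentage change between two paired sets of tract means, using
#' the symmetric (Bland-Altman style) denominator: \eqn{100 (m_2 - m_1) /
#' ((m_1 + m_2)/2)}, plus the mean and sample standard deviation of the
#' changes across tracts.
#'
#' @param means_scan1,means_scan2 equal-length vectors of positive per-tract
#'   means from the two sessions.
#' @return List with \code{change} (per-tract percentage changes),
#'   \code{mean}, \code{sd} (\code{NA} for a single tract).
#' @export
scan_rescan_stats <- function(means_scan1, means_scan2) {
  if (length(means_scan1) != length(means_scan2))
    stop("scan_rescan_stats: paired value lists differ in length")
  if (length(means_scan1) == 0L) stop("scan_rescan_stats: empty input")
  if (any(means_scan1 <= 0) || any(means_scan2 <= 0))
    stop("scan_rescan_stats: tract means must be positive")
  change <- 100 * (means_scan2 - means_scan1) / ((means_scan1 + means_scan2) / 2)
  list(change = change, mean = mean(change),
       sd = if (length(change) > 1L) stats::sd(change) else NA_real_)
}
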