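#' Specification of a synthetic crossing-tract phantom
#'
#' Describes a 2D-slice phantom of four straight white-matter tracts — two
#' horizontal (T1 top, T2 bottom) crossed by two vertical (T3, T4) — on a
#' voxel grid, with known per-tract fiber volume fraction (FVF) and fractional
#' anisotropy (FA) ground truths, cerebrospinal-fluid (CSF) voxels carrying no
#' fixels, and matched straight streamlines per tract. Crossing voxels contain
#' both tracts' fixels; every fixel carries its own tract's ground-truth
#' metrics, so the phantom exercises multi-fixel weighting with an exactly
#' known answer.
#'
#' The horizontal tracts have spatially constant FVF (defaults 0.70 top, 0.66
#' bottom); the vertical tracts' FVF increases linearly from top to bottom of
#' the grid over \code{vertical_fvf_range}. FA ground truths follow the same
#' pattern.
#'
#' @param shape grid dimensions (default \code{c(32, 32, 1)}: one slice).
#' @param voxel_size isotropic voxel size in mm (default 2).
#' @param t1_rows,t2_rows 1-based row (y) indices of the top / bottom
#'   horizontal tract bands.
#' @param t3_cols,t4_cols 1-based column (x) indices of the vertical tract
#'   bands.
#' @param fvf_t1,fvf_t2 horizontal-tract FVF ground truths.
#' @param fa_t1,fa_t2 horizontal-tract FA ground truths.
#' @param vertical_fvf_range,vertical_fa_range vertical-tract metric values at
#'   the top and bottom grid rows (linear in between).
#' @param crossing_fractions volume fractions of the (horizontal, vertical)
#'   fixels in crossing voxels.
#' @param n_streamlines streamlines per tract.
#' @param step_size streamline step size in mm.
#' @param jitter_sd orientation jitter standard deviation in degrees (0 =
#'   perfect fixels).
#' @param seed integer seed controlling streamline offsets and jitter.
#' @param corrupt \code{NULL}, or a list with elements \code{tract},
#'   \code{upper_fraction}, \code{split_angle_deg}, \code{metric_offsets}
#'   describing a spurious-fixel corruption to apply (see
#'   \code{\link{corrupt_fixels}}).
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 1L), voxel_size = 2,
                         t1_rows = 21:24, t2_rows = 9:12,
                         t3_cols = 9:12, t4_cols = 21:24,
                         fvf_t1 = 0.70, fvf_t2 = 0.66,
                         fa_t1 = 0.78, fa_t2 = 0.74,
                         vertical_fvf_range = c(0.40, 0.70),
                         vertical_fa_range = c(0.45, 0.70),
                         crossing_fractions = c(0.5, 0.5),
                         n_streamlines = 50L, step_size = 1,
                         jitter_sd = 0, seed = 1L, corrupt = NULL) {
  spec <- list(shape = as.integer(shape), voxel_size = voxel_size,
               t1_rows = as.integer(t1_rows), t2_rows = as.integer(t2_rows),
               t3_cols = as.integer(t3_cols), t4_cols = as.integer(t4_cols),
               fvf_t1 = fvf_t1, fvf_t2 = fvf_t2, fa_t1 = fa_t1, fa_t2 = fa_t2,
               vertical_fvf_range = vertical_fvf_range,
               vertical_fa_range = vertical_fa_range,
               crossing_fractions = crossing_fractions,
               n_streamlines = as.integer(n_streamlines), step_size = step_size,
               jitter_sd = jitter_sd, seed = as.integer(seed), corrupt = corrupt)
  problems <- character(0)
  p <- function(msg) problems <<- c(problems, msg)
  if (length(spec$shape) != 3L || any(spec$shape < 1L)) p("shape must be 3 positive integers")
  if (spec$voxel_size <= 0) p("voxel_size must be positive")
  rows_ok <- function(r, n) length(r) >= 1L && all(r >= 1L & r <= n)
  if (!rows_ok(spec$t1_rows, spec$shape[2])) p("t1_rows outside grid")
  if (!rows_ok(spec$t2_rows, spec$shape[2])) p("t2_rows outside grid")
  if (!rows_ok(spec$t3_cols, spec$shape[1])) p("t3_cols outside grid")
  if (!rows_ok(spec$t4_cols, spec$shape[1])) p("t4_cols outside grid")
  if (length(intersect(spec$t1_rows, spec$t2_rows))) p("horizontal bands overlap")
  if (length(intersect(spec$t3_cols, spec$t4_cols))) p("vertical bands overlap")
  gt <- c(spec$fvf_t1, spec$fvf_t2, spec$fa_t1, spec$fa_t2,
          spec$vertical_fvf_range, spec$vertical_fa_range)
  if (any(gt < 0 | gt > 1)) p("ground-truth FVF/FA values must lie in [0, 1]")
  if (length(spec$crossing_fractions) != 2L || any(spec$crossing_fractions <= 0) ||
      sum(spec$crossing_fractions) > 1 + 1e-9)
    p("crossing_fractions must be 2 positive values summing to at most 1")
  if (spec$n_streamlines < 1L) p("n_streamlines must be positive")
  if (spec$step_size <= 0) p("step_size must be positive")
  if (spec$jitter_sd < 0) p("jitter_sd must be non-negative")
  if (length(problems))
    stop("invalid phantom spec:\n  - ", paste(problems, collapse = "\n  - "))
  structure(spec, class = "phantom_spec")
}

# Vertical-tract metric ground truth at 1-based row y: linear from range[1] at
# the top grid row to range[2] at the bottom row.
vertical_value <- function(y, ny, range) {
  if (ny == 1L) return(mean(range))
  range[2] + (range[1] - range[2]) * (y - 1) / (ny - 1)
}

#' Generate a synthetic crossing-tract phantom
#'
#' Builds the fixel field, per-tract streamlines and ground-truth manifest
#' described by a \code{\link{phantom_spec}}. Horizontal-tract fixels point
#' along +x, vertical along +y (plus optional seeded angular jitter); crossing
#' voxels hold both fixels (horizontal first); all other voxels are CSF with
#' no fixels. Streamlines are straight polylines spanning the grid along each
#' tract's axis, at seeded random offsets covering the band cross-section.
#' Output is bit-identical for a fixed seed.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return An object of class \code{"phantom_bundle"}: list with
#'   \code{field} (a \code{\link{fixel_field}} with metrics \code{FVF} and
#'   \code{FA}), \code{tracts} (named list of \code{\link{tract}}s T1-T4),
#'   \code{manifest} (per-tract ground truths, per-voxel truth table, and
#'   provenance of the diffusion-simulation parameters the phantom geometry
#'   descends from), and \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(spec$seed)

  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  km <- 2L
  affine <- diag(c(rep(spec$voxel_size, 3), 1))
  orient <- array(0, dim = c(nx, ny, nz, km, 3))
  frac <- array(0, dim = c(nx, ny, nz, km))
  fvf <- array(0, dim = c(nx, ny, nz, km))
  fa <- array(0, dim = c(nx, ny, nz, km))

  horiz <- list(T1 = list(rows = spec$t1_rows, fvf = spec$fvf_t1, fa = spec$fa_t1),
                T2 = list(rows = spec$t2_rows, fvf = spec$fvf_t2, fa = spec$fa_t2))
  vert <- list(T3 = list(cols = spec$t3_cols), T4 = list(cols = spec$t4_cols))
  vcols <- c(spec$t3_cols, spec$t4_cols)
  hrows <- c(spec$t1_rows, spec$t2_rows)

  truth <- list()
  kz <- 1L  # single slice populated; extra slices (if any) stay CSF
  for (tn in names(horiz)) {
    h <- horiz[[tn]]
    for (y in h$rows) for (x in seq_len(nx)) {
      crossing <- x %in% vcols
      orient[x, y, kz, 1L, ] <- c(1, 0, 0)
      frac[x, y, kz, 1L] <- if (crossing) spec$crossing_fractions[1] else 1
      fvf[x, y, kz, 1L] <- h$fvf
      fa[x, y, kz, 1L] <- h$fa
      truth[[length(truth) + 1L]] <- data.frame(
        tract = tn, i = x, j = y, k = kz, fixel = 1L, crossing = crossing,
        fvf = h$fvf, fa = h$fa)
    }
  }
  for (tn in names(vert)) {
    v <- vert[[tn]]
    for (x in v$cols) for (y in seq_len(ny)) {
      crossing <- y %in% hrows
      slot <- if (crossing) 2L else 1L
      vf <- vertical_value(y, ny, spec$vertical_fvf_range)
      va <- vertical_value(y, ny, spec$vertical_fa_range)
      orient[x, y, kz, slot, ] <- c(0, 1, 0)
      frac[x, y, kz, slot] <- if (crossing) spec$crossing_fractions[2] else 1
      fvf[x, y, kz, slot] <- vf
      fa[x, y, kz, slot] <- va
      truth[[length(truth) + 1L]] <- data.frame(
        tract = tn, i = x, j = y, k = kz, fixel = slot, crossing = crossing,
        fvf = vf, fa = va)
    }
  }
  truth <- do.call(rbind, truth)

  if (spec$jitter_sd > 0) {
    for (x in seq_len(nx)) for (y in seq_len(ny)) for (kk in seq_len(km)) {
      if (frac[x, y, kz, kk] <= 0) next
      u <- orient[x, y, kz, kk, ]
      ang <- stats::rnorm(1, 0, spec$jitter_sd) * pi / 180
      ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      w1 <- ref - sum(ref * u) * u; w1 <- w1 / sqrt(sum(w1^2))
      w2 <- c(u[2] * w1[3] - u[3] * w1[2], u[3] * w1[1] - u[1] * w1[3],
              u[1] * w1[2] - u[2] * w1[1])
      phi <- stats::runif(1, 0, 2 * pi)
      w <- cos(phi) * w1 + sin(phi) * w2
      orient[x, y, kz, kk, ] <- cos(ang) * u + sin(ang) * w
    }
  }

  field <- fixel_field(orient, frac, metrics = list(FVF = fvf, FA = fa),
                       affine = affine)

  band_lines <- function(band_idx, horizontal) {
    # random offsets across the band cross-section, kept 0.1 voxel inside
    lo <- min(band_idx) - 1 - 0.4; hi <- max(band_idx) - 1 + 0.4
    offs <- stats::runif(spec$n_streamlines, lo, hi) * spec$voxel_size
    n_along <- if (horizontal) nx else ny
    a0 <- -0.45 * spec$voxel_size
    a1 <- (n_along - 1 + 0.45) * spec$voxel_size
    along <- seq(a0, a1, by = spec$step_size)
    if (a1 - along[length(along)] > 1e-9) along <- c(along, a1)
    lapply(offs, function(o) {
      if (horizontal) cbind(along, o, 0) else cbind(o, along, 0)
    })
  }
  tracts <- list(
    T1 = tract(band_lines(spec$t1_rows, TRUE), step_size = spec$step_size),
    T2 = tract(band_lines(spec$t2_rows, TRUE), step_size = spec$step_size),
    T3 = tract(band_lines(spec$t3_cols, FALSE), step_size = spec$step_size),
    T4 = tract(band_lines(spec$t4_cols, FALSE), step_size = spec$step_size)
  )

  manifest <- list(
    tracts = list(
      T1 = list(kind = "horizontal", rows = spec$t1_rows, fvf = spec$fvf_t1,
                fa = spec$fa_t1),
      T2 = list(kind = "horizontal", rows = spec$t2_rows, fvf = spec$fvf_t2,
                fa = spec$fa_t2),
      T3 = list(kind = "vertical", cols = spec$t3_cols,
                fvf_range = spec$vertical_fvf_range,
                fa_range = spec$vertical_fa_range),
      T4 = list(kind = "vertical", cols = spec$t4_cols,
                fvf_range = spec$vertical_fvf_range,
                fa_range = spec$vertical_fa_range)
    ),
    ground_truth = truth,
    seed = spec$seed,
    provenance = list(
      note = paste("phantom generated directly at the fixel level; the",
                   "diffusion-signal simulation parameters below describe the",
                   "substrate the geometry emulates and are recorded for",
                   "provenance only"),
      intra_axonal_diffusivity_um2_per_ms = 2.0,
      extracellular_diffusivity_um2_per_ms = 1.0,
      axon_diameter_gamma_mean_um = 1.0,
      axon_diameter_gamma_variance_um = 0.6
    )
  )

  bundle <- structure(list(field = field, tracts = tracts, manifest = manifest,
                           spec = spec), class = "phantom_bundle")
  if (!is.null(spec$corrupt)) {
    co <- spec$corrupt
    region <- corruption_region(bundle, tract = co$tract %||% "T3",
                                upper_fraction = co$upper_fraction %||% 0.5)
    bundle <- corrupt_fixels(bundle, region,
                             split_angle_deg = co$split_angle_deg %||% 30,
                             metric_offsets = co$metric_offsets %||% c(FA = 0.1))
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("Crossing-tract phantom:", paste(x$field$shape, collapse = " x "),
      "voxels,", length(x$tracts), "tracts,",
      length(x$tracts$T1$streamlines), "streamlines/tract\n")
  if (!is.null(x$manifest$corruption)) cat("  spurious-fixel corruption applied\n")
  invisible(x)
}

#' Single-fixel region of a phantom tract, for corruption scenarios
#'
#' Selects the voxels of one phantom tract that (a) contain exactly one fixel
#' (i.e. lie outside crossings) and (b) fall in the upper part of the grid —
#' the scenario in which a multi-fixel model spuriously splits one true fiber
#' population into two.
#'
#' @param bundle a \code{\link{generate_phantom}} result.
#' @param tract tract name (default \code{"T3"}, a vertical tract).
#' @param upper_fraction fraction of the grid height (from the top) defining
#'   the corrupted region.
#' @return Logical array of the grid shape.
#' @export
corruption_region <- function(bundle, tract = "T3", upper_fraction = 0.5) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  gt <- bundle$manifest$ground_truth
  sel <- gt[gt$tract == tract & !gt$crossing, , drop = FALSE]
  ny <- bundle$field$shape[2]
  sel <- sel[sel$j > ny * (1 - upper_fraction), , drop = FALSE]
  region <- array(FALSE, dim = bundle$field$shape)
  region[cbind(sel$i, sel$j, sel$k)] <- TRUE
  region
}

#' Inject spurious split fixels into a phantom
#'
#' Emulates a multi-fixel model estimation error: within \code{region}, each
#' true single fixel is replaced by two fixels tilted \eqn{\pm}
#' \code{split_angle_deg / 2} about the true axis, with fractions split
#' 0.5/0.5 and each named metric offset by \eqn{+\delta} (first fixel) and
#' \eqn{-\delta}. The manifest ground truth is unchanged: the corruption is an
#' estimation error, not a change in the underlying tissue.
#'
#' @param bundle a \code{\link{generate_phantom}} result.
#' @param region logical array of the grid shape selecting single-fixel voxels
#'   to corrupt (see \code{\link{corruption_region}}).
#' @param split_angle_deg total angle between the two spurious fixels.
#' @param metric_offsets named numeric vector of metric offsets \eqn{\delta}
#'   (metrics not named are left unchanged on both spurious fixels).
#' @return A corrupted \code{"phantom_bundle"}; \code{manifest$corruption}
#'   records the parameters and affected voxels.
#' @export
corrupt_fixels <- function(bundle, region, split_angle_deg = 30,
                           metric_offsets = c(FA = 0.1)) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  field <- bundle$field
  if (!identical(dim(region), as.integer(field$shape)) &&
      !identical(dim(region), field$shape))
    stop("'region' must be a logical array of the grid shape")
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("corrupt_fixels: empty region")
  kc <- fixel_count(field)
  single <- kc[idx] == 1L
  if (!any(kc[idx] > 0L)) stop("corrupt_fixels: region contains no fixels")
  idx <- idx[single, , drop = FALSE]
  half <- split_angle_deg / 2 * pi / 180
  orient <- field$orientations; frac <- field$fractions
  metrics <- field$metrics
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    slot <- which(frac[i, j, k, ] > 0)[1]
    u <- orient[i, j, k, slot, ]
    # tilt within the slice plane: perpendicular = u x z (fallback u x x)
    w <- c(u[2], -u[1], 0)
    if (sum(w^2) < 1e-12) w <- c(0, u[3], -u[2])
    w <- w / sqrt(sum(w^2))
    f0 <- frac[i, j, k, slot]
    orient[i, j, k, 1L, ] <- cos(half) * u + sin(half) * w
    orient[i, j, k, 2L, ] <- cos(half) * u - sin(half) * w
    frac[i, j, k, ] <- 0
    frac[i, j, k, 1:2] <- f0 / 2
    for (nm in names(metrics)) {
      m0 <- metrics[[nm]][i, j, k, slot]
      delta <- if (nm %in% names(metric_offsets)) metric_offsets[[nm]] else 0
      metrics[[nm]][i, j, k, ] <- 0
      metrics[[nm]][i, j, k, 1L] <- m0 + delta
      metrics[[nm]][i, j, k, 2L] <- m0 - delta
    }
  }
  bundle$field <- fixel_field(orient, frac, metrics, field$affine)
  bundle$manifest$corruption <- list(
    n_voxels = nrow(idx), split_angle_deg = split_angle_deg,
    metric_offsets = as.list(metric_offsets),
    voxels = idx
  )
  bundle
}
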