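#' Construct a fixel field
#'
#' A fixel field holds, for every voxel of a 3D grid, up to \code{k_max} fiber
#' populations ("fixels"), each with a principal orientation (a sign-ambiguous
#' unit vector in world RAS coordinates), a volume fraction, and one or more
#' named microstructural metrics (e.g. FA, FVF). This is the standard output
#' layout of multi-fixel diffusion models (peaks + per-fixel scalar volumes).
#'
#' A fixel slot is considered absent when its fraction is \code{<= 0} or its
#' orientation vector has near-zero norm; absent slots are zeroed on
#' construction so that the per-voxel effective fixel count is simply the
#' number of non-zero slots.
#'
#' @param orientations numeric array of dimension \code{c(shape, k_max, 3)}:
#'   per-voxel fixel orientations in world (RAS) coordinates. Vectors with norm
#'   in \code{[0.9, 1.1]} are re-normalized to unit length; other non-zero
#'   norms are rejected.
#' @param fractions numeric array of dimension \code{c(shape, k_max)}: per-fixel
#'   volume fractions in \code{[0, 1]}. The per-voxel sum may be below 1 (an
#'   isotropic compartment occupies the remainder).
#' @param metrics named list of numeric arrays, each of dimension
#'   \code{c(shape, k_max)}: per-fixel scalar metrics.
#' @param affine 4x4 invertible voxel-to-world transform (mm), voxel centers at
#'   integer (0-based) voxel coordinates.
#' @return An object of class \code{"fixel_field"}: a list with elements
#'   \code{shape}, \code{affine}, \code{k_max}, \code{orientations},
#'   \code{fractions}, \code{metrics}.
#' @examples
#' ff <- fixel_field(
#'   orientations = array(rep(c(1, 0, 0), each = 1), dim = c(1, 1, 1, 1, 3)),
#'   fractions    = array(0.7, dim = c(1, 1, 1, 1)),
#'   metrics      = list(FA = array(0.8, dim = c(1, 1, 1, 1))),
#'   affine       = diag(4)
#' )
#' fixel_count(ff)
#' @export
fixel_field <- function(orientations, fractions, metrics = list(), affine = diag(4)) {
  do <- dim(orientations)
  if (length(do) != 5L || do[5] != 3L)
    stop("'orientations' must be a 5D array of dimension c(shape, k_max, 3)")
  shape <- do[1:3]
  k_max <- do[4]
  if (!identical(dim(fractions), c(shape, k_max)))
    stop("'fractions' must have dimension c(shape, k_max) = (",
         paste(c(shape, k_max), collapse = ", "), ")")
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("'affine' is singular")
  if (length(metrics) && (is.null(names(metrics)) || any(names(metrics) == "")))
    stop("'metrics' must be a named list")
  for (nm in names(metrics))
    if (!identical(dim(metrics[[nm]]), c(shape, k_max)))
      stop("metric '", nm, "' must have dimension c(shape, k_max)")
  if (any(fractions < -1e-9 | fractions > 1 + 1e-9, na.rm = TRUE))
    stop("fixel fractions must lie in [0, 1]")

  nvox <- prod(shape)
  om <- matrix(orientations, nrow = nvox * k_max, ncol = 3L)
  nrm <- sqrt(rowSums(om^2))
  frv <- as.vector(fractions)
  present <- frv > 0 & nrm > 1e-8
  bad <- present & (nrm < 0.9 | nrm > 1.1)
  if (any(bad))
    stop(sum(bad), " fixel orientation(s) have norm outside [0.9, 1.1]; ",
         "not interpretable as unit peak vectors")
  om[present, ] <- om[present, , drop = FALSE] / nrm[present]
  om[!present, ] <- 0
  frv[!present] <- 0
  fsum <- rowSums(matrix(frv, nrow = nvox, ncol = k_max))
  if (any(fsum > 1 + 1e-6))
    stop("per-voxel fixel fractions sum above 1 in ", sum(fsum > 1 + 1e-6), " voxel(s)")
  for (nm in names(metrics)) {
    mv <- as.vector(metrics[[nm]])
    mv[!present] <- 0
    metrics[[nm]] <- array(mv, dim = c(shape, k_max))
  }

  structure(list(
    shape        = as.integer(shape),
    affine       = affine,
    k_max        = as.integer(k_max),
    orientations = array(om, dim = c(shape, k_max, 3L)),
    fractions    = array(frv, dim = c(shape, k_max)),
    metrics      = metrics
  ), class = "fixel_field")
}

#' Per-voxel effective fixel count
#'
#' @param field a \code{\link{fixel_field}}.
#' @return Integer array of the grid shape: the number of present fixels per
#'   voxel (0 for CSF / non-WM voxels).
#' @export
fixel_count <- function(field) {
  stopifnot(inherits(field, "fixel_field"))
  pres <- field$fractions > 0
  array(as.integer(rowSums(matrix(pres, nrow = prod(field$shape)))),
        dim = field$shape)
}

# Present-fixel data of one voxel (1-based index triple) as a list:
# orientations (K x 3), fractions, metrics (named list of length-K vectors).
voxel_fixels <- function(field, i, j, k) {
  fr <- field$fractions[i, j, k, ]
  pres <- which(fr > 0)
  list(
    orientations = matrix(field$orientations[i, j, k, pres, ], ncol = 3L),
    fractions    = fr[pres],
    metrics      = lapply(field$metrics, function(m) m[i, j, k, pres])
  )
}

#' @export
print.fixel_field <- function(x, ...) {
  kc <- fixel_count(x)
  cat("Fixel field:", paste(x$shape, collapse = " x "), "voxels, k_max =",
      x$k_max, "\n")
  cat("  voxels with fixels:", sum(kc > 0), "(multi-fixel:", sum(kc > 1), ")\n")
  cat("  metrics:", if (length(x$metrics)) paste(names(x$metrics), collapse = ", ")
      else "none", "\n")
  invisible(x)
}
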