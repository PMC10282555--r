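#' Voxel grid
#'
#' A 3D voxel grid with an affine voxel-to-world transform (mm). Voxel centers
#' sit at integer 0-based voxel coordinates; voxel \code{(i,j,k)} spans the
#' half-open box \code{[i-0.5, i+0.5)} along each axis, the dominant
#' neuroimaging streamline convention.
#'
#' @param shape 3 positive integers (grid dimensions).
#' @param affine 4x4 invertible voxel-to-world transform (mm).
#' @return An object of class \code{"voxel_grid"}.
#' @export
voxel_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("'shape' must be 3 positive integers")
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("'affine' is singular")
  structure(list(shape = shape, affine = affine, inv_affine = solve(affine)),
            class = "voxel_grid")
}

grid_of <- function(field) voxel_grid(field$shape, field$affine)

same_grid <- function(a, b, tol = 1e-4) {
  identical(as.integer(a$shape), as.integer(b$shape)) &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Convert between world (mm) and continuous voxel coordinates
#'
#' @param grid a \code{\link{voxel_grid}} or \code{\link{fixel_field}}.
#' @param points n x 3 matrix (or 3-vector) of coordinates.
#' @return n x 3 matrix of transformed coordinates (0-based voxel coordinates,
#'   voxel centers at integers).
#' @export
world_to_voxel <- function(grid, points) {
  if (inherits(grid, "fixel_field")) grid <- grid_of(grid)
  p <- rbind(points)
  v <- cbind(p, 1) %*% t(grid$inv_affine)
  v[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(grid, points) {
  if (inherits(grid, "fixel_field")) grid <- grid_of(grid)
  p <- rbind(points)
  w <- cbind(p, 1) %*% t(grid$affine)
  w[, 1:3, drop = FALSE]
}

#' Construct a tract
#'
#' A tract is an ordered set of streamlines, each a polyline of 3D points in
#' world millimeter coordinates. Consecutive duplicate points are removed on
#' construction; streamlines reduced below 2 points are dropped.
#'
#' @param streamlines list of n x 3 numeric matrices (world mm).
#' @param step_size nominal tractography step size in mm (metadata only; no
#'   resampling is performed).
#' @return An object of class \code{"tract"}.
#' @export
tract <- function(streamlines, step_size = NA_real_) {
  if (!is.list(streamlines)) stop("'streamlines' must be a list of n x 3 matrices")
  cleaned <- lapply(streamlines, function(s) {
    s <- rbind(s)
    if (ncol(s) != 3L) stop("each streamline must have 3 columns (x, y, z in mm)")
    if (nrow(s) < 2L) return(NULL)
    keep <- c(TRUE, rowSums(abs(diff(s))) > 0)
    s <- s[keep, , drop = FALSE]
    if (nrow(s) < 2L) NULL else unname(s)
  })
  cleaned <- cleaned[!vapply(cleaned, is.null, logical(1))]
  structure(list(streamlines = cleaned, step_size = step_size), class = "tract")
}

#' @export
print.tract <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat("Tract:", length(x$streamlines), "streamlines,",
      sum(pmax(np - 1L, 0L)), "segments")
  if (!is.na(x$step_size)) cat(", step size", x$step_size, "mm")
  cat("\n")
  invisible(x)
}

#' Total polyline length of a tract
#' @param x a \code{\link{tract}}.
#' @return Total length in mm.
#' @export
tract_length <- function(x) {
  sum(vapply(x$streamlines, function(s) sum(sqrt(rowSums(diff(s)^2))), numeric(1)))
}

#' Subdivide a straight segment at voxel boundaries
#'
#' Splits the world-space segment \code{[p0, p1]} into intra-voxel pieces by
#' parametric ray marching against the half-integer boundary planes of the
#' grid's voxel coordinate system. Piece lengths are measured in world mm and
#' sum to \code{|p1 - p0|}; pieces whose voxel falls outside the grid are
#' flagged out-of-volume.
#'
#' @param p0,p1 segment endpoints (world mm).
#' @param grid a \code{\link{voxel_grid}}.
#' @return Data frame with one row per piece: \code{i, j, k} (1-based voxel
#'   index), \code{dir_x, dir_y, dir_z} (unit direction of the parent segment,
#'   world space), \code{length} (mm), \code{in_volume}.
#' @export
split_segment <- function(p0, p1, grid) {
  d_world <- p1 - p0
  seg_len <- sqrt(sum(d_world^2))
  if (seg_len == 0) return(empty_subsegments())
  v0 <- as.vector(world_to_voxel(grid, p0))
  v1 <- as.vector(world_to_voxel(grid, p1))
  dv <- v1 - v0
  ts <- c(0, 1)
  for (ax in 1:3) {
    if (abs(dv[ax]) < 1e-12) next
    lo <- floor(min(v0[ax], v1[ax]) + 0.5) + 0.5
    hi <- floor(max(v0[ax], v1[ax]) + 0.5) - 0.5
    if (hi < lo) next
    b <- seq(lo, hi, by = 1)
    ts <- c(ts, (b - v0[ax]) / dv[ax])
  }
  ts <- sort(ts[ts > -1e-12 & ts < 1 + 1e-12])
  ts[1] <- 0; ts[length(ts)] <- 1
  ts <- ts[c(TRUE, diff(ts) > 1e-12)]
  n <- length(ts) - 1L
  tm <- (ts[-length(ts)] + ts[-1]) / 2
  mid <- matrix(v0, nrow = n, ncol = 3, byrow = TRUE) + outer(tm, dv)
  idx <- floor(mid + 0.5)
  lens <- diff(ts) * seg_len
  keep <- lens > 0
  idx <- idx[keep, , drop = FALSE]; lens <- lens[keep]
  u <- d_world / seg_len
  inside <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
    idx[, 1] < grid$shape[1] & idx[, 2] < grid$shape[2] & idx[, 3] < grid$shape[3]
  data.frame(
    i = as.integer(idx[, 1]) + 1L, j = as.integer(idx[, 2]) + 1L,
    k = as.integer(idx[, 3]) + 1L,
    dir_x = u[1], dir_y = u[2], dir_z = u[3],
    length = lens, in_volume = inside
  )
}

empty_subsegments <- function() {
  data.frame(streamline = integer(0), segment = integer(0),
             i = integer(0), j = integer(0), k = integer(0),
             dir_x = numeric(0), dir_y = numeric(0), dir_z = numeric(0),
             length = numeric(0), in_volume = logical(0))
}

#' Subdivide every segment of a tract at voxel boundaries
#'
#' Applies \code{\link{split_segment}} to every consecutive point pair of every
#' streamline, in streamline-major then along-streamline order. Out-of-volume
#' pieces are dropped (with a message when a whole streamline falls outside).
#'
#' @param x a \code{\link{tract}}.
#' @param grid a \code{\link{voxel_grid}} (or \code{\link{fixel_field}}, whose
#'   grid is used).
#' @param keep_out_of_volume keep pieces outside the grid (marked by
#'   \code{in_volume = FALSE}) instead of dropping them.
#' @return Data frame of subsegments with provenance columns
#'   \code{streamline}, \code{segment} plus the \code{\link{split_segment}}
#'   columns; the grid is attached as attribute \code{"grid"}.
#' @export
split_tract <- function(x, grid, keep_out_of_volume = FALSE) {
  stopifnot(inherits(x, "tract"))
  if (inherits(grid, "fixel_field")) grid <- grid_of(grid)
  if (length(x$streamlines) == 0L) stop("split_tract: empty tract")
  out <- vector("list", length(x$streamlines))
  for (li in seq_along(x$streamlines)) {
    s <- x$streamlines[[li]]
    pieces <- vector("list", nrow(s) - 1L)
    for (si in seq_len(nrow(s) - 1L)) {
      ss <- split_segment(s[si, ], s[si + 1L, ], grid)
      if (nrow(ss)) { ss$streamline <- li; ss$segment <- si }
      pieces[[si]] <- ss
    }
    res <- do.call(rbind, pieces)
    if (!is.null(res) && nrow(res) && !any(res$in_volume))
      message("split_tract: streamline ", li, " lies entirely outside the grid")
    out[[li]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty_subsegments())
  if (!keep_out_of_volume) res <- res[res$in_volume, , drop = FALSE]
  res <- res[, c("streamline", "segment", "i", "j", "k",
                 "dir_x", "dir_y", "dir_z", "length", "in_volume")]
  rownames(res) <- NULL
  attr(res, "grid") <- grid
  res
}
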