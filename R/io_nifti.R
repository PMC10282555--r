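# NIfTI I/O for fixel fields and maps, through RNifti. The on-disk fixel
# layout is the "peaks" convention: a 4D volume whose last dimension holds
# 3 * k_max values per voxel (consecutive xyz triplets, world RAS unit
# vectors, all-zero triplet = absent fixel); fractions and each metric are 4D
# with last dimension k_max.

read_vol <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img),
       affine = unclass(RNifti::xform(img, useQuaternionFirst = FALSE))[1:4, 1:4])
}

write_vol <- function(data, affine, path, datatype = "float") {
  img <- RNifti::asNifti(data, datatype = datatype)
  RNifti::`sform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a fixel field from NIfTI volumes
#'
#' Loads a peaks volume (last dimension \code{3 * k_max}), a fractions volume
#' and zero or more per-fixel metric volumes (last dimension \code{k_max})
#' sharing one grid and affine, and assembles a \code{\link{fixel_field}}.
#' Peak vectors with norm in \code{[0.9, 1.1]} are re-normalized; other
#' non-zero norms are rejected.
#'
#' @param peaks_path path to the peaks NIfTI.
#' @param fractions_path path to the per-fixel volume-fraction NIfTI.
#' @param metric_paths named character vector of per-fixel metric NIfTIs
#'   (names become metric names).
#' @param affine_tol maximum element-wise affine discrepancy between volumes.
#' @return A \code{\link{fixel_field}}.
#' @export
read_fixel_field <- function(peaks_path, fractions_path,
                             metric_paths = character(0), affine_tol = 1e-4) {
  pk <- read_vol(peaks_path)
  if (length(dim(pk$data)) != 4L || dim(pk$data)[4] %% 3L != 0L)
    stop("peaks volume must be 4D with last dimension a multiple of 3 ",
         "(xyz triplets per fixel); got dimension ",
         paste(dim(pk$data), collapse = " x "))
  shape <- dim(pk$data)[1:3]
  k_max <- dim(pk$data)[4] %/% 3L
  fr <- read_vol(fractions_path)
  check_vol <- function(v, what, last_dim) {
    if (!identical(dim(v$data)[1:3], shape) ||
        length(dim(v$data)) != 4L || dim(v$data)[4] != last_dim)
      stop(what, " volume shape ", paste(dim(v$data), collapse = " x "),
           " does not match peaks grid ", paste(shape, collapse = " x "),
           " with k_max ", k_max)
    if (max(abs(v$affine - pk$affine)) > affine_tol)
      stop(what, " affine differs from peaks affine beyond ", affine_tol,
           ":\npeaks:\n", paste(capture_affine(pk$affine), collapse = "\n"),
           "\n", what, ":\n", paste(capture_affine(v$affine), collapse = "\n"))
  }
  check_vol(fr, "fractions", k_max)
  metrics <- list()
  for (nm in names(metric_paths)) {
    mv <- read_vol(metric_paths[[nm]])
    check_vol(mv, paste0("metric '", nm, "'"), k_max)
    metrics[[nm]] <- array(mv$data, dim = c(shape, k_max))
  }
  # peaks layout (x,y,z,3*k) -> (x,y,z,k,3)
  pkarr <- array(pk$data, dim = c(shape, 3L, k_max))
  orient <- aperm(pkarr, c(1, 2, 3, 5, 4))
  fixel_field(orient, array(fr$data, dim = c(shape, k_max)), metrics, pk$affine)
}

capture_affine <- function(a) apply(round(a, 6), 1, paste, collapse = " ")

#' Write a fixel field to NIfTI volumes
#'
#' Inverse of \code{\link{read_fixel_field}}: writes \code{peaks.nii.gz},
#' \code{fractions.nii.gz} and one \code{metric_<name>.nii.gz} per metric
#' into a directory.
#'
#' @param field a \code{\link{fixel_field}}.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixel_field <- function(field, dir) {
  stopifnot(inherits(field, "fixel_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shape <- field$shape; km <- field$k_max
  peaks <- array(aperm(field$orientations, c(1, 2, 3, 5, 4)),
                 dim = c(shape, 3L * km))
  paths <- c(peaks = file.path(dir, "peaks.nii.gz"),
             fractions = file.path(dir, "fractions.nii.gz"))
  # float64 on disk so a written field reloads bit-identically
  write_vol(peaks, field$affine, paths[["peaks"]], datatype = "double")
  write_vol(field$fractions, field$affine, paths[["fractions"]], datatype = "double")
  for (nm in names(field$metrics)) {
    p <- file.path(dir, paste0("metric_", nm, ".nii.gz"))
    write_vol(field$metrics[[nm]], field$affine, p, datatype = "double")
    paths[nm] <- p
  }
  invisible(paths)
}
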