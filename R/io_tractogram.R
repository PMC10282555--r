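# Tractogram I/O: MRtrix TCK and TrackVis TRK (version 2). Both readers
# return streamline points in world RAS mm. TCK stores scanner-space
# coordinates directly; TRK stores corner-origin "voxel-mm" coordinates that
# are mapped through the header's vox_to_ras affine on load:
#   rasmm = A %*% (p / voxel_size - 0.5).

#' Read a tractogram (TRK or TCK)
#'
#' Dialect is detected from the file magic (falling back to the extension).
#' Streamline points are returned in world RAS millimeters regardless of the
#' on-disk convention.
#'
#' @param path path to a \code{.trk} or \code{.tck} file.
#' @return A \code{\link{tract}}.
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) stop("no such tractogram: ", path)
  con <- file(path, "rb"); magic <- readBin(con, "raw", 13); close(con)
  head <- rawToChar(magic[magic != as.raw(0)])
  if (startsWith(head, "mrtrix tracks")) return(read_tck(path))
  if (startsWith(head, "TRACK")) return(read_trk(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "tck") return(read_tck(path))
  if (ext == "trk") return(read_trk(path))
  stop("unrecognized tractogram format for ", path,
       " (neither MRtrix TCK magic, TRACK magic, nor a known extension)")
}

#' @rdname read_tractogram
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # locate the END marker at byte level (the payload after it is binary)
  raw_head <- readBin(con, "raw", 65536L)
  marker <- charToRaw("\nEND\n")
  end_at <- -1L
  for (p in seq_len(max(0L, length(raw_head) - 4L))) {
    if (raw_head[p] == marker[1] && identical(raw_head[p:(p + 4L)], marker)) {
      end_at <- p; break
    }
  }
  if (end_at < 0) stop("malformed TCK header (no END line) in ", path)
  hdr <- strsplit(rawToChar(raw_head[seq_len(end_at - 1L)]), "\n")[[1]]
  if (!identical(hdr[1], "mrtrix tracks"))
    stop("not a TCK file (missing 'mrtrix tracks' magic): ", path)
  kv <- hdr[-1]
  parse <- function(key) {
    hit <- grep(paste0("^", key, ":"), kv, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  dtype <- parse("datatype")
  if (!dtype %in% c("Float32LE", "Float32BE"))
    stop("unsupported TCK datatype '", dtype, "' in ", path,
         " (only Float32LE/BE)")
  endian <- if (dtype == "Float32LE") "little" else "big"
  offset <- as.integer(strsplit(parse("file"), "[[:space:]]+")[[1]][2])
  step <- suppressWarnings(as.numeric(parse("step_size")))
  seek(con, offset)
  sz <- file.info(path)$size - offset
  vals <- readBin(con, "numeric", n = sz %/% 4, size = 4, endian = endian)
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_sep <- rowSums(is.na(pts)) > 0
  is_end <- rowSums(is.infinite(pts)) > 0
  brk <- which(is_sep | is_end)
  starts <- c(1L, utils::head(brk, -1) + 1L)
  keep <- brk > starts               # drop empty slices (e.g. the terminator)
  streamlines <- mapply(function(s, e) pts[s:(e - 1L), , drop = FALSE],
                        starts[keep], brk[keep], SIMPLIFY = FALSE)
  if (!length(streamlines)) warning("empty tractogram: ", path)
  tract(streamlines, step_size = if (is.na(step)) NA_real_ else step)
}

#' Write a tract as MRtrix TCK
#'
#' @param x a \code{\link{tract}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tck <- function(x, path) {
  stopifnot(inherits(x, "tract"))
  fields <- c("mrtrix tracks", "datatype: Float32LE",
              paste0("count: ", length(x$streamlines)))
  if (!is.na(x$step_size)) fields <- c(fields, paste0("step_size: ", x$step_size))
  # 'file: . N' names its own offset; pad the offset field to a fixed width
  base <- paste0(paste(fields, collapse = "\n"), "\nfile: . ")
  offset <- nchar(base, type = "bytes") + 10L + 5L  # 10-char offset + "\nEND\n"
  hdr <- paste0(base, formatC(offset, width = 10), "\nEND\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in x$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname read_tractogram
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("not a TRK file (missing TRACK magic): ", path)
  dim3 <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))               # scalar names
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))               # property names
  vox2ras <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                    4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444))               # reserved
  invisible(readBin(con, "raw", 4 + 4 + 24 + 2 + 6))  # order, pads, flags
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000L)
    stop("TRK header size ", hdr_size, " != 1000 in ", path,
         " (wrong endianness or corrupt header)")
  if (version < 2L || all(vox2ras == 0))
    stop("TRK version ", version, " without a vox_to_ras affine is not ",
         "supported (world coordinates would be undefined): ", path)
  streamlines <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(np) == 0L) break
    vals <- readBin(con, "numeric", np * (3L + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0)
      invisible(readBin(con, "numeric", n_props, size = 4, endian = "little"))
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm (corner origin) -> voxel -> world RAS
    v <- sweep(m, 2, voxel_size, "/") - 0.5
    w <- cbind(v, 1) %*% t(vox2ras)
    streamlines[[length(streamlines) + 1L]] <- w[, 1:3, drop = FALSE]
  }
  if (n_count > 0 && length(streamlines) != n_count)
    warning("TRK declares ", n_count, " streamlines but ", length(streamlines),
            " were read: ", path)
  if (!length(streamlines)) warning("empty tractogram: ", path)
  tract(streamlines)
}

#' Write a tract as TrackVis TRK (version 2)
#'
#' World RAS points are converted to TRK's corner-origin voxel-mm convention
#' using the supplied grid.
#'
#' @param x a \code{\link{tract}}.
#' @param path output path.
#' @param grid a \code{\link{voxel_grid}} (or \code{\link{fixel_field}})
#'   supplying the reference affine and dimensions stored in the TRK header.
#' @return \code{path}, invisibly.
#' @export
write_trk <- function(x, path, grid) {
  stopifnot(inherits(x, "tract"))
  if (inherits(grid, "fixel_field")) grid <- grid_of(grid)
  voxel_size <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, eos = NULL); writeBin(as.raw(0), con)
  writeBin(as.integer(grid$shape), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")        # origin
  writeBin(0L, con, size = 2, endian = "little")                # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")                # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(grid$affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeChar("RAS", con, eos = NULL); writeBin(as.raw(0), con)   # voxel_order
  writeBin(raw(4), con)                                         # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                         # pad1
  writeBin(raw(6), con)                                         # invert/swap
  writeBin(length(x$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")                # version
  writeBin(1000L, con, size = 4, endian = "little")             # hdr_size
  for (s in x$streamlines) {
    v <- world_to_voxel(grid, s)
    p <- sweep(v + 0.5, 2, voxel_size, "*")
    writeBin(nrow(p), con, size = 4, endian = "little")
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  }
  invisible(path)
}
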