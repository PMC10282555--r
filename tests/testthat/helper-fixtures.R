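# In-code fixtures shared across the suite. Everything is generated from a
# seed so tests are deterministic yet cover varied configurations.

random_unit <- function(n = 1) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# Random fixel field with a mix of 0-, 1- and 2-fixel voxels and two metrics.
random_field <- function(shape = c(6, 5, 4), k_max = 2, seed = 1,
                         p_empty = 0.25) {
  set.seed(seed)
  nvox <- prod(shape)
  orient <- array(0, dim = c(shape, k_max, 3))
  frac <- array(0, dim = c(shape, k_max))
  fa <- array(0, dim = c(shape, k_max))
  fvf <- array(0, dim = c(shape, k_max))
  kv <- sample(0:k_max, nvox, replace = TRUE,
               prob = c(p_empty, rep((1 - p_empty) / k_max, k_max)))
  om <- matrix(orient, nvox * k_max, 3)
  for (v in seq_len(nvox)) {
    if (kv[v] == 0) next
    for (kk in seq_len(kv[v])) {
      om[v + (kk - 1) * nvox, ] <- random_unit()
      frac[v + (kk - 1) * nvox] <- runif(1, 0.05, 1 / k_max)
      fa[v + (kk - 1) * nvox] <- runif(1, 0.1, 0.95)
      fvf[v + (kk - 1) * nvox] <- runif(1, 0.1, 0.9)
    }
  }
  fixel_field(array(om, dim = c(shape, k_max, 3)), frac,
              metrics = list(FA = fa, FVF = fvf),
              affine = diag(c(2, 2, 2, 1)))
}

# Random jittery polylines staying inside the world extent of a grid.
random_tract <- function(grid, n_streamlines = 5, n_points = 12, seed = 1) {
  set.seed(seed)
  lo <- voxel_to_world(grid, c(-0.45, -0.45, -0.45))
  hi <- voxel_to_world(grid, grid$shape - 1 + 0.45)
  sl <- lapply(seq_len(n_streamlines), function(i) {
    p <- runif(3, lo + 1, hi - 1)
    pts <- matrix(NA_real_, n_points, 3)
    pts[1, ] <- p
    for (j in 2:n_points) {
      step <- rnorm(3, 0, 0.8)
      pts[j, ] <- pmin(pmax(pts[j - 1, ] + step, lo), hi)
    }
    pts
  })
  tract(sl, step_size = 1)
}

# Dense-sampling oracle for split_segment: bin 1e4 points along the segment
# by voxel and convert counts to lengths.
sampled_voxel_lengths <- function(p0, p1, grid, n = 1e4) {
  t <- (seq_len(n) - 0.5) / n
  pts <- outer(t, p1 - p0) + matrix(p0, n, 3, byrow = TRUE)
  v <- world_to_voxel(grid, pts)
  idx <- floor(v + 0.5)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  len <- sqrt(sum((p1 - p0)^2))
  tapply(rep(len / n, n), key, sum)
}

# Per-row scalar-path alphas, the independent oracle for the vectorized
# accumulation used by compute_weight_maps.
scalar_alphas <- function(subseg, field, strategy) {
  t(vapply(seq_len(nrow(subseg)), function(r) {
    vf <- voxel_fixels_of(field, subseg$i[r], subseg$j[r], subseg$k[r])
    a <- rep(0, field$k_max)
    if (length(vf$fractions)) {
      u <- c(subseg$dir_x[r], subseg$dir_y[r], subseg$dir_z[r])
      av <- switch(strategy,
                   vol = alpha_vol(vf$fractions),
                   cfo = alpha_cfo(u, vf$orientations),
                   ang = alpha_ang(u, vf$orientations))
      a[vf$slots] <- av
    }
    a
  }, numeric(field$k_max)))
}

voxel_fixels_of <- function(field, i, j, k) {
  fr <- field$fractions[i, j, k, ]
  slots <- which(fr > 0)
  list(slots = slots,
       orientations = matrix(field$orientations[i, j, k, slots, ], ncol = 3),
       fractions = fr[slots])
}

grid_of_field <- function(f) voxel_grid(f$shape, f$affine)

# A minimal hand-built subsegment table on a given grid.
manual_subsegments <- function(rows, grid) {
  if (!length(rows)) {
    df <- data.frame(streamline = integer(0), segment = integer(0),
                     i = integer(0), j = integer(0), k = integer(0),
                     dir_x = numeric(0), dir_y = numeric(0),
                     dir_z = numeric(0), length = numeric(0))
  } else {
    df <- do.call(rbind, lapply(rows, as.data.frame))
  }
  df$in_volume <- rep(TRUE, nrow(df))
  attr(df, "grid") <- grid
  df
}
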