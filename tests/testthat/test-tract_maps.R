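one_voxel_field <- function(orients, fractions, fa) {
  km <- length(fractions)
  fixel_field(array(orients, dim = c(1, 1, 1, km, 3)),
              array(fractions, dim = c(1, 1, 1, km)),
              metrics = list(FA = array(fa, dim = c(1, 1, 1, km))),
              affine = diag(4))
}

test_that("weight maps accumulate alpha-weighted subsegment lengths", {
  f <- one_voxel_field(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.5, 0.5), c(0.9, 0.5))
  g <- grid_of_field(f)
  row1 <- list(streamline = 1L, segment = 1L, i = 1L, j = 1L, k = 1L,
               dir_x = 1, dir_y = 0, dir_z = 0, length = 1)
  wm <- compute_weight_maps(manual_subsegments(list(row1), g), f, "ang")
  expect_equal(as.vector(wm$fixel_weights), c(1, 0))
  expect_equal(as.vector(wm$total_length), 1)
  # two half-length subsegments at 0.6/0.4 contributions (vol weighting)
  f2 <- one_voxel_field(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.6, 0.4), c(0.9, 0.5))
  rows <- list(
    list(streamline = 1L, segment = 1L, i = 1L, j = 1L, k = 1L,
         dir_x = 1, dir_y = 0, dir_z = 0, length = 0.5),
    list(streamline = 1L, segment = 2L, i = 1L, j = 1L, k = 1L,
         dir_x = 0, dir_y = 1, dir_z = 0, length = 0.5))
  wm2 <- compute_weight_maps(manual_subsegments(rows, g), f2, "vol")
  expect_equal(as.vector(wm2$fixel_weights), c(0.6, 0.4))
  expect_equal(as.vector(wm2$total_length), 1)
  # empty subsegment table: all-zero maps
  wm0 <- compute_weight_maps(manual_subsegments(list(), g)[0, ], f, "ang")
  expect_true(all(wm0$fixel_weights == 0) && all(wm0$total_length == 0))
  # grid mismatch is refused
  ss <- manual_subsegments(list(row1), voxel_grid(c(1, 1, 1), diag(c(3, 3, 3, 1))))
  expect_error(compute_weight_maps(ss, f, "ang"), "different grid")
})

test_that("microstructure map is the fixel-weight-weighted metric average", {
  f <- one_voxel_field(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.5, 0.5), c(0.9, 0.5))
  wm <- structure(list(
    fixel_weights = array(c(3, 1), dim = c(1, 1, 1, 2)),
    total_length = array(4, dim = c(1, 1, 1)),
    strategy = "ang", affine = diag(4)), class = "weight_maps")
  m <- compute_microstructure_map(wm, f, "FA")
  expect_equal(as.vector(m$values), 0.8)
  wm$fixel_weights[] <- c(1, 0)
  expect_equal(as.vector(compute_microstructure_map(wm, f, "FA")$values), 0.9)
  wm$fixel_weights[] <- 0
  expect_true(is.nan(as.vector(compute_microstructure_map(wm, f, "FA")$values)))
  expect_error(compute_microstructure_map(wm, f, "MD"), "available: FA")
})

test_that("fixel- and segment-aggregated maps coincide (dual-route identity)", {
  f <- random_field(c(6, 5, 4), seed = 101)
  tr <- random_tract(grid_of_field(f), 8, 12, seed = 102)
  ss <- split_tract(tr, grid_of_field(f))
  for (st in c("ang", "cfo", "vol")) {
    wm <- compute_weight_maps(ss, f, st)
    m1 <- compute_microstructure_map(wm, f, "FA")$values
    m2 <- segment_level_map(ss, f, st, "FA")$values
    same <- is.nan(m1) == is.nan(m2)
    expect_true(all(same))
    d <- is.finite(m1)
    expect_lt(max(abs(m1[d] - m2[d])), 1e-9)
    # per-voxel fixel weights sum to the total segment length where fixels exist
    kv <- fixel_count(f)
    wsum <- apply(wm$fixel_weights, 1:3, sum)
    hasfix <- kv > 0 & wm$total_length > 0
    expect_lt(max(abs(wsum[hasfix] - wm$total_length[hasfix])), 1e-6)
  }
  # total segment length is a tractography-only quantity
  tl <- lapply(c("ang", "cfo", "vol"), function(st)
    compute_weight_maps(ss, f, st)$total_length)
  expect_identical(tl[[1]], tl[[2]])
  expect_identical(tl[[1]], tl[[3]])
})

test_that("tract means follow tsl and roi weighting conventions", {
  # two voxels: A (M = 0.8, w = 3 mm), B (M = 0.6, w = 1 mm)
  m <- structure(list(values = array(c(0.8, 0.6), dim = c(2, 1, 1)),
                      metric_name = "FA", strategy = "ang", affine = diag(4)),
                 class = "microstructure_map")
  wm <- structure(list(fixel_weights = array(c(3, 1), dim = c(2, 1, 1, 1)),
                       total_length = array(c(3, 1), dim = c(2, 1, 1)),
                       strategy = "ang", affine = diag(4)),
                  class = "weight_maps")
  expect_equal(tract_mean(m, wm, "tsl")$mean, 0.75)
  expect_equal(tract_mean(m, wm, "roi")$mean, 0.7)
  expect_equal(tract_mean(m, wm, "roi")$n_voxels, 2L)
  # a min-length threshold drops the thin voxel from the roi
  expect_equal(tract_mean(m, wm, "roi", min_length = 2)$mean, 0.8)
  # constant map: both weightings conserve the constant
  m$values[] <- 0.42
  expect_equal(tract_mean(m, wm, "tsl")$mean, 0.42)
  expect_equal(tract_mean(m, wm, "roi")$mean, 0.42)
  # all-undefined map errors
  m$values[] <- NaN
  expect_error(tract_mean(m, wm, "tsl"), "no defined voxel")
})

test_that("tsl tract mean equals the direct segment-level aggregate", {
  f <- random_field(c(5, 5, 3), seed = 201)
  tr <- random_tract(grid_of_field(f), 6, 10, seed = 202)
  ss <- split_tract(tr, grid_of_field(f))
  for (st in c("ang", "cfo", "vol")) {
    wm <- compute_weight_maps(ss, f, st)
    mp <- compute_microstructure_map(wm, f, "FVF")
    mean_tsl <- tract_mean(mp, wm, "tsl")$mean
    # oracle: sum_v sum_s l_vs M_vs / sum_v sum_s l_vs over fixel-bearing voxels
    num <- 0; den <- 0
    for (r in seq_len(nrow(ss))) {
      vf <- voxel_fixels_of(f, ss$i[r], ss$j[r], ss$k[r])
      if (!length(vf$fractions)) next
      u <- c(ss$dir_x[r], ss$dir_y[r], ss$dir_z[r])
      a <- switch(st, vol = alpha_vol(vf$fractions),
                  cfo = alpha_cfo(u, vf$orientations),
                  ang = alpha_ang(u, vf$orientations))
      mv <- f$metrics$FVF[ss$i[r], ss$j[r], ss$k[r], vf$slots]
      num <- num + ss$length[r] * sum(a * mv)
      den <- den + ss$length[r]
    }
    expect_lt(abs(mean_tsl - num / den), 1e-9)
    # bound: the mean lies within the global metric range over present fixels
    pres <- f$fractions > 0
    expect_gte(mean_tsl, min(f$metrics$FVF[pres]))
    expect_lte(mean_tsl, max(f$metrics$FVF[pres]))
  }
})

test_that("streamline profiles trace per-segment contributions in order", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  # a T1 streamline crosses one-fixel and two-fixel voxels alternately
  pr <- streamline_profile(ph$tracts$T1, ph$field, "ang", "FVF", index = 1)
  expect_true(all(diff(pr$segment) >= 0))
  expect_equal(pr$metric, rep(0.70, nrow(pr)))
  kc <- fixel_count(ph$field)
  kv <- kc[cbind(pr$i, pr$j, pr$k)]
  asum <- rowSums(cbind(pr$alpha_1, pr$alpha_2), na.rm = TRUE)
  expect_lt(max(abs(asum - 1)), 1e-9)
  expect_true(any(kv == 1) && any(kv == 2))
  expect_true(all(is.na(pr$alpha_2[kv == 1])))
  expect_true(all(is.finite(pr$alpha_2[kv == 2])))
  # duplicated consecutive points do not change the profile
  sl <- ph$tracts$T1$streamlines[[1]]
  dup <- sl[rep(seq_len(nrow(sl)), each = 2), ]
  expect_equal(streamline_profile(dup, ph$field, "ang", "FVF"), pr)
  # homogeneous single-fixel region: constant metric, alpha = 1
  sl_v <- ph$tracts$T3$streamlines[[1]]
  prv <- streamline_profile(sl_v, ph$field, "cfo", "FVF")
  expect_true(all(prv$alpha_1[kc[cbind(prv$i, prv$j, prv$k)] == 1] == 1))
})

test_that("scan-rescan summary uses the symmetric percentage change", {
  s <- scan_rescan_stats(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(s$change, c(0, 0, 0))
  expect_equal(s$mean, 0)
  expect_equal(scan_rescan_stats(1.0, 1.1)$change, 100 * 0.1 / 1.05)
  a <- c(0.61, 0.72); b <- c(0.63, 0.69)
  expect_equal(scan_rescan_stats(b, a)$change, -scan_rescan_stats(a, b)$change)
  expect_true(is.na(scan_rescan_stats(1.0, 1.1)$sd))
  expect_error(scan_rescan_stats(c(1, 2), 1), "length")
  expect_error(scan_rescan_stats(c(1, -2), c(1, 2)), "positive")
})
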