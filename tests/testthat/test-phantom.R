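test_that("phantom spec validation lists every violation", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  err <- tryCatch(phantom_spec(t1_rows = 40:42, fvf_t1 = 1.4, n_streamlines = 0),
                  error = function(e) conditionMessage(e))
  expect_match(err, "t1_rows outside grid")
  expect_match(err, "FVF/FA values must lie")
  expect_match(err, "n_streamlines")
  expect_error(phantom_spec(t1_rows = 10:12, t2_rows = 12:14), "overlap")
})

test_that("phantom construction matches its ground-truth manifest", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  f <- ph$field
  kc <- fixel_count(f)
  sp <- ph$spec
  # crossing voxels hold exactly two orthogonal fixels
  for (x in c(sp$t3_cols[1], sp$t4_cols[2]))
    for (y in c(sp$t1_rows[1], sp$t2_rows[2])) {
      expect_equal(kc[x, y, 1], 2L)
      o <- matrix(f$orientations[x, y, 1, , ], ncol = 3)
      expect_equal(axial_angle(o[1, ], o[2, ]), 90)
    }
  # single-tract horizontal voxels: one fixel carrying the tract FVF exactly
  solo_cols <- setdiff(seq_len(sp$shape[1]), c(sp$t3_cols, sp$t4_cols))
  for (x in solo_cols[1:3]) {
    expect_equal(kc[x, sp$t1_rows[1], 1], 1L)
    expect_equal(f$metrics$FVF[x, sp$t1_rows[1], 1, 1], 0.70)
    expect_equal(f$metrics$FVF[x, sp$t2_rows[1], 1, 1], 0.66)
  }
  # every T1 voxel's horizontal fixel carries FVF 0.70
  gt <- ph$manifest$ground_truth
  t1 <- gt[gt$tract == "T1", ]
  expect_true(all(t1$fvf == 0.70))
  for (r in sample(nrow(gt), 50)) {
    expect_equal(f$metrics$FVF[gt$i[r], gt$j[r], gt$k[r], gt$fixel[r]],
                 gt$fvf[r])
    expect_equal(f$metrics$FA[gt$i[r], gt$j[r], gt$k[r], gt$fixel[r]],
                 gt$fa[r])
  }
  # CSF voxels carry no fixels
  incol <- seq_len(sp$shape[1]) %in% c(sp$t3_cols, sp$t4_cols)
  inrow <- seq_len(sp$shape[2]) %in% c(sp$t1_rows, sp$t2_rows)
  expect_true(all(kc[!incol, !inrow, 1] == 0L))
  # vertical FVF increases from top to bottom of the grid (rows are stored
  # bottom -> top, so the stored profile decreases); crossing rows hold the
  # vertical fixel in slot 2 and are skipped
  solo_rows <- setdiff(seq_len(sp$shape[2]), c(sp$t1_rows, sp$t2_rows))
  prof <- f$metrics$FVF[sp$t3_cols[1], solo_rows, 1, 1]
  expect_true(all(diff(prof) < 0))
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(phantom_spec(seed = 4, jitter_sd = 2))
  b <- generate_phantom(phantom_spec(seed = 4, jitter_sd = 2))
  expect_identical(a$field, b$field)
  expect_identical(a$tracts, b$tracts)
  c <- generate_phantom(phantom_spec(seed = 5, jitter_sd = 2))
  expect_false(identical(a$field$orientations, c$field$orientations))
  # without randomness-dependent parts... jitter 0: seeds differ only in offsets
  d0 <- generate_phantom(phantom_spec(seed = 4, jitter_sd = 0))
  d1 <- generate_phantom(phantom_spec(seed = 6, jitter_sd = 0))
  expect_identical(d0$field, d1$field)
})

test_that("tract means recover the generating values on the clean phantom", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  for (st in c("ang", "cfo")) {
    fit1 <- unravel(ph$field, ph$tracts$T1, metrics = "FVF", strategy = st)
    m1 <- tract_mean(fit1$maps$FVF, fit1$weight_maps, "tsl")$mean
    expect_lt(abs(m1 - 0.70), 1e-9)
    fit2 <- unravel(ph$field, ph$tracts$T2, metrics = "FVF", strategy = st)
    m2 <- tract_mean(fit2$maps$FVF, fit2$weight_maps, "tsl")$mean
    expect_lt(abs(m2 - 0.66), 1e-9)
  }
  # relative volume weighting is contaminated by the crossing (lower-FVF)
  # vertical tracts: the high-FVF horizontal mean is pulled downward
  fitv <- unravel(ph$field, ph$tracts$T1, metrics = "FVF", strategy = "vol")
  mv <- tract_mean(fitv$maps$FVF, fitv$weight_maps, "roi")$mean
  expect_lt(mv, 0.70)
})

test_that("spurious-fixel corruption biases cfo but not ang on-axis", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  reg <- corruption_region(ph, "T3", 0.5)
  phc <- corrupt_fixels(ph, reg, split_angle_deg = 30,
                        metric_offsets = c(FA = 0.1))
  # corrupted voxels: two fixels at +/-15 degrees, FA split to +/- 0.1
  v <- which(reg, arr.ind = TRUE)[1, ]
  f <- phc$field
  expect_equal(fixel_count(f)[v[1], v[2], v[3]], 2L)
  o <- matrix(f$orientations[v[1], v[2], v[3], , ], ncol = 3)
  true_axis <- c(0, 1, 0)
  expect_equal(axial_angle(o[1, ], true_axis), 15, tolerance = 1e-9)
  expect_equal(axial_angle(o[2, ], true_axis), 15, tolerance = 1e-9)
  fa0 <- ph$field$metrics$FA[v[1], v[2], v[3], 1]
  expect_equal(sort(f$metrics$FA[v[1], v[2], v[3], ]), sort(fa0 + c(-0.1, 0.1)))
  expect_equal(f$fractions[v[1], v[2], v[3], ], c(0.5, 0.5))
  # manifest truth unchanged; corruption recorded
  expect_identical(phc$manifest$ground_truth, ph$manifest$ground_truth)
  expect_equal(phc$manifest$corruption$n_voxels, sum(reg))
  # on-axis segment: cfo tie-breaks to the +delta fixel, ang splits evenly
  vf <- voxel_fixels_of(f, v[1], v[2], v[3])
  a_cfo <- alpha_cfo(true_axis, vf$orientations)
  a_ang <- alpha_ang(true_axis, vf$orientations)
  mets <- f$metrics$FA[v[1], v[2], v[3], vf$slots]
  expect_equal(segment_metric(a_cfo, mets), fa0 + 0.1)
  expect_equal(segment_metric(a_ang, mets), fa0)
  # zero offset: symmetric split leaves the on-axis ang metric unchanged
  ph0 <- corrupt_fixels(ph, reg, 30, c(FA = 0))
  vf0 <- voxel_fixels_of(ph0$field, v[1], v[2], v[3])
  expect_equal(segment_metric(alpha_ang(true_axis, vf0$orientations),
                              ph0$field$metrics$FA[v[1], v[2], v[3], vf0$slots]),
               fa0)
  # degenerate regions are refused
  empty <- array(FALSE, dim = ph$field$shape); empty[1, 1, 1] <- TRUE
  expect_error(corrupt_fixels(ph, empty), "no fixels")
})

test_that("profile errors of ang stay at or below cfo under corruption", {
  for (seed in c(21, 22, 23)) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    reg <- corruption_region(ph, "T3", 0.5)
    phc <- corrupt_fixels(ph, reg, 30, c(FA = 0.1))
    errs <- sapply(c("ang", "cfo"), function(st) {
      e <- numeric(0)
      for (ix in 1:5) {
        pr <- streamline_profile(phc$tracts$T3, phc$field, st, "FA", index = ix)
        tru <- streamline_profile(ph$tracts$T3, ph$field, st, "FA", index = ix)
        inreg <- reg[cbind(pr$i, pr$j, pr$k)]
        e <- c(e, abs(pr$metric[inreg] - tru$metric[inreg]))
      }
      mean(e)
    })
    expect_lte(errs[["ang"]], errs[["cfo"]])
  }
})
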