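test_that("figures of merit match hand arithmetic", {
  expect_equal(crc_hot(4, 1, 4), 100)
  expect_equal(crc_hot(1, 1, 4), 0)
  expect_error(crc_hot(2, 1, 1), "undefined")
  expect_equal(crc_cold(0, 1), 100)
  expect_equal(crc_cold(0.5, 1), 50)
  expect_equal(background_variability(c(9, 11)), 100 * sqrt(2) / 10)
  expect_equal(background_variability(rep(3, 10)), 0)
  expect_error(background_variability(5), "at least 2")
  expect_equal(cnr(4, 1, 0.5, 0.5), 3 / sqrt(0.5))
  expect_equal(cnr(2, 2, 0.3, 0.4), 0)
  expect_lt(cnr(1, 4, 0.5, 0.5), 0)   # cold contrast gives negative CNR
  expect_error(cnr(4, 1, 0, 0), "undefined")
  # BV is invariant under global scaling
  m <- c(8, 10, 11, 12)
  expect_equal(background_variability(7 * m), background_variability(m))
})

test_that("ROI placement follows the phantom layout", {
  ph <- nema_iq_phantom()
  g <- voxel_grid(256, 256, 1, c(1, 1, 1))
  rois <- place_rois(ph, g)
  expect_length(rois$rois, 6)
  r1 <- rois$rois[[1]]   # 10 mm sphere on a 1 mm grid
  ix <- (r1$roi - 1) %% 256
  expect_equal(diff(range(ix)) + 1, 10)  # ROI spans 10 voxels across
  for (r in rois$rois) expect_length(r$background, 60)
  # background ROIs never overlap a sphere or its wall
  maps <- rasterize_phantom(ph, g)
  info <- attr(ph, "nema")
  ax <- grid_axes(g)
  for (r in rois$rois) for (b in r$background) {
    cc <- tofmix:::voxel_center_from_index(g, b)
    for (k in 1:6) {
      d <- sqrt((cc[, 1] - info$spheres$x[k])^2 +
                  (cc[, 2] - info$spheres$y[k])^2)
      expect_true(all(d > info$spheres$diameter_mm[k] / 2 + info$wall_mm - 1))
    }
    # and keep 15 mm clearance from the body edge
    expect_true(all(sqrt(cc[, 1]^2 + cc[, 2]^2) <=
                      info$body_radius_mm - 15 + 1e-9))
  }
  # placement is deterministic
  rois2 <- place_rois(ph, g)
  expect_identical(rois$rois[[3]]$background, rois2$rois[[3]]$background)
  # too-coarse grids are rejected
  expect_error(place_rois(ph, voxel_grid(32, 32, 1, c(8, 8, 8))), "coarse")
})

test_that("ROI means equal brute-force voxel loops and truth gives CRC 100", {
  ph <- nema_iq_phantom()
  g <- desk_grid()
  rois <- place_rois(ph, g)
  truth <- rasterize_phantom(ph, g)$activity
  for (r in rois$rois[c(1, 5)]) {
    expect_equal(mean(truth[r$roi]), brute_roi_mean(truth, r$roi))
    expect_equal(mean(truth[r$background[[7]]]),
                 brute_roi_mean(truth, r$background[[7]]))
  }
  m <- sphere_metrics(truth, rois)
  expect_equal(m$crc_pct, rep(100, 6))
  expect_equal(m$bv_pct, rep(0, 6))
  expect_true(all(is.na(m$cnr)))   # undefined at zero SD
  # all metrics except bias are scale-invariant
  m7 <- sphere_metrics(7 * truth + 0 * truth, rois)
  expect_equal(m7$crc_pct, m$crc_pct)
  expect_equal(m7$bv_pct, m$bv_pct)
})

test_that("bias analysis measures known offsets across realizations", {
  ph <- nema_iq_phantom()
  g <- desk_grid()
  rois <- place_rois(ph, g)
  truth <- rasterize_phantom(ph, g)$activity
  expect_error(bias_analysis(list(truth), rois), "at least 2")
  b0 <- bias_analysis(list(truth * 1.1, truth * 0.9), rois)
  expect_equal(b0$bias_pct[b0$hot], rep(0, 4), tolerance = 1e-10)
  expect_true(all(b0$se_kBq_cc[b0$hot] > 0))
  b1 <- bias_analysis(list(truth * 1.1, truth * 1.1), rois)
  expect_equal(b1$bias_pct[b1$hot], rep(10, 4))
  expect_equal(b1$se_kBq_cc, rep(0, 6))
})

test_that("metrics tables cover the requested models and iterations", {
  ph <- nema_iq_phantom()
  g <- desk_grid()
  rois <- place_rois(ph, g)
  truth <- rasterize_phantom(ph, g)$activity
  fake <- list(images = list("1" = truth, "5" = truth * 2),
               image = truth * 2)
  out <- metrics_over_iterations(list(truth = fake, other = fake), rois)
  expect_equal(sort(unique(out$iteration)), c(1, 5))
  expect_equal(sort(unique(out$model)), c("other", "truth"))
  expect_equal(nrow(out), 2 * 2 * 6)
  expect_equal(out$crc_pct, rep(100, 24))
  bad <- list(images = list("1" = array(0, c(2, 2, 1))))
  expect_error(metrics_over_iterations(list(x = bad), rois), "grid")
})
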