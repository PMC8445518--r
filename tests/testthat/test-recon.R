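test_that("Siddon traversal matches closed forms and a dense-sampling oracle", {
  g3 <- voxel_grid(3, 3, 1, c(1, 1, 1))
  # axis-aligned ray through the middle row
  p <- siddon_path(g3, c(-2, 0, 0), c(2, 0, 0))
  expect_equal(nrow(p), 3)
  expect_equal(p$length_mm, rep(1, 3))
  expect_true(all(p$iy == 1))
  # diagonal of a single voxel
  g1 <- voxel_grid(1, 1, 1, c(1, 1, 1))
  d <- siddon_path(g1, c(-0.5, -0.5, -0.5), c(0.5, 0.5, 0.5))
  expect_equal(nrow(d), 1)
  expect_equal(d$length_mm, sqrt(3))
  expect_error(siddon_path(g1, c(1, 1, 1), c(1, 1, 1)), "degenerate")

  # random rays on a 16^3 grid against dense sampling
  g16 <- voxel_grid(16, 16, 16, c(1, 1, 1))
  set.seed(71)
  for (i in 1:25) {
    ang <- runif(2, 0, 2 * pi)
    p1 <- 20 * c(cos(ang[1]), sin(ang[1]), runif(1, -0.4, 0.4))
    p2 <- 20 * c(cos(ang[2]), sin(ang[2]), runif(1, -0.4, 0.4))
    sp <- siddon_path(g16, p1, p2)
    chord <- sum(sp$length_mm)
    dense <- dense_ray_lengths(g16, p1, p2, n = 2e4)
    common <- intersect(names(dense), as.character(sp$voxel))
    ref <- setNames(sp$length_mm, as.character(sp$voxel))
    if (length(common) > 0) {
      err <- abs(dense[common] - ref[common])
      expect_lt(max(err / pmax(ref[common], 0.05)), 0.02)
    }
    # lengths sum exactly to the in-grid chord
    if (nrow(sp) > 0) {
      clip <- sum(dense)
      expect_equal(chord, clip, tolerance = 1e-3)
    }
  }
})

test_that("TOF projections follow the sign convention", {
  p1 <- c(-424, 0, 0); p2 <- c(424, 0, 0)
  expect_equal(tof_projection(c(0, 0, 0), p1, p2), 0)
  expect_equal(tof_projection(c(30, 0, 0), p1, p2), 2 * 30 / c_mm_per_ps())
  expect_equal(tof_projection(c(-30, 5, 0), p1, p2),
               -tof_projection(c(30, 5, 0), p1, p2))
  g <- voxel_grid(4, 1, 1, c(10, 10, 10))
  # voxel centers at x = -15, -5, 5, 15
  expect_equal(voxel_tof_projection(g, 1:4, p1, p2),
               2 * c(-15, -5, 5, 15) / c_mm_per_ps())
})

test_that("TOF weights telescope to 1 and match limiting cases", {
  bank <- default_kernel_bank()
  mix <- recon_model("mixture", bank = bank)
  ev <- list(delta_t_ps = 137.4, kernel_id = 13L, component = 1L)
  v <- c(-300, 0, 137.4, 800)
  # sum over bins covering the kernel support telescopes to 1
  k0 <- seq(-4000, 4000 - 1, by = 1) + floor(137.4)
  for (vi in v) {
    expect_equal(sum(tof_weight(mix, ev, vi, bin_ps = 1, bin_start = k0)), 1,
                 tolerance = 1e-12)
  }
  # degenerate mixture (alpha = 1) equals the fast-only Gaussian weight
  kb <- kernel_bank(list(timing_kernel(1, 213, 600, 1)))
  mix1 <- recon_model("mixture", bank = kb)
  gau <- recon_model("gaussian", gaussian_fwhm_ps = 213)
  ev1 <- list(delta_t_ps = -42.2, kernel_id = 1L, component = 1L)
  expect_equal(tof_weight(mix1, ev1, v), tof_weight(gau, ev1, v))
  # at 1 ps bins the weight approximates pdf * bin width at the event dt
  k13 <- bank$kernels[[13]]
  w0 <- tof_weight(mix, ev, v_ps = 137.4)
  expect_equal(w0, mixture_pdf(k13, 0) * 1, tolerance = 1e-3)
  # non-TOF weights are identically one
  expect_equal(tof_weight(recon_model("none"), ev, v), rep(1, 4))
})

test_that("sensitivity image matches an exhaustive pair loop", {
  s <- tiny_scanner(n_crystals = 32, radius = 60, min_sector = 4)
  g <- voxel_grid(8, 8, 1, c(10, 10, 4))
  sens <- sensitivity_image(s, g)
  # brute force: loop over all admissible pairs with siddon_path
  ref <- array(0, c(8, 8, 1))
  cc <- crystal_center(s, 0, 0:31)
  for (i in 1:31) for (j in (i + 1):32) {
    dc <- min(abs(i - j), 32 - abs(i - j))
    if (dc < 4) next
    sp <- siddon_path(g, cc[i, ], cc[j, ])
    for (r in seq_len(nrow(sp)))
      ref[sp$ix[r] + 1, sp$iy[r] + 1, 1] <-
        ref[sp$ix[r] + 1, sp$iy[r] + 1, 1] + sp$length_mm[r]
  }
  expect_equal(sens, ref, tolerance = 1e-12)
  # the grid sits fully inside the ring: strictly positive everywhere
  expect_gt(min(sens), 0)
})

test_that("voxels outside the ring get zero sensitivity and stay zero", {
  s <- tiny_scanner(n_crystals = 32, radius = 40, min_sector = 4)
  g <- voxel_grid(12, 12, 1, c(10, 10, 4))  # corners outside the ring
  sens <- sensitivity_image(s, g)
  expect_equal(sens[1, 1, 1], 0)
  expect_gt(sens[6, 6, 1], 0)
  ph <- phantom_spec(list(region_cylinder(c(0, 0, 0), 30, 2, 50)))
  cfg <- acquisition_config(ph, s, g, duration_s = 0.005,
                            timing_model = "none", seed = 77)
  lm <- simulate_acquisition(cfg)
  res <- lm_mlem(lm, recon_config(g, 3, recon_model("none")),
                 sensitivity = sens)
  expect_equal(res$image[1, 1, 1], 0)
  expect_true(all(res$image >= 0))
})

test_that("MLEM reproduces a hand-computed two-voxel fixed point", {
  s <- tiny_scanner(n_crystals = 8, radius = 30, min_sector = 2)
  g <- voxel_grid(2, 1, 1, c(10, 10, 10))
  sens <- sensitivity_image(s, g)
  ph <- phantom_spec(list(region_sphere(c(-5, 0, 0), 4, 200)))
  cfg <- acquisition_config(ph, s, g, duration_s = 0.01,
                            timing_model = "none", seed = 78)
  lm <- simulate_acquisition(cfg)
  res <- lm_mlem(lm, recon_config(g, 4, recon_model("none"),
                                  save_iterations = 1:4),
                 sensitivity = sens)
  # independent R implementation of the multiplicative update
  rows <- lapply(seq_len(nrow(lm$events)), function(i) {
    ca <- crystal_center(s, lm$events$ring_a[i], lm$events$crystal_a[i])
    cb <- crystal_center(s, lm$events$ring_b[i], lm$events$crystal_b[i])
    sp <- siddon_path(g, ca[1, ], cb[1, ])
    setNames(sp$length_mm, sp$voxel)
  })
  lam <- ifelse(as.numeric(sens) > 0, 1, 0)
  for (it in 1:4) {
    num <- numeric(2)
    for (w in rows) {
      j <- as.integer(names(w))
      y <- sum(w * lam[j])
      if (y > 0) num[j] <- num[j] + w / y
    }
    lam <- ifelse(as.numeric(sens) > 0, lam / as.numeric(sens) * num, 0)
    expect_equal(as.numeric(res$images[[as.character(it)]]), lam,
                 tolerance = 1e-5)
  }
})

test_that("MLEM conserves counts, increases the likelihood, and localizes", {
  s <- desk_scanner(); g <- voxel_grid(64, 64, 1, c(4, 4, 4))
  ph <- point_source_phantom(position = c(30, 10, 0), radius_mm = 3)
  cfg <- acquisition_config(ph, s, g, duration_s = 0.3,
                            timing_model = "single_gaussian",
                            gaussian_fwhm_ps = 213, seed = 79)
  lm <- simulate_acquisition(cfg)
  sens <- sensitivity_image(s, g)
  res <- lm_mlem(lm, recon_config(g, 10, recon_model("gaussian")),
                 sensitivity = sens)
  expect_true(all(abs(res$conservation - res$events_used) /
                    res$events_used < 1e-6))
  expect_true(all(diff(res$loglik) > -1e-4))
  # peak within one voxel of the true position
  pk <- which(res$image == max(res$image), arr.ind = TRUE)[1, ]
  ax <- grid_axes(g)
  expect_lt(abs(ax$x[pk[1]] - 30), 4 + 1e-9)
  expect_lt(abs(ax$y[pk[2]] - 10), 4 + 1e-9)

  # narrower kernels concentrate the point source faster (early iterations
  # expose the kernel footprint directly)
  spread <- function(fwhm) {
    r <- lm_mlem(lm, recon_config(g, 2, recon_model("gaussian",
                                                    gaussian_fwhm_ps = fwhm)),
                 sensitivity = sens)
    img <- r$image / sum(r$image)
    xx <- outer(ax$x - 30, rep(1, 64)); yy <- outer(rep(1, 64), ax$y - 10)
    sum(img[, , 1] * (xx^2 + yy^2))
  }
  expect_lt(spread(100), spread(600))
})

test_that("calibration scales to the reference concentration", {
  img <- array(c(2, 4, 6, 8), c(2, 2, 1))
  mask <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  out <- calibrate(img, mask, 3)
  expect_equal(attr(out, "calibration_scale"), 1)
  out2 <- calibrate(img * 2, mask, 3)
  expect_equal(attr(out2, "calibration_scale"), 0.5)
  expect_equal(mean(out2[mask]), 3)
  expect_error(calibrate(img * 0, mask, 3), "calibration failed")
})

test_that("decomposed reconstruction needs component flags", {
  s <- desk_scanner(); g <- desk_grid()
  cfg <- acquisition_config(nema_iq_phantom(), s, g, duration_s = 0.002,
                            timing_model = "single_gaussian", seed = 80)
  lm <- simulate_acquisition(cfg)
  expect_error(lm_mlem(lm, recon_config(g, 1, recon_model("decomposed"))),
               "component|kernel ids")
})
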