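test_that("emission sampling follows the activity image", {
  g <- voxel_grid(16, 16, 1, c(2, 2, 2))
  act <- array(0, c(16, 16, 1))
  act[4, 7, 1] <- 10   # single hot voxel
  set.seed(1)
  pts <- sample_emissions(act, g, duration_s = 1)
  # rate = 10 kBq/cc * 8 mm^3 = 80 decays/s
  expect_gt(nrow(pts), 80 - 4 * sqrt(80))
  expect_lt(nrow(pts), 80 + 4 * sqrt(80))
  cen <- tofmix:::voxel_center_from_index(g, which(act > 0))
  expect_true(all(abs(pts[, 1] - cen[1]) <= 1))
  expect_true(all(abs(pts[, 2] - cen[2]) <= 1))

  # Poisson mean over repeated draws
  ns <- vapply(1:30, function(s) {
    set.seed(100 + s); nrow(sample_emissions(act, g, 1))
  }, numeric(1))
  expect_lt(abs(mean(ns) - 80), 4 * sqrt(80 / 30))

  # determinism and empty input
  set.seed(9); a <- sample_emissions(act, g, 1)
  set.seed(9); b <- sample_emissions(act, g, 1)
  expect_identical(a, b)
  expect_equal(nrow(sample_emissions(array(0, c(16, 16, 1)), g, 1)), 0)
})

test_that("photon transport respects geometry, sign convention and sectors", {
  s <- tiny_scanner(n_crystals = 360, radius = 424, min_sector = 45)
  # point at the isocenter: exact zero time difference
  pts <- matrix(0, 500, 3)
  set.seed(2)
  det <- emit_and_detect(pts, s)
  expect_gt(nrow(det), 0)
  expect_true(all(det$geometric_dt_ps == 0))
  # canonical ordering and sector rule
  fa <- det$ring_a * 360 + det$crystal_a
  fb <- det$ring_b * 360 + det$crystal_b
  expect_true(all(fa < fb))
  dc <- abs(det$crystal_a - det$crystal_b)
  expect_true(all(pmin(dc, 360 - dc) >= 45))

  # 30 mm displacement along a transaxial LOR: |dt| = 2*30/c = 200.14 ps,
  # negative because the displacement is toward crystal 0 = detector a
  set.seed(3)
  det2 <- emit_and_detect(matrix(rep(c(30, 0, 0), each = 4000), ncol = 3), s)
  axial <- det2[det2$crystal_a == 0 & det2$crystal_b == 180, ]
  expect_gt(nrow(axial), 0)
  expect_equal(axial$geometric_dt_ps,
               rep(-2 * 30 / c_mm_per_ps(), nrow(axial)), tolerance = 1e-2)

  # dt matches the closed form from crystal-center distances, and the LOR
  # through the crystal centers passes near the emission point
  p <- c(40, -25, 0)
  set.seed(4)
  det3 <- emit_and_detect(matrix(rep(p, each = 2000), ncol = 3), s)
  ca <- crystal_center(s, det3$ring_a, det3$crystal_a)
  cb <- crystal_center(s, det3$ring_b, det3$crystal_b)
  da <- sqrt(rowSums((ca - rep(p, each = nrow(ca)))^2))
  db <- sqrt(rowSums((cb - rep(p, each = nrow(cb)))^2))
  # detection position and crystal-bin center differ by at most half the
  # angular pitch (3.7 mm), i.e. ~25 ps on the time difference
  expect_lt(max(abs(det3$geometric_dt_ps - (da - db) / c_mm_per_ps())), 30)
  u <- (cb - ca) / sqrt(rowSums((cb - ca)^2))
  ap <- rep(p, each = nrow(ca)) - ca
  perp <- sqrt(rowSums(ap^2) - rowSums(ap * u)^2)
  expect_true(all(perp <= 2 * pi * 424 / 360))  # within one angular pitch
})

test_that("2D acceptance matches an exhaustive angle sweep", {
  # off-center point with a tight sector cut, so acceptance is fractional
  s <- tiny_scanner(n_crystals = 32, radius = 60, min_sector = 14)
  p <- c(40, 5, 0)
  # oracle: sweep emission angles densely and apply the same binning rules
  phi <- seq(0, pi, length.out = 20001)[-20001]
  hit_crystal <- function(px, py, ux, uy) {
    b <- px * ux + py * uy
    disc <- b^2 - (px^2 + py^2 - 60^2)
    t <- -b + sqrt(disc)
    ang <- atan2(py + t * uy, px + t * ux)
    (round(ang / (2 * pi / 32)) %% 32)
  }
  c1 <- hit_crystal(p[1], p[2], cos(phi), sin(phi))
  c2 <- hit_crystal(p[1], p[2], -cos(phi), -sin(phi))
  dc <- pmin(abs(c1 - c2), 32 - abs(c1 - c2))
  acc_oracle <- mean(dc >= 14 & c1 != c2)
  expect_lt(acc_oracle, 1)   # the sweep must actually exercise the cut

  set.seed(5)
  n <- 2e4
  det <- emit_and_detect(matrix(rep(p, each = n), ncol = 3), s)
  acc <- nrow(det) / n
  expect_lt(abs(acc - acc_oracle),
            3 * sqrt(max(acc_oracle * (1 - acc_oracle), 0.01) / n))
})

test_that("timing spreads are applied per pair as configured", {
  bank <- default_kernel_bank()
  z <- rep(0, 2e5)
  expect_identical(apply_timing_spread(z, "none")$delta_t_ps, z)

  set.seed(6)
  sp <- apply_timing_spread(z, "mixture_bank", bank)
  # kernel categories drawn uniformly over the 25 rows
  expect_gt(chisq.test(table(factor(sp$kernel_id, levels = 1:25)))$p.value,
            0.001)
  # pooled residuals of one category follow that kernel's mixture
  k13 <- bank$kernels[[13]]
  x13 <- sp$delta_t_ps[sp$kernel_id == 13]
  d <- max(abs(ecdf(x13)(x13) - mixture_cdf(k13, x13)))
  expect_lt(d, 2 / sqrt(length(x13)))
  # component flags follow the abundance ratio
  a13 <- mean(sp$component[sp$kernel_id == 13] == 1)
  expect_lt(abs(a13 - k13$alpha_fast), 4 * sqrt(0.43 * 0.57 / length(x13)))

  set.seed(7)
  sm <- apply_timing_spread(z, "single_mixture", bank)
  expect_true(all(sm$kernel_id == 1L))

  set.seed(8)
  sg <- apply_timing_spread(z, "single_gaussian", gaussian_fwhm_ps = 213)
  expect_true(all(sg$kernel_id == 0L & sg$component == 0L))
  expect_equal(fit_zero_mean_gaussian(sg$delta_t_ps)$fwhm_ps, 213,
               tolerance = 1)
})

test_that("acquisitions are reproducible, and scale with duration", {
  s <- desk_scanner(); g <- desk_grid(); ph <- nema_iq_phantom()
  cfg <- acquisition_config(ph, s, g, duration_s = 0.01,
                            timing_model = "mixture_bank", seed = 12)
  lm1 <- simulate_acquisition(cfg)
  lm2 <- simulate_acquisition(cfg)
  expect_identical(lm1$events, lm2$events)
  expect_gt(nrow(lm1$events), 1000)

  cfg2 <- acquisition_config(ph, s, g, duration_s = 0.02,
                             timing_model = "mixture_bank", seed = 13)
  lm3 <- simulate_acquisition(cfg2)
  r <- nrow(lm3$events) / nrow(lm1$events)
  expect_lt(abs(r - 2), 3 * 2 * sqrt(1 / nrow(lm1$events) + 1 / nrow(lm3$events)))

  # point source at the isocenter: measured dt centered at zero
  cfgp <- acquisition_config(point_source_phantom(), s, g, duration_s = 0.5,
                             timing_model = "single_mixture", seed = 14)
  lmp <- simulate_acquisition(cfgp)
  expect_gt(nrow(lmp$events), 5000)
  se <- sd(lmp$events$delta_t_ps) / sqrt(nrow(lmp$events))
  expect_lt(abs(mean(lmp$events$delta_t_ps)), 3 * se)

  # empty phantom
  empty <- phantom_spec(list())
  expect_warning(
    lme <- simulate_acquisition(acquisition_config(empty, s, g, 1, "none")),
    "zero accepted")
  expect_equal(nrow(lme$events), 0)
})

test_that("list-mode files round-trip and thinning matches counts", {
  s <- desk_scanner(); g <- desk_grid()
  cfg <- acquisition_config(nema_iq_phantom(), s, g, duration_s = 0.005,
                            timing_model = "mixture_bank", seed = 15)
  lm <- simulate_acquisition(cfg)
  path <- tempfile(fileext = ".lm")
  write_listmode(lm, path)
  back <- read_listmode(path)
  expect_equal(back$events, lm$events)
  expect_equal(back$scanner, lm$scanner)
  expect_equal(back$header$config_hash, lm$header$config_hash)
  # identical seeds give byte-identical files
  path2 <- tempfile(fileext = ".lm")
  write_listmode(simulate_acquisition(cfg), path2)
  expect_identical(readLines(path), readLines(path2))

  set.seed(16)
  thin <- thin_listmode(lm, 100)
  expect_equal(nrow(thin$events), 100)
  expect_true(all(thin$events$delta_t_ps %in% lm$events$delta_t_ps))
  expect_error(thin_listmode(lm, nrow(lm$events) + 1))
})
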