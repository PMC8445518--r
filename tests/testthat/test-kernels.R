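test_that("packaged kernel bank matches the measured timing categories", {
  bank <- default_kernel_bank()
  expect_length(bank$kernels, 25)
  k1 <- bank$kernels[[1]]
  expect_equal(k1$fwhm_fast_ps, 179.8)
  expect_equal(k1$fwhm_slow_ps, 660.3)
  expect_equal(k1$alpha_fast, 0.594)
  k25 <- bank$kernels[[25]]
  expect_equal(k25$fwhm_fast_ps, 263.8)
  expect_equal(k25$fwhm_slow_ps, 897.3)
  expect_equal(k25$alpha_fast, 0.419)
  expect_equal(sum(bank$category_probs), 1)
  expect_true(all(abs(bank$category_probs - 1 / 25) < 1e-15))
  tab <- as.data.frame(bank)
  expect_true(all(tab$fwhm_fast_ps <= tab$fwhm_slow_ps))
})

test_that("kernel bank files accept comma dialect and flag malformed rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("kernel_id,fwhm_fast_ps,fwhm_slow_ps,alpha_fast",
               "1,100,300,0.5", "2,120,280,0.4"), path)
  bank <- read_kernel_bank(path)
  expect_length(bank$kernels, 2)
  expect_equal(bank$kernels[[2]]$fwhm_fast_ps, 120)

  writeLines(c("kernel_id,fwhm_fast_ps,fwhm_slow_ps,alpha_fast",
               "1,100,300,0.5", "2,oops,280,0.4"), path)
  expect_error(read_kernel_bank(path), "row 2")
})

test_that("kernel invariants are enforced", {
  expect_error(timing_kernel(1, -5, 300, 0.5))
  expect_error(timing_kernel(1, 100, 300, 1.2))
  expect_warning(timing_kernel(0, 400, 300, 0.5), "wider")
  k <- timing_kernel(1, 100, 300, 0.5)
  expect_equal(k$sigma_fast_ps, 100 / (2 * sqrt(2 * log(2))))
  expect_error(kernel_bank(list(k), category_probs = c(0.9)), "sum to 1")
})

test_that("mixture pdf integrates to one, is symmetric, and matches the cdf", {
  bank <- default_kernel_bank()
  for (k in bank$kernels[c(1, 13, 25)]) {
    expect_equal(integrate(function(t) mixture_pdf(k, t), -Inf, Inf,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-9)
    t <- c(13.7, 150, 420)
    expect_equal(mixture_pdf(k, t), mixture_pdf(k, -t))
    expect_equal(mixture_cdf(k, 0), 0.5)
    expect_equal(mixture_cdf(k, 1e5), 1)
    expect_equal(mixture_cdf(k, -1e5), 0)
    expect_equal(mixture_cdf(k, -t), 1 - mixture_cdf(k, t))
    # finite differences of the cdf reproduce the density
    h <- 1e-4
    expect_equal((mixture_cdf(k, t + h) - mixture_cdf(k, t - h)) / (2 * h),
                 mixture_pdf(k, t), tolerance = 1e-6)
    # monotone nondecreasing
    tg <- seq(-2000, 2000, by = 5)
    expect_true(all(diff(mixture_cdf(k, tg)) >= 0))
  }
  # degenerate mixture collapses to the fast Gaussian
  k <- timing_kernel(0, 200, 600, 1)
  t <- seq(-500, 500, by = 50)
  expect_equal(mixture_pdf(k, t), dnorm(t, 0, fwhm_to_sigma(200)))
})

test_that("mixture_fwhm matches components and a dense grid scan", {
  expect_equal(mixture_fwhm(timing_kernel(0, 179.8, 660.3, 1)), 179.8,
               tolerance = 1e-6)
  k0 <- suppressWarnings(timing_kernel(0, 200, 200, 0.3))
  expect_equal(mixture_fwhm(k0), 200, tolerance = 1e-6)
  k13 <- default_kernel_bank()$kernels[[13]]
  # grid-scan oracle at 0.01 ps resolution
  tg <- seq(0, 2 * k13$fwhm_slow_ps, by = 0.01)
  half <- mixture_pdf(k13, 0) / 2
  scan <- 2 * tg[which(mixture_pdf(k13, tg) < half)[1]]
  expect_equal(mixture_fwhm(k13), scan, tolerance = 0.02)
})

test_that("sampling follows the abundance ratio and the mixture distribution", {
  bank <- default_kernel_bank()
  k1 <- bank$kernels[[1]]
  expect_error(sample_delta_t(k1, 0), "n must be")

  set.seed(11)
  s <- sample_delta_t(k1, 2e5)
  p <- mean(s$component == 1)
  expect_lt(abs(p - 0.594), 3 * sqrt(0.594 * 0.406 / 2e5))

  # same seed reproduces the sequence
  set.seed(42); a <- sample_delta_t(k1, 1000)
  set.seed(42); b <- sample_delta_t(k1, 1000)
  expect_identical(a, b)

  # degenerate kernel: empirical FWHM equals the component FWHM
  kd <- suppressWarnings(timing_kernel(0, 250, 250, 0.6))
  set.seed(5)
  x <- sample_delta_t(kd, 2e5)$delta_t_ps
  expect_equal(sigma_to_fwhm(sd(x)), 250, tolerance = 2)

  # Kolmogorov-Smirnov distance against the analytic mixture cdf
  set.seed(7)
  k13 <- bank$kernels[[13]]
  x <- sample_delta_t(k13, 1e5)$delta_t_ps
  d <- max(abs(ecdf(x)(x) - mixture_cdf(k13, x)))
  expect_lt(d, 2 / sqrt(1e5))
})
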