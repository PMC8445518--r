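#' Kernel-fidelity study
#'
#' Reproduces the simulation-accuracy validation: a point source at the
#' isocenter is simulated with a single mixture kernel to produce a time
#' difference histogram (linear and log views are just two renderings of
#' the same counts), and every kernel of the bank is sampled and refit to
#' tabulate the per-kernel sigma errors.  At 1e6 events per kernel the
#' maximum absolute sigma error stays within about 2 ps.
#'
#' @param n_per_kernel samples per kernel for the fidelity table.
#' @param seed integer seed.
#' @param bank a [kernel_bank()].
#' @param histogram_kernel which kernel's point-source histogram to return
#'   (default 13).
#' @param n_histogram events in the point-source histogram.
#' @param binwidth_ps histogram bin width, ps.
#' @return list with `fidelity` (the [validate_bank_fidelity()] table),
#'   `max_sigma_error_ps`, and `histogram` (data.frame `t_ps`, `count` of
#'   the point-source time differences, centered at 0).
#' @export
run_kernel_fidelity_study <- function(n_per_kernel = 1e6, seed = 1,
                                      bank = default_kernel_bank(),
                                      histogram_kernel = 13,
                                      n_histogram = 1e5, binwidth_ps = 10) {
  set.seed(seed)
  # point source at the isocenter: the geometric time difference is zero,
  # so the measured differences are draws from the kernel itself
  scanner <- ring_scanner()
  grid <- voxel_grid(64, 64, 1, c(2, 2, 2))
  one_bank <- kernel_bank(bank$kernels[histogram_kernel])
  cfg <- acquisition_config(point_source_phantom(), scanner, grid,
                            duration_s = n_histogram / 30000,
                            timing_model = "single_mixture", bank = one_bank)
  lm <- simulate_acquisition(cfg)
  dt <- lm$events$delta_t_ps
  edges <- seq(floor(min(dt) / binwidth_ps) * binwidth_ps,
               ceiling(max(dt) / binwidth_ps) * binwidth_ps, by = binwidth_ps)
  h <- graphics::hist(dt, breaks = edges, plot = FALSE)
  fid <- validate_bank_fidelity(bank, n_per_kernel)
  list(fidelity = fid,
       max_sigma_error_ps = max(fid$err_sigma_fast_ps, fid$err_sigma_slow_ps),
       histogram = data.frame(t_ps = h$mids, count = h$counts),
       n_histogram_events = length(dt),
       seed = seed)
}

#' Study configuration for the NEMA comparison
#'
#' The simulation/reconstruction matrix compared by [run_nema_study()]:
#' * `mch` - multi-kernel mixture data reconstructed with the same 25
#'   mixture kernels;
#' * `ch-mix` and `ch-dcmp` - single-mixture data (bank kernel 1)
#'   reconstructed with the mixture kernel and with the exact decomposed
#'   component, from the *same* simulated dataset;
#' * `gauss` - single-Gaussian (213 ps, LYSO-like) data reconstructed with
#'   the matching Gaussian kernel, thinned to `1/sensitivity_ratio` of the
#'   mixture dataset's count to emulate the lower stopping power;
#' * `notof` - the mixture dataset reconstructed without TOF;
#' * `mch-low` - the mixture dataset thinned to the `gauss` count
#'   (count-matched comparison).
#'
#' @param scanner,grid,phantom study geometry (desk-scale defaults).
#' @param duration_s acquisition time per realization, s.
#' @param n_realizations independent noise realizations.
#' @param n_iterations MLEM iterations.
#' @param marker_iterations iterations at which metrics are tabulated.
#' @param sensitivity_ratio trues-count ratio between the mixture-model and
#'   single-Gaussian scanners (default 1.52, the ratio of a BGO to an LYSO
#'   system of this geometry).
#' @param models subset of the model labels above to run.
#' @param seed base seed; realization r uses `seed + r - 1`.
#' @return object of class `study_config`.
#' @export
study_config <- function(scanner = ring_scanner(),
                         grid = voxel_grid(128, 128, 1, c(2, 2, 2)),
                         phantom = nema_iq_phantom(),
                         duration_s = 0.25, n_realizations = 3,
                         n_iterations = 40,
                         marker_iterations = c(1, 2, 3, 4, 5, 10, 20, 40),
                         sensitivity_ratio = 1.52,
                         models = c("mch", "ch-mix", "ch-dcmp", "gauss",
                                    "notof", "mch-low"),
                         seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(scanner = scanner, grid = grid, phantom = phantom,
                 duration_s = duration_s, n_realizations = n_realizations,
                 n_iterations = n_iterations,
                 marker_iterations = marker_iterations,
                 sensitivity_ratio = sensitivity_ratio,
                 models = models, seed = seed),
            class = "study_config")
}

#' Run the NEMA image-quality study
#'
#' Simulates `n_realizations` noise realizations of the NEMA phantom for
#' each timing model of the study matrix (see [study_config()]),
#' reconstructs every model pair, calibrates each image series by the
#' background mean of its final iteration, and tabulates the contrast
#' recovery, background variability and contrast-to-noise metrics at the
#' marker iterations, plus the half-diameter bias across realizations at
#' the final iteration.
#'
#' @param config a [study_config()].
#' @param bank a [kernel_bank()].
#' @param verbose print progress.
#' @return list with `metrics` (per realization/model/iteration/sphere),
#'   `summary` (mean and SE over realizations), `bias` (per model),
#'   `counts` (events per model and realization), and the `config`.
#' @export
run_nema_study <- function(config = study_config(),
                           bank = default_kernel_bank(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  rois <- place_rois(config$phantom, config$grid)
  cal_mask <- nema_background_mask(config$phantom, config$grid)
  bg <- attr(config$phantom, "nema")$background_kBq_cc
  sens <- sensitivity_image(config$scanner, config$grid)
  save_iters <- sort(unique(c(config$marker_iterations, config$n_iterations)))

  sim <- function(timing_model, seed)
    simulate_acquisition(acquisition_config(
      config$phantom, config$scanner, config$grid,
      duration_s = config$duration_s, timing_model = timing_model,
      bank = bank, gaussian_fwhm_ps = 213, seed = seed))
  rc <- function(mode, fwhm = 213)
    recon_config(config$grid, config$n_iterations,
                 recon_model(mode, bank = bank, gaussian_fwhm_ps = fwhm),
                 save_iterations = save_iters)

  metrics <- list()
  counts <- list()
  final_images <- list()

  for (r in seq_len(config$n_realizations)) {
    seed_r <- config$seed + (r - 1L)
    if (verbose) message("realization ", r)
    lm_mch <- sim("mixture_bank", seed_r)
    lm_ch <- sim("single_mixture", seed_r + 10000L)
    lm_gauss <- sim("single_gaussian", seed_r + 20000L)
    n_gauss <- round(nrow(lm_mch$events) / config$sensitivity_ratio)
    set.seed(seed_r + 30000L)
    lm_gauss <- thin_listmode(lm_gauss, min(n_gauss, nrow(lm_gauss$events)))
    set.seed(seed_r + 40000L)
    lm_low <- thin_listmode(lm_mch, nrow(lm_gauss$events))

    runs <- list(
      "mch"     = list(lm = lm_mch, cfg = rc("mixture")),
      "ch-mix"  = list(lm = lm_ch, cfg = rc("mixture")),
      "ch-dcmp" = list(lm = lm_ch, cfg = rc("decomposed")),
      "gauss"   = list(lm = lm_gauss, cfg = rc("gaussian")),
      "notof"   = list(lm = lm_mch, cfg = rc("none")),
      "mch-low" = list(lm = lm_low, cfg = rc("mixture")))
    runs <- runs[config$models]

    results <- list()
    for (model in names(runs)) {
      if (verbose) message("  reconstructing ", model)
      res <- lm_mlem(runs[[model]]$lm, runs[[model]]$cfg, sensitivity = sens)
      # calibrate every saved iteration by the background mean of the final one
      scale <- attr(calibrate(res$image, cal_mask, bg), "calibration_scale")
      res$images <- lapply(res$images, function(img) img * scale)
      res$image <- res$images[[length(res$images)]]
      results[[model]] <- res
      counts[[length(counts) + 1]] <-
        data.frame(realization = r, model = model,
                   n_events = nrow(runs[[model]]$lm$events))
      final_images[[model]] <- c(final_images[[model]], list(res$image))
    }
    m <- metrics_over_iterations(results, rois)
    m$realization <- r
    metrics[[r]] <- m
  }

  metrics <- do.call(rbind, metrics)
  agg <- stats::aggregate(
    cbind(crc_pct, bv_pct, cnr, mu_roi) ~ model + iteration + sphere +
      diameter_mm + hot,
    data = metrics, FUN = mean)
  se <- stats::aggregate(
    cbind(crc_pct, bv_pct, cnr, mu_roi) ~ model + iteration + sphere +
      diameter_mm + hot,
    data = metrics,
    FUN = function(x) sd(x) / sqrt(length(x)))
  names(se)[6:9] <- paste0(names(se)[6:9], "_se")
  summary <- merge(agg, se)

  bias <- NULL
  if (config$n_realizations >= 2) {
    bias <- do.call(rbind, lapply(names(final_images), function(model) {
      b <- bias_analysis(final_images[[model]], rois)
      b$model <- model
      b
    }))
  }

  list(metrics = metrics, summary = summary, bias = bias,
       counts = do.call(rbind, counts), config = config)
}
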