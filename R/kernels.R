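#' Double-Gaussian mixture timing kernel
#'
#' A coincidence time-difference model for detectors whose timing response is
#' a mixture of a narrow "fast" component (events rich in prompt Cherenkov
#' photons) and a wide "slow" component (scintillation-only events).  Both
#' components are zero-mean Gaussians; `alpha_fast` is the mixing weight
#' (abundance) of the fast component.
#'
#' @param kernel_id integer label (1..25 for the packaged bank, 0 means
#'   "none/single Gaussian").
#' @param fwhm_fast_ps,fwhm_slow_ps full widths at half maximum of the fast
#'   and slow components, in picoseconds.  Must be positive; normally
#'   `fwhm_fast_ps <= fwhm_slow_ps` (a warning is emitted otherwise and the
#'   components are kept as given, which can happen for fitted kernels).
#' @param alpha_fast mixing weight of the fast component, in `[0, 1]`.
#' @return an object of class `timing_kernel` with fields `kernel_id`,
#'   `fwhm_fast_ps`, `fwhm_slow_ps`, `alpha_fast`, `sigma_fast_ps`,
#'   `sigma_slow_ps`.
#' @examples
#' k <- timing_kernel(1, 179.8, 660.3, 0.594)
#' mixture_fwhm(k)
#' @export
timing_kernel <- function(kernel_id, fwhm_fast_ps, fwhm_slow_ps, alpha_fast) {
  stopifnot(length(fwhm_fast_ps) == 1, length(fwhm_slow_ps) == 1,
            is.finite(fwhm_fast_ps), is.finite(fwhm_slow_ps),
            fwhm_fast_ps > 0, fwhm_slow_ps > 0,
            alpha_fast >= 0, alpha_fast <= 1)
  if (fwhm_fast_ps > fwhm_slow_ps)
    warning("fast component is wider than slow component (fitted kernel?)")
  structure(list(kernel_id = as.integer(kernel_id),
                 fwhm_fast_ps = fwhm_fast_ps,
                 fwhm_slow_ps = fwhm_slow_ps,
                 alpha_fast = alpha_fast,
                 sigma_fast_ps = fwhm_to_sigma(fwhm_fast_ps),
                 sigma_slow_ps = fwhm_to_sigma(fwhm_slow_ps)),
            class = "timing_kernel")
}

#' @export
print.timing_kernel <- function(x, ...) {
  cat(sprintf(
    "timing kernel %d: fast %.1f ps / slow %.1f ps FWHM, alpha_fast %.3f\n",
    x$kernel_id, x$fwhm_fast_ps, x$fwhm_slow_ps, x$alpha_fast))
  invisible(x)
}

#' Kernel banks
#'
#' A kernel bank is an ordered set of mixture timing kernels together with a
#' category probability vector used when the simulator draws which timing
#' category applies to a coincidence pair (uniform by default).
#' `default_kernel_bank()` loads the packaged bank of 25 timing categories
#' measured for BGO-Cherenkov detector pairs; `read_kernel_bank()` reads a
#' tab- or comma-delimited file with a header row and columns `kernel_id`,
#' `fwhm_fast_ps`, `fwhm_slow_ps`, `alpha_fast`.
#'
#' @param kernels list of [timing_kernel()] objects.
#' @param category_probs probability of each kernel being selected for a
#'   coincidence pair; defaults to uniform.  Must sum to 1 (within 1e-12).
#' @return an object of class `kernel_bank`.
#' @examples
#' bank <- default_kernel_bank()
#' length(bank$kernels)        # 25
#' bank$kernels[[1]]
#' @export
kernel_bank <- function(kernels, category_probs = NULL) {
  stopifnot(length(kernels) >= 1,
            all(vapply(kernels, inherits, logical(1), "timing_kernel")))
  if (is.null(category_probs))
    category_probs <- rep(1 / length(kernels), length(kernels))
  stopifnot(length(category_probs) == length(kernels), all(category_probs >= 0))
  if (abs(sum(category_probs) - 1) > 1e-12)
    stop("category_probs must sum to 1 (within 1e-12)")
  structure(list(kernels = kernels, category_probs = category_probs),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("kernel bank with %d mixture timing kernels\n", length(x$kernels)))
  print(head(as.data.frame(x), 5))
  if (length(x$kernels) > 5) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.kernel_bank <- function(x, ...) {
  data.frame(
    kernel_id = vapply(x$kernels, `[[`, integer(1), "kernel_id"),
    fwhm_fast_ps = vapply(x$kernels, `[[`, numeric(1), "fwhm_fast_ps"),
    fwhm_slow_ps = vapply(x$kernels, `[[`, numeric(1), "fwhm_slow_ps"),
    alpha_fast = vapply(x$kernels, `[[`, numeric(1), "alpha_fast"),
    category_prob = x$category_probs)
}

#' @rdname kernel_bank
#' @param path path to a delimited kernel bank file.
#' @export
read_kernel_bank <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE, strip.white = TRUE)
  need <- c("kernel_id", "fwhm_fast_ps", "fwhm_slow_ps", "alpha_fast")
  if (!all(need %in% names(tab)))
    stop("kernel bank file must have columns: ", paste(need, collapse = ", "))
  for (cn in need)
    tab[[cn]] <- suppressWarnings(as.numeric(as.character(tab[[cn]])))
  kernels <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, need]
    if (any(!is.finite(unlist(row))))
      stop(sprintf("malformed kernel bank row %d (kernel_id %s)",
                   i, as.character(tab$kernel_id[i])))
    kernels[[i]] <- timing_kernel(row$kernel_id, row$fwhm_fast_ps,
                                  row$fwhm_slow_ps, row$alpha_fast)
  }
  kernel_bank(kernels)
}

#' @rdname kernel_bank
#' @export
default_kernel_bank <- function() {
  path <- system.file("extdata", "bgo_cherenkov_kernel_bank.tsv",
                      package = "tofmix", mustWork = TRUE)
  bank <- read_kernel_bank(path)
  stopifnot(length(bank$kernels) == 25)
  bank
}

#' Mixture kernel density, distribution and width
#'
#' `mixture_pdf()` and `mixture_cdf()` evaluate the density and cumulative
#' distribution of a zero-mean double-Gaussian mixture timing kernel;
#' `mixture_fwhm()` computes the full width at half maximum of the mixture
#' density by root-finding (the density is symmetric and unimodal at 0).
#'
#' @param kernel a [timing_kernel()].
#' @param t_ps time difference(s), picoseconds.
#' @return density per ps, probability, or width in ps.
#' @examples
#' k <- default_kernel_bank()$kernels[[13]]
#' mixture_cdf(k, 0)     # 0.5: kernels are centered
#' mixture_fwhm(k)
#' @export
mixture_pdf <- function(kernel, t_ps) {
  kernel$alpha_fast * dnorm(t_ps, 0, kernel$sigma_fast_ps) +
    (1 - kernel$alpha_fast) * dnorm(t_ps, 0, kernel$sigma_slow_ps)
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(kernel, t_ps) {
  kernel$alpha_fast * pnorm(t_ps, 0, kernel$sigma_fast_ps) +
    (1 - kernel$alpha_fast) * pnorm(t_ps, 0, kernel$sigma_slow_ps)
}

#' @rdname mixture_pdf
#' @export
mixture_fwhm <- function(kernel) {
  half <- mixture_pdf(kernel, 0) / 2
  upper <- 2 * max(kernel$fwhm_fast_ps, kernel$fwhm_slow_ps)
  root <- uniroot(function(t) mixture_pdf(kernel, t) - half,
                  lower = 0, upper = upper, tol = 1e-9)$root
  2 * root
}

#' Sample coincidence time differences from a mixture kernel
#'
#' Each draw first selects the fast or slow component with probability
#' `alpha_fast` (Bernoulli), then draws a zero-mean Gaussian time spread with
#' that component's sigma.  Uses R's global random number generator, so
#' results are reproducible under [set.seed()].
#'
#' @param kernel a [timing_kernel()].
#' @param n number of draws (>= 1).
#' @return a list with `delta_t_ps` (numeric) and `component` (integer, 1 =
#'   fast, 2 = slow).
#' @examples
#' set.seed(1)
#' s <- sample_delta_t(default_kernel_bank()$kernels[[1]], 1000)
#' mean(s$component == 1)   # close to alpha_fast = 0.594
#' @export
sample_delta_t <- function(kernel, n) {
  if (length(n) != 1 || !is.finite(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  fast <- runif(n) < kernel$alpha_fast
  sigma <- ifelse(fast, kernel$sigma_fast_ps, kernel$sigma_slow_ps)
  list(delta_t_ps = rnorm(n, 0, sigma),
       component = ifelse(fast, 1L, 2L))
}
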