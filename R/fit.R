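#' Fit mixture weights and chemical shifts to an observed spectrum
#'
#' Builds the joint Bayesian model and draws from its posterior with an
#' adaptive Hamiltonian Monte Carlo sampler. Latent variables are one
#' weight per candidate compound (Half-Cauchy prior), one chemical-shift
#' offset per resonance (Normal prior centered on the predicted shift with
#' the compound's `shift_sigma`), and the residual noise scale
#' (Half-Cauchy). The model spectrum is the weighted sum of candidate
#' lineshapes, normalized to unit area, and the observed density is
#' modeled as that curve plus i.i.d. Gaussian noise at every grid point.
#'
#' The observed spectrum and the simulated candidates both receive the
#' `broaden_hz` Gaussian apodization before fitting (the candidates on top
#' of their intrinsic Lorentzian linewidth), which smooths the posterior
#' geometry and increases gradient overlap between misaligned peaks.
#'
#' This is a single fit; [deconvolute()] wraps it in the iterative
#' prune-and-refit loop.
#'
#' @param observed Observed spectrum (`nmr_spectrum` or data frame with
#'   `ppm`/`intensity`).
#' @param lib Candidate library from [nmr_library()].
#' @param warmup,samples Warmup and retained iterations (defaults 1000 and
#'   3000).
#' @param seed Integer seed; fixes every random draw of the sampler.
#' @param broaden_hz Gaussian apodization fwhm applied to both sides (Hz).
#' @param weight_scale Half-Cauchy scale of the compound weights.
#' @param noise_scale Half-Cauchy scale of the residual noise sd.
#' @param window_ppm Evaluation half-window around each line; `NULL` picks
#'   `0.3 + 3 * max(shift_sigma)` capped at 2 ppm.
#' @param fit_points Number of uniform grid points the observed spectrum
#'   is resampled to before fitting.
#' @param truncate_shifts If `TRUE`, add a soft wall approximating
#'   truncation of the shift priors at +/- 4 prior sd.
#' @param shift_sigma_scale Multiplier on all shift prior sds (the
#'   prior-widening loop of [deconvolute()] uses 3).
#' @param l_max Maximum leapfrog steps per trajectory.
#' @param target_accept Dual-averaging acceptance target.
#' @return An object of class `nmr_fit`; see [tidy.nmr_fit()],
#'   [glance.nmr_fit()] and [autoplot.nmr_fit()].
#' @export
fit_mixture <- function(observed, lib, warmup = 1000, samples = 3000,
                        seed = 1, broaden_hz = 10, weight_scale = 1,
                        noise_scale = 0.5, window_ppm = NULL,
                        fit_points = 2560, truncate_shifts = FALSE,
                        shift_sigma_scale = 1, l_max = 15,
                        target_accept = 0.8) {
  dens <- prepare_observed(observed, broaden_hz, fit_points)
  fit_hmc_core(dens, lib,
               warmup = warmup, samples = samples, seed = seed,
               broaden_hz = broaden_hz, weight_scale = weight_scale,
               noise_scale = noise_scale, window_ppm = window_ppm,
               truncate_shifts = truncate_shifts,
               shift_sigma_scale = shift_sigma_scale,
               l_max = l_max, target_accept = target_accept)
}

# apodize, resample to the fitting grid, normalize to a density
prepare_observed <- function(observed, broaden_hz, fit_points) {
  spec <- as_nmr_spectrum(observed)
  if (broaden_hz > 0) spec <- gaussian_apodize(spec, broaden_hz)
  if (!is.null(fit_points) && fit_points != nrow(spec)) {
    spec <- resample_spectrum(spec, fit_points)
  }
  normalize_density(spec)
}

# The workhorse behind fit_mixture() and the interval fits of
# deconvolute(). `dens` must already be the broadened, unit-area observed
# density on the fitting grid. `interval = c(lo, hi)` restricts both the
# grid and the candidate lines; `normalize = FALSE` fits on an absolute
# scale (used for interval fits, where the global normalization constant
# is unknown).
fit_hmc_core <- function(dens, lib, warmup, samples, seed, broaden_hz,
                         weight_scale = 1, noise_scale = 0.5,
                         window_ppm = NULL, truncate_shifts = FALSE,
                         shift_sigma_scale = 1, l_max = 15,
                         target_accept = 0.8, interval = NULL,
                         normalize = TRUE) {
  stopifnot(warmup >= 1, samples >= 1)
  mhz <- spectrometer_mhz(dens)
  res <- library_resonances(lib)
  lines <- library_lines(lib, mhz)
  comp_area <- vapply(split(lines$amp, lines$comp_idx), sum, 1)

  grid <- dens$ppm
  y <- dens$intensity
  if (!is.null(interval)) {
    keep_g <- grid >= interval[1] & grid <= interval[2]
    if (sum(keep_g) < 8) abort("interval too narrow for the fitting grid")
    grid <- grid[keep_g]
    y <- y[keep_g]
    keep_l <- lines$center_ppm >= interval[1] & lines$center_ppm <= interval[2]
    lines <- lines[keep_l, ]
    if (nrow(lines) == 0) abort("no candidate lines inside the interval")
  }

  # re-index compounds/resonances present in the (possibly restricted) fit
  comp_ids <- sort(unique(lines$comp_idx))
  res_ids <- sort(unique(lines$res_idx))
  comp_map <- match(lines$comp_idx, comp_ids)
  res_map <- match(lines$res_idx, res_ids)
  n_comp <- length(comp_ids)
  res_sd <- res$shift_sigma[res_ids] * shift_sigma_scale

  if (is.null(window_ppm)) {
    window_ppm <- min(0.3 + 3 * max(res_sd), 2)
  }
  pv <- pseudo_voigt_params(lines$fwhm_hz, broaden_hz, mhz)

  # start the noise scale high: early warmup then behaves like an
  # annealed likelihood, letting weights and shifts move freely before
  # sigma contracts to the residual level
  q0 <- c(rep(log(1 / n_comp), n_comp), rep(0, length(res_ids)),
          log(max(sd(y), 1e-9)))
  set.seed(seed)
  raw <- nmr_hmc_cpp(
    grid, y, lines$center_ppm, lines$amp,
    comp_map - 1L, res_map - 1L,
    rep_len(pv$gamma_ppm, nrow(lines)), rep_len(pv$gsd_ppm, nrow(lines)),
    rep_len(pv$eta, nrow(lines)), res_sd,
    n_comp, weight_scale, noise_scale, window_ppm,
    as.integer(warmup), as.integer(samples), as.integer(l_max),
    target_accept, q0, truncate_shifts, normalize
  )
  draws <- raw$draws
  if (anyNA(draws)) abort("sampler produced NaN draws")
  if (raw$divergences > 0.1 * samples) {
    warn(sprintf("%d of %d iterations diverged; results may be unreliable",
                 raw$divergences, samples))
  }

  w_draws <- exp(draws[, seq_len(n_comp), drop = FALSE])
  colnames(w_draws) <- lib$name[comp_ids]
  closed <- w_draws / rowSums(w_draws)
  center <- comp_center(closed)

  d_draws <- draws[, n_comp + seq_along(res_ids), drop = FALSE]
  shift_summary <- tibble(
    compound = res$compound[res_ids],
    resonance = res$res_idx_local[res_ids],
    prior_shift_ppm = res$shift_ppm[res_ids],
    prior_sd_ppm = res_sd,
    post_mean_ppm = res$shift_ppm[res_ids] + colMeans(d_draws),
    post_sd_ppm = apply(d_draws, 2, sd)
  )

  sigma_draws <- exp(draws[, ncol(draws)])
  structure(list(
    library = lib[comp_ids, ],
    center = center,
    weight_samples = closed,
    raw_weight_samples = w_draws,
    compound_area = unname(comp_area[as.character(comp_ids)]),
    shift_summary = shift_summary,
    sigma_noise = exp(mean(log(sigma_draws))),
    observed = nmr_spectrum(grid, y, mhz),
    diagnostics = list(
      accept_rate = raw$accept_rate, divergences = raw$divergences,
      step_size = raw$step_size, warmup = warmup, samples = samples
    ),
    config = list(
      seed = seed, broaden_hz = broaden_hz, weight_scale = weight_scale,
      noise_scale = noise_scale, window_ppm = window_ppm,
      shift_sigma_scale = shift_sigma_scale, truncate_shifts = truncate_shifts,
      interval = interval, normalize = normalize
    )
  ), class = "nmr_fit")
}

#' Remove candidates below the concentration cutoff
#'
#' @param fit An `nmr_fit`.
#' @param cutoff Concentration fraction below which a candidate is
#'   considered absent (default 0.05).
#' @return The surviving rows of the fit's library, in input order.
#' @export
prune_candidates <- function(fit, cutoff = 0.05) {
  stopifnot(inherits(fit, "nmr_fit"))
  keep <- names(fit$center)[fit$center >= cutoff]
  if (length(keep) == 0) abort("no candidates survive cutoff")
  lib <- fit$library[fit$library$name %in% keep, ]
  nmr_library(lib)
}

# posterior-center model curve, for plotting and reporting
fitted_density <- function(fit) {
  lib <- fit$library
  mhz <- spectrometer_mhz(fit$observed)
  offs <- fit$shift_summary$post_mean_ppm - fit$shift_summary$prior_shift_ppm
  res <- library_resonances(lib)
  lines <- library_lines(lib, mhz, shift_offsets = offs)
  pv <- pseudo_voigt_params(lines$fwhm_hz, fit$config$broaden_hz, mhz)
  w <- fit$center[as.character(lib$name)]
  amps <- lines$amp * w[lines$comp_idx]
  yfit <- pv_mixture_cpp(fit$observed$ppm, lines$center_ppm, amps,
                         rep_len(pv$gamma_ppm, nrow(lines)),
                         rep_len(pv$gsd_ppm, nrow(lines)),
                         rep_len(pv$eta, nrow(lines)), Inf)
  if (fit$config$normalize %||% TRUE) {
    yfit <- yfit / trapz(fit$observed$ppm, yfit)
  }
  nmr_spectrum(fit$observed$ppm, yfit, mhz)
}
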