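#' Expand a resonance's J-couplings into a multiplet
#'
#' Applies the first-order N+1 rule: a group of `n` equivalent coupled
#' spins with constant `j_hz` splits a line into `n + 1` lines with
#' intensities from row `n` of Pascal's triangle, adjacent lines spaced
#' `j_hz` apart and the pattern centered on the parent shift (so a doublet
#' sits at +/- J/2). Several coupling groups are combined by convolution.
#' Relative intensities sum to one, so multiplying by the resonance weight
#' conserves total signal.
#'
#' @param couplings `NULL` (no couplings) or a data frame with columns
#'   `j_hz` and `n`.
#' @param spectrometer_mhz Larmor frequency used to convert Hz to ppm.
#' @return A tibble with columns `offset_ppm` (offset from the parent
#'   shift) and `rel_intensity`.
#' @export
#' @examples
#' expand_multiplet(data.frame(j_hz = 10, n = 2))  # 1:2:1 triplet
expand_multiplet <- function(couplings = NULL, spectrometer_mhz = 500) {
  couplings <- validate_couplings(couplings, name = "<resonance>")
  lines <- tibble(offset_hz = 0, rel_intensity = 1)
  if (!is.null(couplings)) {
    for (g in seq_len(nrow(couplings))) {
      j <- couplings$j_hz[g]
      n <- couplings$n[g]
      pat <- tibble(
        offset_hz = j * (0:n - n / 2),
        rel_intensity = choose(n, 0:n) / 2^n
      )
      # convolve the current line set with this splitting pattern
      lines <- tidyr_crossing(lines, pat)
    }
  }
  out <- lines %>%
    dplyr::group_by(.data$offset_hz) %>%
    dplyr::summarise(rel_intensity = sum(.data$rel_intensity), .groups = "drop") %>%
    arrange(.data$offset_hz)
  tibble(offset_ppm = out$offset_hz / spectrometer_mhz,
         rel_intensity = out$rel_intensity)
}

# cross join of two line sets, adding offsets and multiplying intensities
tidyr_crossing <- function(a, b) {
  idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  tibble(
    offset_hz = a$offset_hz[idx$i] + b$offset_hz[idx$j],
    rel_intensity = a$rel_intensity[idx$i] * b$rel_intensity[idx$j]
  )
}

# pseudo-Voigt parameters for a Lorentzian of width fl convolved with a
# Gaussian of width fg (both fwhm, Hz); Thompson-Cox-Hastings mixing.
# Returns gamma (Lorentz hwhm), sd (Gaussian), eta, all for the combined
# width, in ppm.
pseudo_voigt_params <- function(fl_hz, fg_hz, spectrometer_mhz) {
  if (fg_hz <= 0) {
    return(list(gamma_ppm = fl_hz / 2 / spectrometer_mhz,
                gsd_ppm = rep(1, length(fl_hz)), eta = rep(1, length(fl_hz))))
  }
  f <- (fg_hz^5 + 2.69269 * fg_hz^4 * fl_hz + 2.42843 * fg_hz^3 * fl_hz^2 +
          4.47163 * fg_hz^2 * fl_hz^3 + 0.07842 * fg_hz * fl_hz^4 + fl_hz^5)^(1 / 5)
  rho <- fl_hz / f
  eta <- 1.36603 * rho - 0.47719 * rho^2 + 0.11116 * rho^3
  list(
    gamma_ppm = f / 2 / spectrometer_mhz,
    gsd_ppm = f / (2 * sqrt(2 * log(2))) / spectrometer_mhz,
    eta = eta
  )
}

# expand a whole library into a flat line table (one row per multiplet
# line): comp_idx, res_idx (global), center_ppm, amp, fwhm_hz
library_lines <- function(lib, spectrometer_mhz = 500, shift_offsets = NULL) {
  res <- library_resonances(lib)
  if (!is.null(shift_offsets)) {
    stopifnot(length(shift_offsets) == nrow(res))
    res$shift_ppm <- res$shift_ppm + shift_offsets
  }
  purrr::map_dfr(seq_len(nrow(res)), function(i) {
    mult <- expand_multiplet(res$couplings[[i]], spectrometer_mhz)
    tibble(
      comp_idx = res$comp_idx[i], res_idx = i,
      center_ppm = res$shift_ppm[i] + mult$offset_ppm,
      amp = res$weight[i] * mult$rel_intensity,
      fwhm_hz = res$fwhm_hz[i]
    )
  })
}

#' Simulate the spectrum of one or more compounds
#'
#' Renders the frequency-domain spectrum as a sum of unit-area Lorentzian
#' lines (the Fourier transform of exponentially decaying time signals),
#' one multiplet line set per resonance. The trapezoid integral of a
#' single compound equals the sum of its resonance weights when the grid
#' extends well beyond the outermost line.
#'
#' @param lib An `nmr_library` (one or more compounds).
#' @param grid ppm axis (uniform); default [default_grid()].
#' @param spectrometer_mhz Larmor frequency, MHz.
#' @param weights Optional per-compound mixture weights (default all 1).
#' @return An `nmr_spectrum` of the (weighted) sum of compound spectra.
#' @export
render_spectrum <- function(lib, grid = default_grid(),
                            spectrometer_mhz = 500, weights = NULL) {
  lines <- library_lines(lib, spectrometer_mhz)
  if (is.null(weights)) weights <- rep(1, nrow(lib))
  if (length(weights) != nrow(lib)) {
    abort("`weights` must have one entry per compound")
  }
  h <- grid[2] - grid[1]
  min_fwhm_ppm <- min(lines$fwhm_hz) / spectrometer_mhz
  if (min_fwhm_ppm / h < 4) {
    warn(sprintf(
      "grid step %.2g ppm gives fewer than 4 points per %.2g ppm linewidth; peaks may be undersampled",
      h, min_fwhm_ppm))
  }
  amps <- lines$amp * weights[lines$comp_idx]
  nl <- nrow(lines)
  y <- pv_mixture_cpp(grid, lines$center_ppm, amps,
                      lines$fwhm_hz / 2 / spectrometer_mhz,
                      rep(1, nl), rep(1, nl), Inf)
  nmr_spectrum(grid, y, spectrometer_mhz)
}
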