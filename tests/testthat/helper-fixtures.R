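# Small fixtures built in code; every stochastic test fixes its own seed.

two_compound_lib <- function(shift_sigma = 0.05) {
  nmr_library(
    nmr_compound("aceto", c(2.0, 5.0), weight = c(2, 1),
                 shift_sigma = shift_sigma),
    nmr_compound("benzo", c(3.0, 7.0), weight = c(1, 1),
                 shift_sigma = shift_sigma)
  )
}

three_compound_lib <- function(shift_sigma = 0.05) {
  nmr_library(
    two_compound_lib(shift_sigma),
    nmr_compound("pyrro", c(1.2, 6.2, 8.4), weight = c(3, 1, 1),
                 shift_sigma = shift_sigma)
  )
}

render_obs <- function(lib, weights, n = 2^14, from = -1, to = 11) {
  render_spectrum(lib, default_grid(from, to, n), weights = weights)
}

# brute-force multiplet oracle: enumerate every combination of coupled
# spin-1/2 states; each of the 2^N states is equally likely and offsets
# the line by J * (sum of partner spin projections)
multiplet_oracle <- function(couplings, spectrometer_mhz = 500) {
  spins <- rep(couplings$j_hz, couplings$n)
  if (length(spins) == 0) {
    return(tibble::tibble(offset_ppm = 0, rel_intensity = 1))
  }
  states <- expand.grid(rep(list(c(-0.5, 0.5)), length(spins)))
  offset_hz <- as.matrix(states) %*% spins
  agg <- aggregate(
    rep(1 / nrow(states), nrow(states)),
    by = list(offset_hz = round(offset_hz, 9)), FUN = sum
  )
  agg <- agg[order(agg$offset_hz), ]
  tibble::tibble(offset_ppm = agg$offset_hz / spectrometer_mhz,
                 rel_intensity = agg$x)
}

expect_composition_equal <- function(est, truth, tol) {
  expect_equal(unname(est[names(truth)]), unname(truth), tolerance = tol)
}
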