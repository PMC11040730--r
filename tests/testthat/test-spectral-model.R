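test_that("uncoupled resonance expands to a single line", {
  m <- expand_multiplet(NULL)
  expect_equal(m$offset_ppm, 0)
  expect_equal(m$rel_intensity, 1)
})

test_that("a single J-coupling gives a symmetric doublet spaced J in Hz", {
  m <- expand_multiplet(data.frame(j_hz = 10, n = 1), spectrometer_mhz = 500)
  expect_equal(m$offset_ppm, c(-0.01, 0.01))
  expect_equal(m$rel_intensity, c(0.5, 0.5))
})

test_that("N equivalent partners give Pascal-row intensities (vs spin-state enumeration)", {
  for (n in 1:6) {
    cp <- data.frame(j_hz = 7.3, n = n)
    got <- expand_multiplet(cp)
    oracle <- multiplet_oracle(cp)
    expect_equal(got$offset_ppm, oracle$offset_ppm, tolerance = 1e-12)
    expect_equal(got$rel_intensity, oracle$rel_intensity, tolerance = 1e-12)
  }
})

test_that("multiple coupling groups convolve (doublet of doublets and beyond)", {
  dd <- expand_multiplet(data.frame(j_hz = c(5, 10), n = c(1, 1)))
  expect_equal(nrow(dd), 4)
  expect_equal(dd$rel_intensity, rep(0.25, 4))
  # random coupling sets against the brute-force enumeration
  set.seed(42)
  for (k in 1:8) {
    ngroups <- sample(1:3, 1)
    cp <- data.frame(j_hz = round(runif(ngroups, 1, 12), 2),
                     n = sample(1:4, ngroups, replace = TRUE))
    got <- expand_multiplet(cp)
    oracle <- multiplet_oracle(cp)
    expect_equal(sum(got$rel_intensity), 1, tolerance = 1e-12)
    expect_equal(got$offset_ppm, oracle$offset_ppm, tolerance = 1e-9)
    expect_equal(got$rel_intensity, oracle$rel_intensity, tolerance = 1e-9)
  }
})

test_that("multiplet expansion rejects invalid couplings", {
  expect_error(expand_multiplet(data.frame(j_hz = -2, n = 1)), "negative")
  expect_error(expand_multiplet(data.frame(j_hz = 5, n = 0)), "positive integer")
})

test_that("rendered singlet is a unit-area Lorentzian peaked at its shift", {
  lib <- nmr_compound("x", 4.7, weight = 1, shift_sigma = 0.1)
  s <- render_spectrum(lib, default_grid(0, 10, 2^14))
  expect_equal(spectrum_integral(s), 1, tolerance = 0.01)
  expect_equal(s$ppm[which.max(s$intensity)], 4.7, tolerance = 1e-3)
})

test_that("rendering is linear in weights and areas add", {
  lib <- two_compound_lib()
  grid <- default_grid(0, 10, 2^13)
  suppressWarnings({
    mix <- render_spectrum(lib, grid, weights = c(0.6, 0.4))
    a <- render_spectrum(lib[1, ], grid)
    b <- render_spectrum(lib[2, ], grid)
  })
  expect_equal(mix$intensity, 0.6 * a$intensity + 0.4 * b$intensity,
               tolerance = 1e-9)
})

test_that("well-separated singlet heights scale with their weights", {
  lib <- nmr_compound("x", c(2, 8), weight = c(1, 3), shift_sigma = 0.1)
  s <- render_spectrum(lib, default_grid(0, 10, 2^15))
  h1 <- max(s$intensity[s$ppm < 5])
  h3 <- max(s$intensity[s$ppm > 5])
  expect_equal(h3 / h1, 3, tolerance = 0.01)
})

test_that("rendered linewidth matches the requested Lorentzian fwhm", {
  lib <- nmr_compound("x", 5, weight = 1, fwhm_hz = 2, shift_sigma = 0.1)
  s <- render_spectrum(lib, default_grid(4.9, 5.1, 2^14))
  half <- max(s$intensity) / 2
  above <- range(s$ppm[s$intensity >= half])
  expect_equal(diff(above), 2 / 500, tolerance = 0.05)
})

test_that("a too-coarse grid triggers an undersampling warning", {
  lib <- nmr_compound("x", 5, weight = 1, fwhm_hz = 2, shift_sigma = 0.1)
  expect_warning(render_spectrum(lib, default_grid(0, 10, 512)),
                 "undersampled")
})

test_that("gaussian apodization broadens to the kernel width and keeps area", {
  # near-delta line: 0.2 Hz natural width
  lib <- nmr_compound("x", 5, weight = 1, fwhm_hz = 0.2, shift_sigma = 0.1)
  s <- suppressWarnings(render_spectrum(lib, default_grid(0, 10, 2^16)))
  b <- gaussian_apodize(s, 10)
  half <- max(b$intensity) / 2
  width_ppm <- diff(range(b$ppm[b$intensity >= half]))
  expect_equal(width_ppm * 500, 10, tolerance = 0.05)
  expect_equal(spectrum_integral(b), spectrum_integral(s), tolerance = 1e-3)
})

test_that("apodization with a vanishing kernel is the identity", {
  lib <- nmr_compound("x", 5, weight = 1, shift_sigma = 0.1)
  s <- render_spectrum(lib, default_grid(0, 10, 2^14))
  b <- gaussian_apodize(s, 0.01)
  expect_lt(max(abs(b$intensity - s$intensity)) / max(s$intensity), 1e-6)
})

test_that("apodization leaves a flat spectrum unchanged and commutes with sums", {
  flat <- nmr_spectrum(default_grid(0, 10, 2^12), rep(2, 2^12))
  b <- gaussian_apodize(flat, 10)
  inner <- flat$ppm > 1 & flat$ppm < 9
  expect_equal(b$intensity[inner], flat$intensity[inner], tolerance = 1e-9)

  lib <- two_compound_lib()
  grid <- default_grid(0, 10, 2^13)
  suppressWarnings({
    a <- render_spectrum(lib[1, ], grid)
    bb <- render_spectrum(lib[2, ], grid)
    mix <- render_spectrum(lib, grid, weights = c(1, 1))
  })
  lhs <- gaussian_apodize(mix, 10)$intensity
  rhs <- gaussian_apodize(a, 10)$intensity + gaussian_apodize(bb, 10)$intensity
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("density normalization has unit integral, is idempotent and scale-free", {
  lib <- two_compound_lib()
  s <- suppressWarnings(render_spectrum(lib, default_grid(0, 10, 2^13),
                                        weights = c(2, 5)))
  n1 <- normalize_density(s)
  expect_equal(spectrum_integral(n1), 1, tolerance = 1e-9)
  expect_equal(normalize_density(n1)$intensity, n1$intensity, tolerance = 1e-12)
  s7 <- nmr_spectrum(s$ppm, 7 * s$intensity)
  expect_equal(normalize_density(s7)$intensity, n1$intensity, tolerance = 1e-12)
  expect_error(normalize_density(nmr_spectrum(0:10, rep(0, 11))), "empty")
})
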