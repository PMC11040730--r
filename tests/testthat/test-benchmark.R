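test_that("generated components follow the benchmark recipe", {
  set.seed(31)
  for (k in 1:5) {
    cmp <- gen_component("x")
    res <- cmp$resonances[[1]]
    expect_equal(nrow(res), 10)
    expect_true(all(res$shift_ppm >= 0 & res$shift_ppm <= 10))
    expect_true(all(res$weight %in% 0:3))
    coupled <- !vapply(res$couplings, is.null, TRUE)
    expect_equal(sum(coupled), 5)
    js <- unlist(lapply(res$couplings[coupled], function(cp) cp$j_hz))
    expect_true(all(js %in% c(5, 10)))
    expect_true(all(res$fwhm_hz == 2))
  }
})

test_that("component generation is seed-reproducible", {
  set.seed(7); a <- gen_component("x")
  set.seed(7); b <- gen_component("x")
  expect_identical(a$resonances[[1]], b$resonances[[1]])
  set.seed(8); c <- gen_component("x")
  expect_false(identical(a$resonances[[1]]$shift_ppm,
                         c$resonances[[1]]$shift_ppm))
})

test_that("mixture weights are a flat-Dirichlet composition and areas add", {
  set.seed(41)
  comps <- nmr_library(!!!lapply(1:5, function(i) {
    gen_component(paste0("c", i))
  }))
  grid <- default_grid(-1, 11, 2^14)
  mix <- gen_mixture(comps, grid)
  expect_equal(sum(mix$weights), 1, tolerance = 1e-12)
  expect_true(all(mix$weights > 0))
  areas <- vapply(seq_len(5), function(i) {
    spectrum_integral(render_spectrum(comps[i, ], grid))
  }, 1)
  expect_equal(spectrum_integral(mix$spectrum), sum(mix$weights * areas),
               tolerance = 0.01)

  single <- gen_mixture(comps[3, ], grid)
  expect_equal(unname(single$weights), 1)
})

test_that("shift jitter has the requested scale and independence", {
  set.seed(51)
  lib <- nmr_library(!!!lapply(1:4, function(i) gen_component(paste0("c", i))))
  tiny <- jitter_library(lib, 1e-12)
  expect_equal(tiny$resonances[[1]]$shift_ppm, lib$resonances[[1]]$shift_ppm,
               tolerance = 1e-9)
  expect_equal(tiny$shift_sigma, rep(1e-12, 4))

  # E|N(0, 0.1)| = 0.0798 ppm
  set.seed(52)
  offs <- replicate(150, {
    j <- jitter_library(lib[1, ], 0.1)
    j$resonances[[1]]$shift_ppm - lib$resonances[[1]]$shift_ppm
  })
  expect_lt(abs(mean(abs(offs)) - 0.1 * sqrt(2 / pi)), 0.005)
  # per-resonance offsets are uncorrelated
  cors <- cor(t(offs))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.25)
})

test_that("baseline noise matches its construction and reproduces by seed", {
  s <- nmr_spectrum(default_grid(0, 10, 4096), rep(0.5, 4096))
  expect_identical(add_baseline_noise(s, 0)$intensity, s$intensity)
  set.seed(61)
  n1 <- add_baseline_noise(s, 0.01)
  expect_lt(abs(sd(n1$intensity - s$intensity) - 0.01), 0.001)
  set.seed(61)
  n2 <- add_baseline_noise(s, 0.01)
  expect_identical(n1$intensity, n2$intensity)
})

test_that("a small benchmark run returns per-repeat scores", {
  b <- run_benchmark(
    n_true = 2, n_candidates = 3, theory_sigma = 0.05, n_repeats = 2,
    seed = 71, warmup = 150, samples = 300,
    gen_grid = default_grid(-1, 11, 2^14), fit_points = 1024
  )
  expect_equal(nrow(b), 2)
  expect_true(all(is.finite(b$mae_pct)))
  expect_true(all(b$mae_pct >= 0 & b$mae_pct <= 100))
  expect_true(all(b$accuracy_pct >= 0 & b$accuracy_pct <= 100))
  s <- attr(b, "summary")
  expect_equal(s$mean_mae_pct, mean(b$mae_pct))
})

test_that("the full benchmark pipeline is deterministic under one seed", {
  args <- list(n_true = 2, n_candidates = 2, theory_sigma = 0.05,
               n_repeats = 1, seed = 81, warmup = 100, samples = 200,
               gen_grid = default_grid(-1, 11, 2^14), fit_points = 1024)
  b1 <- do.call(run_benchmark, args)
  b2 <- do.call(run_benchmark, args)
  expect_equal(b1$mae_pct, b2$mae_pct, tolerance = 1e-12)
  expect_equal(b1$accuracy_pct, b2$accuracy_pct)
})
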