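# Posterior-sampling tests use short chains on small libraries; the
# acceptance suite exercises the full-scale benchmark conditions.

test_that("analytic posterior gradient matches finite differences", {
  lib <- two_compound_lib()
  obs <- render_obs(lib, c(0.6, 0.4))
  dens <- nmrdecon:::prepare_observed(obs, 10, 1024)
  lines <- nmrdecon:::library_lines(lib, 500)
  pv <- nmrdecon:::pseudo_voigt_params(lines$fwhm_hz, 10, 500)
  res <- nmrdecon:::library_resonances(lib)
  f <- function(q, trunc = FALSE, norm = TRUE) {
    nmrdecon:::nmr_potential_cpp(
      dens$ppm, dens$intensity, lines$center_ppm, lines$amp,
      lines$comp_idx - 1L, lines$res_idx - 1L,
      rep_len(pv$gamma_ppm, nrow(lines)), rep_len(pv$gsd_ppm, nrow(lines)),
      rep_len(pv$eta, nrow(lines)), res$shift_sigma,
      2L, 1, 0.5, 0.6, q, trunc, norm
    )
  }
  set.seed(2)
  for (case in 1:3) {
    q <- c(rnorm(2, 0, 0.5), rnorm(4, 0, 0.03), rnorm(1, -2, 0.3))
    for (trunc in c(FALSE, TRUE)) for (norm in c(TRUE, FALSE)) {
      g <- f(q, trunc, norm)
      num <- vapply(seq_along(q), function(i) {
        e <- 1e-6
        qp <- q; qp[i] <- q[i] + e
        qm <- q; qm[i] <- q[i] - e
        (f(qp, trunc, norm)$U - f(qm, trunc, norm)$U) / (2 * e)
      }, 1)
      expect_equal(g$grad, num, tolerance = 1e-4)
    }
  }
})

test_that("self-fit recovers shifts of a single compound", {
  lib <- nmr_compound("solo", c(2.5, 6.5), weight = c(2, 1),
                      shift_sigma = 0.05)
  obs <- render_obs(lib, 1)
  fit <- fit_mixture(obs, lib, warmup = 300, samples = 600, seed = 3,
                     fit_points = 1024)
  expect_equal(fit$shift_summary$post_mean_ppm, c(2.5, 6.5),
               tolerance = 0.01)
  expect_equal(unname(fit$center), 1)
})

test_that("two-compound mixture weights are recovered on the simplex", {
  lib <- two_compound_lib()
  obs <- render_obs(lib, c(0.7, 0.3))
  fit <- fit_mixture(obs, lib, warmup = 400, samples = 800, seed = 5,
                     fit_points = 1024)
  expect_composition_equal(fit$center, c(aceto = 0.7, benzo = 0.3), tol = 0.02)
})

test_that("an absent candidate collapses below the cutoff", {
  lib <- three_compound_lib()
  obs <- render_obs(lib[1:2, ], c(0.6, 0.4))  # pyrro not in the mixture
  fit <- fit_mixture(obs, lib, warmup = 400, samples = 800, seed = 6,
                     fit_points = 1024)
  expect_lt(fit$center["pyrro"], 0.05)
})

test_that("posterior shift spread contracts below the prior for well-fit lines", {
  lib <- two_compound_lib(shift_sigma = 0.05)
  obs <- render_obs(lib, c(0.5, 0.5))
  fit <- fit_mixture(obs, lib, warmup = 300, samples = 600, seed = 8,
                     fit_points = 1024)
  expect_true(all(fit$shift_summary$post_sd_ppm <
                    fit$shift_summary$prior_sd_ppm))
})

test_that("sampling is deterministic under a fixed seed", {
  lib <- two_compound_lib()
  obs <- render_obs(lib, c(0.7, 0.3))
  f1 <- fit_mixture(obs, lib, warmup = 100, samples = 200, seed = 9,
                    fit_points = 1024)
  f2 <- fit_mixture(obs, lib, warmup = 100, samples = 200, seed = 9,
                    fit_points = 1024)
  expect_identical(f1$weight_samples, f2$weight_samples)
  f3 <- fit_mixture(obs, lib, warmup = 100, samples = 200, seed = 10,
                    fit_points = 1024)
  expect_false(identical(f1$weight_samples, f3$weight_samples))
})

test_that("rescaling the observed intensities leaves the fit unchanged", {
  lib <- two_compound_lib()
  obs <- render_obs(lib, c(0.7, 0.3))
  obs_scaled <- nmr_spectrum(obs$ppm, 37 * obs$intensity)
  f1 <- fit_mixture(obs, lib, warmup = 150, samples = 300, seed = 11,
                    fit_points = 1024)
  f2 <- fit_mixture(obs_scaled, lib, warmup = 150, samples = 300, seed = 11,
                    fit_points = 1024)
  # both sides are normalized to densities before sampling; agreement is
  # limited only by floating-point rescaling noise amplified by the chain
  expect_equal(f1$center, f2$center, tolerance = 0.01)
})

test_that("pruning removes sub-cutoff candidates and keeps input order", {
  lib <- three_compound_lib()
  obs <- render_obs(lib, c(0.55, 0.42, 0.03))
  fit <- fit_mixture(obs, lib, warmup = 300, samples = 600, seed = 12,
                     fit_points = 1024)
  kept <- prune_candidates(fit, cutoff = 0.05)
  expect_equal(kept$name, c("aceto", "benzo"))
  expect_error(prune_candidates(fit, cutoff = 0.99), "survive")
})

test_that("deconvolute keeps a fully present library in one iteration", {
  lib <- three_compound_lib()
  obs <- render_obs(lib, c(0.2, 0.3, 0.5))
  fit <- deconvolute(obs, lib, warmup = 300, samples = 600, seed = 13,
                     fit_points = 1024)
  expect_true(all(fit$present))
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 1)
  expect_composition_equal(fit$composition,
                           c(aceto = 0.2, benzo = 0.3, pyrro = 0.5),
                           tol = 0.03)
})

test_that("deconvolute prunes absent candidates and reports zero for them", {
  lib6 <- nmr_library(
    three_compound_lib(),
    nmr_compound("ghost1", c(1.7, 4.4), weight = c(2, 2), shift_sigma = 0.05),
    nmr_compound("ghost2", c(3.6, 9.1), weight = c(1, 2), shift_sigma = 0.05),
    nmr_compound("ghost3", c(0.8, 6.8), weight = c(2, 1), shift_sigma = 0.05)
  )
  truth <- c(0.2, 0.3, 0.5, 0, 0, 0)
  obs <- render_obs(lib6[1:3, ], truth[1:3])
  fit <- deconvolute(obs, lib6, warmup = 400, samples = 800, seed = 14,
                     fit_points = 1024)
  expect_equal(unname(fit$present),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(
    classification_accuracy(fit$present, truth > 0), 100
  )
  expect_equal(unname(fit$composition[4:6]), c(0, 0, 0))
  expect_composition_equal(fit$composition[1:3],
                           c(aceto = 0.2, benzo = 0.3, pyrro = 0.5),
                           tol = 0.04)
})

test_that("an empty spectrum errors out before fitting", {
  lib <- two_compound_lib()
  flat <- nmr_spectrum(default_grid(0, 10, 2048), rep(0, 2048))
  expect_error(deconvolute(flat, lib, warmup = 50, samples = 50), "empty")
})

test_that("permuting the library permutes the recovered center", {
  lib <- three_compound_lib()
  obs <- render_obs(lib, c(0.2, 0.3, 0.5))
  f1 <- fit_mixture(obs, lib, warmup = 300, samples = 600, seed = 15,
                    fit_points = 1024)
  f2 <- fit_mixture(obs, lib[c(3, 1, 2), ], warmup = 300, samples = 600,
                    seed = 15, fit_points = 1024)
  expect_equal(f2$center[names(f1$center)], f1$center, tolerance = 0.02)
})

test_that("interval mode prunes candidates with empty predicted regions", {
  # only 'keep' is in the mixture; the other two predict lines above 8 ppm
  # where the observed spectrum is empty, so the entropy-ranked interval
  # pass should remove them before the global fit
  keep <- nmr_compound("keep", c(1.5, 3.0), weight = c(2, 1),
                       shift_sigma = 0.05)
  ald <- nmr_compound("ald", c(9.6, 9.9), weight = c(1, 1),
                      shift_sigma = 0.05)
  acid <- nmr_compound("acid", c(8.7, 9.0), weight = c(1, 2),
                       shift_sigma = 0.05)
  lib <- nmr_library(keep, ald, acid)
  obs <- render_obs(keep, 1)
  fit <- suppressWarnings(
    deconvolute(obs, lib, warmup = 300, samples = 600, seed = 16,
                fit_points = 1024, intervals = TRUE)
  )
  expect_equal(unname(fit$present), c(TRUE, FALSE, FALSE))
  expect_false(is.null(fit$interval_table))
  expect_true(any(grepl("interval", fit$history$stage)))
})

test_that("tidy, glance and plots expose the fit", {
  lib <- two_compound_lib()
  obs <- render_obs(lib, c(0.7, 0.3))
  fit <- deconvolute(obs, lib, warmup = 150, samples = 300, seed = 17,
                     fit_points = 1024)
  td <- tidy(fit)
  expect_named(td, c("compound", "estimate", "conf.low", "conf.high", "present"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_candidates, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_composition(fit, truth = c(aceto = 0.7, benzo = 0.3)),
                  "ggplot")
})
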