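#' @export
print.nmr_fit <- function(x, ...) {
  cat("<nmr_fit> ", length(x$center), " candidate(s), ",
      x$diagnostics$samples, " posterior draws\n", sep = "")
  comp <- if (!is.null(x$composition)) x$composition else x$center
  for (nm in names(comp)) {
    flag <- if (!is.null(x$present) && !x$present[nm]) " (absent)" else ""
    cat(sprintf("  %-16s %6.3f%s\n", nm, comp[nm], flag))
  }
  cat(sprintf("  sigma_noise = %.3g, accept = %.2f, divergences = %d\n",
              x$sigma_noise, x$diagnostics$accept_rate,
              x$diagnostics$divergences))
  if (!is.null(x$converged) && !x$converged) cat("  ! prune loop unconverged\n")
  invisible(x)
}

#' Tidy the composition estimate of a fit
#'
#' One row per candidate with the geometric-mean center estimate and the
#' 2.5/97.5 percentile credible interval of the closed weight draws.
#' Candidates pruned before the final fit carry zero estimates.
#'
#' @param x An `nmr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `compound`, `estimate`, `conf.low`,
#'   `conf.high`, `present`.
#' @export
tidy.nmr_fit <- function(x, ...) {
  nms <- if (!is.null(x$composition)) names(x$composition) else names(x$center)
  ci <- apply(x$weight_samples, 2, quantile, probs = c(0.025, 0.975))
  est <- if (!is.null(x$composition)) x$composition else x$center
  lo <- hi <- setNames(numeric(length(nms)), nms)
  lo[colnames(ci)] <- ci[1, ]
  hi[colnames(ci)] <- ci[2, ]
  tibble(
    compound = nms,
    estimate = unname(est[nms]),
    conf.low = unname(lo),
    conf.high = unname(hi),
    present = if (!is.null(x$present)) unname(x$present[nms]) else
      unname(est[nms] >= (x$cutoff %||% 0.05))
  )
}

#' One-row summary of a fit
#'
#' @param x An `nmr_fit`.
#' @param ... Unused.
#' @return A tibble with sampler diagnostics and loop status.
#' @export
glance.nmr_fit <- function(x, ...) {
  tibble(
    n_candidates = length(x$center),
    n_resonances = nrow(x$shift_summary),
    sigma_noise = x$sigma_noise,
    accept_rate = x$diagnostics$accept_rate,
    divergences = x$diagnostics$divergences,
    n_iterations = x$n_iterations %||% 1L,
    converged = x$converged %||% TRUE
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed versus fitted spectrum
#'
#' Overlays the (broadened, normalized) observed density with the model
#' curve evaluated at the posterior composition and shift means.
#'
#' @param object An `nmr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmr_fit <- function(object, ...) {
  fitc <- fitted_density(object)
  df <- bind_rows(
    tibble(ppm = object$observed$ppm, intensity = object$observed$intensity,
           curve = "observed"),
    tibble(ppm = fitc$ppm, intensity = fitc$intensity, curve = "fitted")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$intensity,
                                   color = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "density", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the recovered composition with credible intervals
#'
#' @param fit An `nmr_fit`.
#' @param truth Optional named true composition to overlay.
#' @return A ggplot.
#' @export
plot_composition <- function(fit, truth = NULL) {
  td <- tidy(fit)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$compound, y = .data$estimate)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$present), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high), width = 0.2) +
    ggplot2::labs(x = NULL, y = "mole fraction") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tdf <- tibble(compound = names(truth), truth = unname(truth))
    p <- p + ggplot2::geom_point(data = tdf,
                                 ggplot2::aes(y = .data$truth), shape = 4,
                                 size = 3, color = "black")
  }
  p
}

#' Plot a spectrum
#'
#' @param object An `nmr_spectrum`.
#' @param ... Unused.
#' @return A ggplot with the conventional reversed ppm axis.
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}
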