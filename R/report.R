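#' Write a JSON run report for a fit
#'
#' Serializes the composition estimate with credible intervals, the
#' present/absent calls, the per-resonance shift posterior, the pruning
#' history, the interval table (when interval mode was used), sampler
#' diagnostics and the configuration needed to reproduce the run. When a
#' ground-truth composition is supplied, the report also carries the
#' mole-fraction MAE and classification accuracy against it.
#'
#' @param fit An `nmr_fit` from [deconvolute()] or [fit_mixture()].
#' @param path Output path.
#' @param truth Optional named true composition (mole fractions over the
#'   candidate names; omitted candidates count as zero).
#' @return The report list, invisibly.
#' @export
write_report <- function(fit, path, truth = NULL) {
  stopifnot(inherits(fit, "nmr_fit"))
  td <- tidy(fit)
  report <- list(
    package = "nmrdecon",
    version = as.character(utils::packageVersion("nmrdecon")),
    config = fit$config[c("seed", "broaden_hz", "weight_scale",
                          "noise_scale", "window_ppm")],
    cutoff = fit$cutoff,
    composition = as.list(setNames(td$estimate, td$compound)),
    credible_intervals = lapply(seq_len(nrow(td)), function(i) {
      list(compound = td$compound[i], lo = td$conf.low[i], hi = td$conf.high[i])
    }),
    present = as.list(setNames(td$present, td$compound)),
    shift_posterior = lapply(seq_len(nrow(fit$shift_summary)), function(i) {
      s <- fit$shift_summary[i, ]
      list(compound = s$compound, resonance = s$resonance,
           prior_ppm = s$prior_shift_ppm, prior_sd_ppm = s$prior_sd_ppm,
           post_mean_ppm = s$post_mean_ppm, post_sd_ppm = s$post_sd_ppm)
    }),
    diagnostics = fit$diagnostics,
    sigma_noise = fit$sigma_noise,
    converged = fit$converged %||% TRUE,
    n_iterations = fit$n_iterations %||% 1L
  )
  if (!is.null(fit$history) && nrow(fit$history) > 0) {
    report$prune_history <- lapply(seq_len(nrow(fit$history)), function(i) {
      as.list(fit$history[i, ])
    })
  }
  if (!is.null(fit$interval_table)) {
    it <- fit$interval_table
    report$intervals <- lapply(seq_len(nrow(it)), function(i) {
      list(lo = it$lo[i], hi = it$hi[i], entropy = it$entropy[i],
           members = it$members[[i]], fit_order = it$fit_order[i])
    })
  }
  if (!is.null(truth)) {
    full <- setNames(numeric(nrow(td)), td$compound)
    full[intersect(names(truth), td$compound)] <-
      truth[intersect(names(truth), td$compound)]
    report$mae_pct <- composition_mae(td$estimate, unname(full))
    report$accuracy_pct <- classification_accuracy(td$present, full > 0)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
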