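#' Linear shielding-to-shift calibration
#'
#' DFT-calculated isotropic nuclear shieldings map to isotropic chemical
#' shifts through an affine line, `shift = slope * shielding + intercept`.
#' Fitting the line against experimentally observed shifts absorbs the
#' systematic error of the electronic-structure method and acts as a
#' simple rovibrational correction.
#'
#' @param slope Dimensionless slope.
#' @param intercept Intercept, ppm.
#' @param residual_mae Mean absolute residual of the fit, ppm (optional).
#' @param r_squared Coefficient of determination (optional).
#' @return An object of class `calibration_line`.
#' @export
calibration_line <- function(slope, intercept, residual_mae = NA_real_,
                             r_squared = NA_real_) {
  if (!is.finite(slope) || slope == 0) abort("`slope` must be finite and nonzero")
  if (!is.finite(intercept)) abort("`intercept` must be finite")
  structure(
    list(slope = slope, intercept = intercept,
         residual_mae = residual_mae, r_squared = r_squared),
    class = "calibration_line"
  )
}

#' Default proton calibration line
#'
#' The line `shift = -0.9548 * shielding + 30.435` (R^2 = 0.9941, mean
#' absolute residual about 0.1 ppm), obtained from B3LYP/cc-pVTZ gas-phase
#' shieldings of compounds with experimental CDCl3 spectra. Ships as the
#' default because the underlying training spectra are not redistributable;
#' refit with [fit_calibration()] for other levels of theory.
#'
#' @return A `calibration_line`.
#' @export
default_calibration <- function() {
  calibration_line(slope = -0.9548, intercept = 30.435,
                   residual_mae = 0.1, r_squared = 0.9941)
}

#' Convert isotropic shieldings to chemical shifts
#'
#' @param shielding Isotropic shielding(s), ppm.
#' @param line A `calibration_line`; defaults to [default_calibration()].
#' @return Chemical shift(s), ppm.
#' @export
#' @examples
#' shielding_to_shift(25)
shielding_to_shift <- function(shielding, line = default_calibration()) {
  stopifnot(inherits(line, "calibration_line"))
  line$slope * shielding + line$intercept
}

#' Fit a calibration line from (shielding, shift) pairs
#'
#' Ordinary least squares of observed shift on calculated shielding.
#'
#' @param pairs A data frame with columns `shielding` and `shift` (ppm).
#' @return A `calibration_line` carrying the residual MAE and R^2 on the
#'   training pairs.
#' @export
fit_calibration <- function(pairs) {
  if (!all(c("shielding", "shift") %in% names(pairs))) {
    abort("`pairs` needs columns `shielding` and `shift`")
  }
  if (nrow(pairs) < 2 || length(unique(pairs$shielding)) < 2) {
    abort("rank-deficient calibration: need >= 2 distinct shieldings")
  }
  fit <- stats::lm(shift ~ shielding, data = pairs)
  pred <- stats::fitted(fit)
  ss_res <- sum((pairs$shift - pred)^2)
  ss_tot <- sum((pairs$shift - mean(pairs$shift))^2)
  calibration_line(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    residual_mae = mean(abs(pairs$shift - pred)),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  )
}

#' Read calibration pairs from a two-column CSV
#'
#' Columns: shielding, shift (header optional, `#` comments ignored).
#'
#' @param path File path.
#' @return A tibble with columns `shielding` and `shift`.
#' @export
read_calibration_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  fields <- strsplit(trimws(lines), "[,\\s]+")
  first <- suppressWarnings(as.numeric(fields[[1]][1]))
  if (is.na(first)) fields <- fields[-1]  # header row
  tibble(
    shielding = as.numeric(vapply(fields, `[[`, "", 1)),
    shift = as.numeric(vapply(fields, `[[`, "", 2))
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line> shift = %.4f * shielding + %.3f ppm\n",
              x$slope, x$intercept))
  if (is.finite(x$r_squared)) {
    cat(sprintf("  R^2 = %.4f, residual MAE = %.3g ppm\n",
                x$r_squared, x$residual_mae))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration line
#'
#' @param x A `calibration_line`.
#' @param ... Unused.
#' @return One row per coefficient (`slope`, `intercept`).
#' @export
tidy.calibration_line <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' One-row summary of a calibration line
#'
#' @param x A `calibration_line`.
#' @param ... Unused.
#' @export
glance.calibration_line <- function(x, ...) {
  tibble(r_squared = x$r_squared, residual_mae = x$residual_mae)
}
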