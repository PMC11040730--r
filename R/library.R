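#' Describe a candidate compound by its predicted resonances
#'
#' Each resonance is one proton environment: an isotropic chemical shift,
#' a signal weight proportional to the number of equivalent protons, an
#' optional set of J-couplings (each entered once per equivalent-spin group
#' with a multiplicity count), and a Lorentzian natural linewidth. The
#' linewidth encodes the time-domain decay rate lambda through
#' `lambda = pi * fwhm`.
#'
#' @param name Compound identifier (unique within a library).
#' @param shift_ppm Numeric vector of resonance shifts, ppm.
#' @param weight Signal weights (>= 0), recycled. Default 1.
#' @param couplings A list with one element per resonance, each `NULL` or a
#'   data frame with columns `j_hz` (coupling constant, Hz) and `n`
#'   (number of equivalent coupled spins). `NULL` means no couplings.
#' @param fwhm_hz Lorentzian full width at half maximum, Hz, recycled.
#' @param shift_sigma Prior standard deviation of the predicted shifts,
#'   ppm. Use about 0.4 for rule-based predictions, 0.1 for DFT-level
#'   predictions, and 0.01 for shifts taken from spectral libraries.
#' @return A one-row tibble (a library of one compound).
#' @export
#' @examples
#' ethanol_like <- nmr_compound(
#'   "etoh", shift_ppm = c(1.2, 3.7), weight = c(3, 2),
#'   couplings = list(data.frame(j_hz = 7, n = 2), data.frame(j_hz = 7, n = 3)),
#'   shift_sigma = 0.1
#' )
nmr_compound <- function(name, shift_ppm, weight = 1, couplings = NULL,
                         fwhm_hz = 2, shift_sigma = 0.1) {
  nr <- length(shift_ppm)
  if (nr < 1) abort(paste0("compound `", name, "`: needs at least one resonance"))
  weight <- rep_len(weight, nr)
  fwhm_hz <- rep_len(fwhm_hz, nr)
  if (is.null(couplings)) couplings <- rep(list(NULL), nr)
  if (length(couplings) != nr) {
    abort(paste0("compound `", name, "`: `couplings` must have one entry per resonance"))
  }
  couplings <- lapply(couplings, validate_couplings, name = name)
  if (any(!is.finite(shift_ppm))) abort(paste0("compound `", name, "`: shifts must be finite"))
  if (any(weight < 0)) abort(paste0("compound `", name, "`: weights must be >= 0"))
  if (any(fwhm_hz <= 0)) abort(paste0("compound `", name, "`: `fwhm_hz` must be positive"))
  if (!(shift_sigma > 0)) abort(paste0("compound `", name, "`: `shift_sigma` must be positive"))
  res <- tibble(
    shift_ppm = as.numeric(shift_ppm), weight = as.numeric(weight),
    fwhm_hz = as.numeric(fwhm_hz), couplings = couplings
  )
  out <- tibble(name = as.character(name), shift_sigma = shift_sigma,
                resonances = list(res))
  class(out) <- c("nmr_library", class(out))
  out
}

validate_couplings <- function(cp, name) {
  if (is.null(cp) || (is.data.frame(cp) && nrow(cp) == 0)) return(NULL)
  if (!is.data.frame(cp) || !all(c("j_hz", "n") %in% names(cp))) {
    abort(paste0("compound `", name, "`: couplings must be data frames with `j_hz` and `n`"))
  }
  if (any(cp$j_hz < 0)) abort(paste0("compound `", name, "`: negative J-coupling"))
  if (any(cp$n < 1) || any(cp$n != round(cp$n))) {
    abort(paste0("compound `", name, "`: coupling multiplicity `n` must be a positive integer"))
  }
  tibble(j_hz = as.numeric(cp$j_hz), n = as.integer(cp$n))
}

#' Combine compounds into a candidate library
#'
#' @param ... Compounds from [nmr_compound()] or existing libraries.
#' @return A tibble of class `nmr_library` with one row per compound and
#'   columns `name`, `shift_sigma`, `resonances` (list of resonance tables).
#' @export
nmr_library <- function(...) {
  out <- bind_rows(...)
  if (nrow(out) == 0) abort("a library needs at least one compound")
  if (anyDuplicated(out$name)) {
    abort(paste0("duplicate compound names: ",
                 paste(unique(out$name[duplicated(out$name)]), collapse = ", ")))
  }
  if (!inherits(out, "nmr_library")) class(out) <- c("nmr_library", class(out))
  out
}

# flatten a library into one row per resonance (used by the fitter and
# the segmentation module)
library_resonances <- function(lib) {
  purrr::map_dfr(seq_len(nrow(lib)), function(i) {
    res <- lib$resonances[[i]]
    tibble(
      compound = lib$name[i], comp_idx = i,
      res_idx_local = seq_len(nrow(res)),
      shift_ppm = res$shift_ppm, weight = res$weight,
      fwhm_hz = res$fwhm_hz, couplings = res$couplings,
      shift_sigma = lib$shift_sigma[i]
    )
  })
}

#' Read a candidate library from JSON
#'
#' The schema is an array of compounds:
#' `{name, shift_sigma, resonances: [{shift_ppm | shielding, weight,
#' couplings: [{j_hz, n}], fwhm_hz}]}`. When a resonance gives `shielding`
#' instead of `shift_ppm`, the DFT isotropic shielding is converted with
#' the active calibration line.
#'
#' @param path JSON file path.
#' @param calibration A [calibration_line()] for shielding conversion.
#' @return An `nmr_library`.
#' @export
read_library <- function(path, calibration = default_calibration()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.list(raw) && !is.null(raw$compounds)) raw <- raw$compounds
  if (length(raw) == 0) abort("library JSON contains no compounds")
  comps <- lapply(seq_along(raw), function(i) {
    cmp <- raw[[i]]
    where <- paste0("/", i - 1)
    if (is.null(cmp$name)) abort(paste0("library JSON: missing `name` at ", where))
    if (is.null(cmp$resonances) || length(cmp$resonances) == 0) {
      abort(paste0("compound `", cmp$name, "`: empty resonance list (at ", where, ")"))
    }
    shift <- vapply(cmp$resonances, function(r) {
      if (!is.null(r$shift_ppm)) as.numeric(r$shift_ppm)
      else if (!is.null(r$shielding)) shielding_to_shift(as.numeric(r$shielding), calibration)
      else abort(paste0("compound `", cmp$name, "`: resonance lacks `shift_ppm`/`shielding`"))
    }, 1)
    weight <- vapply(cmp$resonances, function(r) as.numeric(r$weight %||% 1), 1)
    fwhm <- vapply(cmp$resonances, function(r) as.numeric(r$fwhm_hz %||% 2), 1)
    cps <- lapply(cmp$resonances, function(r) {
      if (is.null(r$couplings) || length(r$couplings) == 0) return(NULL)
      tibble(
        j_hz = vapply(r$couplings, function(cc) as.numeric(cc$j_hz), 1),
        n = vapply(r$couplings, function(cc) as.integer(cc$n %||% 1L), 1L)
      )
    })
    nmr_compound(cmp$name, shift, weight, cps, fwhm,
                 shift_sigma = as.numeric(cmp$shift_sigma %||% 0.1))
  })
  nmr_library(!!!comps)
}

#' Write a candidate library to JSON
#'
#' @param lib An `nmr_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  payload <- lapply(seq_len(nrow(lib)), function(i) {
    res <- lib$resonances[[i]]
    list(
      name = lib$name[i], shift_sigma = lib$shift_sigma[i],
      resonances = lapply(seq_len(nrow(res)), function(j) {
        cp <- res$couplings[[j]]
        out <- list(shift_ppm = res$shift_ppm[j], weight = res$weight[j],
                    fwhm_hz = res$fwhm_hz[j])
        if (!is.null(cp) && nrow(cp) > 0) {
          out$couplings <- lapply(seq_len(nrow(cp)), function(k) {
            list(j_hz = cp$j_hz[k], n = cp$n[k])
          })
        }
        out
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
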