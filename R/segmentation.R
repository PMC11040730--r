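#' Bernoulli information entropy of a spectral interval
#'
#' The discriminating power of an interval is scored by the entropy of the
#' indicator "a randomly chosen library compound has a predicted line in
#' this interval": with `p = n_members / library_size`,
#' `H = -p log2 p - (1-p) log2 (1-p)` (with `0 log 0 = 0`). Intervals with
#' p near one half are the most informative — fitting them is most likely
#' to rule candidates in or out.
#'
#' @param n_members Number of compounds with at least one predicted line
#'   in the interval (vectorized).
#' @param library_size Total number of candidate compounds.
#' @return Entropy in bits.
#' @export
#' @examples
#' interval_entropy(5, 10)  # 1 bit
interval_entropy <- function(n_members, library_size) {
  if (library_size <= 0) abort("`library_size` must be positive")
  if (any(n_members < 0 | n_members > library_size)) {
    abort("`n_members` must lie in [0, library_size]")
  }
  p <- n_members / library_size
  plogp <- function(q) ifelse(q <= 0, 0, q * log2(q))
  -plogp(p) - plogp(1 - p)
}

#' Segment the spectrum into candidate-informative intervals
#'
#' Builds an interval of +/- `halfwidth_ppm` around every predicted
#' resonance of every library compound, merges overlapping or touching
#' intervals, and records which compounds fall in each merged interval
#' along with its information entropy.
#'
#' @param lib An `nmr_library`.
#' @param halfwidth_ppm Half-width of the seed intervals (default 0.5).
#' @return A tibble with columns `lo`, `hi` (ppm), `members` (list of
#'   compound names), `n_members` and `entropy` (bits), sorted by `lo`.
#' @export
build_intervals <- function(lib, halfwidth_ppm = 0.5) {
  res <- library_resonances(lib)
  seeds <- tibble(lo = res$shift_ppm - halfwidth_ppm,
                  hi = res$shift_ppm + halfwidth_ppm,
                  compound = res$compound) %>% arrange(.data$lo)
  lo <- hi <- numeric(0)
  members <- list()
  for (i in seq_len(nrow(seeds))) {
    k <- length(lo)
    if (k > 0 && seeds$lo[i] <= hi[k]) {
      hi[k] <- max(hi[k], seeds$hi[i])
      members[[k]] <- union(members[[k]], seeds$compound[i])
    } else {
      lo <- c(lo, seeds$lo[i])
      hi <- c(hi, seeds$hi[i])
      members[[k + 1]] <- seeds$compound[i]
    }
  }
  tibble(
    lo = lo, hi = hi, members = members,
    n_members = vapply(members, length, 1L),
    entropy = interval_entropy(vapply(members, length, 1L), nrow(lib))
  )
}

#' Order intervals for sequential fitting
#'
#' Descending information entropy; ties broken from least shielded to most
#' shielded (highest ppm first), mirroring how spectra are read manually.
#'
#' @param intervals Interval table from [build_intervals()].
#' @return The reordered table.
#' @export
rank_intervals <- function(intervals) {
  arrange(intervals, desc(.data$entropy), desc(.data$hi))
}
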