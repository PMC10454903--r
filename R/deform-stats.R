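#' Summarize an elongation-ratio distribution
#'
#' Reduces a sample's per-cell elongation ratios to the standard
#' deformability parameters: the average ER (AER), the median ER (MER), the
#' percentage of undeformable cells (%UDFC, `ER <= udfc_threshold`), the
#' percentage of low-deformable cells (%LDFC, `ER <= ldfc_threshold`), and
#' the coefficient of variation (CV, percent, sample standard deviation
#' over the mean). Both thresholds are inclusive, so a cell at exactly 1.1
#' counts as undeformable and the UDFC set is always a subset of the LDFC
#' set.
#'
#' Undeformable cells barely respond to shear; whether they should enter
#' the average is a judgment call. They are included by default;
#' `exclude_udfc_from_aer = TRUE` computes AER, MER and CV on cells above
#' the UDFC cutoff while the percentage parameters always use all cells.
#'
#' @param er_values numeric vector of per-cell ERs, each finite and `>= 1`.
#' @param udfc_threshold,ldfc_threshold inclusive ER cutoffs
#'   (defaults 1.1 and 1.3).
#' @param exclude_udfc_from_aer compute AER/MER/CV without UDFC cells.
#' @return An object of class `er_distribution`: list with `er_values`,
#'   `n_cells`, `aer`, `mer`, `pct_udfc`, `pct_ldfc`, `cv` (and the
#'   thresholds used).
#' @examples
#' summarize_er(c(1.0, 1.2, 1.4, 1.6))
#' @export
summarize_er <- function(er_values, udfc_threshold = 1.1,
                         ldfc_threshold = 1.3,
                         exclude_udfc_from_aer = FALSE) {
  if (!length(er_values)) stop("no ER values: the distribution is empty")
  if (any(!is.finite(er_values))) {
    stop("all ER values must be finite (flag degenerate cells upstream)")
  }
  if (any(er_values < 1)) {
    stop("contract violation: ER values below 1 must be flagged upstream")
  }
  if (udfc_threshold > ldfc_threshold) {
    stop("udfc_threshold must not exceed ldfc_threshold")
  }
  loc <- if (exclude_udfc_from_aer) {
    kept <- er_values[er_values > udfc_threshold]
    if (!length(kept)) stop("no cells above the UDFC cutoff")
    kept
  } else {
    er_values
  }
  structure(list(
    er_values = er_values,
    n_cells = length(er_values),
    aer = mean(loc),
    mer = median(loc),
    pct_udfc = 100 * mean(er_values <= udfc_threshold),
    pct_ldfc = 100 * mean(er_values <= ldfc_threshold),
    cv = if (length(loc) > 1) 100 * sd(loc) / mean(loc) else 0,
    udfc_threshold = udfc_threshold,
    ldfc_threshold = ldfc_threshold
  ), class = "er_distribution")
}

#' @export
print.er_distribution <- function(x, ...) {
  cat(sprintf(
    "ER distribution: %d cells\n  AER %.4f | MER %.4f | %%UDFC %.1f | %%LDFC %.1f | CV %.2f%%\n",
    x$n_cells, x$aer, x$mer, x$pct_udfc, x$pct_ldfc, x$cv))
  invisible(x)
}

#' @export
as.data.frame.er_distribution <- function(x, ...) {
  data.frame(n_cells = x$n_cells, aer = x$aer, mer = x$mer,
             pct_udfc = x$pct_udfc, pct_ldfc = x$pct_ldfc, cv = x$cv)
}
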