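#' Configuration for a synthetic proteomics + deformability cohort
#'
#' Describes a cohort of `n_samples` RBC samples with `n_proteins`
#' quantified membrane proteins, of which the named `signal_genes` carry a
#' prescribed Pearson correlation with the per-sample average elongation
#' ratio (AER) and a prescribed mutual inter-correlation. Defaults
#' reproduce the reference study conditions: 16 samples, 752 proteins, the
#' 14-protein deformability panel with its reported protein-AER
#' correlations and inter-correlation matrix, AER uniform on
#' \[1.36, 1.83\], and Ln(LFQ) levels centered at 26.55 with SD 0.55 (so a
#' 16-sample draw spans roughly 25.6-27.5, the reported ezrin range).
#'
#' @param n_samples number of samples (default 16).
#' @param n_proteins total proteins including the signal panel
#'   (default 752).
#' @param signal_genes character vector of signal gene symbols.
#' @param target_signal_corr per-gene target Pearson correlation with AER.
#' @param signal_intercorr symmetric unit-diagonal matrix of target
#'   protein-protein correlations for the signal genes (dimnames must
#'   cover `signal_genes`).
#' @param lnlfq_mean,lnlfq_sd per-protein location and scale of Ln(LFQ);
#'   scalars are recycled across proteins.
#' @param aer_range length-2 numeric, the AER range (low < high).
#' @param max_projection_shift warn when the nearest-correlation projection
#'   moves any target entry by more than this (default 0.05): the requested
#'   structure is then unattainable as stated.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples = 16, n_proteins = 752,
                              signal_genes = deformability_protein_panel()$gene,
                              target_signal_corr = deformability_protein_panel()$r,
                              signal_intercorr = deformability_panel_intercorr(),
                              lnlfq_mean = 26.55, lnlfq_sd = 0.55,
                              aer_range = c(1.36, 1.83),
                              max_projection_shift = 0.05, seed = NULL) {
  k <- length(signal_genes)
  if (length(target_signal_corr) != k) {
    stop("target_signal_corr must have one entry per signal gene")
  }
  if (any(abs(target_signal_corr) > 1)) {
    stop("target correlations must lie in [-1, 1]")
  }
  if (k > 0) {
    if (!is.matrix(signal_intercorr) ||
        nrow(signal_intercorr) != ncol(signal_intercorr)) {
      stop("signal_intercorr must be a square matrix")
    }
    if (is.null(dimnames(signal_intercorr)) ||
        !all(signal_genes %in% rownames(signal_intercorr))) {
      stop("signal_intercorr dimnames must cover all signal genes")
    }
    signal_intercorr <- signal_intercorr[signal_genes, signal_genes, drop = FALSE]
    if (max(abs(signal_intercorr - t(signal_intercorr))) > 1e-8 ||
        max(abs(diag(signal_intercorr) - 1)) > 1e-8 ||
        max(abs(signal_intercorr)) > 1 + 1e-8) {
      stop("signal_intercorr must be symmetric with unit diagonal and entries in [-1, 1]")
    }
  }
  if (n_proteins < k) stop("n_proteins must be >= the number of signal genes")
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (length(aer_range) != 2 || aer_range[1] >= aer_range[2]) {
    stop("aer_range must be c(low, high) with low < high")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_proteins = as.integer(n_proteins),
                 signal_genes = signal_genes,
                 target_signal_corr = target_signal_corr,
                 signal_intercorr = signal_intercorr,
                 lnlfq_mean = lnlfq_mean, lnlfq_sd = lnlfq_sd,
                 aer_range = aer_range,
                 max_projection_shift = max_projection_shift,
                 seed = seed),
            class = "cohort_sim_config")
}

#' Simulate a proteomics cohort with a planted deformability signal
#'
#' Draws one joint `(AER, signal proteins)` multivariate-normal sample per
#' cohort and adds independent Gaussian null proteins, so that the signal
#' proteins reproduce both the target protein-AER correlations and the
#' target protein-protein correlations.
#'
#' Construction: a `(1 + k)`-dimensional latent Gaussian is assembled from
#' the protein inter-correlation block and the AER column, projected to
#' the nearest valid correlation matrix ([nearest_correlation()]); the AER
#' margin is then mapped rank-preservingly onto `aer_range` via the normal
#' CDF. Because that uniform margin attenuates Pearson correlations by
#' `sqrt(3/pi)`, the latent AER-protein correlations are pre-scaled by
#' `sqrt(pi/3)` so the *post-transform* correlations hit the targets
#' exactly (the usual NORTA-style margin correction). Signal proteins are
#' scaled to `lnlfq_mean`/`lnlfq_sd`; null proteins are independent
#' homoscedastic Gaussians on the Ln(LFQ) scale with no missingness.
#'
#' @param config a [cohort_sim_config()].
#' @return A list of class `cohort_sim`: `table` (a `protein_quant` with
#'   signal genes first, then `NULL####` genes), `aer` (named per-sample
#'   vector), `latent_target` and `latent_projected` (the assembled and
#'   projected `(1+k)`-dimensional correlation matrices, AER first), and
#'   `projection_shift` (largest entry moved by the projection; a shift
#'   above `config$max_projection_shift` triggers a warning that the
#'   requested structure is unattainable as stated).
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(seed = 1))
#' range(sim$aer)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  k <- length(config$signal_genes)
  target <- diag(k + 1)
  if (k > 0) {
    target[2:(k + 1), 2:(k + 1)] <- config$signal_intercorr
    # NORTA margin correction: the uniform AER margin attenuates Pearson r
    # by sqrt(3/pi); pre-scale the latent correlations to compensate.
    lat <- pmin(pmax(config$target_signal_corr * sqrt(pi / 3), -0.999), 0.999)
    target[1, 2:(k + 1)] <- lat
    target[2:(k + 1), 1] <- lat
  }
  dimnames(target) <- list(c("AER", config$signal_genes),
                           c("AER", config$signal_genes))
  projected <- nearest_correlation(target)
  shift <- attr(projected, "max_shift")
  if (shift > config$max_projection_shift) {
    warning(sprintf(
      "correlation structure unattainable as stated: projection moved an entry by %.3f",
      shift))
  }

  n <- config$n_samples
  p <- config$n_proteins
  mean_p <- rep_len(config$lnlfq_mean, p)
  sd_p <- rep_len(config$lnlfq_sd, p)
  samples <- sprintf("S%02d", seq_len(n))

  draw <- function() {
    z <- MASS::mvrnorm(n, rep(0, k + 1), projected)
    aer <- config$aer_range[1] +
      diff(config$aer_range) * pnorm(z[, 1])
    lnlfq <- matrix(NA_real_, n, p)
    if (k > 0) {
      lnlfq[, seq_len(k)] <- sweep(sweep(z[, -1, drop = FALSE], 2,
                                         sd_p[seq_len(k)], "*"),
                                   2, mean_p[seq_len(k)], "+")
    }
    if (p > k) {
      nul <- seq.int(k + 1, p)
      lnlfq[, nul] <- sweep(sweep(matrix(rnorm(n * length(nul)), n), 2,
                                  sd_p[nul], "*"),
                            2, mean_p[nul], "+")
    }
    list(aer = aer, lnlfq = lnlfq)
  }
  d <- with_seed_opt(config$seed, draw())

  genes <- c(config$signal_genes,
             if (p > k) sprintf("NULL%04d", seq_len(p - k)))
  ids <- paste0("SIM:", sub("/", "-", genes))
  tab <- protein_quant(d$lnlfq, genes, ids, samples,
                       provenance = list(source = "simulate_cohort",
                                         filter_log = integer()))
  structure(list(table = tab, aer = setNames(d$aer, samples),
                 latent_target = target, latent_projected = projected,
                 projection_shift = shift, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "cohort_sim: %d samples x %d proteins (%d signal), AER in [%.2f, %.2f]\n",
    x$config$n_samples, x$config$n_proteins, length(x$config$signal_genes),
    min(x$aer), max(x$aer)))
  invisible(x)
}

#' Write the simulated AER vector as CSV
#'
#' @param sim a `cohort_sim` object (or any named AER vector).
#' @param path output CSV path (columns `sample`, `aer`).
#' @return `path`, invisibly.
#' @export
write_aer_csv <- function(sim, path) {
  aer <- if (inherits(sim, "cohort_sim")) sim$aer else sim
  write.csv(data.frame(sample = names(aer), aer = unname(aer)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample deformability table
#'
#' @param path CSV with columns `sample` and `aer`.
#' @return A named numeric vector of AER values.
#' @export
read_aer_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "aer") %in% names(df))) {
    stop("deformability table must have columns 'sample' and 'aer'")
  }
  setNames(df$aer, df$sample)
}
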