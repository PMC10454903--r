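#' Pearson product-moment correlation with contract checks
#'
#' Thin wrapper around [stats::cor()] that enforces the screening
#' contract: equal lengths of at least 3 and non-degenerate variance in
#' both inputs.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return The Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired observations are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate input: zero variance")
  }
  cor(x, y)
}

#' Two-tailed p-value for a Pearson correlation
#'
#' Computes the exact two-tailed significance of a Pearson coefficient at
#' sample size `n` from the t relation `t = r * sqrt(n - 2) / sqrt(1 -
#' r^2)` on `n - 2` degrees of freedom (equivalently the incomplete-beta
#' form used by [stats::cor.test()]); no normal approximation is involved,
#' which matters at the small cohort sizes this screen targets. The
#' p-value is symmetric in the sign of `r` and monotone decreasing in
#' `|r|`. A perfect correlation (`|r| = 1`) returns `p = 0` flagged as
#' degenerate via the `"degenerate"` attribute.
#'
#' @param r Pearson coefficient(s) in `[-1, 1]`.
#' @param n sample size, `>= 3`.
#' @return p-value(s) in `[0, 1]`, with a logical `"degenerate"`
#'   attribute marking `|r| = 1` entries.
#' @examples
#' r_to_p(0.79, 16)  # ~3e-4
#' @export
r_to_p <- function(r, n) {
  if (any(!is.finite(n)) || any(n < 3)) stop("n must be >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("r must lie in [-1, 1]")
  r <- pmin(pmax(r, -1), 1)
  degen <- abs(r) >= 1 - 1e-15
  p <- numeric(length(r))
  t <- r[!degen] * sqrt(n - 2) / sqrt(1 - r[!degen]^2)
  p[!degen] <- 2 * pt(-abs(t), n - 2)
  p[degen] <- 0
  attr(p, "degenerate") <- degen
  p
}

#' Screen all proteins for correlation with deformability
#'
#' Computes, for every protein column, the Pearson correlation between its
#' Ln(LFQ) level and the per-sample AER, the exact two-tailed p-value, and
#' a selection flag: `selected = (p < p_threshold) & (r > 0)` — a positive
#' association screen with raw (uncorrected) p-values, mirroring how such
#' small-cohort membrane screens are reported. Benjamini-Hochberg q-values
#' are included for transparency but never drive selection. Results are
#' ranked by ascending p, then descending r.
#'
#' @param table a `protein_quant` object, or a samples x proteins numeric
#'   matrix with column names.
#' @param aer per-sample AER vector; if named, aligned to the table's
#'   sample names.
#' @param p_threshold selection cutoff on the two-tailed p (default
#'   0.005).
#' @return A data.frame of class `screen_result` with columns `rank`,
#'   `gene`, `protein_id`, `r`, `p`, `q`, `degenerate`, `selected`;
#'   attributes `n_samples` and `p_threshold`.
#' @export
screen_proteins <- function(table, aer, p_threshold = 0.005) {
  m <- as_lnlfq_matrix(table)
  aer <- align_aer(aer, rownames(m), nrow(m))
  n <- nrow(m)
  if (n < 3) stop("at least 3 complete samples are required")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("degenerate protein column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  r <- as.vector(cor(aer, m))
  p <- r_to_p(r, n)
  degen <- attr(p, "degenerate")
  q <- p.adjust(as.numeric(p), method = "BH")
  ids <- if (inherits(table, "protein_quant")) table$protein_ids else colnames(m)
  out <- data.frame(gene = colnames(m), protein_id = ids,
                    r = r, p = as.numeric(p), q = q,
                    degenerate = degen,
                    selected = as.numeric(p) < p_threshold & r > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$r), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "n_samples") <- n
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Pairwise correlation matrix of selected proteins
#'
#' @param table a `protein_quant` or samples x proteins matrix.
#' @param genes genes to include (default: all columns). At least 2.
#' @return A symmetric correlation matrix with unit diagonal, gene symbols
#'   as dimnames.
#' @export
correlation_matrix <- function(table, genes = NULL) {
  m <- as_lnlfq_matrix(table)
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(m))
    if (length(missing)) {
      stop("gene(s) not in the table: ", paste(missing, collapse = ", "))
    }
    m <- m[, genes, drop = FALSE]
  }
  if (ncol(m) < 1) stop("at least one gene is required")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("degenerate column for gene(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  cm <- cor(m)
  # enforce exact symmetry and unit diagonal against floating-point drift
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  cm
}

#' Split a protein panel by mean inter-correlation
#'
#' Each gene's grouping statistic is the mean of its off-diagonal
#' correlations; genes at or above `threshold` form the highly
#' inter-correlated group 1, the rest group 2. For the reference panel this
#' reproduces the reported 12/2 split, with ezrin and G-adducin in
#' group 2.
#'
#' @param m correlation matrix (symmetric, unit diagonal, named).
#' @param threshold grouping cutoff on the mean off-diagonal r
#'   (default 0.775).
#' @return A list of class `group_split`: `group1`, `group2` (gene
#'   vectors), `statistic` (named per-gene mean off-diagonal r),
#'   `threshold`.
#' @examples
#' split_groups(deformability_panel_intercorr())
#' @export
split_groups <- function(m, threshold = 0.775) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2) {
    stop("m must be a square correlation matrix with at least 2 genes")
  }
  if (is.null(rownames(m))) stop("m must have gene names as dimnames")
  stat <- (rowSums(m) - diag(m)) / (ncol(m) - 1)
  structure(list(group1 = rownames(m)[stat >= threshold],
                 group2 = rownames(m)[stat < threshold],
                 statistic = stat, threshold = threshold),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("group split at mean off-diagonal r >= %.3f\n", x$threshold))
  cat("  group 1 (", length(x$group1), "):",
      paste(x$group1, collapse = ", "), "\n")
  cat("  group 2 (", length(x$group2), "):",
      paste(x$group2, collapse = ", "), "\n")
  invisible(x)
}

# accept protein_quant or plain samples x proteins matrix
as_lnlfq_matrix <- function(table) {
  if (inherits(table, "protein_quant")) return(table$lnlfq)
  if (is.matrix(table) && is.numeric(table)) {
    if (is.null(colnames(table))) {
      stop("a plain matrix needs gene symbols as column names")
    }
    return(table)
  }
  stop("table must be a protein_quant object or a samples x proteins matrix")
}
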