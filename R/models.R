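#' Fit a one- or two-protein linear deformability model
#'
#' Ordinary least squares of the per-sample AER on the Ln(LFQ) level of one
#' or two proteins: `AER = b1*[gene1] (+ b2*[gene2]) + intercept`.
#' Diagnostics report the Pearson correlation between predicted and
#' observed AER (for a single predictor this equals the simple protein-AER
#' correlation), its exact two-tailed p, the sample size, and the residual
#' standard deviation.
#'
#' @param table a `protein_quant` or samples x proteins matrix.
#' @param aer per-sample AER vector (aligned by name when named).
#' @param genes one or two gene symbols.
#' @return An object of class `deformability_model`: `genes`,
#'   `coefficients` (named, AER units per Ln(LFQ) unit), `intercept`,
#'   `diagnostics` (`r`, `p`, `n`, `residual_sd`), `fitted`, `residuals`.
#' @examples
#' x <- matrix(runif(32, 25.6, 27.5), 16, dimnames = list(NULL, c("EZR", "EPB41")))
#' aer <- 0.1964 * x[, "EZR"] - 3.642
#' fit_linear(x, aer, "EZR")
#' @export
fit_linear <- function(table, aer, genes) {
  m <- as_lnlfq_matrix(table)
  if (length(genes) < 1 || length(genes) > 2) {
    stop("genes must name one or two predictors")
  }
  missing <- setdiff(genes, colnames(m))
  if (length(missing)) {
    stop("gene(s) not in the table: ", paste(missing, collapse = ", "))
  }
  aer <- align_aer(aer, rownames(m), nrow(m))
  n <- nrow(m)
  if (n <= length(genes) + 1) {
    stop("need more samples than predictors + 1")
  }
  X <- m[, genes, drop = FALSE]
  if (any(apply(X, 2, sd) == 0)) {
    stop("degenerate predictor: zero variance in ",
         paste(genes[apply(X, 2, sd) == 0], collapse = ", "))
  }
  if (length(genes) == 2 && abs(cor(X[, 1], X[, 2])) > 0.999) {
    stop("singular fit: predictors ", genes[1], " and ", genes[2],
         " are collinear")
  }
  df <- data.frame(.aer = aer, X, check.names = FALSE)
  fit <- lm(.aer ~ ., data = df)
  cf <- coef(fit)
  pred <- fitted(fit)
  r <- cor(pred, aer)
  structure(list(genes = genes,
                 coefficients = setNames(cf[-1], genes),
                 intercept = unname(cf[1]),
                 diagnostics = list(r = r,
                                    p = as.numeric(r_to_p(r, n)),
                                    n = n,
                                    residual_sd = summary(fit)$sigma),
                 fitted = pred, residuals = residuals(fit)),
            class = "deformability_model")
}

#' @export
print.deformability_model <- function(x, ...) {
  terms <- paste(sprintf("%.4g x [%s]", x$coefficients, x$genes),
                 collapse = " + ")
  cat(sprintf("AER = %s %+.4g\n", terms, x$intercept))
  cat(sprintf("  predicted-vs-observed r = %.3f (p = %.3g, n = %d)\n",
              x$diagnostics$r, x$diagnostics$p, x$diagnostics$n))
  invisible(x)
}

#' Predict AER from a fitted deformability model
#'
#' @param model a `deformability_model`.
#' @param table a `protein_quant` or samples x proteins matrix containing
#'   the model's genes.
#' @return A named numeric vector of predicted AER values.
#' @export
predict_aer <- function(model, table) {
  stopifnot(inherits(model, "deformability_model"))
  m <- as_lnlfq_matrix(table)
  missing <- setdiff(model$genes, colnames(m))
  if (length(missing)) {
    stop("gene(s) missing from the table: ", paste(missing, collapse = ", "))
  }
  out <- drop(m[, model$genes, drop = FALSE] %*% model$coefficients) +
    model$intercept
  if (any(!is.finite(out))) stop("non-finite prediction")
  out
}

#' Exhaustive cross-group search for the best two-protein model
#'
#' Fits every pair combining one gene from `split$group1` (the highly
#' inter-correlated group) with one from `split$group2`, and returns the
#' pair whose fitted model maximizes the predicted-vs-observed AER
#' correlation. Ties are broken by the lower absolute inter-correlation of
#' the pair, then lexicographic gene order. The full search log (all pairs
#' with their scores) is returned so the winner can be re-scored
#' independently.
#'
#' @param table a `protein_quant` or samples x proteins matrix.
#' @param aer per-sample AER vector.
#' @param split a `group_split` from [split_groups()]; both groups must be
#'   non-empty and present in the table.
#' @return A list of class `pair_search`: `gene1` (from group 1), `gene2`
#'   (from group 2), `model` (the winning `deformability_model`), and
#'   `log` (data.frame: `gene1`, `gene2`, `r`, `intercorr`, `singular`).
#' @export
select_pair <- function(table, aer, split) {
  stopifnot(inherits(split, "group_split"))
  if (!length(split$group1) || !length(split$group2)) {
    stop("both groups must be non-empty")
  }
  m <- as_lnlfq_matrix(table)
  aer <- align_aer(aer, rownames(m), nrow(m))
  grid <- expand.grid(gene1 = split$group1, gene2 = split$group2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  score <- rep(NA_real_, nrow(grid))
  intercorr <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- c(grid$gene1[i], grid$gene2[i])
    intercorr[i] <- cor(m[, g[1]], m[, g[2]])
    fit_i <- tryCatch(fit_linear(m, aer, g), error = function(e) NULL)
    if (!is.null(fit_i)) score[i] <- fit_i$diagnostics$r
  }
  log <- data.frame(grid, r = score, intercorr = intercorr,
                    singular = is.na(score), stringsAsFactors = FALSE)
  if (all(is.na(score))) stop("all candidate pair fits are singular")
  ord <- order(-score, abs(intercorr), grid$gene1, grid$gene2,
               na.last = TRUE)
  best <- ord[1]
  model <- fit_linear(m, aer, c(grid$gene1[best], grid$gene2[best]))
  structure(list(gene1 = grid$gene1[best], gene2 = grid$gene2[best],
                 model = model, log = log),
            class = "pair_search")
}

#' @export
print.pair_search <- function(x, ...) {
  cat(sprintf("best cross-group pair: %s (group 1) x %s (group 2)\n",
              x$gene1, x$gene2))
  print(x$model)
  invisible(x)
}
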