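# internal constructor for the samples x proteins Ln(LFQ) container
protein_quant <- function(lnlfq, gene_symbols, protein_ids, samples,
                          provenance = list()) {
  stopifnot(is.matrix(lnlfq),
            nrow(lnlfq) == length(samples),
            ncol(lnlfq) == length(gene_symbols),
            length(protein_ids) == length(gene_symbols))
  if (anyDuplicated(gene_symbols)) {
    stop("gene symbols must be unique after deduplication")
  }
  if (any(!is.finite(lnlfq))) {
    stop("Ln(LFQ) matrix must be fully finite after filtering")
  }
  dimnames(lnlfq) <- list(samples, gene_symbols)
  structure(list(lnlfq = lnlfq, gene_symbols = gene_symbols,
                 protein_ids = protein_ids, samples = samples,
                 provenance = provenance),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d samples x %d proteins (Ln LFQ)\n",
              length(x$samples), length(x$gene_symbols)))
  if (length(x$provenance$filter_log)) {
    fl <- x$provenance$filter_log
    cat("  filters:", paste(names(fl), fl, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Reads a tab-separated proteinGroups table with per-sample
#' `"LFQ intensity <name>"` columns into the analysis container. Filtering
#' follows the usual label-free workflow for a small complete-case cohort:
#' rows flagged `Reverse == "+"` or `Potential contaminant == "+"` are
#' removed; an LFQ intensity of 0 is treated as missing; proteins missing
#' in any retained sample are dropped (complete-case; with 16 samples
#' imputation is deliberately avoided); remaining intensities are
#' natural-log transformed (the Ln(LFQ) convention, not log2); duplicate
#' gene symbols are resolved by keeping the row with the highest median
#' intensity. All removals are counted in the filter log, which reconciles:
#' `rows_in = rows_out + reverse + contaminant + missing_dropped +
#' duplicates_dropped`.
#'
#' @param path path to the TSV file.
#' @param sample_map optional named character vector renaming LFQ columns:
#'   names are the column suffixes (the `<name>` part), values the sample
#'   labels to use. Unknown names raise an error naming them. `NULL` keeps
#'   the file's suffixes.
#' @return A `protein_quant` object: `lnlfq` (samples x proteins matrix of
#'   Ln-transformed intensities), `gene_symbols`, `protein_ids`, `samples`,
#'   and `provenance` (source path and filter log).
#' @export
read_protein_groups <- function(path, sample_map = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lfq_cols <- grep("^LFQ intensity ", names(df), value = TRUE)
  if (!length(lfq_cols)) {
    stop("format error: no 'LFQ intensity <sample>' columns in ", path)
  }
  suffixes <- sub("^LFQ intensity ", "", lfq_cols)
  if (!is.null(sample_map)) {
    unknown <- setdiff(names(sample_map), suffixes)
    if (length(unknown)) {
      stop("sample_map names not present in the table: ",
           paste(unknown, collapse = ", "))
    }
    lfq_cols <- paste0("LFQ intensity ", names(sample_map))
    samples <- unname(sample_map)
  } else {
    samples <- suffixes
  }

  rows_in <- nrow(df)
  flag <- function(col) {
    if (col %in% names(df)) !is.na(df[[col]]) & df[[col]] == "+" else rep(FALSE, nrow(df))
  }
  rev_f <- flag("Reverse")
  con_f <- flag("Potential contaminant") & !rev_f
  df2 <- df[!rev_f & !con_f, , drop = FALSE]

  mat <- as.matrix(df2[, lfq_cols, drop = FALSE])
  storage.mode(mat) <- "double"
  mat[mat == 0] <- NA_real_
  complete <- rowSums(!is.finite(mat)) == 0
  n_missing <- sum(!complete)
  df3 <- df2[complete, , drop = FALSE]
  mat <- mat[complete, , drop = FALSE]

  genes <- if ("Gene names" %in% names(df3)) df3[["Gene names"]] else NA_character_
  ids <- if ("Protein IDs" %in% names(df3)) df3[["Protein IDs"]] else NA_character_
  genes <- ifelse(is.na(genes) | genes == "", ids, genes)
  med <- apply(mat, 1, median)
  keep <- rep(TRUE, nrow(mat))
  for (g in unique(genes[duplicated(genes)])) {
    at <- which(genes == g)
    keep[at[-which.max(med[at])]] <- FALSE
  }
  n_dup <- sum(!keep)
  mat <- mat[keep, , drop = FALSE]

  log_counts <- c(rows_in = rows_in, reverse = sum(rev_f),
                  contaminant = sum(con_f), missing_dropped = n_missing,
                  duplicates_dropped = n_dup, rows_out = nrow(mat))
  protein_quant(lnlfq = t(log(mat)),
                gene_symbols = genes[keep],
                protein_ids = ids[keep],
                samples = samples,
                provenance = list(source = path, filter_log = log_counts))
}

#' Write a protein table in the MaxQuant proteinGroups dialect
#'
#' Writes a `protein_quant` object (or the `table` element of a
#' [simulate_cohort()] result) as a tab-separated proteinGroups-style file
#' with raw-scale (exponentiated) LFQ intensities, so that reading it back
#' through [read_protein_groups()] exercises the Ln transform.
#'
#' @param x a `protein_quant` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(x, path) {
  stopifnot(inherits(x, "protein_quant"))
  out <- data.frame(`Protein IDs` = x$protein_ids,
                    `Gene names` = x$gene_symbols,
                    Reverse = "", `Potential contaminant` = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  lfq <- t(exp(x$lnlfq))
  colnames(lfq) <- paste0("LFQ intensity ", x$samples)
  out <- cbind(out, as.data.frame(lfq, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
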