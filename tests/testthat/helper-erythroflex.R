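# match each truth cell to its nearest measured centroid; returns the row
# indices into `cells` (one per truth row)
match_to_truth <- function(cells, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    which.min((cells$cx - truth$cx[i])^2 + (cells$cy - truth$cy[i])^2)
  }, 0L)
}

# independent ellipse rasterizer used as a coordinate fixture for the
# moment estimator: pixel centers on a 0-based grid inside the ellipse
ellipse_coords <- function(cx, cy, a_semi, b_semi, theta) {
  pad <- ceiling(a_semi) + 2
  g <- expand.grid(row = seq(floor(cy) - pad, ceiling(cy) + pad),
                   col = seq(floor(cx) - pad, ceiling(cx) + pad))
  dx <- g$col - cx; dy <- g$row - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a_semi
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_semi
  as.matrix(g[u^2 + v^2 <= 1, c("row", "col")])
}

# small signal-only cohort config (14 panel proteins, no nulls)
panel_only_config <- function(n_samples, seed) {
  cohort_sim_config(n_samples = n_samples, n_proteins = 14, seed = seed)
}

# write a minimal proteinGroups-style TSV from a named list of columns
write_pg_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
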