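test_that("pearson_r matches exact linear relationships", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(1)
  expect_lt(abs(pearson_r(rnorm(1e5), rnorm(1e5))), 0.02)
  expect_error(pearson_r(1:5, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("the t-relation p-value reproduces published screen anchors", {
  expect_equal(signif(as.numeric(r_to_p(0.79, 16)), 1), 3e-4)
  expect_equal(signif(as.numeric(r_to_p(0.75, 16)), 1), 8e-4)
  expect_equal(as.numeric(r_to_p(0, 16)), 1)
  expect_equal(as.numeric(r_to_p(-0.6, 16)), as.numeric(r_to_p(0.6, 16)))
  p1 <- r_to_p(1, 10)
  expect_equal(as.numeric(p1), 0)
  expect_true(attr(p1, "degenerate"))
})

test_that("the t-relation p agrees with a permutation null", {
  # frozen oracle: 10^6 label permutations of this fixed n = 16 dataset
  # give p_perm = 0.346717 (MC se 4.8e-4)
  set.seed(42)
  xy <- MASS::mvrnorm(16, c(0, 0), matrix(c(1, .5, .5, 1), 2))
  r_obs <- cor(xy[, 1], xy[, 2])
  expect_equal(r_obs, 0.2520548853, tolerance = 1e-9)
  expect_lt(abs(as.numeric(r_to_p(r_obs, 16)) - 0.346717), 0.005)
})

test_that("p is monotone in |r| and in n", {
  r <- seq(0.05, 0.95, by = 0.05)
  p <- as.numeric(r_to_p(r, 16))
  expect_true(all(diff(p) < 0))
  n <- c(5, 10, 16, 30, 100)
  pn <- vapply(n, function(k) as.numeric(r_to_p(0.5, k)), 0.0)
  expect_true(all(diff(pn) < 0))
})

test_that("screen ranks by significance and flags exact duplicates of AER", {
  sim <- simulate_cohort(panel_only_config(n_samples = 16, seed = 21))
  m <- cbind(sim$table$lnlfq, MIRROR = sim$aer)
  scr <- screen_proteins(m, sim$aer)
  expect_equal(scr$gene[1], "MIRROR")
  expect_equal(scr$r[1], 1)
  expect_true(scr$degenerate[1])
  expect_equal(scr$p[1], 0)
  expect_true(all(diff(scr$p) >= 0))
  expect_true(all(scr$selected == (scr$p < 0.005 & scr$r > 0)))
  expect_error(screen_proteins(m[1:2, ], sim$aer[1:2]), "3")
})

test_that("screen power on default cohorts matches the Monte-Carlo oracle", {
  # frozen oracle (4000/500 reps of the t-test at the panel effect sizes,
  # n = 16): median total selected = 14; mean planted selected = 10.89
  set.seed(55)
  seeds <- sample.int(1e6, 150)
  stats <- vapply(seeds, function(s) {
    sim <- simulate_cohort(cohort_sim_config(seed = s))
    scr <- screen_proteins(sim$table, sim$aer)
    sel <- scr$gene[scr$selected]
    c(total = length(sel),
      planted = sum(sel %in% deformability_protein_panel()$gene))
  }, c(total = 0, planted = 0))
  expect_gte(median(stats["total", ]), 12)
  expect_lte(median(stats["total", ]), 18)
  se <- sd(stats["planted", ]) / sqrt(ncol(stats))
  expect_lt(abs(mean(stats["planted", ]) - 10.89), 3 * sqrt(se^2 + 0.07^2))
})

test_that("null screens select at the binomial false-positive rate", {
  # under the null, P(p < 0.005 & r > 0) = 0.0025 per protein
  set.seed(66)
  counts <- vapply(1:200, function(i) {
    m <- matrix(rnorm(16 * 752), 16)
    colnames(m) <- sprintf("G%03d", 1:752)
    aer <- runif(16, 1.36, 1.83)
    sum(screen_proteins(m, aer)$selected)
  }, 0.0)
  expected <- 752 * 0.0025
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("permuting the deformability labels destroys the planted signal", {
  sim <- simulate_cohort(cohort_sim_config(seed = 8))
  panel <- deformability_protein_panel()$gene
  set.seed(99)
  recall <- vapply(1:100, function(i) {
    scr <- screen_proteins(sim$table, sample(unname(sim$aer)))
    sum(scr$gene[scr$selected] %in% panel) / length(panel)
  }, 0.0)
  expect_lt(median(recall), 0.2)
})

test_that("correlation_matrix is symmetric, exact and order-invariant", {
  sim <- simulate_cohort(panel_only_config(n_samples = 16, seed = 14))
  m <- sim$table$lnlfq
  cm <- correlation_matrix(m)
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), setNames(rep(1, 14), colnames(m)))
  perm <- sample(nrow(m))
  expect_equal(correlation_matrix(m[perm, ]), cm, tolerance = 1e-12)

  dup <- cbind(A = m[, 1], B = m[, 1])
  expect_equal(correlation_matrix(dup)["A", "B"], 1)
  expect_equal(correlation_matrix(m[, "EZR", drop = FALSE]),
               matrix(1, 1, 1, dimnames = list("EZR", "EZR")))
  bad <- cbind(m, FLAT = rep(2, 16))
  expect_error(correlation_matrix(bad), "FLAT")
})

test_that("large-sample correlation matrices match the projected targets", {
  sim <- simulate_cohort(panel_only_config(n_samples = 1e5, seed = 15))
  cm <- correlation_matrix(sim$table)
  genes <- colnames(cm)
  expect_lt(max(abs(cm - sim$latent_projected[genes, genes])), 0.01)
})

test_that("mean off-diagonal grouping reproduces the reported panel split", {
  split <- split_groups(deformability_panel_intercorr())
  expect_setequal(split$group2, c("EZR", "ADD3"))
  expect_length(split$group1, 12)
  # hand-summed oracle: mean of the 13 printed EZR row entries = 0.700
  expect_equal(round(unname(split$statistic["EZR"]), 3), 0.700)

  m <- matrix(0.9, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(m) <- 1
  expect_length(split_groups(m)$group2, 0)
})
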