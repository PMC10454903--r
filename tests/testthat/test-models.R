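test_that("noiseless fits recover coefficients to machine precision", {
  x <- matrix(seq(25.6, 27.5, length.out = 16), 16,
              dimnames = list(sprintf("S%02d", 1:16), "EZR"))
  aer <- 0.2 * x[, "EZR"] - 3
  fit <- fit_linear(x, aer, "EZR")
  expect_equal(unname(fit$coefficients["EZR"]), 0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, -3, tolerance = 1e-10)
  expect_equal(fit$diagnostics$r, 1)
  expect_equal(mean(fit$residuals), 0, tolerance = 1e-12)
})

test_that("one-predictor diagnostics equal the simple correlation", {
  sim <- simulate_cohort(panel_only_config(n_samples = 16, seed = 17))
  fit <- fit_linear(sim$table, sim$aer, "EZR")
  expect_equal(fit$diagnostics$r,
               cor(sim$table$lnlfq[, "EZR"], unname(sim$aer)),
               tolerance = 1e-12)
  pred <- predict_aer(fit, sim$table)
  expect_equal(unname(pred), unname(fit$fitted), tolerance = 1e-12)
  expect_equal(mean(unname(sim$aer) - pred), 0, tolerance = 1e-12)
})

test_that("prediction evaluates the printed one-parameter model exactly", {
  model <- structure(list(genes = "EZR",
                          coefficients = c(EZR = 0.1964),
                          intercept = -3.642), class = "deformability_model")
  tab <- matrix(26.0, 1, 1, dimnames = list("s1", "EZR"))
  expect_equal(unname(predict_aer(model, tab)), 1.4644, tolerance = 1e-12)
  zero <- structure(list(genes = "EZR", coefficients = c(EZR = 0),
                         intercept = 1.5), class = "deformability_model")
  tab2 <- matrix(rnorm(5, 26.5), 5, 1, dimnames = list(NULL, "EZR"))
  expect_equal(unname(predict_aer(zero, tab2)), rep(1.5, 5))
  expect_error(predict_aer(model, matrix(1, 1, 1, dimnames = list(NULL, "X"))),
               "EZR")
})

test_that("nesting the ezrin model never lowers the in-sample correlation", {
  for (s in 1:10) {
    sim <- simulate_cohort(panel_only_config(n_samples = 16, seed = 200 + s))
    r1 <- fit_linear(sim$table, sim$aer, "EZR")$diagnostics$r
    r2 <- fit_linear(sim$table, sim$aer, c("EZR", "EPB41"))$diagnostics$r
    expect_gte(r2, r1 - 1e-12)
  }
})

test_that("collinear and degenerate predictors fail loudly", {
  x <- matrix(rnorm(32, 26.5, 0.5), 16)
  colnames(x) <- c("A", "B")
  x <- cbind(x, C = x[, "A"])
  aer <- runif(16, 1.36, 1.83)
  expect_error(fit_linear(x, aer, c("A", "C")), "collinear")
  expect_error(fit_linear(x, aer, c("A", "B", "C")), "one or two")
  expect_error(fit_linear(x, aer, "Z"), "Z")
  expect_error(fit_linear(x[1:2, ], aer[1:2], "A"), "more samples")
})

test_that("replicated cohorts recover the printed regression coefficients", {
  # scaled-down version of the recovery runs (full sizes in the
  # acceptance suite): OLS is unbiased, so the replicate mean slope
  # approaches the generating coefficient
  set.seed(31)
  slopes <- vapply(1:100, function(i) {
    ez <- matrix(runif(16, 25.6, 27.5), 16, dimnames = list(NULL, "EZR"))
    aer <- 0.1964 * ez[, 1] - 3.642 + rnorm(16, 0, 0.07)
    unname(fit_linear(ez, aer, "EZR")$coefficients["EZR"])
  }, 0.0)
  expect_lt(abs(mean(slopes) - 0.1964), 3 * sd(slopes) / sqrt(100))

  set.seed(32)
  co <- vapply(1:200, function(i) {
    x <- MASS::mvrnorm(16, c(26.5, 26.5),
                       0.55^2 * matrix(c(1, .71, .71, 1), 2))
    colnames(x) <- c("EZR", "EPB41")
    aer <- 0.129 * x[, 1] + 0.066 * x[, 2] - 4.09 + rnorm(16, 0, 0.05)
    unname(fit_linear(x, aer, c("EZR", "EPB41"))$coefficients["EZR"])
  }, 0.0)
  expect_lt(abs(mean(co) - 0.129), 3 * sd(co) / sqrt(200))
})

test_that("cross-group search returns the trivial pair for singleton groups", {
  x <- matrix(rnorm(48, 26.5, 0.5), 16)
  colnames(x) <- c("A", "B", "D")
  aer <- 1.5 + 0.1 * x[, "A"] - 0.1 * 26.5 + rnorm(16, 0, 0.02)
  split <- structure(list(group1 = "A", group2 = "B",
                          statistic = c(A = 0.9, B = 0.5), threshold = 0.775),
                     class = "group_split")
  res <- select_pair(x, aer, split)
  expect_equal(res$gene1, "A")
  expect_equal(res$gene2, "B")
  expect_equal(nrow(res$log), 1)
})

test_that("the planted best pair wins the exhaustive search", {
  # planted design with population score gap ~0.16 between (EPB41, EZR)
  # and the runner-up; oracle recovery rate 0.977 (600 reps)
  split <- structure(list(group1 = c("EPB41", "STOM"),
                          group2 = c("ADD3", "EZR"),
                          statistic = c(EPB41 = .9, STOM = .9,
                                        ADD3 = .5, EZR = .5),
                          threshold = 0.775), class = "group_split")
  set.seed(44)
  wins <- vapply(1:200, function(i) {
    x <- cbind(MASS::mvrnorm(16, c(26.5, 26.5),
                             0.55^2 * matrix(c(1, .3, .3, 1), 2)),
               matrix(rnorm(32, 26.5, 0.55), 16))
    colnames(x) <- c("EZR", "EPB41", "STOM", "ADD3")
    aer <- 0.129 * x[, "EZR"] + 0.12 * x[, "EPB41"] - 4.09 +
      rnorm(16, 0, 0.05)
    res <- select_pair(x, aer, split)
    res$gene1 == "EPB41" && res$gene2 == "EZR"
  }, NA)
  expect_gte(mean(wins), 0.95)
})

test_that("the search log re-scores consistently", {
  sim <- simulate_cohort(cohort_sim_config(seed = 23))
  scr <- screen_proteins(sim$table, sim$aer)
  cm <- correlation_matrix(sim$table, scr$gene[scr$selected])
  split <- split_groups(cm)
  res <- select_pair(sim$table, sim$aer, split)
  # every logged score must match an independent OLS recomputation
  m <- sim$table$lnlfq
  for (i in seq_len(nrow(res$log))) {
    fit <- lm(unname(sim$aer) ~ m[, res$log$gene1[i]] + m[, res$log$gene2[i]])
    expect_equal(res$log$r[i], cor(fitted(fit), unname(sim$aer)),
                 tolerance = 1e-12)
  }
  expect_equal(res$model$diagnostics$r, max(res$log$r), tolerance = 1e-12)
})
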