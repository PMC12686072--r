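# Contingency-table tests, proportions, Mann-Whitney and correlation blocks.

test_that("chi-square reproduces published clinical association statistics", {
  tabs <- clinical_tables()
  for (nm in names(tabs)) {
    res <- chi_square_test(tabs[[nm]])
    expect_equal(round(res$statistic, 3), unname(clinical_expected[nm]),
                 info = nm)
    expect_gte(res$statistic, 0)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
  }
  lauren <- chi_square_test(tabs$acrg_lauren)
  expect_equal(lauren$df, 4)
})

test_that("chi-square handles independence, degenerate margins and oracles", {
  expect_equal(chi_square_test(matrix(c(10, 20, 20, 40), 2))$statistic, 0)

  set.seed(8)
  for (i in 1:5) {
    tab <- matrix(rpois(12, 20) + 1, 3, 4)
    expect_equal(chi_square_test(tab)$statistic, chisq_oracle(tab),
                 tolerance = 1e-9)
  }

  zm <- rbind(c(5, 10), c(0, 0), c(7, 3))
  expect_warning(res <- chi_square_test(zm), "zero-margin")
  expect_equal(res$df, 1)
  expect_error(suppressWarnings(chi_square_test(rbind(c(5, 10)))),
               "degenerate")
  expect_true(chi_square_test(matrix(c(2, 3, 1, 4), 2))$low_expected)
})

test_that("chi-square obeys permutation, scaling and monotonicity properties", {
  tab <- clinical_tables()$acrg_lauren
  s0 <- chi_square_test(tab)$statistic
  set.seed(2)
  expect_equal(chi_square_test(tab[sample(3), sample(3)])$statistic, s0,
               tolerance = 1e-12)
  expect_equal(chi_square_test(tab * 7)$statistic, 7 * s0,
               tolerance = 1e-9)
  # p monotone decreasing in the statistic at fixed df
  stats_seq <- c(1, 5, 10, 20)
  ps <- pchisq(stats_seq, df = 4, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("association tests build covariate-by-subtype tables with Missing rows", {
  tab <- clinical_tables()$tcga_differentiation
  n <- colSums(tab)
  assignments <- data.frame(
    sample_id = paste0("s", seq_len(sum(tab))),
    subtype = rep(c("EPC", "HPC", "MPC"), n),
    stringsAsFactors = FALSE)
  cats <- c("G1 and G2", "G3", "Uncertain")
  meta <- data.frame(
    sample_id = assignments$sample_id,
    differentiation = unlist(lapply(1:3, function(j)
      rep(cats, tab[, j]))),
    stringsAsFactors = FALSE)
  res <- association_test(assignments, meta, "differentiation")
  expect_equal(round(res$test$statistic, 3), 32.766)
  # excluding Uncertain changes the table
  res2 <- association_test(assignments, meta, "differentiation",
                           include_missing = FALSE)
  expect_equal(nrow(res2$table), 2)
  expect_error(association_test(assignments, meta, "nope"), "unknown")
  # single remaining category degenerates
  meta$flat <- "onlyone"
  expect_error(suppressWarnings(
    association_test(assignments, meta, "flat")), "degenerate")
})

test_that("subtype proportions match published percentages", {
  subtype <- rep(c("EPC", "HPC", "MPC"), c(110, 117, 73))
  pr <- subtype_proportions(subtype)
  expect_equal(pr$table$percent, c(36.7, 39.0, 24.3))
  expect_equal(sum(pr$table$n), 300)

  pr_eq <- subtype_proportions(rep(c("EPC", "HPC", "MPC"), each = 10))
  expect_equal(pr_eq$table$percent, rep(33.3, 3))

  # cluster composition: an HPC cluster of 39 tumor + 1 normal sample
  comp <- subtype_proportions(rep(c("tumor", "normal"), c(39, 1)),
                              group = rep("HPC", 40))
  tab <- comp$table
  expect_equal(tab$percent[tab$subtype == "tumor"], 97.5)
  expect_equal(tab$percent[tab$subtype == "normal"], 2.5)
})

test_that("Mann-Whitney U matches its conventions and the exact oracle", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
  expect_equal(mann_whitney(c(1, 2), c(10, 20))$U, 0)
  expect_equal(mann_whitney(c(10, 20), c(1, 2))$U, 4)

  # exact enumeration agrees with wilcox.test where both are exact
  a <- c(1, 3, 5); b <- c(2, 4)
  res <- mann_whitney(a, b)
  wt <- wilcox.test(a, b, exact = TRUE)
  expect_equal(res$U + 0, unname(3 * 2 - wt$statistic))  # orientation
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
  expect_match(res$method, "exact")

  # normal approximation tracks wilcox.test with ties at larger n
  set.seed(3)
  x <- round(rnorm(25), 1); y <- round(rnorm(30, 0.5), 1)
  big <- mann_whitney(x, y)
  wt2 <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(big$p_value, wt2$p.value, tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("correlation blocks summarize within- and between-panel structure", {
  p <- new_gene_panel(c("E1", "E2", "E3"), c("M1", "M2"))
  base <- c(1, 2, 3, 4, 5, 6)
  x <- rbind(E1 = base, E2 = base, E3 = base,
             M1 = -base, M2 = -base)
  colnames(x) <- paste0("s", 1:6)
  cb <- correlation_blocks(x, p)
  expect_equal(cb$ee, 1)
  expect_equal(cb$mm, 1)
  expect_equal(cb$em, -1)
  expect_equal(cb$matrix, t(cb$matrix))
  expect_equal(unname(diag(cb$matrix)), rep(1, 5))

  # invariant to positive affine per-gene rescaling
  x2 <- x * 3.5 + 11
  cb2 <- correlation_blocks(x2, p)
  expect_equal(cb$em, cb2$em, tolerance = 1e-12)
  expect_error(correlation_blocks(x[, 1:2], p), "3 samples")
})

test_that("simulated normal cohorts are more anti-correlated than tumors", {
  simn <- simulate_cohort(n_samples = 150, tissue = "normal", seed = 42)
  simt <- simulate_cohort(n_samples = 150, tissue = "tumor", seed = 42)
  emn <- correlation_blocks(simn$expression, default_panel())$em
  emt <- correlation_blocks(simt$expression, default_panel())$em
  expect_lt(emn, emt)
  expect_lt(emn, 0)
})
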