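# The classifier core: scores, clustering, labeling, enrichment and the
# end-to-end fit.

make_pm <- function(mat, n_epi) {
  structure(mat,
            subpanel = rep(c("epithelial", "mesenchymal"),
                           c(n_epi, nrow(mat) - n_epi)),
            class = c("panel_matrix", class(mat)))
}

test_that("EMT scores are sub-panel means and delta their difference", {
  m <- rbind(e1 = c(0, 1, 0.5), e2 = c(0, 1, 1.5),
             m1 = c(0, -1, -1), m2 = c(0, -1, 0))
  colnames(m) <- c("zero", "polar", "toy")
  sc <- compute_emt_scores(make_pm(m, 2))
  expect_equal(sc$epithelial_score, c(0, 1, 1.0))
  expect_equal(sc$mesenchymal_score, c(0, -1, -0.5))
  expect_equal(sc$delta, sc$epithelial_score - sc$mesenchymal_score)
  expect_equal(sc$delta, c(0, 2, 1.5))
})

test_that("correlation distance is a proper bounded dissimilarity", {
  set.seed(21)
  pm <- matrix(rnorm(60), 6, 10,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  D <- as.matrix(pearson_distance(pm))
  expect_true(all(D >= 0 - 1e-12 & D <= 2 + 1e-12))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  pm[, 3] <- 5  # constant vector has no defined correlation
  expect_error(pearson_distance(pm), "s03|s3")
})

test_that("planted orthogonal profiles give pure clusters and zero-height ties", {
  profiles <- cbind(c(2, 2, -1, -1, -1, -1), c(-1, -1, 2, 2, -1, -1),
                    c(-1, -1, -1, -1, 2, 2))
  pm <- toy_panel_matrix(profiles, reps = c(3, 3, 3))
  cl <- cluster_samples(pm, k = 3)
  expect_length(unique(cl$cluster), 3)
  # each planted group is one cluster
  expect_equal(unname(apply(table(rep(1:3, each = 3), cl$cluster), 1, max)),
               c(3, 3, 3))
  # identical samples merge at height 0 first
  expect_equal(cl$tree$height[1:6], rep(0, 6), tolerance = 1e-12)
})

test_that("clustering matches a brute-force complete-linkage oracle (n <= 8)", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:8, 1)
    pm <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:n)))
    D <- pearson_distance(pm)
    tree <- stats::hclust(D, method = "complete")
    oracle <- brute_force_complete_linkage(D)
    expect_equal(sort(tree$height), sort(oracle$heights), tolerance = 1e-12)
    for (k in 2:(n - 1)) {
      expect_true(same_partition(unname(stats::cutree(tree, k)),
                                 oracle$partitions[[k]]))
    }
  }
})

test_that("clustering is invariant to sample column order", {
  set.seed(33)
  pm <- matrix(rnorm(38 * 12), 38, 12,
               dimnames = list(paste0("g", 1:38), paste0("s", 1:12)))
  cl1 <- cluster_samples(pm)$cluster
  perm <- sample(ncol(pm))
  cl2 <- cluster_samples(pm[, perm])$cluster
  expect_true(same_partition(unname(cl1[perm]), unname(cl2)))
})

test_that("merge heights are monotone and small cohorts are rejected", {
  set.seed(5)
  pm <- matrix(rnorm(38 * 15), 38, 15,
               dimnames = list(paste0("g", 1:38), paste0("s", 1:15)))
  tree <- cluster_samples(pm)$tree
  expect_true(all(diff(tree$height) >= -1e-12))
  expect_error(cluster_samples(pm[, 1:2]), "at least 3")
})

test_that("cluster labeling ranks by mean delta with the stated tie-breaks", {
  sc <- function(delta, epi) data.frame(
    sample_id = paste0("s", seq_along(delta)),
    epithelial_score = epi, mesenchymal_score = epi - delta, delta = delta)
  cl <- c(1, 2, 3)
  lab <- label_clusters(cl, sc(c(2.0, 0.1, -1.9), c(1, 0, -1)))
  expect_identical(unname(lab$map[c("1", "2", "3")]),
                   c("EPC", "HPC", "MPC"))
  lab2 <- label_clusters(cl, sc(c(-1.9, 2.0, 0.1), c(-1, 1, 0)))
  expect_identical(unname(lab2$map[c("1", "2", "3")]),
                   c("MPC", "EPC", "HPC"))
  # tied deltas: larger mean epithelial score wins EPC
  lab3 <- label_clusters(cl, sc(c(1.0, 1.0, -1.0), c(0.9, 0.5, 0)))
  expect_identical(unname(lab3$map[c("1", "2", "3")]),
                   c("EPC", "HPC", "MPC"))
  # full tie falls back to smaller cluster index
  lab4 <- label_clusters(cl, sc(c(1, 1, 1), c(0.5, 0.5, 0.5)))
  expect_identical(unname(lab4$map[c("1", "2", "3")]),
                   c("EPC", "HPC", "MPC"))
  # ordering invariant: EPC >= HPC >= MPC mean delta
  for (lab_i in list(lab, lab2, lab3, lab4)) {
    cm <- lab_i$cluster_means
    d <- cm$mean_delta[match(c("EPC", "HPC", "MPC"), cm$subtype)]
    expect_true(all(diff(d) <= 1e-12))
  }
  expect_error(label_clusters(c(1, 1, 2), sc(c(1, 1, 0), c(1, 1, 0))),
               "3 non-empty")
})

test_that("enrichment score follows the normalized mean-rank formula", {
  G <- 100
  expr <- stats::setNames(seq_len(G) / 10, paste0("G", seq_len(G)))
  top10 <- paste0("G", 91:100)
  expect_equal(enrichment_score(expr, top10),
               (95.5 - 50.5) / 49.5, tolerance = 1e-12)
  expect_equal(enrichment_score(expr, names(expr)), 0)
  expect_error(enrichment_score(expr, c("NOPE")), "overlap")
})

test_that("enrichment score is invariant under strictly monotone transforms", {
  set.seed(77)
  for (i in 1:10) {
    expr <- stats::setNames(rnorm(50), paste0("G", 1:50))
    gset <- sample(names(expr), 8)
    base <- enrichment_score(expr, gset)
    expect_equal(enrichment_score(exp(expr), gset), base, tolerance = 1e-12)
    expect_equal(enrichment_score(atan(expr), gset), base, tolerance = 1e-12)
    expect_equal(enrichment_score(3 * expr + 7, gset), base,
                 tolerance = 1e-12)
    expect_gte(base, -1)
    expect_lte(base, 1)
  }
})

test_that("verification reports concordance against enrichment tertiles", {
  n <- 30
  subtype <- factor(rep(c("EPC", "HPC", "MPC"), each = 10),
                    levels = c("EPC", "HPC", "MPC"))
  epi <- c(rnorm(10, 5), rnorm(10, 0), rnorm(10, -5))
  stromal <- -epi
  rep_ideal <- verify_assignments(subtype, epi, stromal)
  expect_equal(unname(rep_ideal$by_subtype), c(1, 1, 1))
  expect_equal(rep_ideal$overall, 1)

  # random labels sit near the permutation chance level
  set.seed(12)
  perm_conc <- replicate(200, {
    verify_assignments(sample(subtype), epi, stromal)$overall
  })
  chance <- mean(perm_conc)
  expect_lt(abs(mean(verify_assignments(sample(subtype), epi,
                                        stromal)$overall) - chance), 0.35)
  expect_lt(chance, 0.75)  # well below the ideal 1.0

  # tertiles undefined for tiny cohorts
  tiny <- verify_assignments(factor("EPC", levels = levels(subtype)), 1, 1)
  expect_true(is.na(tiny$samples$concordant))
})

test_that("the full fit recovers planted labels and validates inputs", {
  p0 <- sim_params(sigma = 1e-6)
  sim <- simulate_cohort(n_samples = 90, params = p0, seed = 13)
  fit <- ehbmt(sim$expression)
  expect_identical(as.character(subtypes(fit)), sim$truth$state)

  expect_error(ehbmt(sim$expression[, 1:2]), "at least 3")

  # determinism: identical input, identical assignments
  fit2 <- ehbmt(sim$expression)
  expect_identical(fit$assignments, fit2$assignments)

  # methods run
  expect_output(print(fit), "EHBMT typing of 90 samples")
  expect_output(print(summary(fit)), "subtype counts")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit, which = "both"))
})
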