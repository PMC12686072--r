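# Independent oracles and small fixture builders shared across tests.

# Brute-force agglomerative clustering with complete linkage: recomputes
# the maximum pairwise member distance between every cluster pair at every
# step. Returns merge heights (in merge order) and the partition at each k.
brute_force_complete_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# TRUE iff two partitions of the same items agree up to label renaming.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(cbind(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Independent k-group log-rank statistic: U' V^- U over distinct event
# times with hypergeometric moments, dropping the last group.
logrank_oracle <- function(time, event, group) {
  group <- factor(group)
  k <- nlevels(group)
  ts <- sort(unique(time[event == 1]))
  U <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ts) {
    at_risk <- time >= t
    N <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g), 0)
    dg <- vapply(levels(group), function(g)
      sum(event == 1 & time == t & group == g), 0)
    U <- U + dg - d * ng / N
    if (N > 1) {
      for (g in seq_len(k)) for (h in seq_len(k)) {
        V[g, h] <- V[g, h] + d * (N - d) / (N - 1) *
          (ng[g] * ((g == h) * N - ng[h])) / N^2
      }
    }
  }
  idx <- seq_len(k - 1L)
  drop(t(U[idx]) %*% solve(V[idx, idx]) %*% U[idx])
}

# Hand-computable product-limit values for the worked survival fixture.
km_fixture <- function() {
  list(time = c(6, 7, 10, 15, 19, 25),
       event = c(1, 0, 1, 1, 0, 1),
       # events at 6 (n=6), 10 (n=4), 15 (n=3), 25 (n=1)
       expected_times = c(6, 10, 15, 25),
       expected_surv = c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0))
}

# Pearson chi-square statistic by explicit cell-by-cell summation.
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / total
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# Count tables typed from published clinical association tables
# (rows = covariate categories, columns = EPC/HPC/MPC).
clinical_tables <- function() {
  list(
    acrg_lauren = matrix(c(74, 51, 21, 26, 60, 48, 10, 6, 4),
                         nrow = 3, byrow = TRUE),
    acrg_pt = matrix(c(80, 76, 32, 23, 34, 34, 7, 7, 7),
                     nrow = 3, byrow = TRUE),
    acrg_pn = matrix(c(16, 13, 9, 50, 61, 20, 25, 28, 27, 19, 15, 17),
                     nrow = 4, byrow = TRUE),
    acrg_ajcc = matrix(c(16, 10, 5, 39, 46, 12, 28, 36, 31, 27, 25, 25),
                       nrow = 4, byrow = TRUE),
    tcga_lauren = matrix(c(68, 72, 21, 13, 31, 30, 42, 74, 22),
                         nrow = 3, byrow = TRUE),
    tcga_differentiation = matrix(c(69, 64, 13, 51, 111, 56, 3, 2, 4),
                                  nrow = 3, byrow = TRUE),
    tcga_pt = matrix(c(13, 5, 1, 108, 169, 69, 2, 3, 3),
                     nrow = 3, byrow = TRUE),
    tcga_race = matrix(c(24, 31, 18, 72, 115, 51, 8, 3, 0, 19, 28, 4),
                       nrow = 4, byrow = TRUE),
    tcga_hpylori = matrix(c(62, 66, 16, 5, 7, 5, 56, 104, 52),
                          nrow = 3, byrow = TRUE))
}

# Statistics the same published tables print, to 3 dp.
clinical_expected <- c(acrg_lauren = 35.229, acrg_pt = 16.573,
                       acrg_pn = 13.753, acrg_ajcc = 17.956,
                       tcga_lauren = 32.687, tcga_differentiation = 32.766,
                       tcga_pt = 13.142, tcga_race = 15.172,
                       tcga_hpylori = 16.374)

# A small panel matrix with planted structure for clustering fixtures.
toy_panel_matrix <- function(profiles, reps, noise = 0, seed = 1) {
  set.seed(seed)
  cols <- do.call(cbind, lapply(seq_len(ncol(profiles)), function(j) {
    matrix(rep(profiles[, j], reps[j]), ncol = reps[j]) +
      matrix(stats::rnorm(nrow(profiles) * reps[j], 0, noise),
             ncol = reps[j])
  }))
  colnames(cols) <- sprintf("s%02d", seq_len(ncol(cols)))
  rownames(cols) <- sprintf("g%02d", seq_len(nrow(profiles)))
  cols
}
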