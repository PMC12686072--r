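# The EHBMT classifier: complete-linkage clustering on 1 - Pearson distance
# over the EMT panel, epi-high/medium/low labelling of the three clusters,
# and rank-based enrichment verification of the labels.

SUBTYPES <- c("EPC", "HPC", "MPC")

#' Per-sample epithelial/mesenchymal summary scores
#'
#' For each sample, the mean z-score over the epithelial panel genes
#' present, the mean over the mesenchymal panel genes, and their difference
#' (delta). Delta operationalizes the epi-high / epi-medium / epi-low axis
#' used to name the clusters.
#'
#' @param pm A \code{"panel_matrix"} from [select_panel()].
#' @return A data.frame with columns \code{sample_id},
#'   \code{epithelial_score}, \code{mesenchymal_score}, \code{delta}.
#' @export
compute_emt_scores <- function(pm) {
  sub <- attr(pm, "subpanel")
  epi <- colMeans(pm[sub == "epithelial", , drop = FALSE])
  mes <- colMeans(pm[sub == "mesenchymal", , drop = FALSE])
  data.frame(sample_id = colnames(pm),
             epithelial_score = unname(epi),
             mesenchymal_score = unname(mes),
             delta = unname(epi - mes),
             stringsAsFactors = FALSE)
}

#' Correlation distance between samples
#'
#' \code{d(i, j) = 1 - cor(x_i, x_j)} over the panel z-score vectors;
#' values lie in [0, 2], zero on the diagonal.
#'
#' @param pm Numeric matrix, genes x samples.
#' @return A \code{dist} object over samples.
#' @export
pearson_distance <- function(pm) {
  v <- apply(pm, 2, stats::sd)
  if (any(v == 0))
    stop("zero-variance panel vector for sample(s): ",
         paste(colnames(pm)[v == 0], collapse = ", "))
  stats::as.dist(1 - stats::cor(pm))
}

#' Cluster samples on the panel
#'
#' Agglomerative clustering of samples with complete linkage on the
#' 1 - Pearson correlation distance between panel z-score vectors; the tree
#' is cut into exactly \code{k} clusters.
#'
#' @param pm A \code{"panel_matrix"} (or any genes x samples matrix with at
#'   least two rows).
#' @param k Number of clusters (default 3).
#' @return A list with the \code{hclust} tree (\code{tree}) and integer
#'   cluster ids per sample (\code{cluster}), named by sample.
#' @export
cluster_samples <- function(pm, k = 3L) {
  if (ncol(pm) < k)
    stop(sprintf("need at least %d samples, got %d", k, ncol(pm)))
  if (nrow(pm) < 2L) stop("need at least 2 panel genes")
  d <- pearson_distance(pm)
  tree <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(tree, k = k)
  list(tree = tree, cluster = cl)
}

#' Label clusters EPC / HPC / MPC
#'
#' Clusters are ranked by their mean delta (epithelial minus mesenchymal
#' score): highest becomes EPC (epi-high), middle HPC (epi-medium), lowest
#' MPC (epi-low). Ties are broken by the larger mean epithelial score, then
#' by the smaller cluster index, so the map cluster -> subtype is always a
#' bijection.
#'
#' @param cluster Integer cluster ids (1..k), named by sample.
#' @param scores Data.frame from [compute_emt_scores()], same sample order.
#' @return A list: \code{subtype} factor per sample, \code{map} named
#'   character vector cluster id -> subtype, and \code{cluster_means}
#'   data.frame of per-cluster mean scores.
#' @export
label_clusters <- function(cluster, scores) {
  ids <- sort(unique(cluster))
  if (length(ids) != 3L)
    stop("exactly 3 non-empty clusters required, got ", length(ids))
  mean_delta <- vapply(ids, function(i) mean(scores$delta[cluster == i]), 0)
  mean_epi <- vapply(ids, function(i)
    mean(scores$epithelial_score[cluster == i]), 0)
  ord <- order(-mean_delta, -mean_epi, ids)
  map <- stats::setNames(character(3L), as.character(ids))
  map[as.character(ids[ord])] <- SUBTYPES
  subtype <- factor(unname(map[as.character(cluster)]), levels = SUBTYPES)
  names(subtype) <- names(cluster)
  list(subtype = subtype,
       map = map,
       cluster_means = data.frame(cluster = ids,
                                  mean_delta = mean_delta,
                                  mean_epithelial = mean_epi,
                                  subtype = unname(map[as.character(ids)])))
}

#' Normalized mean-rank enrichment score
#'
#' A single-sample gene-set score: all G measured genes are ranked within
#' the sample by ascending expression (ties get average rank) and the score
#' is \code{(mean rank of set members - (G + 1) / 2) / ((G - 1) / 2)}, which
#' lies in [-1, 1] and is invariant under any strictly monotone transform of
#' the sample's expression vector. Serves as a rank-based stand-in for
#' deconvolution-style epithelial/stromal scoring.
#'
#' @param expr Named numeric vector: one sample's expression over all genes.
#' @param gene_set Character vector of gene symbols.
#' @return A single numeric score in [-1, 1].
#' @export
enrichment_score <- function(expr, gene_set) {
  if (length(expr) < 2L) stop("need at least 2 measured genes")
  members <- names(expr) %in% canonicalize_genes(gene_set)
  if (!any(members)) stop("gene set has no overlap with measured genes")
  r <- rank(expr, ties.method = "average")
  G <- length(expr)
  (mean(r[members]) - (G + 1) / 2) / ((G - 1) / 2)
}

.tertile_labels <- function(score) {
  # deterministic count-based tertiles; ties resolved toward the lower
  # tertile by rank order
  n <- length(score)
  if (n < 3L)
    return(factor(rep(NA_character_, n), levels = c("low", "medium", "high")))
  r <- rank(score, ties.method = "first")
  lo <- floor(n / 3)
  hi <- n - floor(n / 3)
  lab <- ifelse(r <= lo, "low", ifelse(r > hi, "high", "medium"))
  factor(lab, levels = c("low", "medium", "high"))
}

#' Verify subtype labels against enrichment tertiles
#'
#' Tertile-labels every sample by its epithelial enrichment score and by its
#' stromal enrichment score (cohort tertiles), then checks concordance with
#' the cluster-derived subtype: EPC should be epithelial-high and
#' stromal-low, MPC epithelial-low and stromal-high, HPC anything in
#' between (neither extreme pattern). Discordant samples keep their label
#' but are flagged; verification is a check, not a gate.
#'
#' @param subtype Factor of EPC/HPC/MPC per sample.
#' @param epi_enrich,stromal_enrich Numeric enrichment scores per sample.
#' @return A list: per-sample data.frame (\code{samples}) with tertile
#'   labels and \code{concordant} flag, and per-subtype concordance
#'   fractions (\code{by_subtype}). With fewer than 3 samples tertiles are
#'   undefined and concordance is \code{NA}.
#' @export
verify_assignments <- function(subtype, epi_enrich, stromal_enrich) {
  epi_t <- .tertile_labels(epi_enrich)
  str_t <- .tertile_labels(stromal_enrich)
  concordant <- ifelse(
    is.na(epi_t) | is.na(str_t), NA,
    ifelse(subtype == "EPC", epi_t == "high" & str_t == "low",
    ifelse(subtype == "MPC", epi_t == "low" & str_t == "high",
           !(epi_t == "high" & str_t == "low") &
           !(epi_t == "low" & str_t == "high"))))
  samples <- data.frame(subtype = subtype,
                        epithelial_tertile = epi_t,
                        stromal_tertile = str_t,
                        concordant = concordant)
  by_subtype <- vapply(SUBTYPES, function(s) {
    sel <- subtype == s
    if (!any(sel)) return(NA_real_)
    mean(concordant[sel], na.rm = FALSE)
  }, 0)
  list(samples = samples, by_subtype = by_subtype,
       overall = mean(concordant))
}

#' EMT-heterogeneity-based molecular typing of a cohort
#'
#' The main fitting function. Normalizes the expression matrix, extracts the
#' EMT panel submatrix, clusters the samples by complete linkage on the
#' 1 - Pearson correlation distance, cuts the tree into three clusters,
#' names them EPC / HPC / MPC by their mean epithelial-minus-mesenchymal
#' score, and verifies the labels with rank-based epithelial and stromal
#' enrichment tertiles computed on the full matrix. The whole procedure is
#' deterministic given its inputs.
#'
#' @param x Numeric expression matrix, genes in rows (symbols), samples in
#'   columns, or the result of [read_expression_matrix()].
#' @param panel A \code{"gene_panel"}; defaults to [default_panel()].
#' @param norm Normalization mode passed to [normalize_expression()].
#' @param min_coverage Minimum sub-panel coverage for [select_panel()].
#' @param k Number of clusters; the method is defined for \code{k = 3}.
#' @return An object of class \code{"ehbmt"}: a list with
#'   \describe{
#'     \item{assignments}{data.frame: sample_id, cluster_id, subtype,
#'       epithelial_score, mesenchymal_score, delta, enrichment scores,
#'       tertiles, concordance flag}
#'     \item{tree}{the \code{hclust} dendrogram}
#'     \item{panel_matrix}{the z-scored panel submatrix}
#'     \item{labeling}{cluster -> subtype map and per-cluster means}
#'     \item{verification}{concordance report}
#'     \item{params}{the call parameters, incl. panel name/version}
#'   }
#' @export
#' @examples
#' sim <- simulate_cohort(n_samples = 60, seed = 1)
#' fit <- ehbmt(sim$expression)
#' table(subtypes(fit), sim$truth$state)
ehbmt <- function(x, panel = default_panel(),
                  norm = c("auto", "log_zscore", "zscore_only", "none"),
                  min_coverage = 0.6, k = 3L) {
  norm <- match.arg(norm)
  z <- normalize_expression(x, mode = norm)
  pm <- select_panel(z, panel, min_coverage = min_coverage)
  cl <- cluster_samples(pm, k = k)
  scores <- compute_emt_scores(pm)
  lab <- label_clusters(cl$cluster, scores)
  epi_enrich <- apply(z, 2, enrichment_score, gene_set = panel$epithelial)
  str_enrich <- apply(z, 2, enrichment_score, gene_set = panel$mesenchymal)
  verif <- verify_assignments(lab$subtype, epi_enrich, str_enrich)
  assignments <- data.frame(
    sample_id = scores$sample_id,
    cluster_id = unname(cl$cluster),
    subtype = as.character(lab$subtype),
    epithelial_score = scores$epithelial_score,
    mesenchymal_score = scores$mesenchymal_score,
    delta = scores$delta,
    epithelial_enrichment = unname(epi_enrich),
    stromal_enrichment = unname(str_enrich),
    epithelial_tertile = as.character(verif$samples$epithelial_tertile),
    stromal_tertile = as.character(verif$samples$stromal_tertile),
    concordant = verif$samples$concordant,
    stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 tree = cl$tree,
                 panel_matrix = pm,
                 labeling = lab,
                 verification = verif,
                 params = list(panel = panel$name,
                               panel_version = panel$version,
                               norm = norm,
                               min_coverage = min_coverage,
                               k = k,
                               note = if (panel$name == "ehbmt-default")
                                 "default panel uses ESRP1 for the EARP1 misprint"
                               else NULL)),
            class = "ehbmt")
}

#' Extract subtype labels from a fitted typing
#'
#' @param object An \code{"ehbmt"} fit.
#' @return Factor of EPC/HPC/MPC, named by sample id.
#' @export
subtypes <- function(object) {
  stopifnot(inherits(object, "ehbmt"))
  stats::setNames(factor(object$assignments$subtype, levels = SUBTYPES),
                  object$assignments$sample_id)
}

#' @export
print.ehbmt <- function(x, ...) {
  n <- nrow(x$assignments)
  tab <- table(factor(x$assignments$subtype, levels = SUBTYPES))
  cat(sprintf("EHBMT typing of %d samples (panel '%s' v%s)\n",
              n, x$params$panel, x$params$panel_version))
  for (s in SUBTYPES)
    cat(sprintf("  %s: %3d (%s%%)\n", s, tab[[s]],
                formatC(round(100 * tab[[s]] / n, 1), format = "f",
                        digits = 1)))
  cat(sprintf("Label/enrichment concordance: %.2f\n",
              x$verification$overall))
  invisible(x)
}

#' @export
summary.ehbmt <- function(object, ...) {
  out <- list(counts = table(factor(object$assignments$subtype,
                                    levels = SUBTYPES)),
              cluster_means = object$labeling$cluster_means,
              concordance = object$verification$by_subtype,
              coverage = attr(object$panel_matrix, "coverage"),
              params = object$params)
  class(out) <- "summary.ehbmt"
  out
}

#' @export
print.summary.ehbmt <- function(x, ...) {
  cat("EHBMT subtype counts:\n")
  print(x$counts)
  cat("\nPer-cluster mean scores:\n")
  print(x$cluster_means, row.names = FALSE)
  cat("\nPanel coverage: epithelial",
      formatC(x$coverage[["epithelial"]], format = "f", digits = 2),
      "mesenchymal",
      formatC(x$coverage[["mesenchymal"]], format = "f", digits = 2), "\n")
  cat("Concordance with enrichment tertiles:\n")
  print(round(x$concordance, 3))
  invisible(x)
}

#' Plot a fitted typing
#'
#' Draws the sample dendrogram (colored cut into the three clusters is left
#' to the reader) and the per-sample epithelial vs mesenchymal score
#' scatter, colored by subtype.
#'
#' @param x An \code{"ehbmt"} fit.
#' @param which \code{"scores"}, \code{"dendrogram"}, or \code{"both"}.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.ehbmt <- function(x, which = c("scores", "dendrogram", "both"), ...) {
  which <- match.arg(which)
  cols <- c(EPC = "#1b9e77", HPC = "#7570b3", MPC = "#d95f02")
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("dendrogram", "both"))
    plot(x$tree, labels = FALSE, main = "Complete linkage, 1 - Pearson",
         xlab = "", sub = "", ...)
  if (which %in% c("scores", "both")) {
    a <- x$assignments
    plot(a$epithelial_score, a$mesenchymal_score,
         col = cols[a$subtype], pch = 19,
         xlab = "epithelial score", ylab = "mesenchymal score",
         main = "EMT panel scores", ...)
    graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                     bty = "n")
  }
  invisible(x)
}
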