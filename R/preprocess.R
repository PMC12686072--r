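# Expression normalization and panel-submatrix extraction.

#' Normalize an expression matrix
#'
#' Standard heatmap-style normalization: optional \code{log2(x + 1)}
#' transform followed by a per-gene z-score across samples. The z-score uses
#' the population standard deviation (divide by n); either convention is
#' defensible, but one must be fixed for reproducibility. In \code{auto}
#' mode the log transform is applied only when the matrix maximum exceeds 50
#' (z-scored or log-scale data never reaches that; FPKM and counts do).
#' Genes with zero variance are dropped with a warning, since a z-score is
#' undefined for them.
#'
#' @param x Numeric matrix, genes in rows, samples in columns.
#' @param mode One of \code{"auto"}, \code{"log_zscore"}, \code{"zscore_only"},
#'   \code{"none"}.
#' @return The normalized matrix, with attribute \code{"normalized"} set to
#'   \code{"zscore"} (or \code{"raw"} untouched for mode \code{"none"}).
#' @export
normalize_expression <- function(x, mode = c("auto", "log_zscore",
                                             "zscore_only", "none")) {
  mode <- match.arg(mode)
  if (!all(is.finite(x))) stop("expression values must be finite")
  if (mode == "none") return(x)
  do_log <- switch(mode,
                   auto = max(x) > 50,
                   log_zscore = TRUE,
                   zscore_only = FALSE)
  if (do_log) {
    if (any(x < 0)) stop("negative values: log2(x + 1) transform undefined")
    x <- log2(x + 1)
  }
  mu <- rowMeans(x)
  n <- ncol(x)
  sdev <- sqrt(rowMeans((x - mu)^2))  # population sd
  zero <- sdev == 0
  if (any(zero)) {
    warning("dropping zero-variance gene(s): ",
            paste(rownames(x)[zero], collapse = ", "))
    x <- x[!zero, , drop = FALSE]
    mu <- mu[!zero]
    sdev <- sdev[!zero]
  }
  z <- (x - mu) / sdev
  attr(z, "normalized") <- "zscore"
  z
}

#' Extract the panel submatrix
#'
#' Restricts a z-scored expression matrix to the panel genes present and
#' checks that each sub-panel is sufficiently covered. The method is a panel
#' consensus: below the coverage floor the epithelial/mesenchymal axes are
#' under-determined and the call fails, naming the missing genes.
#'
#' @param x Z-scored numeric matrix (genes x samples).
#' @param panel A \code{"gene_panel"} object.
#' @param min_coverage Minimum fraction of each sub-panel that must be
#'   present (default 0.6).
#' @return A matrix of class \code{"panel_matrix"} restricted to panel
#'   genes, with attributes \code{panel}, \code{coverage} (named fractions
#'   for epithelial and mesenchymal) and the sub-panel membership of each
#'   retained row.
#' @export
select_panel <- function(x, panel, min_coverage = 0.6) {
  stopifnot(inherits(panel, "gene_panel"))
  epi_found <- intersect(panel$epithelial, rownames(x))
  mes_found <- intersect(panel$mesenchymal, rownames(x))
  coverage <- c(epithelial = length(epi_found) / length(panel$epithelial),
                mesenchymal = length(mes_found) / length(panel$mesenchymal))
  if (any(coverage < min_coverage)) {
    missing <- c(setdiff(panel$epithelial, epi_found),
                 setdiff(panel$mesenchymal, mes_found))
    stop(sprintf(
      "panel coverage below %.2f (epithelial %.2f, mesenchymal %.2f); missing: %s",
      min_coverage, coverage[["epithelial"]], coverage[["mesenchymal"]],
      paste(missing, collapse = ", ")))
  }
  keep <- c(epi_found, mes_found)
  pm <- x[keep, , drop = FALSE]
  structure(pm,
            panel = panel,
            coverage = coverage,
            subpanel = c(rep("epithelial", length(epi_found)),
                         rep("mesenchymal", length(mes_found))),
            normalized = attr(x, "normalized"),
            class = c("panel_matrix", class(pm)))
}
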