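# Contingency-table association tests, subtype proportion analysis,
# Mann-Whitney two-group comparison and marker correlation blocks.

#' Round-half-even percentage helper
#'
#' Percentages are reported to 1 decimal place with banker's rounding
#' (round-half-even, base R \code{round}), which reproduces printed figures
#' such as 26/32 = 81.2\%.
#' @noRd
.pct1 <- function(x) round(100 * x, 1)

#' Pearson chi-square test of independence
#'
#' Computes the Pearson statistic \eqn{\sum (O - E)^2 / E} with expected
#' counts \eqn{E = row\_total \cdot col\_total / grand\_total} and no
#' continuity correction for any table size; the p-value is the upper tail
#' of the chi-square distribution at \eqn{df = (r-1)(c-1)}, evaluated with
#' the regularized upper incomplete gamma function (\code{stats::pchisq},
#' \code{lower.tail = FALSE}). Rows or columns whose marginal total is zero
#' are dropped with a warning before testing; a flag marks tables with any
#' expected count below 5.
#'
#' @param counts Numeric matrix of nonnegative counts, at least 2 x 2 after
#'   zero-margin dropping.
#' @return A list of class \code{"chisq_result"}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{expected}, \code{observed},
#'   \code{low_expected} flag.
#' @export
#' @examples
#' lauren <- matrix(c(74, 51, 21, 26, 60, 48, 10, 6, 4),
#'                  nrow = 3, byrow = TRUE)
#' chi_square_test(lauren)$statistic  # 35.229 to 3 dp
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("empty table: zero grand total")
  rz <- rowSums(counts) == 0
  cz <- colSums(counts) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-margin rows/columns")
    counts <- counts[!rz, !cz, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("degenerate table: need at least 2 rows and 2 columns with data")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 expected = res$expected,
                 observed = counts,
                 low_expected = any(res$expected < 5)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (x$low_expected)
    cat("  note: some expected counts < 5\n")
  invisible(x)
}

#' Subtype-by-covariate association test
#'
#' Builds the covariate x subtype contingency table from an assignment set
#' and a metadata table sharing sample ids, then runs [chi_square_test()].
#' Explicit "Missing"/"Uncertain" categories are included as ordinary rows
#' by default, matching how published clinical tables count them.
#'
#' @param assignments Data.frame with \code{sample_id} and \code{subtype}
#'   (e.g. the \code{assignments} slot of an [ehbmt()] fit).
#' @param meta Data.frame from [read_sample_table()].
#' @param covariate Name of a column in \code{meta}.
#' @param include_missing Keep "Missing"/"Uncertain" rows (default TRUE).
#' @return A list: \code{table} (contingency counts) and \code{test}
#'   (\code{"chisq_result"}).
#' @export
association_test <- function(assignments, meta, covariate,
                             include_missing = TRUE) {
  if (!covariate %in% names(meta))
    stop("unknown covariate: ", covariate)
  m <- merge(assignments[, c("sample_id", "subtype")],
             meta[, c("sample_id", covariate)], by = "sample_id")
  if (!include_missing)
    m <- m[!m[[covariate]] %in% c("Missing", "Uncertain"), , drop = FALSE]
  tab <- table(m[[covariate]],
               factor(m$subtype, levels = SUBTYPES))
  tab <- unclass(tab)[, colSums(unclass(tab)) > 0, drop = FALSE]
  list(table = tab, test = chi_square_test(tab))
}

#' Subtype proportion analysis
#'
#' Counts and percentages of each category within each group; percentages
#' to 1 dp with round-half-even. The canonical uses are subtype
#' composition per tissue/cohort group (category = EPC/HPC/MPC) and
#' cluster composition (category = tissue, group = cluster). When more
#' than one group is present the category distribution is also compared
#' across groups by chi-square.
#'
#' @param subtype Category per sample: EPC/HPC/MPC subtypes, or any other
#'   labelling such as tissue status.
#' @param group Optional grouping vector (same length); a single group is
#'   assumed when omitted.
#' @return A list: \code{table} (long data.frame of group, subtype, n,
#'   percent) and \code{test} (\code{"chisq_result"} across groups, or NULL
#'   for a single group).
#' @export
subtype_proportions <- function(subtype, group = NULL) {
  subtype <- as.character(subtype)
  lev <- if (all(subtype %in% SUBTYPES)) SUBTYPES else sort(unique(subtype))
  subtype <- factor(subtype, levels = lev)
  if (is.null(group)) group <- rep("all", length(subtype))
  if (!length(subtype)) stop("empty input")
  counts <- table(group, subtype)
  long <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(long) <- c("group", "subtype", "n")
  totals <- stats::setNames(as.vector(rowSums(counts)), rownames(counts))
  long$percent <- .pct1(long$n / totals[long$group])
  test <- if (nrow(counts) > 1L) chi_square_test(unclass(counts)) else NULL
  list(table = long[order(long$group, long$subtype), ], test = test)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties, oriented as the number of
#' (a, b) pairs with a < b plus half the ties (so U = 0 when every value of
#' group A exceeds every value of group B). For groups of at most 8
#' observations each the two-sided p-value is computed by exact enumeration
#' over all rank splits (valid under ties); larger groups use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return A list: \code{U}, \code{p_value}, \code{method}.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= 8L) {
    # exact enumeration of U over all choose(n1+n2, n1) assignments of the
    # observed midranks to group A
    splits <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    mu <- n1 * n2 / 2
    z <- (abs(U - mu) - 0.5) / sigma
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(1, p)
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method)
}

#' Marker correlation blocks
#'
#' Pairwise Pearson correlations across samples among the panel genes,
#' summarized as the mean within-epithelial (E&E), within-mesenchymal
#' (M&M) and between-panel (E&M) correlation; the unit diagonal is excluded
#' from within-block means. In normal tissue the epithelial and mesenchymal
#' programmes are negatively coupled (E&M well below zero); in tumors the
#' coupling loosens.
#'
#' @param x Expression matrix, genes x samples (any consistent scale;
#'   Pearson r is invariant to per-gene positive affine rescaling).
#' @param panel A \code{"gene_panel"}.
#' @return A list: \code{ee}, \code{mm}, \code{em} (block means) and
#'   \code{matrix} (full pairwise correlation matrix over panel genes).
#' @export
correlation_blocks <- function(x, panel) {
  epi <- intersect(panel$epithelial, rownames(x))
  mes <- intersect(panel$mesenchymal, rownames(x))
  if (ncol(x) < 3L) stop("need at least 3 samples")
  if (length(epi) < 2L || length(mes) < 2L)
    stop("need at least 2 genes per sub-panel present")
  cc <- stats::cor(t(x[c(epi, mes), , drop = FALSE]))
  i_e <- seq_along(epi)
  i_m <- length(epi) + seq_along(mes)
  off_mean <- function(block) mean(block[upper.tri(block)])
  list(ee = off_mean(cc[i_e, i_e, drop = FALSE]),
       mm = off_mean(cc[i_m, i_m, drop = FALSE]),
       em = mean(cc[i_e, i_m]),
       matrix = cc)
}
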