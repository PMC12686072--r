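# Reading and writing the delimited files the package consumes and produces:
# expression matrices (genes x samples), sample metadata tables, and result
# bundles (assignments + statistics + run metadata).

# Minimal symbol alias map applied after uppercasing. EARP1 is a recurrent
# typo for the epithelial splicing regulator ESRP1; C1ORF116 casing variants
# collapse to the uppercase form by the uppercasing step itself.
.gene_aliases <- c(
  EARP1 = "ESRP1"
)

#' Canonicalize gene symbols
#'
#' Uppercases symbols, trims surrounding whitespace and applies a small
#' built-in alias map (e.g. the \code{EARP1} typo maps to \code{ESRP1}).
#' Canonicalization is idempotent.
#'
#' @param genes Character vector of gene symbols.
#' @return Character vector of canonical symbols, same length.
#' @export
#' @examples
#' canonicalize_genes(c("vim", "Cdh1", "EARP1"))
canonicalize_genes <- function(genes) {
  g <- toupper(trimws(as.character(genes)))
  hit <- g %in% names(.gene_aliases)
  g[hit] <- unname(.gene_aliases[g[hit]])
  g
}

.guess_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a gene-expression matrix from delimited text
#'
#' Reads a TSV/CSV file with one header row and one key column into a numeric
#' expression matrix. Gene symbols are canonicalized (uppercased, alias
#' mapped); duplicate gene rows are collapsed by their mean with a warning.
#' Orientation is never auto-detected: state it explicitly.
#'
#' @param path Path to a TSV or CSV file.
#' @param orientation Either \code{"genes_in_rows"} (default: first column is
#'   the gene symbol, remaining columns are samples) or
#'   \code{"samples_in_rows"} (transposed layout).
#' @return A numeric matrix, genes in rows and samples in columns, with a
#'   \code{"normalized"} attribute set to \code{"raw"}.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  keys <- as.character(df[[1L]])
  snames <- names(df)[-1L]  # before subsetting, which uniquifies duplicates
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) & !anyNA(v)) {
        bad <- which(is.na(vn))[1L]
        stop(sprintf("non-numeric value %s at row '%s', column '%s'",
                     dQuote(v[bad]), keys[bad], names(vals)[j]))
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  if (orientation == "samples_in_rows") {
    m <- t(m)
    colnames(m) <- keys
    rownames(m) <- snames
  } else {
    rownames(m) <- keys
    colnames(m) <- snames
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  rownames(m) <- canonicalize_genes(rownames(m))
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    warning("collapsing duplicate gene rows by mean: ",
            paste(dups, collapse = ", "))
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(factor(rownames(m), levels = unique(rownames(m)))))
  }
  if (!all(is.finite(m)))
    stop("expression matrix contains missing or non-finite values")
  attr(m, "normalized") <- "raw"
  m
}

#' Read a sample metadata table
#'
#' Reads a delimited file with a required \code{sample_id} column. Reserved
#' columns are \code{sample_id}, \code{patient_id}, \code{tissue},
#' \code{os_time}, \code{os_event}, \code{dfs_time}, \code{dfs_event}; any
#' other column is retained as a clinical covariate, with blank cells recoded
#' to the explicit category \code{"Missing"}.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @return A data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  if (!"sample_id" %in% names(df)) stop("missing required column 'sample_id'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("tissue" %in% names(df)) {
    bad <- setdiff(unique(df$tissue), c("normal", "tumor", "", NA))
    if (length(bad))
      stop("tissue must be 'normal' or 'tumor'; found: ",
           paste(bad, collapse = ", "))
  }
  for (ev in c("os_event", "dfs_event")) {
    if (ev %in% names(df)) {
      v <- df[[ev]]
      v[v == ""] <- NA
      v <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & !v %in% c(0, 1)))
        stop(ev, " must be 0, 1 or blank")
      df[[ev]] <- v
    }
  }
  for (tm in c("os_time", "dfs_time")) {
    if (tm %in% names(df)) {
      v <- suppressWarnings(as.numeric(df[[tm]]))
      if (any(!is.na(v) & v < 0)) stop(tm, " must be nonnegative")
      df[[tm]] <- v
    }
  }
  reserved <- c("sample_id", "patient_id", "tissue",
                "os_time", "os_event", "dfs_time", "dfs_event")
  for (cn in setdiff(names(df), reserved)) {
    v <- as.character(df[[cn]])
    v[is.na(v) | v == ""] <- "Missing"
    df[[cn]] <- v
  }
  df
}

#' Write a result bundle to a directory
#'
#' Writes the assignments table to \code{assignments.tsv}, each statistics
#' table to \code{stats_<name>.tsv}, and run metadata (panel name/version,
#' parameters, seed, package version) to \code{run_metadata.json}. An empty
#' statistics section is omitted and noted in the returned manifest.
#'
#' @param bundle A list with elements \code{assignments} (data.frame),
#'   \code{statistics} (named list of data.frames, may be empty) and
#'   \code{metadata} (list).
#' @param directory Output directory; created if absent.
#' @return Invisibly, a character vector manifest of files written.
#' @seealso [read_results()] for the inverse.
#' @export
write_results <- function(bundle, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (file.access(directory, mode = 2L) != 0L)
    stop("directory not writable: ", directory)
  manifest <- character(0)
  f <- file.path(directory, "assignments.tsv")
  utils::write.table(bundle$assignments, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- c(manifest, "assignments.tsv")
  stats_tabs <- bundle$statistics
  if (length(stats_tabs)) {
    for (nm in names(stats_tabs)) {
      fn <- paste0("stats_", nm, ".tsv")
      utils::write.table(stats_tabs[[nm]], file.path(directory, fn),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- c(manifest, fn)
    }
  } else {
    manifest <- c(manifest, "(statistics omitted: empty)")
  }
  meta <- bundle$metadata
  meta$tool_version <- as.character(utils::packageVersion("ehbmt"))
  jsonlite::write_json(meta, file.path(directory, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- c(manifest, "run_metadata.json")
  invisible(manifest)
}

#' Read back a result bundle written by [write_results()]
#'
#' @param directory Directory previously populated by [write_results()].
#' @return A bundle list with \code{assignments}, \code{statistics},
#'   \code{metadata}.
#' @export
read_results <- function(directory) {
  assignments <- utils::read.table(file.path(directory, "assignments.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE,
                                   check.names = FALSE)
  stat_files <- list.files(directory, pattern = "^stats_.*\\.tsv$")
  statistics <- list()
  for (fn in stat_files) {
    nm <- sub("^stats_(.*)\\.tsv$", "\\1", fn)
    statistics[[nm]] <- utils::read.table(file.path(directory, fn),
                                          header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE,
                                          check.names = FALSE)
  }
  metadata <- jsonlite::read_json(file.path(directory, "run_metadata.json"),
                                  simplifyVector = TRUE)
  list(assignments = assignments, statistics = statistics,
       metadata = metadata)
}
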