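# The EMT marker panel: canonical built-in signature plus user overrides.

#' The built-in EMT marker panel
#'
#' Returns the canonical panel of classic EMT biomarkers on which the
#' subtyping operates: 22 epithelial signature genes (keratins, junctional
#' and polarity genes, epithelial splicing regulators and transcription
#' factors) and 16 mesenchymal signature genes (the core EMT transcription
#' factors, intermediate filament and extracellular-matrix genes). ESRP1
#' appears in place of the occasionally-seen misprint "EARP1".
#'
#' @return An object of class \code{"gene_panel"}: a list with character
#'   vectors \code{epithelial} and \code{mesenchymal}, plus \code{name} and
#'   \code{version}.
#' @export
#' @examples
#' p <- default_panel()
#' length(p$epithelial)  # 22
#' length(p$mesenchymal) # 16
default_panel <- function() {
  new_gene_panel(
    epithelial = c("KRT18", "KRT19", "CDH1", "EPCAM", "F11R", "ESRP1",
                   "ESRP2", "CLDN1", "CLDN4", "CLDN7", "S100A14", "PRSS8",
                   "PRSS22", "ST14", "ZNF165", "C1ORF116", "KDF1", "CRB3",
                   "ELF3", "HNF4A", "OVOL1", "OVOL2"),
    mesenchymal = c("ZEB1", "ZEB2", "SNAI1", "SNAI2", "TWIST1", "TWIST2",
                    "VIM", "TGFB1", "TGFB2", "TGFB3", "FN1", "SPARC",
                    "COL1A1", "COL1A2", "MMP2", "TCF4"),
    name = "ehbmt-default",
    version = "1.0"
  )
}

#' Construct a validated gene panel
#'
#' @param epithelial,mesenchymal Character vectors of gene symbols; each
#'   non-empty, canonicalized, and mutually disjoint.
#' @param name,version Optional identification strings.
#' @return A \code{"gene_panel"} object.
#' @export
new_gene_panel <- function(epithelial, mesenchymal,
                           name = "custom", version = "0") {
  epithelial <- unique(canonicalize_genes(epithelial))
  mesenchymal <- unique(canonicalize_genes(mesenchymal))
  if (!length(epithelial) || !length(mesenchymal))
    stop("both panel gene lists must be non-empty")
  overlap <- intersect(epithelial, mesenchymal)
  if (length(overlap))
    stop("genes present in both sub-panels: ",
         paste(overlap, collapse = ", "))
  structure(list(epithelial = epithelial, mesenchymal = mesenchymal,
                 name = name, version = version),
            class = "gene_panel")
}

#' Load a gene panel from JSON or YAML
#'
#' The file must provide keys \code{epithelial} and \code{mesenchymal}
#' (lists of gene symbols); \code{name} and \code{version} are optional.
#' Symbols are canonicalized; overlapping symbols are rejected.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{"gene_panel"} object.
#' @export
load_panel <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(x$epithelial) || is.null(x$mesenchymal))
    stop("panel file must define 'epithelial' and 'mesenchymal'")
  new_gene_panel(unlist(x$epithelial), unlist(x$mesenchymal),
                 name = if (is.null(x$name)) basename(path) else x$name,
                 version = if (is.null(x$version)) "0" else x$version)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel '%s' (version %s)\n", x$name, x$version))
  cat(sprintf("  epithelial  (%d): %s\n", length(x$epithelial),
              paste(x$epithelial, collapse = ", ")))
  cat(sprintf("  mesenchymal (%d): %s\n", length(x$mesenchymal),
              paste(x$mesenchymal, collapse = ", ")))
  invisible(x)
}
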