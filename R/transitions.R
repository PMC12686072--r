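# Traceability analysis: pairing normal and tumor samples per patient,
# building the 3x3 subtype transition table, conversion rates and Sankey
# export.

#' Pair normal and tumor samples by patient
#'
#' Patients with exactly one normal and one tumor sample form a pair; all
#' other configurations (tumor-only, normal-only, replicates) are reported
#' unpaired, with a warning for ambiguous patients having replicates of a
#' tissue.
#'
#' @param meta Data.frame with \code{sample_id}, \code{patient_id},
#'   \code{tissue}.
#' @return A list: \code{pairs} (data.frame patient_id, normal_id,
#'   tumor_id) and \code{unpaired} (character vector of sample ids).
#' @export
build_pairs <- function(meta) {
  stopifnot(all(c("sample_id", "patient_id", "tissue") %in% names(meta)))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  sp <- split(meta, meta$patient_id)
  pairs <- list()
  unpaired <- character(0)
  ambiguous <- character(0)
  for (p in names(sp)) {
    d <- sp[[p]]
    nrm <- d$sample_id[d$tissue == "normal"]
    tmr <- d$sample_id[d$tissue == "tumor"]
    if (length(nrm) == 1L && length(tmr) == 1L) {
      pairs[[p]] <- data.frame(patient_id = p, normal_id = nrm,
                               tumor_id = tmr, stringsAsFactors = FALSE)
    } else {
      unpaired <- c(unpaired, d$sample_id)
      if (length(nrm) > 1L || length(tmr) > 1L) ambiguous <- c(ambiguous, p)
    }
  }
  if (length(ambiguous))
    warning("excluding patient(s) with replicate tissue samples: ",
            paste(ambiguous, collapse = ", "))
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(patient_id = character(0), normal_id = character(0),
               tumor_id = character(0), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, unpaired = unpaired)
}

#' Subtype transition table over paired samples
#'
#' Counts patient pairs by (normal-tissue subtype, tumor-tissue subtype);
#' rows and columns are fixed in the order EPC, HPC, MPC, and the grand
#' total equals the number of pairs.
#'
#' @param pairs Data.frame from [build_pairs()] (\code{$pairs}).
#' @param assignments Data.frame with \code{sample_id} and \code{subtype}
#'   covering every paired sample.
#' @return A 3x3 integer matrix, rows = normal subtype, columns = tumor
#'   subtype.
#' @export
transition_table <- function(pairs, assignments) {
  lut <- stats::setNames(as.character(assignments$subtype),
                         assignments$sample_id)
  need <- c(pairs$normal_id, pairs$tumor_id)
  miss <- setdiff(need, names(lut))
  if (length(miss))
    stop("no subtype assignment for paired sample(s): ",
         paste(miss, collapse = ", "))
  from <- factor(lut[pairs$normal_id], levels = SUBTYPES)
  to <- factor(lut[pairs$tumor_id], levels = SUBTYPES)
  tab <- table(from, to)
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(normal = SUBTYPES, tumor = SUBTYPES))
  m
}

#' Subtype conversion rate
#'
#' Percentage of pairs whose normal tissue had subtype \code{from} and
#' whose tumor tissue falls in \code{to}: 100 x count(to) / row total,
#' rounded to 1 dp (round-half-even, so 26/32 prints as 81.2).
#'
#' @param tab 3x3 transition matrix from [transition_table()].
#' @param from Normal-tissue subtype, one of EPC/HPC/MPC.
#' @param to Character vector of tumor-tissue subtypes.
#' @return Percentage, 1 decimal place.
#' @export
#' @examples
#' tab <- matrix(c(6, 12, 14, 0, 0, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
#'               dimnames = list(normal = c("EPC", "HPC", "MPC"),
#'                               tumor = c("EPC", "HPC", "MPC")))
#' conversion_rate(tab, "EPC", c("HPC", "MPC"))  # 81.2
conversion_rate <- function(tab, from, to) {
  from <- match.arg(from, SUBTYPES)
  to <- match.arg(to, SUBTYPES, several.ok = TRUE)
  row_total <- sum(tab[from, ])
  if (row_total == 0)
    stop("no pairs with normal subtype ", from)
  .pct1(sum(tab[from, to]) / row_total)
}

#' Export a transition table as Sankey-style JSON
#'
#' Writes nodes ("normal:EPC", ..., "tumor:MPC") and one link per nonzero
#' cell with \code{value} = count; total link flow equals the pair count.
#' The JSON is renderer-agnostic.
#'
#' @param tab 3x3 transition matrix.
#' @param path Output file path.
#' @return Invisibly, the list structure written.
#' @export
export_sankey <- function(tab, path) {
  nodes <- c(paste0("normal:", SUBTYPES), paste0("tumor:", SUBTYPES))
  links <- list()
  for (i in SUBTYPES) for (j in SUBTYPES) {
    if (tab[i, j] > 0)
      links[[length(links) + 1L]] <- list(source = paste0("normal:", i),
                                          target = paste0("tumor:", j),
                                          value = unname(tab[i, j]))
  }
  out <- list(nodes = as.list(nodes), links = links)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Read a Sankey JSON back into a transition table
#'
#' @param path File written by [export_sankey()].
#' @return 3x3 integer transition matrix.
#' @export
read_sankey <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- matrix(0L, 3, 3, dimnames = list(normal = SUBTYPES, tumor = SUBTYPES))
  for (lk in x$links) {
    i <- sub("^normal:", "", lk$source)
    j <- sub("^tumor:", "", lk$target)
    m[i, j] <- as.integer(lk$value)
  }
  m
}
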