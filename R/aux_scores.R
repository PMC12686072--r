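# Ancillary quantitative procedures: single-cell E/M ratio, mIHC scoring
# and IHC-based CDH1/VIM subtyping.

#' Epithelial-to-mesenchymal cell ratio
#'
#' For an annotated single-cell sample,
#' \code{epithelial / (epithelial + fibroblast + endothelial)}. A zero
#' denominator yields \code{NA} (undefined, not zero).
#'
#' @param epithelial,fibroblast,endothelial Nonnegative cell counts
#'   (vectorized).
#' @return Ratio in [0, 1], or \code{NA} where the denominator is zero.
#' @export
em_ratio <- function(epithelial, fibroblast, endothelial) {
  stopifnot(all(epithelial >= 0), all(fibroblast >= 0),
            all(endothelial >= 0))
  denom <- epithelial + fibroblast + endothelial
  ifelse(denom > 0, epithelial / denom, NA_real_)
}

#' Multiplex IHC staining score
#'
#' The product of the staining intensity score (0-3) and the positive-cell
#' percentage category (0-4), giving an integer in 0-12.
#'
#' @param intensity Integer 0-3 (vectorized).
#' @param percentage Integer 0-4 (vectorized).
#' @return Integer score 0-12.
#' @export
ihc_score <- function(intensity, percentage) {
  if (any(!intensity %in% 0:3)) stop("intensity must be in 0..3")
  if (any(!percentage %in% 0:4)) stop("percentage category must be in 0..4")
  as.integer(intensity) * as.integer(percentage)
}

#' IHC-based EMT subtype from CDH1 and VIM scores
#'
#' Classifies by the CDH1/VIM score ratio r: r >= 3 is EPC, r <= 0.5 is
#' MPC, in between is HPC. VIM = 0 with CDH1 > 0 is EPC (the ratio's
#' limit); both zero is indeterminate rather than guessed.
#'
#' @param cdh1,vim IHC scores in 0-12 (vectorized).
#' @return Character vector: "EPC", "HPC", "MPC" or "indeterminate".
#' @export
ihc_subtype <- function(cdh1, vim) {
  if (any(cdh1 < 0 | cdh1 > 12) || any(vim < 0 | vim > 12))
    stop("scores must lie in 0..12")
  out <- character(length(cdh1))
  both_zero <- cdh1 == 0 & vim == 0
  inf_ratio <- vim == 0 & cdh1 > 0
  r <- ifelse(vim > 0, cdh1 / vim, NA_real_)
  out[both_zero] <- "indeterminate"
  out[inf_ratio] <- "EPC"
  fin <- !both_zero & !inf_ratio
  out[fin & r >= 3] <- "EPC"
  out[fin & r <= 0.5] <- "MPC"
  out[fin & r > 0.5 & r < 3] <- "HPC"
  out
}
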