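#' Log2 fold change against the CD34+ reference
#'
#' Each miRNA measurement is expressed as log2(sample / baseline) so that a
#' positive value indicates upregulation relative to the CD34+ ancestor and a
#' negative value downregulation. Cells where the sample or the baseline is
#' zero or missing are masked (NA); a warning reports how many cells were
#' masked by zero baselines or zero samples.
#'
#' @param table an `hn_abundance`.
#' @param reference an `hn_reference` over the identical feature set.
#' @return an `hn_logfc` with transform `"logFC_vs_reference"`.
#' @export
compute_logfc <- function(table, reference) {
  stopifnot(inherits(table, "hn_abundance"), inherits(reference, "hn_reference"))
  if (!identical(rownames(table$values), names(reference$values))) {
    stop("feature sets of table and reference are not aligned")
  }
  base <- reference$values
  v <- table$values
  bad <- is.na(base) | base <= 0
  out <- log2(sweep(v, 1, ifelse(bad, NA_real_, base), "/"))
  zero_sample <- !is.na(v) & v == 0
  out[zero_sample] <- NA_real_
  n_masked <- sum(is.na(out)) - sum(is.na(v) & !zero_sample)
  if (n_masked > 0) {
    warning(sprintf("%d cells masked by zero/missing baseline or zero sample",
                    n_masked))
  }
  logfc_table(out, space = table$space, transform = "logFC_vs_reference")
}

#' Log2-transformed concentrations
#'
#' The cytokine space is analysed on the log2 concentration scale. A
#' pseudocount (default 1 pg/mL) maps zero concentrations to 0 and preserves
#' ordering.
#'
#' @param table an `hn_abundance`.
#' @param pseudocount non-negative value added before taking log2.
#' @return an `hn_logfc` with transform `"log2_concentration"`.
#' @export
log2_concentration <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "hn_abundance"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  v <- table$values + pseudocount
  out <- ifelse(!is.na(v) & v > 0, log2(v), NA_real_)
  logfc_table(out, space = table$space, transform = "log2_concentration")
}

#' Per-sample sets of extreme features
#'
#' For each sample, the features whose absolute log2 value meets the
#' threshold (inclusive), sorted by decreasing magnitude with ties broken by
#' feature id. This reproduces the "expression value >= |3|" labelling used
#' for the per-stage barplots.
#'
#' @param logfc an `hn_logfc`.
#' @param tau positive threshold on `|value|` (default 3).
#' @return named list (one element per sample code) of character vectors.
#' @export
extreme_features <- function(logfc, tau = 3) {
  stopifnot(inherits(logfc, "hn_logfc"), is.numeric(tau), tau > 0)
  ids <- rownames(logfc$values)
  out <- lapply(seq_len(ncol(logfc$values)), function(j) {
    v <- logfc$values[, j]
    keep <- which(!is.na(v) & abs(v) >= tau)
    keep <- keep[order(-abs(v[keep]), ids[keep])]
    ids[keep]
  })
  names(out) <- colnames(logfc$values)
  out
}
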