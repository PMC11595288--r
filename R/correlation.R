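#' Pearson correlation with pairwise deletion
#'
#' Masked (NA) entries are removed pairwise; at least 3 complete pairs are
#' required. A zero-variance vector makes the correlation undefined and the
#' result is NA.
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson r in [-1, 1], or NA when undefined.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Sample-sample Pearson correlation matrix
#'
#' Correlations between sample profiles over the full feature vector (the
#' Euclidean/parametric view of each space). Pairs with fewer than 3 shared
#' unmasked features, or with a zero-variance profile, are masked.
#'
#' @param logfc an `hn_logfc`.
#' @return object of class `hn_corr`: list with `r` (symmetric matrix,
#'   diagonal 1) and `samples` (the sample key data.frame).
#' @export
sample_correlation_matrix <- function(logfc) {
  stopifnot(inherits(logfc, "hn_logfc"))
  v <- logfc$values
  n <- ncol(v)
  r <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
  obs <- crossprod(!is.na(v))          # shared unmasked features per pair
  r[obs < 3] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, samples = logfc$samples), class = "hn_corr")
}

#' @export
print.hn_corr <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d samples\n", ncol(x$r)))
  invisible(x)
}

#' Within/between-lineage correlation summary
#'
#' Averages the sample-sample correlations inside each lineage block
#' (unordered same-lineage pairs, self-pairs excluded) and across each
#' lineage pair, then aggregates: the overall within (between) mean is the
#' arithmetic mean of the listed per-lineage (per-pair) values, and the
#' within/between ratio is their quotient — the lineage-specificity score of
#' a space.
#'
#' @param corr an `hn_corr`.
#' @return list with `within` (named per-lineage means), `between` (named
#'   per-pair means), `within_mean`, `between_mean`, `ratio`.
#' @export
within_between_summary <- function(corr) {
  stopifnot(inherits(corr, "hn_corr"))
  lin <- corr$samples$lineage
  lineages <- intersect(LINEAGES, unique(lin))
  within <- sapply(lineages, function(L) {
    idx <- which(lin == L)
    if (length(idx) < 2) return(NA_real_)
    m <- corr$r[idx, idx]
    mean(m[upper.tri(m)], na.rm = TRUE)
  })
  pairs <- combn(lineages, 2)
  between <- apply(pairs, 2, function(p)
    mean(corr$r[lin == p[1], lin == p[2]], na.rm = TRUE))
  names(between) <- paste(pairs[1, ], pairs[2, ], sep = ":")
  aggregate_lineage_correlations(within, between)
}

#' Aggregate per-group correlation values
#'
#' Computes overall within- and between-lineage means as arithmetic means of
#' the per-group values, plus their ratio. Works directly on printed summary
#' cells as well as on values computed from a correlation matrix.
#'
#' @param within per-lineage within-lineage mean correlations.
#' @param between per-lineage-pair between-lineage mean correlations.
#' @param digits optional rounding applied to the two overall means before
#'   the ratio is formed (as when reading values off a printed table).
#' @return list with `within`, `between`, `within_mean`, `between_mean`,
#'   `ratio`.
#' @export
aggregate_lineage_correlations <- function(within, between, digits = NULL) {
  wm <- mean(within, na.rm = TRUE)
  bm <- mean(between, na.rm = TRUE)
  if (!is.null(digits)) {
    wm <- round(wm, digits)
    bm <- round(bm, digits)
  }
  list(within = within, between = between,
       within_mean = wm, between_mean = bm, ratio = wm / bm)
}

#' Two-factor ANOVA (additive model, Type II sums of squares)
#'
#' F-tests for two crossed factors on one response, with no interaction term.
#' Type II sums of squares make the test well defined for unbalanced designs:
#' each factor is assessed by the residual-sum-of-squares drop when it is
#' added to the model already containing the other factor.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors (or coercible) with both levels present.
#' @param names_ab labels for the two factor rows of the result.
#' @return data.frame with columns `factor`, `df`, `sum_sq`, `F`, `p`.
#'   Perfect separation yields `F = Inf`, `p = 0`.
#' @export
two_factor_anova <- function(values, factor_a, factor_b,
                             names_ab = c("factor_a", "factor_b")) {
  fa <- as.factor(factor_a)
  fb <- as.factor(factor_b)
  stopifnot(length(values) == length(fa), length(values) == length(fb))
  if (nlevels(droplevels(fa)) < 2 || nlevels(droplevels(fb)) < 2) {
    stop("each factor must have both levels represented")
  }
  if (sd(values) == 0) stop("constant response: F undefined")
  rss <- function(fml) sum(resid(lm(fml))^2)
  rss_full <- rss(values ~ fa + fb)
  df_res <- length(values) - 1L - (nlevels(fa) - 1L) - (nlevels(fb) - 1L)
  ms_res <- rss_full / df_res
  row <- function(name, ss, df) {
    f <- if (ms_res <= .Machine$double.eps * sum(values^2)) Inf else (ss / df) / ms_res
    data.frame(factor = name, df = df, sum_sq = ss, F = f,
               p = pf(f, df, df_res, lower.tail = FALSE))
  }
  out <- rbind(
    row(names_ab[1], rss(values ~ fb) - rss_full, nlevels(fa) - 1L),
    row(names_ab[2], rss(values ~ fa) - rss_full, nlevels(fb) - 1L)
  )
  rownames(out) <- NULL
  out
}

#' @importFrom stats lm resid pf
NULL
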