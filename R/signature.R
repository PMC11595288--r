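#' Coverage filter over time points
#'
#' A feature is retained iff the fraction of its unmasked time points meets
#' the threshold (default 60%), the prerequisite for meaningful clustering of
#' time courses.
#'
#' @param logfc an `hn_logfc` (typically restricted to one lineage's columns).
#' @param min_coverage required unmasked fraction, in (0, 1].
#' @return character vector of retained feature ids.
#' @export
coverage_filter <- function(logfc, min_coverage = 0.6) {
  stopifnot(inherits(logfc, "hn_logfc"),
            min_coverage > 0, min_coverage <= 1)
  frac <- rowMeans(!is.na(logfc$values))
  rownames(logfc$values)[frac >= min_coverage]
}

# mean silhouette width for a clustering, from a full distance matrix
mean_silhouette <- function(d, cluster) {
  n <- length(cluster)
  ks <- sort(unique(cluster))
  sizes <- table(factor(cluster, levels = ks))
  # sum of distances from each point to each cluster
  M <- sapply(ks, function(k) rowSums(d[, cluster == k, drop = FALSE]))
  own <- cbind(seq_len(n), match(cluster, ks))
  a <- M[own] / pmax(sizes[match(cluster, ks)] - 1, 1)
  Mo <- sweep(M, 2, as.numeric(sizes), "/")
  Mo[own] <- Inf
  b <- apply(Mo, 1, min)
  s <- ifelse(sizes[match(cluster, ks)] == 1, 0, (b - a) / pmax(a, b))
  mean(s)
}

#' Select signature miRNAs per lineage by k-means clustering
#'
#' For each lineage, features passing the coverage filter are clustered on
#' their (T1, T2, T3) log2 fold-change time courses with a Euclidean metric.
#' A cluster is called significant when the largest absolute component of its
#' centroid reaches `centroid_tau`; the lineage's signature is the union of
#' the significant clusters' members. The default is a generous fixed
#' `k = 12`: the selection is a union over significance-gated clusters, so it
#' is insensitive to over-clustering, while an automatically chosen coarse k
#' can merge small signature clusters into the dominant near-zero background
#' and lose them. With `k = "auto"` the number of clusters is instead chosen
#' in 2..10 by mean silhouette width (smallest k on ties).
#'
#' @param logfc miRNA `hn_logfc` over all lineages.
#' @param k integer number of clusters, or `"auto"`.
#' @param centroid_tau significance threshold on the centroid max |logFC|.
#' @param min_coverage coverage prerequisite passed to [coverage_filter()].
#' @param lineages lineages to process.
#' @param seed seed for the k-means initialisation (k-means++-style restarts
#'   via `nstart`), making the selection deterministic.
#' @return object of class `hn_selection`: per-lineage ordered id sets,
#'   per-lineage k and centroids, and the selection parameters.
#' @export
kmeans_select <- function(logfc, k = 12, centroid_tau = 2.0,
                          min_coverage = 0.6, lineages = LINEAGES, seed = 1) {
  stopifnot(inherits(logfc, "hn_logfc"))
  res <- list()
  for (L in lineages) {
    idx <- lineage_columns(logfc, L)
    if (length(idx) == 0) stop("no samples for lineage ", L)
    sub <- logfc$values[, idx, drop = FALSE]
    # average replicates per stage so clustering sees one time course
    stages <- logfc$samples$stage[idx]
    tc <- sapply(STAGES[STAGES %in% stages], function(t)
      rowMeans(sub[, stages == t, drop = FALSE], na.rm = TRUE))
    colnames(tc) <- paste(L, colnames(tc), sep = "_")
    keep <- coverage_filter(
      logfc_table(tc, space = logfc$space, transform = logfc$transform),
      min_coverage)
    x <- tc[keep, , drop = FALSE]
    x[is.na(x)] <- 0   # coverage-passing features: treat residual gaps as no displacement
    n_distinct <- nrow(unique(x))
    ks <- if (identical(k, "auto")) 2:min(10, nrow(x) - 1) else k
    if (max(ks) > nrow(x)) stop("k exceeds the number of filtered features")
    ks <- pmin(ks, n_distinct)   # k-means needs distinct initial centers
    ks <- unique(ks)
    d <- if (identical(k, "auto") && length(ks) > 1) as.matrix(dist(x)) else NULL
    fits <- with_seed(seed, lapply(ks, function(kk)
      kmeans(x, centers = kk, nstart = 10, iter.max = 100)))
    pick <- if (identical(k, "auto") && length(ks) > 1) {
      sil <- vapply(fits, function(f) mean_silhouette(d, f$cluster), 0)
      which.max(sil)   # ties: which.max takes the first, i.e. smallest k
    } else 1L
    fit <- fits[[pick]]
    sig_clusters <- which(apply(abs(fit$centers), 1, max) >= centroid_tau)
    res[[L]] <- list(
      selected = sort(names(fit$cluster)[fit$cluster %in% sig_clusters]),
      k = ks[pick], centers = fit$centers, cluster = fit$cluster)
  }
  structure(list(
    selected = lapply(res, `[[`, "selected"),
    k = vapply(res, function(r) as.integer(r$k), 0L),
    centers = lapply(res, `[[`, "centers"),
    cluster = lapply(res, `[[`, "cluster"),
    params = list(k = k, centroid_tau = centroid_tau,
                  min_coverage = min_coverage, seed = seed)
  ), class = "hn_selection")
}

#' @export
print.hn_selection <- function(x, ...) {
  cat("<signature_selection>\n")
  for (L in names(x$selected)) {
    cat(sprintf("  %-3s: %d miRNAs (k = %d)\n", L, length(x$selected[[L]]), x$k[[L]]))
  }
  invisible(x)
}

#' Venn region counts of the per-lineage signature sets
#'
#' Counts over the inclusion-exclusion partition: each miRNA in the union is
#' assigned to the exact subset of lineages whose signature contains it. The
#' disjoint region counts therefore sum to the size of the union.
#'
#' @param selection an `hn_selection`, or a named list of id sets.
#' @return named integer vector over all non-empty lineage subsets (names
#'   like `"E"`, `"E&Mo"`, ..., `"E&Mo&G&Mk"`).
#' @export
venn_counts <- function(selection) {
  sets <- if (inherits(selection, "hn_selection")) selection$selected else selection
  lineages <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  subsets <- unlist(lapply(seq_along(lineages), function(n)
    combn(lineages, n, simplify = FALSE)), recursive = FALSE)
  counts <- vapply(subsets, function(ss) {
    inside <- rowSums(membership[, ss, drop = FALSE]) == length(ss)
    outside <- rowSums(membership[, setdiff(lineages, ss), drop = FALSE]) == 0
    sum(inside & outside)
  }, 0L)
  setNames(counts, vapply(subsets, paste, "", collapse = "&"))
}
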