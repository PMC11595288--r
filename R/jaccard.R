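#' Build the binary presence/absence matrix over significant miRNAs
#'
#' Rows are the union of all selected miRNAs, columns the (lineage, stage)
#' conditions. An entry is 1 when the miRNA belongs to the lineage's
#' signature set and (by default) shows a per-stage log2 fold change of at
#' least `stage_tau` in magnitude, making columns stage-specific; with
#' `mode = "lineage_only"` membership in the lineage set alone suffices, so a
#' lineage's three columns coincide.
#'
#' @param selection an `hn_selection`.
#' @param logfc the miRNA `hn_logfc` (needed for the stage gate).
#' @param stage_tau magnitude gate for per-condition significance.
#' @param mode `"stage_gated"` (default) or `"lineage_only"`.
#' @return binary matrix (class `hn_presence`), rows guaranteed to contain at
#'   least one 1.
#' @export
build_presence_matrix <- function(selection, logfc = NULL, stage_tau = 1,
                                  mode = c("stage_gated", "lineage_only")) {
  mode <- match.arg(mode)
  sets <- selection$selected
  if (all(lengths(sets) == 0)) stop("all selections are empty")
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    warning("empty selection for lineage(s): ", paste(empty, collapse = ", "),
            "; their columns are all zero")
  }
  if (mode == "stage_gated" && is.null(logfc)) {
    stop("stage_gated mode needs the logfc table")
  }
  universe <- sort(unique(unlist(sets)))
  lineages <- names(sets)
  cols <- as.vector(outer(lineages, STAGES, paste, sep = "_"))
  pm <- matrix(0L, length(universe), length(cols),
               dimnames = list(universe, cols))
  for (L in lineages) {
    ids <- sets[[L]]
    if (length(ids) == 0) next
    for (t in STAGES) {
      col <- paste(L, t, sep = "_")
      if (mode == "lineage_only") {
        pm[ids, col] <- 1L
      } else {
        idx <- which(logfc$samples$lineage == L & logfc$samples$stage == t)
        if (length(idx) == 0) next
        v <- rowMeans(logfc$values[ids, idx, drop = FALSE], na.rm = TRUE)
        pm[ids[!is.na(v) & abs(v) >= stage_tau], col] <- 1L
      }
    }
  }
  keep <- rowSums(pm) > 0
  if (any(!keep)) pm <- pm[keep, , drop = FALSE]
  structure(pm, class = c("hn_presence", class(pm)))
}

#' Jaccard distance between two binary vectors
#'
#' `D = 1 - |A intersect B| / |A union B|` on the supports of the two
#' vectors. Undefined (NA, with a warning) when both supports are empty.
#'
#' @param a,b binary (0/1 or logical) vectors of equal length.
#' @return distance in [0, 1], or NA.
#' @export
jaccard_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) {
    warning("both supports empty: Jaccard distance undefined")
    return(NA_real_)
  }
  1 - sum(a & b) / un
}

#' Jaccard distance matrix between the columns of a presence matrix
#'
#' @param pm binary matrix (features x conditions).
#' @return symmetric distance matrix over conditions.
#' @export
jaccard_distance_matrix <- function(pm) {
  m <- ncol(pm)
  x <- (as.matrix(pm) != 0) * 1
  inter <- crossprod(x)
  sums <- colSums(x)
  un <- outer(sums, sums, "+") - inter
  d <- ifelse(un > 0, 1 - inter / un, NA_real_)
  if (anyNA(d)) warning("condition pair(s) with empty joint support")
  diag(d) <- 0
  dimnames(d) <- list(colnames(pm), colnames(pm))
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Torgerson double-centering of `-D^2/2`, eigendecomposition, and scaling of
#' the top positive-eigenvalue axes by `sqrt(lambda)`. Negative eigenvalues
#' (possible because Jaccard matrices need not be Euclidean) are discarded
#' and reported in the diagnostics. Axis signs follow a deterministic
#' convention: the first nonzero loading of each axis is positive.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param dims number of axes requested.
#' @return list with `coords` (conditions x axes), `eigenvalues` (all, sorted
#'   descending), `gof` = (sum of the returned eigenvalues) / (sum of the
#'   positive eigenvalues).
#' @export
pcoa_embed <- function(d, dims = 2) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), all(abs(diag(d)) < 1e-12),
            max(abs(d - t(d))) < 1e-12, all(d >= 0))
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-10 * max(abs(e$values), 1))
  keep <- head(pos, dims)
  if (length(keep) < dims) {
    warning("only ", length(keep), " positive eigenvalue axes available")
  }
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coords = coords, eigenvalues = e$values,
       gof = sum(e$values[keep]) / sum(e$values[pos]))
}

#' Ordinate conditions by Jaccard distance + PCoA
#'
#' Convenience wrapper: distance matrix from the presence matrix, 2-D
#' embedding, and optionally a CD34+ origin point. The origin corresponds to
#' the ancestor state with no significant displacements (an all-zero column,
#' whose Jaccard distance is undefined); it is placed at the centroid of the
#' embedded conditions and flagged in the result rather than entering the
#' distance computation.
#'
#' @param pm an `hn_presence` matrix.
#' @param dims number of axes.
#' @param add_origin append the flagged CD34+ origin point.
#' @return list with `coords`, `distances`, `eigenvalues`, `gof`, `origin`
#'   (row label of the origin point or NULL).
#' @export
ordinate_conditions <- function(pm, dims = 2, add_origin = FALSE) {
  d <- jaccard_distance_matrix(pm)
  emb <- pcoa_embed(d, dims = dims)
  origin <- NULL
  if (add_origin) {
    o <- matrix(colMeans(emb$coords), 1, dimnames = list("CD34", NULL))
    emb$coords <- rbind(emb$coords, o)
    origin <- "CD34"
  }
  list(coords = emb$coords, distances = d, eigenvalues = emb$eigenvalues,
       gof = emb$gof, origin = origin)
}
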