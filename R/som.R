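#' Train a self-organizing map on feature expression profiles
#'
#' Batch SOM on a rectangular grid with a Gaussian neighborhood: features
#' (miRNAs) with similar profiles across the conditions end up on nearby
#' nodes, giving the mosaic view of expression dynamics. Profiles are
#' standardized per feature before training (scaled logFC), the neighborhood
#' radius decays linearly from `max(shape)/2` to 0.1 over the epochs (the
#' final updates are effectively per-node batch means), and the
#' codebook update is the neighborhood-weighted batch mean, so a fixed seed
#' fully determines the trained map.
#'
#' @param logfc an `hn_logfc` (features x conditions).
#' @param shape grid shape, `c(rows, cols)`.
#' @param epochs number of batch updates.
#' @param scale standardize each feature profile to mean 0, sd 1 first.
#' @param seed seed for the codebook initialisation (random feature draws).
#' @return object of class `hn_som`: `codebook` (nodes x conditions),
#'   `assignment` (feature -> node index), `shape`, `grid` (node row/col
#'   layout), `qe` (quantization errors at initialisation and convergence),
#'   `data` (the training matrix, kept for condition projections).
#' @export
train_som <- function(logfc, shape = c(10, 10), epochs = 100,
                      scale = TRUE, seed = 1) {
  stopifnot(inherits(logfc, "hn_logfc"), length(shape) == 2, all(shape >= 1),
            epochs >= 1)
  x <- logfc$values
  if (nrow(x) == 0) stop("empty input: no features to map")
  if (scale) {
    mu <- rowMeans(x, na.rm = TRUE)
    s <- apply(x, 1, sd, na.rm = TRUE)
    s[is.na(s) | s == 0] <- 1
    x <- (x - mu) / s
  }
  x[is.na(x)] <- 0
  n_nodes <- prod(shape)
  grid <- expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2]))
  gd2 <- as.matrix(dist(grid))^2          # squared grid distances
  codebook <- with_seed(seed,
    x[sample(nrow(x), n_nodes, replace = nrow(x) < n_nodes), , drop = FALSE])
  rownames(codebook) <- NULL

  nearest <- function(cb) {
    # argmin_j ||x_i - cb_j||^2 via the expanded inner product
    cross <- x %*% t(cb)
    d2 <- outer(rowSums(x^2), rowSums(cb^2), "+") - 2 * cross
    max.col(-d2, ties.method = "first")
  }
  qe_of <- function(cb, bmu) {
    mean(sqrt(rowSums((x - cb[bmu, , drop = FALSE])^2)))
  }
  bmu <- nearest(codebook)
  qe0 <- qe_of(codebook, bmu)
  r_max <- max(max(shape) / 2, 1)
  r_min <- 0.1   # final epochs are effectively per-node batch (Lloyd) updates
  for (ep in seq_len(epochs)) {
    radius <- r_max + (r_min - r_max) * (ep - 1) / max(epochs - 1, 1)
    bmu <- nearest(codebook)
    h <- exp(-gd2[, bmu, drop = FALSE] / (2 * radius^2))  # nodes x features
    w <- h %*% x
    denom <- rowSums(h)
    upd <- denom > 1e-12
    codebook[upd, ] <- w[upd, , drop = FALSE] / denom[upd]
  }
  bmu <- nearest(codebook)
  structure(list(
    codebook = codebook,
    assignment = setNames(bmu, rownames(x)),
    shape = shape, grid = grid,
    qe = c(init = qe0, final = qe_of(codebook, bmu)),
    data = logfc$values,
    scaled = x,
    params = list(epochs = epochs, scale = scale, seed = seed)
  ), class = "hn_som")
}

#' @export
print.hn_som <- function(x, ...) {
  cat(sprintf("<som> %dx%d grid, %d features, QE %.3f -> %.3f\n",
              x$shape[1], x$shape[2], length(x$assignment),
              x$qe["init"], x$qe["final"]))
  invisible(x)
}

#' Project a condition onto a trained SOM grid
#'
#' The feature-to-node assignment is frozen after training; each node's value
#' for a condition is the mean raw value of its assigned features in that
#' condition (nodes with no features are NA). `condition = "mean"` gives the
#' reference mosaic: the average expression of each feature across all
#' samples.
#'
#' @param som an `hn_som`.
#' @param condition a sample code present in the training table, or
#'   `"mean"`.
#' @return numeric matrix of shape `som$shape` (rows x cols of the grid).
#' @export
project_condition <- function(som, condition) {
  stopifnot(inherits(som, "hn_som"))
  v <- if (identical(condition, "mean")) {
    rowMeans(som$data, na.rm = TRUE)
  } else {
    if (!condition %in% colnames(som$data)) {
      stop("unknown condition '", condition, "'")
    }
    som$data[, condition]
  }
  node_vals <- rep(NA_real_, nrow(som$codebook))
  agg <- tapply(v, som$assignment, mean, na.rm = TRUE)
  node_vals[as.integer(names(agg))] <- agg
  matrix(node_vals, nrow = som$shape[1], ncol = som$shape[2])
}
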