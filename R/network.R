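#' Build a per-lineage bipartite miRNA-cytokine network
#'
#' Implements the four construction constraints: only miRNA-cytokine pairs
#' (no within-space edges), only significantly modified miRNAs (the selected
#' set), only negative correlations, and only near-to-unity correlations
#' (Pearson r at or below the threshold, default -0.9). Correlations are
#' computed over the lineage's stage series; by default the common CD34+
#' origin both series share is prepended (miRNA logFC 0, cytokine baseline
#' log2 concentration), because three stage points alone constrain |r| >= 0.9
#' only weakly.
#'
#' @param mirna_logfc miRNA `hn_logfc` (logFC vs the CD34+ reference).
#' @param cytokine_logfc cytokine `hn_logfc` (log2 concentrations).
#' @param selected character vector of miRNA ids admitted as nodes.
#' @param lineage lineage code.
#' @param r_threshold edge insertion threshold (edge iff r <= r_threshold).
#' @param cytokine_reference optional `hn_reference` supplying the CD34+
#'   supernatant baseline for the origin point.
#' @param pseudocount pseudocount used when the cytokine table was built, so
#'   the baseline is placed on the same scale.
#' @param include_baseline prepend the CD34+ origin to both series (requires
#'   `cytokine_reference`).
#' @param drop_isolated drop nodes with no qualifying edge.
#' @return an igraph graph with vertex attribute `type` ("miRNA" or
#'   "cytokine"), edge attribute `weight` (the Pearson r), and graph
#'   attributes `lineage` and `r_threshold`.
#' @export
build_network <- function(mirna_logfc, cytokine_logfc, selected, lineage,
                          r_threshold = -0.9, cytokine_reference = NULL,
                          pseudocount = 1, include_baseline = !is.null(cytokine_reference),
                          drop_isolated = TRUE) {
  stopifnot(inherits(mirna_logfc, "hn_logfc"), inherits(cytokine_logfc, "hn_logfc"),
            length(selected) > 0, lineage %in% LINEAGES)
  mi <- lineage_columns(mirna_logfc, lineage)
  ci <- lineage_columns(cytokine_logfc, lineage)
  if (!identical(mirna_logfc$samples$code[mi], cytokine_logfc$samples$code[ci])) {
    stop("miRNA and cytokine tables do not share the lineage's sample series")
  }
  selected <- intersect(selected, rownames(mirna_logfc$values))
  mx <- mirna_logfc$values[selected, mi, drop = FALSE]
  cx <- cytokine_logfc$values[, ci, drop = FALSE]
  if (include_baseline) {
    if (is.null(cytokine_reference)) {
      stop("include_baseline = TRUE requires the cytokine reference profile")
    }
    base <- cytokine_reference$values[rownames(cx)]
    mx <- cbind(T0 = 0, mx)
    cx <- cbind(T0 = log2(base + pseudocount), cx)
  }
  if (ncol(mx) < 3) stop("lineage series has fewer than 3 points")
  r <- suppressWarnings(cor(t(mx), t(cx), use = "pairwise.complete.obs"))
  hits <- which(!is.na(r) & r <= r_threshold, arr.ind = TRUE)
  mirna_nodes <- rownames(mx)
  cyt_nodes <- rownames(cx)
  edges <- data.frame(mirna = mirna_nodes[hits[, 1]],
                      cytokine = cyt_nodes[hits[, 2]],
                      weight = r[hits], stringsAsFactors = FALSE)
  nodes <- data.frame(
    name = c(mirna_nodes, cyt_nodes),
    type = rep(c("miRNA", "cytokine"), c(length(mirna_nodes), length(cyt_nodes))),
    stringsAsFactors = FALSE)
  if (drop_isolated) {
    used <- unique(c(edges$mirna, edges$cytokine))
    nodes <- nodes[nodes$name %in% used, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("mirna", "cytokine", "weight")], directed = FALSE,
    vertices = nodes)
  g <- igraph::set_graph_attr(g, "lineage", lineage)
  g <- igraph::set_graph_attr(g, "r_threshold", r_threshold)
  assert_bipartite(g)
  g
}

# post-construction invariant: no edge joins two nodes of the same type
assert_bipartite <- function(g) {
  if (igraph::ecount(g) == 0) return(invisible(g))
  ends <- igraph::ends(g, igraph::E(g))
  type <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  if (any(type[ends[, 1]] == type[ends[, 2]])) {
    stop("internal error: same-type edge in bipartite graph")
  }
  invisible(g)
}

#' Edge betweenness of every edge
#'
#' Number of shortest paths between node pairs traversing each edge, counted
#' fractionally over degenerate shortest paths; geodesics are unweighted
#' regardless of stored correlation weights.
#'
#' @param g an igraph graph.
#' @return numeric vector, one value per edge (ordered as `E(g)`).
#' @export
edge_betweenness_scores <- function(g) {
  igraph::edge_betweenness(g, directed = FALSE, weights = NA)
}

#' Newman modularity of a partition
#'
#' `Q = sum_s (e_ss - a_s^2)`, where `e_ss` is the fraction of edges inside
#' community s and `a_s` the fraction of edge ends attached to s (unweighted
#' edges). A graph with no edges has Q = 0 by convention.
#'
#' @param g an igraph graph.
#' @param membership named (or `V(g)`-ordered) community labels covering the
#'   node set.
#' @return Q in [-0.5, 1].
#' @export
modularity_q <- function(g, membership) {
  g <- ensure_named(g)
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  memb <- align_membership(g, membership)
  ends <- igraph::ends(g, igraph::E(g))
  within <- memb[ends[, 1]] == memb[ends[, 2]]
  deg <- igraph::degree(g)
  e_ss <- tapply(within, memb[ends[, 1]], sum)
  e_ss <- e_ss[!is.na(e_ss)] / m
  a_s <- tapply(deg, memb[names(deg)], sum) / (2 * m)
  sum(e_ss) - sum(a_s^2)
}

# graphs built outside the package may lack vertex names; give positional ones
ensure_named <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

align_membership <- function(g, membership) {
  nm <- igraph::V(g)$name
  if (!is.null(names(membership))) {
    if (!all(nm %in% names(membership))) {
      stop("membership does not cover the node set")
    }
    membership[nm]
  } else {
    stopifnot(length(membership) == length(nm))
    setNames(membership, nm)
  }
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the highest betweenness (recomputed
#' after every removal; ties broken by lexicographic endpoint order), records
#' the connected-component partition after each removal, and returns the
#' partition with maximal modularity over the whole dendrogram. Connected
#' components of the input are the communities at step 0.
#'
#' @param g an igraph graph.
#' @return list of class `hn_partition`: `membership` (named labels), `q`
#'   (modularity of the returned partition on the input graph), and
#'   `dendrogram` (data.frame of removed edges with the modularity after
#'   each removal).
#' @export
girvan_newman <- function(g) {
  stopifnot(igraph::vcount(g) >= 1)
  g <- ensure_named(g)
  comp_membership <- function(h) {
    setNames(igraph::components(h)$membership, igraph::V(h)$name)
  }
  best <- comp_membership(g)
  best_q <- modularity_q(g, best)
  work <- g
  dendro <- data.frame(step = integer(), edge = character(), q = numeric(),
                       stringsAsFactors = FALSE)
  step <- 0
  while (igraph::ecount(work) > 0) {
    step <- step + 1
    eb <- edge_betweenness_scores(work)
    ends <- igraph::ends(work, igraph::E(work))
    key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
    pick <- order(-eb, key)[1]
    work <- igraph::delete_edges(work, pick)
    memb <- comp_membership(work)
    q <- modularity_q(g, memb)
    dendro <- rbind(dendro, data.frame(step = step, edge = key[pick], q = q,
                                       stringsAsFactors = FALSE))
    if (q > best_q) {
      best <- memb
      best_q <- q
    }
  }
  structure(list(membership = best, q = best_q, dendrogram = dendro),
            class = "hn_partition")
}

#' @export
print.hn_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.3f\n",
              length(unique(x$membership)), x$q))
  invisible(x)
}

#' Node topology: degree, within-module degree Z, participation P, roles
#'
#' `Z_i = (kappa_i - mu_s) / sigma_s`, where `kappa_i` counts the links of
#' node i inside its own module and `mu_s`, `sigma_s` are the mean and
#' (population) standard deviation of kappa over that module's nodes
#' (`sigma_s = 0` gives Z = 0). `P_i = 1 - sum_s (K_is / K_i)^2` with `K_is`
#' the links of i into module s (K = 0 gives P = 0). Roles follow the
#' Guimera-Amaral quadrants: high Z marks module hubs, high P marks
#' connectors between modules.
#'
#' @param g an igraph graph.
#' @param partition an `hn_partition` or membership vector.
#' @param z_threshold,p_threshold quadrant thresholds.
#' @return data.frame with one row per node: `node`, `type`, `module`,
#'   `degree`, `z`, `p`, `betweenness`, `role`.
#' @export
node_roles <- function(g, partition, z_threshold = 2.5, p_threshold = 0.62) {
  g <- ensure_named(g)
  memb <- align_membership(g,
    if (inherits(partition, "hn_partition")) partition$membership else partition)
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  mods <- sort(unique(memb))
  # K_is: links of each node into each module
  k_is <- sapply(mods, function(s) rowSums(adj[, memb == s, drop = FALSE]))
  if (length(nm) == 1L) k_is <- matrix(k_is, nrow = 1)
  kappa <- k_is[cbind(seq_along(nm), match(memb, mods))]
  z <- numeric(length(nm))
  for (s in mods) {
    idx <- which(memb == s)
    mu <- mean(kappa[idx])
    sig <- sqrt(mean((kappa[idx] - mu)^2))
    z[idx] <- if (sig == 0) 0 else (kappa[idx] - mu) / sig
  }
  p <- ifelse(deg == 0, 0, 1 - rowSums((k_is / pmax(deg, 1))^2))
  role <- ifelse(z >= z_threshold,
                 ifelse(p >= p_threshold, "hub_connector", "module_hub"),
                 ifelse(p >= p_threshold, "connector", "peripheral"))
  data.frame(
    node = nm,
    type = if (!is.null(igraph::V(g)$type)) igraph::V(g)$type else NA_character_,
    module = as.vector(memb),
    degree = as.vector(deg),
    z = z, p = p,
    betweenness = as.vector(igraph::betweenness(g, directed = FALSE, weights = NA)),
    role = role,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Graph-level network descriptors
#'
#' Edge density over all nodes present, diameter (longest geodesic) within
#' the largest connected component, and Freeman centralization indices for
#' degree, closeness (largest component) and betweenness.
#'
#' @param g an igraph graph.
#' @return list with `density`, `diameter`, `centr_degree`,
#'   `centr_closeness`, `centr_betweenness`, `n_nodes`, `n_edges`.
#' @export
descriptors <- function(g) {
  n <- igraph::vcount(g)
  density <- if (n < 2) NA_real_ else igraph::edge_density(g)
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  diam <- if (igraph::vcount(giant) < 2) 0L else
    igraph::diameter(giant, directed = FALSE, weights = NA)
  list(
    density = density,
    diameter = as.integer(diam),
    centr_degree = if (n < 3) NA_real_ else
      igraph::centr_degree(g, loops = FALSE)$centralization,
    centr_closeness = if (igraph::vcount(giant) < 3) NA_real_ else
      igraph::centr_clo(giant)$centralization,
    centr_betweenness = if (n < 3) NA_real_ else
      igraph::centr_betw(g, directed = FALSE)$centralization,
    n_nodes = n, n_edges = igraph::ecount(g)
  )
}

#' Nodes ranked by betweenness centrality
#'
#' @param g an igraph graph.
#' @return data.frame sorted by decreasing betweenness, ties broken by node
#'   id.
#' @export
node_betweenness_ranking <- function(g) {
  g <- ensure_named(g)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  df <- data.frame(node = igraph::V(g)$name,
                   type = if (!is.null(igraph::V(g)$type)) igraph::V(g)$type else NA,
                   betweenness = as.vector(b), stringsAsFactors = FALSE)
  df <- df[order(-df$betweenness, df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Most-connected cytokine of each community
#'
#' @param g an igraph graph with a `type` vertex attribute.
#' @param partition an `hn_partition` or membership vector.
#' @return data.frame with `module`, `cytokine`, `degree` (one row per
#'   community that contains at least one cytokine; ties broken by id).
#' @export
central_cytokines <- function(g, partition) {
  g <- ensure_named(g)
  memb <- align_membership(g,
    if (inherits(partition, "hn_partition")) partition$membership else partition)
  deg <- igraph::degree(g)
  type <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  rows <- lapply(sort(unique(memb)), function(s) {
    ids <- names(memb)[memb == s & type[names(memb)] == "cytokine"]
    if (length(ids) == 0) return(NULL)
    ids <- ids[order(-deg[ids], ids)]
    data.frame(module = s, cytokine = ids[1], degree = deg[[ids[1]]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
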