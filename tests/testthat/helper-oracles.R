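# independent brute-force oracles for the graph algorithms (tiny n only)

# all set partitions of 1..n as restricted-growth membership vectors
all_partitions <- function(n) {
  out <- list()
  grow <- function(memb, next_label) {
    i <- length(memb) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      grow(c(memb, lab), next_label + (lab == next_label))
    }
  }
  grow(integer(0), 1L)
  out
}

# modularity by direct edge counting from an adjacency matrix
brute_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (s in unique(membership)) {
    idx <- membership == s
    e_ss <- sum(adj[idx, idx]) / 2 / m
    a_s <- sum(deg[idx]) / (2 * m)
    q <- q + e_ss - a_s^2
  }
  q
}

# enumerate every shortest path between every unordered node pair and count
# fractional traversals of each edge (and of each intermediate node)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  enames <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  eb <- setNames(numeric(nrow(enames)),
                 paste(enames[, 1], enames[, 2], sep = "-"))
  nb <- numeric(n)
  sp_dist <- function(s) { # BFS distances
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(adj[v, ] > 0)) if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  for (s in seq_len(n - 1)) {
    ds <- sp_dist(s)
    for (t in (s + 1):n) {
      if (!is.finite(ds[t])) next
      # enumerate all shortest s-t paths by DFS through the distance DAG
      dt <- sp_dist(t)
      paths <- list()
      dfs <- function(v, path) {
        if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
        for (w in which(adj[v, ] > 0)) {
          if (ds[w] == ds[v] + 1 && ds[w] + dt[w] == ds[t]) dfs(w, c(path, w))
        }
      }
      dfs(s, s)
      np <- length(paths)
      for (p in paths) {
        if (length(p) > 2) nb[p[-c(1, length(p))]] <- nb[p[-c(1, length(p))]] + 1 / np
        for (i in seq_len(length(p) - 1)) {
          key <- paste(min(p[i], p[i + 1]), max(p[i], p[i + 1]), sep = "-")
          eb[key] <- eb[key] + 1 / np
        }
      }
    }
  }
  list(edge = eb, node = nb)
}

# exhaustive max-modularity over all partitions (n <= 8)
brute_max_modularity <- function(adj) {
  parts <- all_partitions(nrow(adj))
  qs <- vapply(parts, function(p) brute_modularity(adj, p), 0)
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# deterministic random connected-ish test graph on n nodes
random_adj <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  up <- upper.tri(adj)
  adj[up] <- rbinom(sum(up), 1, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  adj
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
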