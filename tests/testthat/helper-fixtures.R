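# small in-code fixtures shared across test files

tiny_abundance <- function(space = "miRNA") {
  m <- matrix(c(10, 20, 40, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("E_T1", "E_T2", "E_T3")))
  abundance_table(m, space = space)
}

# logfc table from a plain matrix, naming columns over all lineages/stages
lfc_fixture <- function(values, transform = "logFC_vs_reference") {
  logfc_table(values, space = "miRNA", transform = transform)
}

all_conditions <- as.vector(outer(c("E", "Mo", "G", "Mk"), c("T1", "T2", "T3"),
                                  paste, sep = "_"))

# igraph from an edge list given as a 2-column matrix of vertex names
graph_fixture <- function(edges, vertices = NULL, type = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(vertices)) {
    g <- igraph::add_vertices(g, length(setdiff(vertices, igraph::V(g)$name)),
                              name = setdiff(vertices, igraph::V(g)$name))
  }
  if (!is.null(type)) igraph::V(g)$type <- type[igraph::V(g)$name]
  g
}
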