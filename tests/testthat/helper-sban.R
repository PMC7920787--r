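# shared fixtures, built in code

the_catalog <- species_catalog()

# a minimal 3-species catalog for hand-built graphs
mini_catalog <- validate_catalog(data.frame(
  species_id = c("A", "B", "C"),
  scientific_name = c("Aus aus", "Bus bus", "Cus cus"),
  guild = c("G1", "G1", "G2"),
  stringsAsFactors = FALSE
))

# event-row constructor with defaults
ev_row <- function(event_id, species_id, count,
                   behavior_class = "forage", date = "2016-11-01",
                   site_id = "L1", regime = "R1", habitat = "MF") {
  data.frame(event_id = event_id, date = date, site_id = site_id,
             regime = regime, habitat = habitat, species_id = species_id,
             behavior_class = behavior_class, count = count,
             stringsAsFactors = FALSE)
}

# build an sban_network directly from labels and an edge data.frame
make_net <- function(labels, edges = NULL, stratum = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(stratum = stratum, nodes = parse_node_labels(labels),
                 edges = edges), class = "sban_network")
}

# random weighted graph over a label universe
random_net <- function(labels, p_edge = 0.1, weights = NULL) {
  pairs <- utils::combn(labels, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      weight = if (is.null(weights))
                        stats::runif(sum(keep), 0.01, 1) else weights,
                      stringsAsFactors = FALSE)
  make_net(labels, edges)
}

# independent hub-score oracle: dense eigendecomposition per component,
# scaled by the component eigenvalue, global max normalized to 1
hub_oracle <- function(net) {
  labels <- net$nodes$node
  A <- adjacency_matrix(net)
  score <- stats::setNames(numeric(length(labels)), labels)
  if (nrow(net$edges) > 0) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = labels))
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) < 2) next
      e <- eigen(A[members, members, drop = FALSE], symmetric = TRUE)
      v <- abs(e$vectors[, 1])
      score[members] <- e$values[1] * v / sqrt(sum(v^2))
    }
    if (max(score) > 0) score <- score / max(score)
  }
  unname(score)
}

# independent PageRank oracle: direct linear solve of the stationary system
pagerank_oracle <- function(net, damping = 0.85) {
  labels <- net$nodes$node
  n <- length(labels)
  A <- adjacency_matrix(net)
  s <- rowSums(A)
  P <- matrix(1 / n, n, n)
  nz <- s > 0
  P[nz, ] <- A[nz, , drop = FALSE] / s[nz]
  solve(diag(n) - damping * t(P), rep((1 - damping) / n, n))
}
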