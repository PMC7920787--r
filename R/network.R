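#' Pearson correlation between node columns
#'
#' Sample Pearson correlation of every pair of (species, behavior-class)
#' abundance columns of one stratum. Columns with zero variance (species
#' never seen in the stratum, or constant counts) get correlation 0 with
#' every other column by policy, so absent species stay in the universe as
#' isolates rather than producing undefined values.
#'
#' @param matrix An abundance matrix from [pivot_abundance()] with at least
#'   two rows (selection events).
#' @return Symmetric correlation matrix over the node labels, diagonal 1,
#'   with the `stratum` attribute carried over.
#' @export
correlate_nodes <- function(matrix) {
  if (nrow(matrix) < 2) {
    stratum <- attr(matrix, "stratum")
    stop("insufficient data to correlate stratum ",
         if (!is.null(stratum)) paste(stratum, collapse = "-") else "?",
         ": need >= 2 selection events, got ", nrow(matrix), call. = FALSE)
  }
  sds <- apply(matrix, 2, stats::sd)
  corr <- suppressWarnings(stats::cor(matrix))
  corr[is.na(corr)] <- 0
  corr[sds == 0, ] <- 0
  corr[, sds == 0] <- 0
  diag(corr) <- 1
  attr(corr, "stratum") <- attr(matrix, "stratum")
  corr
}

#' Apply a sign policy to a correlation matrix
#'
#' Negative correlations carry no edge weight in the association network.
#' Under `zero_negative` (the default policy) they are set to 0; under
#' `absolute` their magnitude is kept as importance.
#'
#' @param corr Correlation matrix from [correlate_nodes()].
#' @param policy `"zero_negative"` or `"absolute"`.
#' @return The transformed matrix (off-diagonal values in `[0, 1]`).
#' @export
apply_sign_policy <- function(corr, policy = c("zero_negative", "absolute")) {
  policy <- match.arg(policy)
  out <- if (policy == "zero_negative") pmax(corr, 0) else abs(corr)
  attributes(out) <- attributes(corr)
  out
}

#' Threshold a correlation matrix
#'
#' Zeroes weak entries. The build threshold (default 0.05) uses non-strict
#' semantics: entries *below* the threshold become 0 and ties are kept. The
#' keystone simplification cutoff (0.4) uses strict semantics: only entries
#' *higher than* the cutoff survive, so ties are dropped. The diagonal is
#' left untouched (it never contributes edges).
#'
#' @param corr Correlation matrix (typically sign-policed).
#' @param threshold Real in `[0, 1]`.
#' @param strict Logical; `FALSE` keeps ties (build rule), `TRUE` drops them
#'   (keystone rule).
#' @return The thresholded matrix.
#' @export
threshold_adjacency <- function(corr, threshold, strict = FALSE) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  out <- corr
  drop <- if (strict) out <= threshold else out < threshold
  diag(drop) <- FALSE
  out[drop] <- 0
  attributes(out) <- attributes(corr)
  out
}

#' Build the social-behavioral association network
#'
#' Turns a sign-policed, thresholded correlation matrix into an undirected
#' weighted simple graph: one edge per strictly positive off-diagonal entry,
#' weight equal to the entry. The node universe is the full label set of the
#' matrix, isolates included, so network attributes are comparable across
#' strata.
#'
#' @param corr Thresholded correlation matrix.
#' @param stratum Length-2 character vector `c(regime, habitat)`; defaults
#'   to the matrix's `stratum` attribute.
#' @param catalog Optional catalog used to attach guild metadata to nodes.
#' @return An object of class `sban_network`: list with `stratum`, `nodes`
#'   (data.frame `node`, `species_id`, `behavior_class`, and `guild` when a
#'   catalog is given) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_network <- function(corr, stratum = attr(corr, "stratum"),
                          catalog = NULL) {
  labels <- colnames(corr)
  nodes <- parse_node_labels(labels)
  if (!is.null(catalog)) {
    nodes$guild <- catalog$guild[match(nodes$species_id, catalog$species_id)]
  }
  ut <- upper.tri(corr)
  hit <- which(ut & corr > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = labels[hit[, 1]],
    to = labels[hit[, 2]],
    weight = corr[hit],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(stratum = stratum, nodes = nodes, edges = edges),
            class = "sban_network")
}

#' @export
print.sban_network <- function(x, ...) {
  cat("SBAN network",
      if (!is.null(x$stratum)) paste0("[", paste(x$stratum, collapse = "-"), "]"),
      "-", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Weighted adjacency matrix of a network
#'
#' @param net An `sban_network`.
#' @return Symmetric numeric matrix over the full node universe.
#' @export
adjacency_matrix <- function(net) {
  labels <- net$nodes$node
  A <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$from, labels)
    j <- match(net$edges$to, labels)
    A[cbind(i, j)] <- net$edges$weight
    A[cbind(j, i)] <- net$edges$weight
  }
  A
}

#' Convert to an igraph object
#'
#' Node attributes `species_id`, `behavior_class` (and `guild` if present)
#' and the edge attribute `weight` are carried over.
#'
#' @param net An `sban_network`.
#' @return An undirected weighted [igraph::igraph] graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a network as GraphML and edge-list CSV
#'
#' @param net An `sban_network`.
#' @param graphml_path Output GraphML path (skipped when `NULL`).
#' @param edgelist_path Output CSV path with header `source,target,weight`
#'   (skipped when `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    el <- net$edges
    names(el) <- c("source", "target", "weight")
    utils::write.csv(el, edgelist_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(graphml = graphml_path, edgelist = edgelist_path))
}

#' Build the SBAN for one stratum from events
#'
#' Convenience composition: pivot, correlate, sign-police, threshold, build.
#'
#' @param events Validated (daily-filtered) events.
#' @param catalog A validated species catalog.
#' @param regime,habitat The stratum.
#' @param threshold Build threshold on correlations (default 0.05, ties
#'   kept).
#' @param sign_policy `"zero_negative"` (default) or `"absolute"`.
#' @return An `sban_network`.
#' @export
build_stratum_network <- function(events, catalog, regime, habitat,
                                  threshold = 0.05,
                                  sign_policy = "zero_negative") {
  mat <- pivot_abundance(events, catalog, regime, habitat)
  corr <- correlate_nodes(mat)
  corr <- apply_sign_policy(corr, sign_policy)
  corr <- threshold_adjacency(corr, threshold, strict = FALSE)
  build_network(corr, catalog = catalog)
}
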