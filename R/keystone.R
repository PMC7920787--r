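#' Simplify a network for keystone identification
#'
#' Drops every edge whose weight is not strictly greater than the cutoff
#' (default 0.4): only strong associations feed the hub ranking. The node
#' universe is unchanged.
#'
#' @param net An `sban_network`.
#' @param cutoff Real in `[0, 1]`.
#' @return The simplified `sban_network`.
#' @export
simplify_network <- function(net, cutoff = 0.4) {
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("cutoff must lie in [0, 1]", call. = FALSE)
  }
  net$edges <- net$edges[net$edges$weight > cutoff, ]
  rownames(net$edges) <- NULL
  net
}

# connected components over the edge set (isolates are singleton components)
graph_components <- function(labels, edges) {
  comp <- seq_along(labels)
  names(comp) <- labels
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    fi <- match(edges$from, labels)
    ti <- match(edges$to, labels)
    for (k in seq_along(fi)) {
      a <- find(fi[k]); b <- find(ti[k])
      if (a != b) comp[a] <- b
    }
  }
  vapply(seq_along(labels), find, integer(1))
}

#' Hub-centrality scores of every node
#'
#' Hub centrality here is the HITS hub score on the weighted adjacency; for
#' an undirected graph hub and authority coincide with the principal
#' (Perron) eigenvector of the adjacency matrix. Scores are computed per
#' connected component by shifted power iteration (the diagonal shift makes
#' bipartite components converge), each component's eigenvector is scaled by
#' its dominant eigenvalue so that better-connected components dominate, and
#' the combined vector is normalized to maximum 1. Isolated nodes score 0;
#' an edgeless network scores 0 everywhere.
#'
#' @param net An `sban_network`.
#' @param tol Power-iteration convergence tolerance.
#' @param max_iter Iteration cap.
#' @return data.frame `node`, `species_id`, `behavior_class`, `score`.
#' @export
hub_scores <- function(net, tol = 1e-12, max_iter = 10000) {
  labels <- net$nodes$node
  score <- stats::setNames(numeric(length(labels)), labels)
  if (nrow(net$edges) > 0) {
    A <- adjacency_matrix(net)
    comp <- graph_components(labels, net$edges)
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) < 2) next
      Ac <- A[members, members, drop = FALSE]
      shift <- max(rowSums(Ac)) * 0.05 + 1e-9
      B <- Ac + diag(shift, length(members))
      v <- rep(1 / sqrt(length(members)), length(members))
      for (it in seq_len(max_iter)) {
        w <- as.vector(B %*% v)
        w <- w / sqrt(sum(w^2))
        if (sum(abs(w - v)) < tol) break
        v <- w
      }
      lambda <- as.vector(v %*% Ac %*% v)  # Rayleigh quotient, unshifted
      score[members] <- lambda * v
    }
    if (max(score) > 0) score <- score / max(score)
  }
  out <- net$nodes[, c("node", "species_id", "behavior_class")]
  out$score <- unname(score)
  out
}

#' PageRank scores of every node
#'
#' PageRank on the weighted undirected graph: each edge acts as two directed
#' arcs, a node distributes its rank over neighbors proportionally to edge
#' weight, and isolated (dangling) nodes teleport uniformly. Solved by power
#' iteration to an L1 tolerance of 1e-9 (at most 1,000 iterations); the
#' scores sum to 1 over the full universe, so an edgeless network is uniform
#' at `1/T`.
#'
#' @param net An `sban_network`.
#' @param damping Damping factor in `(0, 1)`; 0.85 by default.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return data.frame `node`, `species_id`, `behavior_class`, `score`.
#' @export
pagerank_scores <- function(net, damping = 0.85, tol = 1e-9,
                            max_iter = 1000) {
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    stop("damping must lie in (0, 1)", call. = FALSE)
  }
  labels <- net$nodes$node
  n <- length(labels)
  A <- adjacency_matrix(net)
  strength <- rowSums(A)
  dangling <- strength == 0
  P <- A
  P[!dangling, ] <- A[!dangling, , drop = FALSE] / strength[!dangling]
  x <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    x_new <- (1 - damping) / n +
      damping * (as.vector(crossprod(P, x)) + sum(x[dangling]) / n)
    if (sum(abs(x_new - x)) < tol) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged) {
    stop("PageRank failed to converge within ", max_iter, " iterations",
         call. = FALSE)
  }
  out <- net$nodes[, c("node", "species_id", "behavior_class")]
  out$score <- x / sum(x)
  out
}

#' Score every node by both centrality measures
#'
#' @param net An `sban_network`.
#' @param damping PageRank damping factor.
#' @return data.frame `node`, `species_id`, `behavior_class`, `hub_score`,
#'   `pagerank_score`.
#' @export
node_scores <- function(net, damping = 0.85) {
  hub <- hub_scores(net)
  pr <- pagerank_scores(net, damping = damping)
  out <- hub
  names(out)[names(out) == "score"] <- "hub_score"
  out$pagerank_score <- pr$score[match(out$node, pr$node)]
  out
}

#' Rank species by node centrality
#'
#' Aggregates per-node scores to a per-species keystone score (default:
#' maximum over the species' five nodes -- a species is a keystone if any of
#' its activity or behavior nodes is a hub; `sum` is offered as an
#' alternative). Species are sorted by decreasing score; ties are broken by
#' the other aggregate, then by species id. Species whose nodes all score 0
#' are excluded.
#'
#' @param scores data.frame from [node_scores()] (columns `hub_score` and
#'   `pagerank_score`) or from [hub_scores()]/[pagerank_scores()] (column
#'   `score`, in which case `method` is ignored).
#' @param method `"hub"` (default) or `"pagerank"`.
#' @param aggregate `"max"` (default) or `"sum"`.
#' @return data.frame `species_id`, `score`, `rank`, sorted by rank.
#' @export
rank_species <- function(scores, method = c("hub", "pagerank"),
                         aggregate = c("max", "sum")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  col <- if ("score" %in% names(scores)) "score"
         else paste0(if (method == "hub") "hub" else "pagerank", "_score")
  if (!col %in% names(scores)) {
    stop("scores lack column ", col, call. = FALSE)
  }
  agg <- function(fun) {
    tapply(scores[[col]], scores$species_id, fun)
  }
  primary <- agg(if (aggregate == "max") max else sum)
  secondary <- agg(if (aggregate == "max") sum else max)
  species <- names(primary)
  keep <- primary > 0
  species <- species[keep]
  if (length(species) == 0) {
    return(data.frame(species_id = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  ord <- order(-primary[species], -secondary[species], species)
  species <- species[ord]
  data.frame(species_id = species,
             score = unname(primary[species]),
             rank = seq_along(species),
             stringsAsFactors = FALSE)
}

#' Keystone species of a network
#'
#' Simplifies the network at the keystone cutoff, scores nodes, ranks
#' species, and reports every species whose score is within a relative
#' tolerance of the leader (several near-tied hubs may share keystone
#' status).
#'
#' @param net An `sban_network` (unsimplified; pass `cutoff = 0` to skip
#'   simplification).
#' @param cutoff Keystone simplification cutoff (strict; default 0.4).
#' @param method,aggregate Passed to [rank_species()].
#' @param tol Relative near-leader tolerance (default 0.05).
#' @return Character vector of keystone species ids (possibly empty).
#' @export
keystone_species <- function(net, cutoff = 0.4, method = "hub",
                             aggregate = "max", tol = 0.05) {
  simplified <- simplify_network(net, cutoff)
  ranking <- rank_species(node_scores(simplified), method = method,
                          aggregate = aggregate)
  if (nrow(ranking) == 0) return(character())
  leader <- ranking$score[1]
  ranking$species_id[ranking$score >= leader * (1 - tol)]
}
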