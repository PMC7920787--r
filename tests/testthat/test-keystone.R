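star_net <- function(w = rep(1, 4)) {
  labels <- c("A:forage", "B:forage", "B:roost", "C:forage", "C:roost")
  make_net(labels, data.frame(from = "A:forage", to = labels[-1],
                              weight = w, stringsAsFactors = FALSE))
}

test_that("simplify_network drops ties at the cutoff", {
  net <- make_net(c("A:forage", "B:forage", "C:forage"),
                  data.frame(from = c("A:forage", "A:forage"),
                             to = c("B:forage", "C:forage"),
                             weight = c(0.41, 0.40), stringsAsFactors = FALSE))
  kept <- simplify_network(net, 0.4)
  expect_identical(kept$edges$to, "B:forage")      # 0.41 retained
  expect_identical(nrow(kept$nodes), 3L)           # universe unchanged
  expect_identical(nrow(simplify_network(net, 0)$edges), 2L)
  expect_error(simplify_network(net, 1.2), "cutoff")
})

test_that("hub scores: star center dominates, symmetry gives equal scores", {
  hs <- hub_scores(star_net())
  expect_equal(hs$score[hs$node == "A:forage"], 1)
  expect_true(all(hs$score[hs$node != "A:forage"] < 1))
  # the four leaves are automorphic images of one another
  expect_equal(length(unique(round(hs$score[hs$node != "A:forage"], 10))), 1L)

  # edgeless network scores 0 everywhere
  hs0 <- hub_scores(make_net(node_labels(mini_catalog)))
  expect_true(all(hs0$score == 0))
})

test_that("hub scores match the dense eigen oracle on a path graph", {
  labels <- paste0(c("A", "B", "C", "D"), ":forage")
  net <- make_net(labels, data.frame(from = labels[1:3], to = labels[2:4],
                                     weight = 1, stringsAsFactors = FALSE))
  hs <- hub_scores(net)
  expect_equal(hs$score, hub_oracle(net), tolerance = 1e-9)
  # P4 principal eigenvector is sin(k*pi/5), max-normalized
  expected <- sin(1:4 * pi / 5) / max(sin(1:4 * pi / 5))
  expect_equal(hs$score, expected, tolerance = 1e-9)
})

test_that("pagerank: uniform on regular and edgeless graphs, triangle solve", {
  # 4-cycle with equal weights is regular: uniform scores
  labels <- paste0(c("A", "B", "C", "D"), ":forage")
  cyc <- make_net(labels, data.frame(from = labels,
                                     to = labels[c(2, 3, 4, 1)],
                                     weight = 0.5, stringsAsFactors = FALSE))
  expect_equal(pagerank_scores(cyc)$score, rep(0.25, 4), tolerance = 1e-8)

  iso <- make_net(node_labels(mini_catalog))
  expect_equal(pagerank_scores(iso)$score, rep(1 / 15, 15), tolerance = 1e-12)

  tri <- make_net(labels[1:3], data.frame(
    from = c("A:forage", "A:forage", "B:forage"),
    to = c("B:forage", "C:forage", "C:forage"),
    weight = c(0.9, 0.2, 0.5), stringsAsFactors = FALSE))
  pr <- pagerank_scores(tri)
  expect_equal(pr$score, pagerank_oracle(tri), tolerance = 1e-7)
  expect_equal(sum(pr$score), 1, tolerance = 1e-8)
  expect_error(pagerank_scores(tri, damping = 1), "damping")
})

test_that("rank_species aggregates, breaks ties, and drops zero species", {
  scores <- data.frame(
    node = c("A:forage", "A:roost", "B:forage", "B:roost", "C:forage"),
    species_id = c("A", "A", "B", "B", "C"),
    behavior_class = c("forage", "roost", "forage", "roost", "forage"),
    hub_score = c(1.0, 0.1, 0.8, 0.8, 0),
    pagerank_score = c(0.3, 0.1, 0.25, 0.25, 0.1),
    stringsAsFactors = FALSE)
  r <- rank_species(scores, method = "hub", aggregate = "max")
  expect_identical(r$species_id, c("A", "B"))   # C all-zero: excluded
  expect_equal(r$score, c(1.0, 0.8))
  # under sum, B (1.6) overtakes A (1.1)
  r2 <- rank_species(scores, method = "hub", aggregate = "sum")
  expect_identical(r2$species_id[1], "B")
  # max tie between A and B resolved by the sum aggregate
  scores$hub_score <- c(0.8, 0.1, 0.8, 0.5, 0)
  r3 <- rank_species(scores, method = "hub", aggregate = "max")
  expect_identical(r3$species_id, c("B", "A"))
  # exact tie on both aggregates falls back to species id
  scores$hub_score <- c(0.8, 0.5, 0.8, 0.5, 0)
  r4 <- rank_species(scores, method = "hub", aggregate = "max")
  expect_identical(r4$species_id, c("A", "B"))
  expect_identical(rank_species(transform(scores, hub_score = 0))$species_id,
                   character(0))
})

test_that("rankings are invariant to uniform edge-weight rescaling", {
  labels <- node_labels(mini_catalog)
  set.seed(15)
  net <- random_net(labels, p_edge = 0.25)
  scaled <- net
  scaled$edges$weight <- scaled$edges$weight * 0.37
  for (m in c("hub", "pagerank")) {
    r1 <- rank_species(node_scores(net), method = m)
    r2 <- rank_species(node_scores(scaled), method = m)
    expect_identical(r1$species_id, r2$species_id)
  }
})

test_that("a planted star-of-stars center species is recovered rank-1", {
  # species A's forage node is the center of a star whose leaves each carry
  # a small sub-star; both centrality measures must put A first
  labels <- node_labels(the_catalog)
  hubs <- paste0(c("C_nigra", "A_cinerea", "G_grus"), ":forage")
  leaves <- lapply(c("C_nigra", "A_cinerea", "G_grus"), function(s)
    paste0(s, ":", c("roost", "competition")))
  edges <- rbind(
    data.frame(from = "A_alba:forage", to = hubs, weight = 0.9,
               stringsAsFactors = FALSE),
    do.call(rbind, Map(function(h, l)
      data.frame(from = h, to = l, weight = 0.5, stringsAsFactors = FALSE),
      hubs, leaves))
  )
  net <- make_net(labels, edges)
  for (m in c("hub", "pagerank")) {
    r <- rank_species(node_scores(net), method = m, aggregate = "max")
    expect_identical(r$species_id[1], "A_alba")
  }
})

test_that("keystone_species reports near-tied leaders", {
  net <- star_net(w = c(0.9, 0.9, 0.6, 0.5))
  # cutoff 0.4 keeps all edges; A leads, B's best node is close behind
  ks_tight <- keystone_species(net, cutoff = 0.4, tol = 1e-6)
  expect_identical(ks_tight, "A")
  ks_loose <- keystone_species(net, cutoff = 0.95, tol = 0.05)
  expect_identical(ks_loose, character(0))
})
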