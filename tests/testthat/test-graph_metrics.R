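path3 <- function() graph_from_edges(data.frame(drug_a = c("a", "b"),
                                                drug_b = c("b", "c")))

test_that("density, degrees and components behave on closed-form graphs", {
  tri <- graph_from_edges(data.frame(drug_a = c("a", "a", "b"),
                                     drug_b = c("b", "c", "c")))
  expect_equal(graph_density(tri), 1)
  empty <- graph_from_edges(data.frame(drug_a = character(0),
                                       drug_b = character(0)))
  expect_equal(graph_density(empty), 0)
  expect_equal(nrow(degree_metrics(empty)), 0)

  dm <- degree_metrics(path3())
  expect_equal(dm$degree[match(c("a", "b", "c"), dm$drug)], c(1, 2, 1))

  two <- graph_from_edges(data.frame(drug_a = c("a", "c"),
                                     drug_b = c("b", "d")))
  comp <- graph_components(two)
  expect_equal(comp$n_components, 2)
  expect_equal(comp$sizes, c(2, 2))
  expect_equal(graph_components(tri)$n_components, 1)
})

test_that("betweenness and closeness match closed forms on paths and cliques", {
  bc <- betweenness_centrality(path3())
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))
  k4 <- random_ddi_graph(4, 1.1)
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))

  cc <- closeness_centrality(path3())
  expect_equal(unname(cc["b"]), 1)
  expect_equal(unname(cc["a"]), 2 / 3)
  iso <- graph_from_edges(data.frame(drug_a = "a", drug_b = "b"),
                          nodes = "loner")
  expect_equal(unname(closeness_centrality(iso)["loner"]), 0)
})

test_that("eigenvector centrality matches closed forms for cliques and stars", {
  k3 <- random_ddi_graph(3, 1.1)
  expect_equal(unname(eigenvector_centrality(k3)), rep(1 / sqrt(3), 3),
               tolerance = 1e-6)
  star <- graph_from_edges(data.frame(
    drug_a = "hub", drug_b = c("l1", "l2", "l3", "l4")))
  ev <- eigenvector_centrality(star, tol = 1e-10)
  expect_equal(unname(ev["hub"]), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(unname(ev[c("l1", "l2", "l3", "l4")]),
               rep(1 / (2 * sqrt(2)), 4), tolerance = 1e-6)
  expect_equal(sum(ev^2), 1, tolerance = 1e-9)
  expect_error(eigenvector_centrality(
    graph_from_edges(data.frame(drug_a = character(0),
                                drug_b = character(0)))),
    "at least one edge")
})

test_that("clustering coefficients are 1 on triangles and 0 on stars and trees", {
  tri <- graph_from_edges(data.frame(drug_a = c("a", "a", "b"),
                                     drug_b = c("b", "c", "c")))
  cl <- clustering_coefficients(tri)
  expect_equal(as.vector(cl), rep(1, 3))
  expect_equal(attr(cl, "average"), 1)
  star <- graph_from_edges(data.frame(drug_a = "hub",
                                      drug_b = c("l1", "l2", "l3")))
  expect_equal(as.vector(clustering_coefficients(star)), rep(0, 4))
  # any tree has zero clustering everywhere
  set.seed(31)
  parent <- c(NA, sample(1:9, 9, replace = TRUE))
  tree_edges <- data.frame(drug_a = sprintf("n%02d", 2:10),
                           drug_b = sprintf("n%02d", pmin(parent[2:10], 1:9)))
  tree <- graph_from_edges(tree_edges)
  expect_true(all(clustering_coefficients(tree) == 0))
  expect_true(all(betweenness_centrality(tree)[
    colSums(adjmat(tree)) == 1] == 0))
})

test_that("complete graphs have unit density/clustering, zero betweenness, equal eigenvector", {
  kn <- random_ddi_graph(7, 1.1)
  expect_equal(graph_density(kn), 1)
  expect_equal(as.vector(clustering_coefficients(kn)), rep(1, 7))
  expect_equal(unname(betweenness_centrality(kn)), rep(0, 7))
  ev <- eigenvector_centrality(kn, tol = 1e-10)
  expect_equal(unname(ev), rep(1 / sqrt(7), 7), tolerance = 1e-6)
})

test_that("metrics agree with igraph as an independent library oracle", {
  set.seed(47)
  for (rep in 1:5) {
    g <- random_ddi_graph(25, runif(1, 0.15, 0.5), retain_isolated = FALSE)
    ig <- igraph::graph_from_data_frame(g$edges[, c("drug_a", "drug_b")],
                                        directed = FALSE,
                                        vertices = g$nodes)
    expect_equal(unname(betweenness_centrality(g)),
                 unname(igraph::betweenness(ig, normalized = TRUE)),
                 tolerance = 1e-9)
    cl <- igraph::transitivity(ig, type = "local", isolates = "zero")
    expect_equal(as.vector(clustering_coefficients(g)), unname(cl),
                 tolerance = 1e-12)
    expect_equal(graph_components(g)$n_components,
                 igraph::components(ig)$no)
    expect_equal(graph_density(g), igraph::edge_density(ig),
                 tolerance = 1e-12)
    if (igraph::is_connected(ig)) {
      expect_equal(unname(closeness_centrality(g)),
                   unname(igraph::closeness(ig, normalized = TRUE)),
                   tolerance = 1e-9)
      v <- igraph::eigen_centrality(ig)$vector  # rescaled to unit norm below
      expect_equal(unname(eigenvector_centrality(g, tol = 1e-10)),
                   unname(abs(v) / sqrt(sum(v^2))),
                   tolerance = 1e-5)
    }
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(53)
  g <- random_ddi_graph(15, 0.3)
  perm <- sample(letters[1:15])
  names(perm) <- g$nodes
  relabeled <- graph_from_edges(data.frame(
    drug_a = unname(perm[g$edges$drug_a]),
    drug_b = unname(perm[g$edges$drug_b]),
    severity = g$edges$severity), nodes = unname(perm))
  for (metric in list(betweenness_centrality, closeness_centrality,
                      clustering_coefficients)) {
    m1 <- metric(g)
    m2 <- metric(relabeled)
    expect_equal(unname(m2[perm[g$nodes]]), unname(m1)[seq_along(m1)],
                 tolerance = 1e-12)
  }
})

test_that("node and graph metric tables are consistent", {
  set.seed(59)
  g <- random_ddi_graph(20, 0.25, retain_isolated = FALSE)
  nm <- suppressWarnings(node_metrics(g))
  expect_equal(nrow(nm), length(g$nodes))
  expect_true(!is.unsorted(-nm$degree))
  expect_equal(sum(nm$degree), 2 * nrow(g$edges))  # handshake
  gm <- graph_metrics(g)
  expect_equal(gm$avg_degree, 2 * gm$n_edges / gm$n_nodes)
  expect_equal(gm$avg_clustering, mean(nm$clustering))
  expect_equal(gm$degree_max, max(nm$degree))
  expect_equal(sum(gm$component_sizes), gm$n_nodes)
})
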