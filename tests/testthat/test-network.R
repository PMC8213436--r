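test_that("network nodes are the gene union and edges are restricted PPI", {
  ppi <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "d"))
  net <- build_network("a", tibble::tibble(constituent = "x", gene = "b"),
                       "c", ppi)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2) # (c, d) dropped
  expect_true(igraph::V(net)$role_anti[igraph::V(net)$name == "a"])
  expect_true(igraph::V(net)$role_disease[igraph::V(net)$name == "c"])
})

test_that("disconnected gene sets give an edgeless network with a warning", {
  ppi <- tibble::tibble(from = "x", to = "y")
  expect_warning(net <- build_network("a", NULL, "b", ppi), "edgeless")
  expect_equal(igraph::ecount(net), 0)
  expect_equal(igraph::vcount(net), 2)
})

test_that("self-loops and duplicate edges are dropped on ingest", {
  ppi <- tibble::tibble(from = c("a", "a", "b", "a"), to = c("a", "b", "a", "b"))
  warns <- capture_warnings(net <- build_network(c("a", "b"), NULL, character(0), ppi))
  expect_match(warns, "self-loop", all = FALSE)
  expect_match(warns, "duplicate", all = FALSE)
  expect_equal(igraph::ecount(net), 1)
})

test_that("star and path centralities match hand enumeration", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", paste0("leaf", 1:4))
  ct <- centralities(star)
  expect_equal(ct$degree, c(4, 1, 1, 1, 1))
  expect_equal(ct$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(ct$closeness, c(1, 4/7, 4/7, 4/7, 4/7))

  path <- igraph::make_graph(~ a - b, b - c, c - d)
  ctp <- centralities(path)
  expect_equal(ctp$degree[match(c("a", "b"), ctp$node)], c(1, 2))
  expect_equal(ctp$closeness[match(c("a", "b"), ctp$node)], c(0.5, 0.75))
})

test_that("an isolated node has zero degree, betweenness and closeness", {
  g <- igraph::make_graph(~ a - b) + igraph::vertex("iso")
  ct <- centralities(g)
  expect_equal(unlist(ct[ct$node == "iso", -1]),
               c(degree = 0, betweenness = 0, closeness = 0))
})

test_that("centralities equal the matrix-power oracle on random graphs", {
  for (s in 1:30) {
    A <- random_adjacency(s)
    ct <- centralities(graph_from_adj(A))
    o <- oracle_centralities(A)
    expect_equal(ct$degree, o$degree)
    expect_equal(ct$betweenness, o$betweenness, tolerance = 1e-9)
    expect_equal(ct$closeness, o$closeness, tolerance = 1e-9)
  }
})

test_that("the median screen keeps the star center and rejects a cycle", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", paste0("leaf", 1:4))
  expect_identical(select_core(centralities(star)), "center")
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- paste0("r", 1:5)
  expect_identical(select_core(centralities(ring)), character(0))
})

test_that("core selection is invariant under relabeling and rescaling", {
  A <- random_adjacency(99)
  ct <- centralities(graph_from_adj(A))
  sel <- select_core(ct)
  # relabel nodes: permute the adjacency and assign fresh labels
  set.seed(100)
  perm <- sample(nrow(A))
  B <- A[perm, perm]
  new_labels <- paste0("w", seq_len(nrow(A)))
  back_to_old <- setNames(rownames(A)[perm], new_labels)
  dimnames(B) <- list(new_labels, new_labels)
  sel_b <- select_core(centralities(graph_from_adj(B)))
  expect_setequal(unname(back_to_old[sel_b]), sel)
  # positive rescaling of betweenness/closeness leaves selection unchanged
  ct2 <- ct
  ct2$betweenness <- ct2$betweenness * 17.3
  ct2$closeness <- ct2$closeness * 0.01
  expect_identical(select_core(ct2), sel)
})

test_that("density uses the ordered-pair convention", {
  expect_equal(round(network_density(2251, 53254), 3), 0.011)
  expect_equal(round(network_density(566, 23558), 3), 0.074)
  # the unordered convention would double both and disagree with the
  # reported values
  expect_false(round(53254 / choose(2251, 2), 3) == 0.011)
  expect_equal(network_density(2, 1), 0.5)
  expect_error(network_density(1, 0))
  # monotone in edges at fixed node count
  d <- vapply(0:10, function(e) network_density(6, e), numeric(1))
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("two-stage extraction recovers a planted hub tier", {
  g <- gen_network_inputs(tiny_config(seed = 2))
  net <- build_network(g$anti_genes, g$target_map, g$disease_genes, g$ppi)
  h <- extract_hubs(net, ppi = g$ppi)
  expect_setequal(h$hubs, g$ground_truth$hub_tier)
  expect_setequal(h$core, c(g$ground_truth$hub_tier, g$ground_truth$core_tier))
  expect_true(all(h$hubs %in% h$core))
  expect_gt(h$stages$density[2], h$stages$density[1])
  expect_equal(h$stages$density[1],
               network_density(igraph::vcount(net), igraph::ecount(net)))
})

test_that("a regular graph yields no core and skips stage 2", {
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("r", 1:8)
  expect_warning(h <- extract_hubs(ring), "skipped")
  expect_identical(h$hubs, character(0))
  expect_true(h$stage2_skipped)
})

test_that("hub tidiers expose per-node flags and stage summaries", {
  g <- gen_network_inputs(tiny_config(seed = 6))
  net <- build_network(g$anti_genes, g$target_map, g$disease_genes, g$ppi)
  h <- extract_hubs(net, ppi = g$ppi)
  td <- tidy(h)
  expect_true(all(td$node[td$in_hub] %in% h$hubs))
  gl <- glance(h)
  expect_equal(gl$n_hubs, length(h$hubs))
  expect_true(gl$density_increased)
})
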