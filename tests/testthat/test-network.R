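test_that("edge-list loading collapses duplicates and drops self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc", "b\tc"), f)
  net <- load_edge_list(f, node_kinds = c(a = "protein", b = "protein",
                                          c = "protein"))
  expect_equal(unname(network_size(net)), c(3L, 2L))
  expect_equal(net$n_dropped_dup, 1L)

  writeLines(c("a\ta", "a\tb"), f)
  net2 <- load_edge_list(f, node_kinds = c(a = "protein", b = "protein"))
  expect_equal(net2$n_dropped_self, 1L)
  expect_equal(unname(network_size(net2)), c(2L, 1L))
})

test_that("malformed rows and unknown kinds are rejected with context", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "loner"), f)
  expect_error(load_edge_list(f, node_kinds = c(a = "protein", b = "protein")),
               "line 2")
  writeLines("a\tb", f)
  expect_error(
    load_edge_list(f, node_kinds = c(a = "protein"), default_kind = NULL),
    "no kind")
  expect_warning(
    load_edge_list(f, node_kinds = c(a = "protein"), default_kind = "protein"),
    "default")
  expect_error(
    background_network(data.frame(a = "x", b = "y"),
                       kinds = c(x = "gene", y = "protein")),
    "invalid kind")
})

test_that("loaded networks match an independent adjacency-set oracle", {
  set.seed(42)
  for (rep in 1:10) {
    edges <- random_edge_df(12, 0.25)
    # inject duplicates and a self-loop
    edges <- rbind(edges, edges[1L, ], data.frame(from = "n01", to = "n01"))
    net <- background_network(edges, kinds = all_protein_kinds(edges))
    adj <- oracle_adjacency(edges)
    expect_equal(sort(network_nodes(net)), names(adj))
    expect_equal(unname(network_size(net)["edges"]),
                 sum(lengths(adj)) / 2)
    expect_equal(node_degrees(net)[names(adj)],
                 vapply(adj, length, integer(1L)),
                 ignore_attr = FALSE)
    # degree sum identity
    expect_equal(sum(node_degrees(net)), 2L * unname(network_size(net)["edges"]))
  }
})

test_that("network merge is a typed set union", {
  k <- function(...) {
    ids <- c(...)
    stats::setNames(rep("protein", length(ids)), ids)
  }
  a <- background_network(data.frame(f = c("a", "b"), t = c("b", "c")),
                          kinds = k("a", "b", "c"))
  b <- background_network(data.frame(f = c("x", "y"), t = c("y", "z")),
                          kinds = k("x", "y", "z"))
  m <- merge_networks(a, b)
  expect_equal(unname(network_size(m)), c(6L, 4L))

  # shared node and shared edge deduplicate
  b2 <- background_network(data.frame(f = c("c", "b"), t = c("d", "c")),
                           kinds = k("b", "c", "d"))
  m2 <- merge_networks(a, b2)
  expect_equal(unname(network_size(m2)["nodes"]), 3L + 3L - 2L)
  expect_equal(unname(network_size(m2)["edges"]), 2L + 2L - 1L)

  # kind conflicts are fatal
  bad <- background_network(data.frame(f = "c", t = "w"),
                            kinds = c(c = "metabolite", w = "protein"))
  expect_error(merge_networks(a, bad), "conflicting")
})

test_that("merge is commutative and idempotent and matches a set oracle", {
  set.seed(7)
  for (rep in 1:5) {
    e1 <- random_edge_df(10, 0.2)
    e2 <- random_edge_df(10, 0.2)
    n1 <- background_network(e1, kinds = all_protein_kinds(e1))
    n2 <- background_network(e2, kinds = all_protein_kinds(e2))
    ab <- merge_networks(n1, n2)
    ba <- merge_networks(n2, n1)
    expect_equal(sort(network_nodes(ab)), sort(network_nodes(ba)))
    expect_equal(network_size(ab), network_size(ba))
    aa <- merge_networks(n1, n1)
    expect_equal(network_size(aa), network_size(n1))
    # set-union oracle
    adj <- oracle_adjacency(rbind(e1, e2))
    expect_equal(sort(network_nodes(ab)), names(adj))
    expect_equal(unname(network_size(ab)["edges"]), sum(lengths(adj)) / 2)
  }
})

test_that("largest connected component selection matches a BFS oracle", {
  k <- all_protein_kinds
  conn <- data.frame(f = c("a", "b", "c"), t = c("b", "c", "d"))
  net <- background_network(conn, kinds = k(conn))
  expect_equal(sort(network_nodes(suppressMessages(
    largest_connected_component(net)))), c("a", "b", "c", "d"))

  two <- rbind(data.frame(f = c("a", "b", "c", "d"), t = c("b", "c", "d", "e")),
               data.frame(f = c("x", "y"), t = c("y", "z")))
  lcc <- suppressMessages(largest_connected_component(
    background_network(two, kinds = k(two))))
  expect_equal(sort(network_nodes(lcc)), c("a", "b", "c", "d", "e"))

  set.seed(11)
  for (rep in 1:5) {
    e <- random_edge_df(14, 0.08)
    net <- background_network(e, kinds = k(e))
    lcc <- suppressMessages(largest_connected_component(net))
    comps <- oracle_components(oracle_adjacency(e))
    sizes <- lengths(comps)
    best <- comps[sizes == max(sizes)]
    firsts <- vapply(best, `[[`, character(1L), 1L)
    expect_equal(sort(network_nodes(lcc)), best[[order(firsts)[1L]]])
  }

  expect_error(largest_connected_component(
    structure(list(graph = igraph::make_empty_graph()),
              class = "background_network")), "empty")
})

test_that("degree bins partition nodes and respect the minimum size", {
  k <- all_protein_kinds
  ring <- data.frame(f = sprintf("v%02d", 1:30),
                     t = sprintf("v%02d", c(2:30, 1)))
  net <- background_network(ring, kinds = k(ring))
  bins <- build_degree_bins(net, min_bin_size = 10L)
  expect_length(bins$bins, 1L)        # all degrees equal -> one bin
  expect_length(bins$bins[[1L]]$nodes, 30L)

  # star + ring mixture: distinct degrees, min_bin_size 1 -> one bin each
  star <- data.frame(f = "hub", t = sprintf("s%02d", 1:6))
  snet <- background_network(star, kinds = k(star))
  b1 <- build_degree_bins(snet, 1L)
  expect_length(b1$bins, 2L)           # degree 1 leaves, degree 6 hub

  # partition + range invariants on a random graph
  set.seed(3)
  e <- random_edge_df(25, 0.2)
  rnet <- background_network(e, kinds = k(e))
  for (mbs in c(1L, 5L, 10L)) {
    bb <- build_degree_bins(rnet, mbs)
    all_nodes <- unlist(lapply(bb$bins, `[[`, "nodes"))
    expect_setequal(all_nodes, network_nodes(rnet))
    expect_equal(anyDuplicated(all_nodes), 0L)
    deg <- node_degrees(rnet)
    for (b in bb$bins) {
      expect_true(all(deg[b$nodes] >= b$degree_range[1L] &
                      deg[b$nodes] <= b$degree_range[2L]))
    }
    sizes <- lengths(lapply(bb$bins, `[[`, "nodes"))
    if (length(sizes) > 1L) expect_true(all(sizes >= mbs))
  }
  expect_error(build_degree_bins(rnet, 10000L), "exceeds")
})
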