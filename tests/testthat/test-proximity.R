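path_net <- function(ids = c("a", "b", "c", "d")) {
  e <- data.frame(f = ids[-length(ids)], t = ids[-1L])
  background_network(e, kinds = stats::setNames(rep("protein", length(ids)),
                                                ids))
}

test_that("closest distance averages per-target minima over shortest paths", {
  net <- path_net()
  expect_equal(closest_distance(net, c("a", "b"), c("a", "b", "c")), 0)
  expect_equal(closest_distance(net, "a", "d"), 3)
  expect_equal(closest_distance(net, c("a", "d"), "c"), (2 + 1) / 2)
  expect_error(closest_distance(net, "zz", "a"), "no target")
  expect_error(closest_distance(net, "a", "zz"), "no module node")
})

test_that("closest distance equals the brute-force BFS oracle", {
  set.seed(23)
  for (rep in 1:60) {
    e <- random_edge_df(sample(8:20, 1L), 0.25)
    net <- background_network(e, kinds = all_protein_kinds(e))
    ids <- network_nodes(net)
    T_ <- sample(ids, sample(1:3, 1L))
    S_ <- sample(ids, sample(1:5, 1L))
    want <- oracle_closest_distance(e, T_, S_)
    if (is.nan(want)) {
      # no target reaches the module at all
      expect_error(suppressWarnings(closest_distance(net, T_, S_)), "reaches")
      next
    }
    got <- suppressWarnings(closest_distance(net, T_, S_))
    expect_identical(got, want)
    # and the precomputed-matrix path agrees exactly
    D <- distance_matrix(net)
    expect_identical(suppressWarnings(closest_distance(net, T_, S_, D)), got)
  }
})

test_that("enlarging the module set never increases the distance", {
  set.seed(29)
  e <- random_edge_df(25, 0.15)
  net <- suppressMessages(largest_connected_component(
    background_network(e, kinds = all_protein_kinds(e))))
  ids <- network_nodes(net)
  for (rep in 1:20) {
    T_ <- sample(ids, 3)
    S1 <- sample(ids, 4)
    S2 <- union(S1, sample(ids, 3))
    expect_lte(closest_distance(net, T_, S2), closest_distance(net, T_, S1))
  }
})

test_that("degree-matched sampling matches size and bins", {
  # singleton bin: the only choice is the reference node itself
  star <- data.frame(f = "hub", t = sprintf("s%03d", 1:120))
  net <- background_network(star, kinds = all_protein_kinds(star))
  bins <- build_degree_bins(net, min_bin_size = 1L)
  got <- sample_degree_matched(net, "hub", bins)
  expect_identical(got, "hub")

  # ring: single bin, plain uniform sampling of distinct nodes
  ring <- data.frame(f = sprintf("r%02d", 1:40), t = sprintf("r%02d", c(2:40, 1)))
  rnet <- background_network(ring, kinds = all_protein_kinds(ring))
  rbins <- build_degree_bins(rnet, min_bin_size = 10L)
  s <- sample_degree_matched(rnet, sprintf("r%02d", 1:5), rbins)
  expect_length(s, 5L)
  expect_equal(anyDuplicated(s), 0L)

  # draw frequencies are uniform within binomial bounds
  set.seed(61)
  counts <- table(replicate(4000, sample_degree_matched(rnet, "r01", rbins)))
  expect_length(counts, 40L)
  p0 <- 1 / 40
  bound <- 3 * sqrt(4000 * p0 * (1 - p0))
  expect_true(all(abs(counts - 4000 * p0) <= bound))
})

test_that("degree-matched draws preserve the reference degree profile", {
  b <- synth_bundle(seed = 3)
  bins <- build_degree_bins(b$net)
  deg <- node_degrees(b$net)
  set.seed(71)
  ref <- sample(network_nodes(b$net), 40)
  for (rep in 1:5) {
    got <- sample_degree_matched(b$net, ref, bins)
    expect_length(got, 40L)
    ref_bins <- sort(bins$bin_of[ref])
    got_bins <- sort(bins$bin_of[got])
    expect_equal(unname(ref_bins), unname(got_bins))
  }
})

test_that("proximity z and p behave at the proximal extreme and reproduce", {
  b <- synth_bundle(seed = 4)
  bins <- build_degree_bins(b$net)
  D <- distance_matrix(b$net)
  inside <- sample(b$planted[node_kinds(b$net)[b$planted] == "protein"], 4)
  r1 <- proximity_z(b$net, inside, b$planted, bins, n_perm = 200L,
                    dist_matrix = D, seed = 5L)
  expect_equal(r1$d_obs, 0)
  expect_lt(r1$z, 0)
  expect_lt(r1$p_perm, 0.01)
  expect_gt(r1$p_perm, 0)
  r2 <- proximity_z(b$net, inside, b$planted, bins, n_perm = 200L,
                    dist_matrix = D, seed = 5L)
  expect_identical(r1, r2)
})

test_that("a degenerate permutation null is flagged, not fabricated", {
  # module covering the whole graph: every null distance is exactly 0
  ids <- sprintf("k%d", 1:12)
  e <- data.frame(t(utils::combn(ids, 2L)))
  net <- background_network(e, kinds = all_protein_kinds(e))
  bins <- build_degree_bins(net, min_bin_size = 4L)
  res <- proximity_z(net, ids[1L], ids, bins, n_perm = 100L, seed = 2L)
  expect_true(res$degenerate)
  expect_true(is.na(res$z))
  expect_gt(res$p_perm, 0)
})

test_that("the drug screen flags by the joint rule and sorts by z", {
  b <- synth_bundle(seed = 6)
  drugs <- drug_target_sets(b$drugs$drug_id, b$drugs$drug_name,
                            b$drugs$target_id)
  sub <- drugs[c(b$truth$proximal_drugs[1:3], b$truth$distal_drugs[1:5])]
  res <- suppressMessages(screen_drugs(b$net, sub, b$planted,
                                       n_perm = 200L, seed = 9L))
  expect_equal(nrow(res), 8L)
  expect_true(!is.unsorted(res$z))
  expect_identical(res$candidate,
                   res$z < -2.5 & res$p_perm < 0.01 & !is.na(res$z))
  # proximal drugs flagged, distal not
  expect_true(all(res$candidate[res$drug_id %in% b$truth$proximal_drugs[1:3]]))
  expect_false(any(res$candidate[res$drug_id %in% b$truth$distal_drugs[1:5]]))

  res2 <- suppressMessages(screen_drugs(b$net, sub, b$planted,
                                        n_perm = 200L, seed = 9L))
  expect_identical(res, res2)
})

test_that("drug tables round-trip and unscreenable drugs are skipped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tdrug_name\ttarget_id",
               "D1\taspirin\ta", "D1\taspirin\tb", "D1\taspirin\tb",
               "D2\tghost\tnowhere"), f)
  drugs <- read_drug_targets(f)
  expect_length(drugs, 2L)
  expect_equal(drugs[["D1"]]$targets, c("a", "b"))

  net <- path_net()
  expect_message(
    res <- screen_drugs(net, drugs, "d", n_perm = 100L, seed = 1L,
                        bins = build_degree_bins(net, 2L)),
    "skipped")
  expect_equal(res$drug_id, "D1")
})
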