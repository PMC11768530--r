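test_that("connectivity significance matches exhaustive hypergeometric sums", {
  expect_equal(connectivity_pvalue(50, 10, 4, 0), 1)        # full mass
  expect_equal(connectivity_pvalue(10, 3, 2, 2), 3 / 45)    # single term
  expect_error(connectivity_pvalue(10, 10, 2, 1))           # m < N violated
  expect_error(connectivity_pvalue(10, 3, 2, 3))            # k_m > min(k_i, m)

  set.seed(12)
  for (rep in 1:200) {
    N <- sample(5:60, 1L)
    m <- sample.int(N - 1L, 1L)
    k_i <- sample.int(N - 1L, 1L)
    k_m <- sample.int(min(k_i, m) + 1L, 1L) - 1L
    expect_equal(connectivity_pvalue(N, m, k_i, k_m),
                 oracle_hyper_tail(N, m, k_i, k_m), tolerance = 1e-9)
  }
})

test_that("connectivity significance is monotone nonincreasing in k_m", {
  for (N in c(20, 45)) {
    m <- 8; k_i <- 6
    ps <- vapply(0:min(k_i, m), function(km) connectivity_pvalue(N, m, k_i, km),
                 numeric(1L))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("module-score recursion has the running-mean closed form", {
  mu <- 0.3
  expect_equal(updated_module_score(1.5, mu, 0, 0), 1.5 - mu)  # first node
  # neutral node shrinks the score toward zero
  z5 <- updated_module_score(mu, mu, 1.0, 5)
  expect_equal(z5, 1.0 * 5 / 6)

  set.seed(8)
  for (rep in 1:20) {
    s <- runif(sample(2:12, 1L), 0, 3)
    z <- 0
    for (i in seq_along(s)) z <- updated_module_score(s[i], mu, z, i - 1L)
    expect_equal(z, mean(s - mu), tolerance = 1e-9)
    # order invariance
    sp <- sample(s)
    z2 <- 0
    for (i in seq_along(sp)) z2 <- updated_module_score(sp[i], mu, z2, i - 1L)
    expect_equal(z2, z, tolerance = 1e-9)
  }
})

# fixture: a 5-clique of high-score nodes attached to a long zero-score
# chain. Growth from a clique member must absorb the whole clique: the first
# addition has k_m = 1, k_i <= 5, m = 1, so P = 1 - C(N-1, k_i)/C(N, k_i)
# ~ k_i/N, which needs N >> k_i/alpha -- hence the 600-node background
# (each step's P verified against the exhaustive oracle when choosing sizes).
clique_fixture <- function(n_background = 600L) {
  cl <- sprintf("c%d", 1:5)
  cl_edges <- t(utils::combn(cl, 2L))
  bg <- sprintf("b%02d", seq_len(n_background))
  bg_edges <- cbind(bg[-length(bg)], bg[-1L])
  bridge <- rbind(c("c1", bg[1L]))
  edges <- data.frame(rbind(cl_edges, bg_edges, bridge))
  kinds <- stats::setNames(rep("protein", length(cl) + length(bg)),
                           c(cl, bg))
  net <- background_network(edges, kinds = kinds)
  s <- stats::setNames(numeric(length(cl) + length(bg)), c(cl, bg))
  s[cl] <- 10
  scores <- structure(list(scores = s, mu = mean(s)), class = "node_scores")
  list(net = net, scores = scores, clique = cl)
}

test_that("growth absorbs a high-score clique seeded from inside", {
  fx <- clique_fixture()
  for (rng in c(1L, 2L, 3L)) {
    mod <- grow_module(fx$net, fx$scores, seed = "c3", seed_rng = rng)
    expect_true(all(fx$clique %in% mod$members))
    # zero-score background can never be drawn
    expect_true(all(mod$members %in% fx$clique))
  }
})

test_that("growth stops at the seed when no neighbor is eligible", {
  fx <- clique_fixture()
  # b10 sits in the zero-score chain: all neighbors have s = 0
  mod <- grow_module(fx$net, fx$scores, seed = "b10", seed_rng = 1L)
  expect_equal(mod$members, "b10")
  expect_equal(mod$score, 0 - fx$scores$mu)
})

test_that("growth is deterministic under a fixed rng seed", {
  fx <- clique_fixture()
  m1 <- grow_module(fx$net, fx$scores, seed = "c1", seed_rng = 99L)
  m2 <- grow_module(fx$net, fx$scores, seed = "c1", seed_rng = 99L)
  expect_identical(m1$members, m2$members)
  expect_identical(m1$z_trace, m2$z_trace)
})

test_that("every growth step keeps the module connected and the score rising", {
  set.seed(31)
  for (rep in 1:10) {
    e <- random_edge_df(40, 0.12)
    net <- background_network(e, kinds = all_protein_kinds(e))
    ids <- network_nodes(net)
    s <- stats::setNames(runif(length(ids), 0, 2), ids)
    scores <- structure(list(scores = s, mu = mean(s)), class = "node_scores")
    for (variant in c("mean", "sqrt")) {
      mod <- grow_module(net, scores, seed = ids[1L], alpha = 0.3,
                         variant = variant, seed_rng = rep)
      # replay: each added node must touch an earlier member
      if (length(mod$members) > 1L) {
        adj <- oracle_adjacency(igraph::as_data_frame(net$graph, "edges"))
        for (i in 2:length(mod$members)) {
          expect_true(any(adj[[mod$members[i]]] %in% mod$members[1:(i - 1L)]))
        }
      }
      expect_true(all(diff(mod$z_trace) > 0))
      if (variant == "mean") {
        expect_equal(mod$score, mean(s[mod$members] - scores$mu),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("ensembles are ranked, reproducible, and demand a scored seed pool", {
  fx <- clique_fixture()
  e1 <- build_ensemble(fx$net, fx$scores, n_modules = 1L, seed = 5L)
  expect_length(e1$modules, 1L)

  e2 <- build_ensemble(fx$net, fx$scores, n_modules = 25L, seed = 7L)
  e3 <- build_ensemble(fx$net, fx$scores, n_modules = 25L, seed = 7L)
  expect_identical(lapply(e2$modules, `[[`, "members"),
                   lapply(e3$modules, `[[`, "members"))
  sc <- vapply(e2$modules, `[[`, numeric(1L), "score")
  expect_true(all(diff(sc) <= 1e-12))

  zero <- structure(list(scores = fx$scores$scores * 0, mu = 0),
                    class = "node_scores")
  expect_error(build_ensemble(fx$net, zero, n_modules = 5L, seed = 1L),
               "no positive-score")
})

test_that("consensus assembly respects its fractions and tie rules", {
  fx <- clique_fixture()
  ens <- build_ensemble(fx$net, fx$scores, n_modules = 50L, seed = 13L)
  cons <- consensus_module(ens, fx$net)
  # every module lives inside the clique, so must the consensus
  expect_true(all(cons$nodes %in% fx$clique))
  expect_equal(unname(cons$tally["protein"]), length(cons$nodes))
  expect_equal(sum(cons$tally), length(cons$nodes))

  # node_frac trims to the requested share of distinct pooled nodes
  all_of_top <- consensus_module(ens, fx$net, top_module_frac = 0.1,
                                 node_frac = 1.0)
  trimmed <- consensus_module(ens, fx$net, top_module_frac = 0.1,
                              node_frac = 0.4)
  expect_equal(length(trimmed$nodes),
               ceiling(0.4 * length(all_of_top$nodes)))
  expect_true(all(trimmed$nodes %in% all_of_top$nodes))

  expect_error(consensus_module(ens, fx$net, top_module_frac = 0), "\\(0, 1\\]")
  expect_error(consensus_module(ens, fx$net, node_frac = 1.5), "\\(0, 1\\]")
})
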