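#' Connectivity-significance p-value of a candidate node
#'
#' Probability, under a hypergeometric null, that a node of degree
#' \code{k_i} has at least \code{k_m} of its neighbors inside a module of
#' \code{m} nodes drawn from a network of \code{N} nodes:
#' \deqn{P(i) = \sum_{k = k_m}^{k_i} \frac{\binom{m}{k} \binom{N-m}{k_i-k}}
#'   {\binom{N}{k_i}}.}
#' Computed in log-gamma space; terms with \code{k > m} or
#' \code{k_i - k > N - m} contribute zero, and the result is clamped to
#' \code{[0, 1]} against roundoff.
#'
#' @param N network node count.
#' @param m module size, \code{0 <= m < N}.
#' @param k_i candidate node degree.
#' @param k_m number of the candidate's neighbors inside the module,
#'   \code{0 <= k_m <= min(k_i, m)}.
#' @return the tail probability in \code{[0, 1]}.
#' @examples
#' connectivity_pvalue(10, 3, 2, 2)  # 3/45
#' @export
connectivity_pvalue <- function(N, m, k_i, k_m) {
  stopifnot(length(N) == 1L, length(m) == 1L, length(k_i) == 1L,
            length(k_m) == 1L, N >= 1, m >= 0, m < N,
            k_i >= 0, k_i <= N - 1, k_m >= 0, k_m <= k_i, k_m <= m)
  conn_p_batch(N, m, k_i, k_m)
}

# vectorized over candidates (k_i, k_m); trusted-argument internal hot path
conn_p_batch <- function(N, m, k_i, k_m) {
  lden <- lchoose(N, k_i)
  vapply(seq_along(k_i), function(j) {
    ks <- seq.int(k_m[j], k_i[j])
    ks <- ks[ks <= m & (k_i[j] - ks) <= (N - m)]
    if (!length(ks)) return(0)
    p <- sum(exp(lchoose(m, ks) + lchoose(N - m, k_i[j] - ks) - lden[j]))
    min(max(p, 0), 1)
  }, numeric(1L))
}

#' Updated module score after adding one node
#'
#' Recursion for the running module score: adding node i with score
#' \code{s_i} to a module of \code{m} nodes and score \code{Z_m} gives
#' \deqn{Z_{m+1}(i) = \frac{s_i - \mu + Z_m \cdot m}{m + 1},}
#' whose closed form is the mean of \code{s - mu} over the members. The
#' \code{"sqrt"} variant normalizes the centred score sum by \code{sqrt(m)}
#' instead of \code{m}, i.e. \code{Z_{m+1} = (Z_m sqrt(m) + s_i - mu) /
#' sqrt(m+1)}, which rewards module size the way the original module-growth
#' methodology does (see the package vignette).
#'
#' @param s_i candidate node score.
#' @param mu mean node score over the whole background network.
#' @param Z_m current module score (\code{Z_0 = 0} for the empty module).
#' @param m current module size (\code{m = 0} before seeding).
#' @param variant \code{"mean"} (running average, as above) or \code{"sqrt"}.
#' @return the updated score \code{Z_{m+1}}; vectorized over \code{s_i}.
#' @export
updated_module_score <- function(s_i, mu, Z_m, m, variant = c("mean", "sqrt")) {
  variant <- match.arg(variant)
  stopifnot(m >= 0)
  if (variant == "mean") {
    (s_i - mu + Z_m * m) / (m + 1)
  } else {
    (Z_m * sqrt(m) + s_i - mu) / sqrt(m + 1)
  }
}

# Shared growth context: integer-indexed adjacency, degrees, scores.
grow_context <- function(net, scores) {
  stopifnot(inherits(net, "background_network"), inherits(scores, "node_scores"))
  g <- net$graph
  ids <- igraph::V(g)$name
  if (!setequal(names(scores$scores), ids)) {
    stop("node_scores were built on a different node set than this network")
  }
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  list(ids = ids, adj = adj, deg = as.integer(igraph::degree(g)),
       s = unname(scores$scores[ids]), mu = scores$mu, N = length(ids))
}

# Core growth loop on integer node indices. Returns members (int), z trace.
grow_one <- function(ctx, seed_idx, alpha, max_size, variant) {
  s <- ctx$s; mu <- ctx$mu; adj <- ctx$adj; deg <- ctx$deg; N <- ctx$N
  sqrtv <- variant == "sqrt"
  members <- integer(0L)
  km <- integer(N)           # neighbors-in-module count
  in_mod <- logical(N)
  Z <- 0                      # Z_0: empty module
  ztrace <- numeric(0L)

  add_node <- function(v) {
    members[length(members) + 1L] <<- v
    in_mod[v] <<- TRUE
    for (u in adj[[v]]) km[u] <<- km[u] + 1L
  }

  # the seed is admitted unconditionally
  Z <- s[seed_idx] - mu      # identical under both variants at m = 1
  add_node(seed_idx)
  ztrace <- Z
  cand <- adj[[seed_idx]]
  cand <- cand[s[cand] > 0 & cand != seed_idx]

  while (length(members) < max_size && length(cand)) {
    m <- length(members)
    Znew <- if (sqrtv) (Z * sqrt(m) + s[cand] - mu) / sqrt(m + 1)
            else       (s[cand] - mu + Z * m) / (m + 1)
    ok_z <- Znew > Z
    if (!any(ok_z)) break
    P <- rep(1, length(cand))
    P[ok_z] <- conn_p_batch(N, m, deg[cand[ok_z]], km[cand[ok_z]])
    elig <- which(ok_z & P < alpha)
    if (!length(elig)) break
    w <- s[cand[elig]]
    pick <- if (length(elig) == 1L) elig else {
      elig[sample.int(length(elig), 1L, prob = w)]
    }
    v <- cand[pick]
    Z <- Znew[pick]
    ztrace[length(ztrace) + 1L] <- Z
    add_node(v)
    cand <- cand[cand != v]
    new_cand <- adj[[v]]
    new_cand <- new_cand[s[new_cand] > 0 & !in_mod[new_cand]]
    if (length(new_cand)) cand <- unique(c(cand, new_cand))
  }
  list(members = members, z = Z, ztrace = ztrace)
}

#' Grow one score-weighted disease module from a seed node
#'
#' Starting from the seed (admitted unconditionally), the module repeatedly
#' considers its first-order neighbors as candidates. A candidate i is
#' eligible when adding it would strictly increase the module score
#' (\code{updated_module_score}) and its connectivity-significance p-value
#' (\code{connectivity_pvalue}) is below \code{alpha}. One eligible node is
#' drawn with probability proportional to its score s(i) and appended;
#' growth stops when no eligible candidate remains or \code{max_size} is
#' reached. Candidates with s(i) = 0 carry zero selection probability and
#' are never added.
#'
#' @param net a \code{background_network}.
#' @param scores a \code{node_scores} built on the same network.
#' @param seed seed node id (must exist in the network).
#' @param alpha connectivity-significance level (default 0.01, strict "<").
#' @param max_size hard cap on module size (default 500).
#' @param variant module-score variant passed to
#'   \code{\link{updated_module_score}}; default \code{"sqrt"}.
#' @param seed_rng optional integer to seed the RNG (restored afterwards).
#' @return an object of class \code{gps_module}: list with \code{members}
#'   (ids in addition order), \code{score} (final Z_m), \code{z_trace},
#'   \code{seed} and \code{variant}.
#' @export
grow_module <- function(net, scores, seed, alpha = 0.01, max_size = 500L,
                        variant = c("sqrt", "mean"), seed_rng = NULL) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, alpha < 1)
  ctx <- grow_context(net, scores)
  seed_idx <- match(seed, ctx$ids)
  if (is.na(seed_idx)) stop("seed node not in network: ", seed)
  res <- with_seed(seed_rng, grow_one(ctx, seed_idx, alpha, max_size, variant))
  structure(list(members = ctx$ids[res$members], score = res$z,
                 z_trace = res$ztrace, seed = seed, variant = variant),
            class = "gps_module")
}

#' @export
print.gps_module <- function(x, ...) {
  cat("gps_module: m =", length(x$members), ", Z =", signif(x$score, 5),
      ", seed =", x$seed, ", variant =", x$variant, "\n")
  invisible(x)
}

#' Build an ensemble of stochastic disease modules
#'
#' Runs \code{\link{grow_module}} \code{n_modules} times from seeds drawn
#' uniformly with replacement from the seed pool (by default, nodes with
#' positive score; \code{seed_pool = "all"} uses every network node), and
#' ranks the modules by score (descending), breaking ties toward the smaller
#' module and then the lexicographically smaller seed id.
#'
#' @param net a \code{background_network}.
#' @param scores a \code{node_scores}.
#' @param n_modules number of raw modules (default 10000; the original
#'   interactome-scale analysis used 100000).
#' @param alpha connectivity-significance level (default 0.01).
#' @param seed integer RNG seed for reproducibility.
#' @param seed_pool \code{"positive"} (default) or \code{"all"}.
#' @param max_size per-module size cap.
#' @param variant module-score variant, see \code{\link{grow_module}}.
#' @return an object of class \code{module_ensemble}: list with
#'   \code{modules} (ranked list of \code{gps_module}), \code{scores}
#'   (the \code{node_scores} used), and the call parameters.
#' @export
build_ensemble <- function(net, scores, n_modules = 10000L, alpha = 0.01,
                           seed = NULL, seed_pool = c("positive", "all"),
                           max_size = 500L, variant = c("sqrt", "mean")) {
  seed_pool <- match.arg(seed_pool)
  variant <- match.arg(variant)
  stopifnot(n_modules >= 1L)
  ctx <- grow_context(net, scores)
  pool <- if (seed_pool == "positive") which(ctx$s > 0) else seq_len(ctx$N)
  if (!length(pool)) stop("no positive-score node available as a module seed")
  mods <- with_seed(seed, {
    seeds <- pool[sample.int(length(pool), n_modules, replace = TRUE)]
    lapply(seeds, function(si) {
      r <- grow_one(ctx, si, alpha, max_size, variant)
      list(members = ctx$ids[r$members], score = r$z, z_trace = r$ztrace,
           seed = ctx$ids[si], variant = variant)
    })
  })
  sc <- vapply(mods, `[[`, numeric(1L), "score")
  sz <- vapply(mods, function(m) length(m$members), integer(1L))
  sd_id <- vapply(mods, `[[`, character(1L), "seed")
  ord <- order(-sc, sz, sd_id)
  mods <- lapply(mods[ord], function(m) structure(m, class = "gps_module"))
  structure(list(modules = mods, scores = scores, n_modules = n_modules,
                 alpha = alpha, seed_pool = seed_pool, variant = variant),
            class = "module_ensemble")
}

#' @export
print.module_ensemble <- function(x, ...) {
  sz <- vapply(x$modules, function(m) length(m$members), integer(1L))
  cat("module_ensemble: ", length(x$modules), " modules (sizes ",
      min(sz), "-", max(sz), "), top score ",
      signif(x$modules[[1L]]$score, 5), "\n", sep = "")
  invisible(x)
}

#' Assemble the consensus disease module from a module ensemble
#'
#' Takes the best \code{ceiling(top_module_frac * n)} modules of the ranked
#' ensemble, counts how often each node occurs in them, ranks nodes by that
#' frequency (ties broken toward higher node score, then lexicographic id),
#' and keeps the top \code{ceiling(node_frac * d)} nodes, where d is the
#' number of distinct nodes appearing in those top modules. The default
#' \code{node_frac = 1} keeps every node of the top modules, which is the
#' appropriate setting when the ensemble concentrates on the signal
#' neighborhood (benchmark scale); at interactome scale with very large
#' ensembles a small fraction (e.g. 0.05) trims the long low-frequency tail
#' (see the package vignette).
#'
#' @param ens a \code{module_ensemble}.
#' @param net the \code{background_network} the ensemble was grown on.
#' @param top_module_frac fraction of top-ranked modules to pool
#'   (default 0.01).
#' @param node_frac fraction of the distinct pooled nodes to keep
#'   (default 1).
#' @return an object of class \code{consensus_module}: list with
#'   \code{nodes}, \code{frequency} (named counts), \code{graph} (induced
#'   igraph subgraph), \code{n_components}, \code{n_edges} and \code{tally}
#'   (protein/metabolite counts).
#' @export
consensus_module <- function(ens, net, top_module_frac = 0.01, node_frac = 1.0) {
  stopifnot(inherits(ens, "module_ensemble"),
            inherits(net, "background_network"))
  if (top_module_frac <= 0 || top_module_frac > 1 ||
      node_frac <= 0 || node_frac > 1) {
    stop("top_module_frac and node_frac must lie in (0, 1]")
  }
  n_top <- ceiling(top_module_frac * length(ens$modules))
  top <- ens$modules[seq_len(n_top)]
  freq_tab <- table(unlist(lapply(top, `[[`, "members")))
  freq <- as.integer(freq_tab)
  names(freq) <- names(freq_tab)
  s <- ens$scores$scores[names(freq)]
  ord <- order(-freq, -s, names(freq))
  n_keep <- ceiling(node_frac * length(freq))
  keep <- names(freq)[ord][seq_len(n_keep)]
  g <- igraph::induced_subgraph(net$graph, keep)
  kinds <- igraph::V(g)$kind
  structure(list(
    nodes = sort(keep),
    frequency = freq[sort(keep)],
    graph = g,
    n_components = igraph::components(g)$no,
    n_edges = igraph::ecount(g),
    tally = c(protein = sum(kinds == "protein"),
              metabolite = sum(kinds == "metabolite")),
    n_top_modules = n_top
  ), class = "consensus_module")
}

#' @export
print.consensus_module <- function(x, ...) {
  cat("consensus_module:", length(x$nodes), "nodes (",
      x$tally[["protein"]], "proteins,", x$tally[["metabolite"]],
      "metabolites ),", x$n_edges, "edges,", x$n_components,
      "component(s); pooled from top", x$n_top_modules, "modules\n")
  invisible(x)
}

#' Write a consensus module as node and edge TSV tables
#'
#' @param cons a \code{consensus_module}.
#' @param scores the \code{node_scores} used to grow the ensemble.
#' @param node_path,edge_path output TSV paths.
#' @export
write_consensus <- function(cons, scores, node_path, edge_path) {
  kinds <- igraph::V(cons$graph)$kind
  names(kinds) <- igraph::V(cons$graph)$name
  nodes <- data.frame(id = cons$nodes,
                      kind = unname(kinds[cons$nodes]),
                      frequency = unname(cons$frequency[cons$nodes]),
                      score = unname(scores$scores[cons$nodes]),
                      stringsAsFactors = FALSE)
  write_tsv_plain(nodes, node_path)
  ed <- igraph::as_data_frame(cons$graph, what = "edges")[, 1:2]
  names(ed) <- c("from", "to")
  write_tsv_plain(ed[order(ed$from, ed$to), , drop = FALSE], edge_path)
  invisible(c(node_path, edge_path))
}
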