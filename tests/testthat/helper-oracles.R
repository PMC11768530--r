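# Independent oracles: adjacency sets + hand-rolled BFS, exhaustive
# hypergeometric sums, rank-assignment enumeration, step-up BH. None of them
# touch igraph or the package's own code paths.

# edge data.frame -> named adjacency list over character ids
oracle_adjacency <- function(edges) {
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  lo <- lo[first]; hi <- hi[first]
  ids <- sort(unique(c(lo, hi)))
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(lo)) {
    adj[[lo[i]]] <- c(adj[[lo[i]]], hi[i])
    adj[[hi[i]]] <- c(adj[[hi[i]]], lo[i])
  }
  adj
}

# plain queue BFS; returns named hop counts from `from` (Inf if unreachable)
oracle_bfs <- function(adj, from) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (!is.finite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

oracle_components <- function(adj) {
  seen <- character(0L)
  comps <- list()
  for (v in names(adj)) {
    if (v %in% seen) next
    d <- oracle_bfs(adj, v)
    comp <- names(d)[is.finite(d)]
    comps[[length(comps) + 1L]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}

oracle_closest_distance <- function(edges, T_, S_) {
  adj <- oracle_adjacency(edges)
  mins <- vapply(T_, function(t) min(oracle_bfs(adj, t)[S_]), numeric(1L))
  mean(mins[is.finite(mins)])
}

# exhaustive hypergeometric tail using exact choose()
oracle_hyper_tail <- function(N, m, k_i, k_m) {
  total <- 0
  for (k in k_m:k_i) {
    if (k > m || (k_i - k) > (N - m)) next
    total <- total + choose(m, k) * choose(N - m, k_i - k)
  }
  total / choose(N, k_i)
}

# brute-force step-up BH
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[ord[i]] * n / i)
    q[ord[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# exact two-sided Mann-Whitney p by enumerating all rank assignments
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  W_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  Ws <- apply(combs, 2L, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  min(1, mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9))
}

# random edge data.frame over n nodes (may be disconnected)
random_edge_df <- function(n, p_edge = 0.1) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(ncol(pairs), 1L)] <- TRUE
  data.frame(from = ids[pairs[1L, keep]], to = ids[pairs[2L, keep]],
             stringsAsFactors = FALSE)
}

all_protein_kinds <- function(edges) {
  ids <- unique(c(as.character(edges[[1L]]), as.character(edges[[2L]])))
  stats::setNames(rep("protein", length(ids)), ids)
}

# small omics table with programmed per-feature log2 effects
toy_omics <- function(effects, n_per_group = 6L, sigma = 0.2, base = 10,
                      vip = NULL, seed = 1L) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    groups <- rep(c("control", "case"), each = n_per_group)
    names(groups) <- paste0(groups, "_", seq_along(groups))
    m <- 2^(base + outer(effects, as.numeric(groups == "case")) +
              matrix(rnorm(length(effects) * length(groups), sd = sigma),
                     nrow = length(effects)))
    rownames(m) <- names(effects)
    colnames(m) <- names(groups)
    omics_table(m, groups, vip = vip)
  })
}
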