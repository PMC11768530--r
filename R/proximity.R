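#' Read a drug-target table
#'
#' Expects a TSV with one row per drug-target pair and columns drug_id,
#' drug_name, target_id (header optional; DrugBank-style identifiers are
#' treated as opaque strings). Duplicate targets within a drug collapse to a
#' set.
#'
#' @param path TSV file.
#' @return a named list of \code{drug_target_set} objects (lists with
#'   \code{drug_id}, \code{drug_name}, \code{targets}).
#' @export
read_drug_targets <- function(path) {
  df <- read_tsv_plain(path, header = FALSE)
  if (ncol(df) < 3L) stop("drug table needs columns drug_id, drug_name, target_id")
  if (identical(tolower(as.character(df[1L, 1L])), "drug_id")) df <- df[-1L, ]
  drug_target_sets(df[[1L]], df[[2L]], df[[3L]])
}

#' @rdname read_drug_targets
#' @param drug_id,drug_name,target_id parallel vectors, one element per
#'   drug-target pair.
#' @export
drug_target_sets <- function(drug_id, drug_name, target_id) {
  drug_id <- as.character(drug_id)
  drug_name <- as.character(drug_name)
  target_id <- as.character(target_id)
  ids <- unique(drug_id)
  out <- lapply(ids, function(d) {
    rows <- drug_id == d
    structure(list(drug_id = d, drug_name = drug_name[rows][1L],
                   targets = sort(unique(target_id[rows]))),
              class = "drug_target_set")
  })
  stats::setNames(out, ids)
}

#' Closest-distance network proximity between two node sets
#'
#' The closest measure: for each target t in T, take the shortest-path hop
#' count to the nearest node of S, and average over T:
#' \deqn{d(T, S) = \frac{1}{|T|} \sum_{t \in T} \min_{s \in S} d(t, s).}
#' Node ids absent from the network are dropped before the computation;
#' targets with no finite path to any node of S (impossible on a connected
#' component) are excluded from the average with a warning.
#'
#' @param net a \code{background_network}.
#' @param targets character vector of target node ids (T).
#' @param module_nodes character vector of module node ids (S).
#' @param dist_matrix optional precomputed all-pairs hop-count matrix (as
#'   from \code{\link{distance_matrix}}) used instead of fresh BFS.
#' @return the mean closest distance (0 iff every mapped target is in S).
#' @export
closest_distance <- function(net, targets, module_nodes, dist_matrix = NULL) {
  ids <- network_nodes(net)
  T_ <- intersect(unique(targets), ids)
  S_ <- intersect(unique(module_nodes), ids)
  if (!length(T_)) stop("no target maps to the network")
  if (!length(S_)) stop("no module node maps to the network")
  if (is.null(dist_matrix)) {
    D <- igraph::distances(net$graph, v = T_, to = S_)
  } else {
    D <- dist_matrix[T_, S_, drop = FALSE]
  }
  mins <- apply(D, 1L, min)
  if (any(!is.finite(mins))) {
    warning(sum(!is.finite(mins)),
            " target(s) unreachable from the module; excluded from the average")
    mins <- mins[is.finite(mins)]
    if (!length(mins)) stop("no target reaches the module")
  }
  mean(mins)
}

#' All-pairs hop-count distance matrix of a background network
#'
#' Convenience wrapper used to make permutation screens fast on networks of
#' a few thousand nodes (the matrix takes 8 N^2 bytes).
#'
#' @param net a \code{background_network}.
#' @return numeric matrix with node ids as dimnames.
#' @export
distance_matrix <- function(net) {
  igraph::distances(net$graph)
}

#' Degree-matched random node set
#'
#' Draws, for each node of \code{reference}, one node uniformly from the
#' reference node's degree bin, without replacement within the returned
#' sample, so the result has \code{length(reference)} distinct nodes whose
#' degree distribution matches the reference at bin resolution. When a bin
#' is exhausted the draw falls back to the nearest neighboring bin.
#'
#' @param net a \code{background_network}.
#' @param reference character vector of node ids to match.
#' @param bins a \code{degree_binning} built on \code{net}.
#' @return character vector of sampled node ids.
#' @export
sample_degree_matched <- function(net, reference, bins) {
  stopifnot(inherits(bins, "degree_binning"))
  reference <- unique(reference)
  bi <- bins$bin_of[reference]
  if (any(is.na(bi))) stop("reference node(s) not covered by the binning")
  nb <- length(bins$bins)
  need <- tabulate(bi, nbins = nb)
  chosen <- vector("list", nb)
  overflow <- 0L
  over_mid <- numeric(0L)
  # draws are exchangeable within a bin, so sample each bin's quota at once
  for (b in seq_len(nb)) {
    if (!need[b]) next
    pool <- bins$bins[[b]]$nodes
    take <- min(need[b], length(pool))
    chosen[[b]] <- pool[sample.int(length(pool), take)]
    if (need[b] > take) {
      overflow <- overflow + (need[b] - take)
      over_mid <- c(over_mid, mean(bins$bins[[b]]$degree_range))
    }
  }
  out <- unlist(chosen, use.names = FALSE)
  if (overflow > 0L) {
    # bin exhausted: fall back to the remaining nodes nearest in degree
    message(overflow, " draw(s) spilled into neighboring degree bins")
    rest <- setdiff(unlist(lapply(bins$bins, `[[`, "nodes")), out)
    if (length(rest) < overflow) stop("sample larger than network")
    deg <- node_degrees(net)
    rest <- rest[order(abs(deg[rest] - mean(over_mid)))]
    out <- c(out, rest[seq_len(overflow)])
  }
  out
}

#' Permutation-normalized network proximity of one drug
#'
#' Computes the observed closest distance d(T, S) between the drug's mapped
#' targets and the module, then builds a degree-preserving permutation null:
#' in each of \code{n_perm} rounds a random node set of the same size and
#' degree distribution as the drug's targets replaces them, and the random
#' distance d_r to the (fixed) module is recorded;
#' \code{randomize = "both"} additionally replaces the module set with a
#' degree-matched draw each round. The fixed-module null is exchangeable
#' under the no-association hypothesis and yields uniform empirical
#' p-values; the double-randomized null is not, because a connected module
#' and its scattered degree-matched replacement cover the network
#' differently. The proximity z-score is
#' \code{z = (d_obs - mean(d_r)) / sd(d_r)} and the empirical p-value is the
#' one-sided (small-distance) tail with add-one and mid-p tie correction,
#' \code{p = (1 + #\{d_r < d_obs\} + 0.5 #\{d_r = d_obs\}) / (n_perm + 1)},
#' so p is never 0. The mid-p treatment of ties matters because closest
#' distances live on the lattice of multiples of 1/|T|: counting the full
#' tie mass in the tail would make p systematically conservative.
#'
#' @param net a \code{background_network} (distances are meaningful on a
#'   connected component).
#' @param drug a \code{drug_target_set} or a character vector of target ids.
#' @param module_nodes module node ids (S).
#' @param bins a \code{degree_binning} on \code{net}.
#' @param n_perm number of permutation rounds (default 1000).
#' @param randomize \code{"targets-only"} (default) or \code{"both"}.
#' @param dist_matrix optional precomputed \code{\link{distance_matrix}}.
#' @param seed optional RNG seed (restored afterwards).
#' @return a one-row data.frame: drug_id, drug_name, n_targets, n_mapped,
#'   d_obs, mu_rand, sigma_rand, z, p_perm, n_perm, degenerate.
#' @export
proximity_z <- function(net, drug, module_nodes, bins, n_perm = 1000L,
                        randomize = c("targets-only", "both"),
                        dist_matrix = NULL, seed = NULL) {
  randomize <- match.arg(randomize)
  stopifnot(n_perm >= 100L)
  if (is.character(drug)) {
    drug <- structure(list(drug_id = "drug", drug_name = "drug",
                           targets = sort(unique(drug))),
                      class = "drug_target_set")
  }
  ids <- network_nodes(net)
  T_ <- intersect(drug$targets, ids)
  S_ <- intersect(unique(module_nodes), ids)
  if (!length(T_)) stop("drug ", drug$drug_id, " has no target in the network")
  if (!length(S_)) stop("module has no node in the network")
  d_obs <- closest_distance(net, T_, S_, dist_matrix = dist_matrix)
  d_rand <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      Tr <- sample_degree_matched(net, T_, bins)
      Sr <- if (randomize == "both") sample_degree_matched(net, S_, bins) else S_
      closest_distance(net, Tr, Sr, dist_matrix = dist_matrix)
    }, numeric(1L))
  })
  mu <- mean(d_rand)
  sigma <- stats::sd(d_rand)
  degenerate <- !is.finite(sigma) || sigma == 0
  z <- if (degenerate) NA_real_ else (d_obs - mu) / sigma
  p <- (1 + sum(d_rand < d_obs - 1e-12) +
          0.5 * sum(abs(d_rand - d_obs) <= 1e-12)) / (n_perm + 1)
  data.frame(drug_id = drug$drug_id, drug_name = drug$drug_name,
             n_targets = length(drug$targets), n_mapped = length(T_),
             d_obs = d_obs, mu_rand = mu, sigma_rand = sigma, z = z,
             p_perm = p, n_perm = n_perm, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Screen a drug library against a disease module
#'
#' Runs \code{\link{proximity_z}} for every drug with at least
#' \code{min_targets} mapped targets and flags candidates with
#' \code{z < z_thresh} and \code{p_perm < p_thresh}. Results are sorted by
#' z ascending (most proximal first), ties broken by drug_id. On networks of
#' at most \code{precompute_max} nodes an all-pairs distance matrix is
#' precomputed once.
#'
#' @param net a \code{background_network}.
#' @param drugs list of \code{drug_target_set} (as from
#'   \code{\link{read_drug_targets}}).
#' @param module_nodes module node ids (S).
#' @param bins optional \code{degree_binning}; built with the default
#'   \code{min_bin_size} when absent.
#' @param z_thresh,p_thresh candidate thresholds (defaults -2.5 and 0.01).
#' @param n_perm permutations per drug (default 1000).
#' @param min_targets minimum mapped targets for a drug to be screened
#'   (default 1).
#' @param randomize see \code{\link{proximity_z}}.
#' @param seed RNG seed governing the whole screen.
#' @param precompute_max largest node count for which the all-pairs distance
#'   matrix is precomputed (default 5000).
#' @return data.frame with one row per screened drug (columns as in
#'   \code{\link{proximity_z}} plus \code{candidate}), sorted by z.
#' @export
screen_drugs <- function(net, drugs, module_nodes, bins = NULL,
                         z_thresh = -2.5, p_thresh = 0.01, n_perm = 1000L,
                         min_targets = 1L,
                         randomize = c("targets-only", "both"), seed = NULL,
                         precompute_max = 5000L) {
  randomize <- match.arg(randomize)
  if (is.null(bins)) bins <- build_degree_bins(net)
  ids <- network_nodes(net)
  keep <- vapply(drugs, function(d) {
    sum(d$targets %in% ids) >= min_targets
  }, logical(1L))
  if (!any(keep)) stop("no screenable drug (all below min_targets mapped targets)")
  if (any(!keep)) {
    message(sum(!keep), " drug(s) skipped: fewer than ", min_targets,
            " mapped target(s)")
  }
  D <- if (length(ids) <= precompute_max) distance_matrix(net) else NULL
  rows <- with_seed(seed, {
    lapply(drugs[keep], function(d) {
      proximity_z(net, d, module_nodes, bins, n_perm = n_perm,
                  randomize = randomize, dist_matrix = D, seed = NULL)
    })
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$candidate <- !is.na(res$z) & res$z < z_thresh & res$p_perm < p_thresh
  res[order(res$z, res$drug_id), , drop = FALSE]
}
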