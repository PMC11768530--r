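#' Construct a typed metabolite-protein background network
#'
#' The background network is an undirected simple graph whose nodes are
#' proteins or metabolites. It is the arena for disease-module growth and for
#' network-proximity distances: it supplies the node count N and the node
#' degrees used by the connectivity-significance test and by degree-preserving
#' permutation sampling.
#'
#' Self-loops and duplicate edges are dropped (with counts recorded in the
#' returned object), so the graph is always simple.
#'
#' @param edges two-column data.frame (or matrix) of node-id pairs, one edge
#'   per row; additional columns are ignored.
#' @param kinds named character vector or two-column data.frame (id, kind)
#'   mapping node ids to \code{"protein"} or \code{"metabolite"}. Ids absent
#'   from \code{kinds} take \code{default_kind}.
#' @param default_kind kind assigned to ids missing from \code{kinds};
#'   \code{NULL} (the default) makes missing kinds an error.
#' @return an object of class \code{background_network}: a list with elements
#'   \code{graph} (an \pkg{igraph} graph with vertex attributes \code{name}
#'   and \code{kind}), \code{n_dropped_self} and \code{n_dropped_dup}.
#' @examples
#' net <- background_network(data.frame(from = c("a", "b"), to = c("b", "c")),
#'                           kinds = c(a = "protein", b = "protein",
#'                                     c = "metabolite"))
#' network_size(net)
#' @export
background_network <- function(edges, kinds, default_kind = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge table needs at least two columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  bad <- is.na(a) | is.na(b) | a == "" | b == ""
  if (any(bad)) {
    stop("malformed edge row(s) at line(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  # canonical unordered representation for dedup
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]

  ids <- sort(unique(c(lo, hi)))
  kind_map <- as_kind_map(kinds)
  kind <- unname(kind_map[ids])
  missing <- is.na(kind)
  if (any(missing)) {
    if (is.null(default_kind)) {
      stop("no kind for node id(s): ",
           paste(utils::head(ids[missing], 5L), collapse = ", "),
           " and no default_kind configured")
    }
    kind[missing] <- default_kind
    warning(sum(missing), " node(s) without a kind assigned default '",
            default_kind, "'")
  }
  bad_kind <- !kind %in% c("protein", "metabolite")
  if (any(bad_kind)) {
    stop("invalid kind(s): ", paste(unique(kind[bad_kind]), collapse = ", "))
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, kind = kind, stringsAsFactors = FALSE)
  )
  structure(list(graph = g, n_dropped_self = n_self, n_dropped_dup = n_dup),
            class = "background_network")
}

as_kind_map <- function(kinds) {
  if (is.null(kinds)) return(character(0))
  if (is.data.frame(kinds)) {
    stopifnot(ncol(kinds) >= 2L)
    stats::setNames(as.character(kinds[[2L]]), as.character(kinds[[1L]]))
  } else {
    stopifnot(!is.null(names(kinds)))
    stats::setNames(as.character(kinds), names(kinds))
  }
}

#' Read an edge list file into a background network
#'
#' Accepts whitespace/tab-delimited two-column edge lists, or SIF rows
#' (\code{a interaction b}, in which case the middle column is dropped when
#' three or more columns are present and \code{sif = TRUE}). Lines starting
#' with \code{#} are comments. Duplicate edges and self-loops are removed.
#'
#' @param path edge-list file.
#' @param node_kinds named character vector / data.frame id -> kind, or a path
#'   to a two-column TSV (id, kind).
#' @param default_kind kind used for ids missing from \code{node_kinds}
#'   (default \code{"protein"}, with a warning).
#' @param sif treat 3+ column rows as SIF and drop the interaction column.
#' @return a \code{background_network}.
#' @export
load_edge_list <- function(path, node_kinds = NULL, default_kind = "protein",
                           sif = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("no edges in ", path)
  parts <- strsplit(trimws(lines), "[\t ]+")
  nfield <- lengths(parts)
  bad <- nfield < 2L
  if (any(bad)) {
    stop("malformed row (fewer than 2 node ids) at line ",
         lineno[which(bad)[1L]], " of ", path)
  }
  a <- vapply(parts, `[[`, character(1L), 1L)
  b <- vapply(parts, function(p) if (sif && length(p) >= 3L) p[[3L]] else p[[2L]],
              character(1L))
  if (is.character(node_kinds) && length(node_kinds) == 1L &&
      is.null(names(node_kinds)) && file.exists(node_kinds)) {
    node_kinds <- read_node_kinds(node_kinds)
  }
  background_network(data.frame(from = a, to = b, stringsAsFactors = FALSE),
                     kinds = node_kinds, default_kind = default_kind)
}

#' Read a node-kind table (two-column TSV: id, kind)
#' @param path TSV file with columns id and kind (header optional).
#' @return named character vector id -> kind.
#' @export
read_node_kinds <- function(path) {
  df <- read_tsv_plain(path, header = FALSE)
  if (identical(tolower(as.character(df[1L, 2L])), "kind")) df <- df[-1L, ]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @export
print.background_network <- function(x, ...) {
  g <- x$graph
  k <- table(igraph::V(g)$kind)
  cat("background_network:", igraph::vcount(g), "nodes (",
      paste(sprintf("%s %s", k, names(k)), collapse = ", "), "),",
      igraph::ecount(g), "edges\n")
  if (x$n_dropped_self + x$n_dropped_dup > 0) {
    cat("  dropped at load:", x$n_dropped_self, "self-loop(s),",
        x$n_dropped_dup, "duplicate edge(s)\n")
  }
  invisible(x)
}

#' Node ids, kinds, counts and degrees of a background network
#' @param net a \code{background_network}.
#' @return \code{network_nodes}: character vector of node ids;
#'   \code{node_kinds}: named kind vector; \code{network_size}: named vector
#'   with \code{nodes} and \code{edges}; \code{node_degrees}: named integer
#'   degree vector.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' @rdname network_nodes
#' @export
node_kinds <- function(net) {
  stats::setNames(igraph::V(net$graph)$kind, igraph::V(net$graph)$name)
}

#' @rdname network_nodes
#' @export
network_size <- function(net) {
  c(nodes = igraph::vcount(net$graph), edges = igraph::ecount(net$graph))
}

#' @rdname network_nodes
#' @export
node_degrees <- function(net) {
  d <- igraph::degree(net$graph)
  stats::setNames(as.integer(d), igraph::V(net$graph)$name)
}

#' Merge a protein-protein and a metabolite-enzyme network
#'
#' Node set is the union of the inputs; the edge set is the deduplicated
#' union. Shared ids (typically enzymes present in both layers) must carry
#' the same kind in both inputs. The merge is commutative and idempotent.
#'
#' @param ppi,metabolic \code{background_network} objects sharing a consistent
#'   id namespace.
#' @return the merged \code{background_network}.
#' @export
merge_networks <- function(ppi, metabolic) {
  stopifnot(inherits(ppi, "background_network"),
            inherits(metabolic, "background_network"))
  k1 <- node_kinds(ppi); k2 <- node_kinds(metabolic)
  shared <- intersect(names(k1), names(k2))
  conflict <- shared[k1[shared] != k2[shared]]
  if (length(conflict)) {
    stop("conflicting node kinds for shared id(s): ",
         paste(utils::head(conflict, 10L), collapse = ", "))
  }
  e1 <- igraph::as_data_frame(ppi$graph, what = "edges")
  e2 <- igraph::as_data_frame(metabolic$graph, what = "edges")
  kinds <- c(k1, k2[setdiff(names(k2), names(k1))])
  # isolated nodes (none by construction, but keep the union semantics exact)
  all_edges <- rbind(e1[, 1:2], e2[, 1:2])
  background_network(all_edges, kinds = kinds)
}

#' Restrict a network to its largest connected component
#'
#' Module growth and network proximity are computed on the largest connected
#' component (LCC) so that all shortest-path distances are finite. Ties in
#' component size are broken toward the component containing the
#' lexicographically smallest node id.
#'
#' @param net a nonempty \code{background_network}.
#' @return the induced \code{background_network} on the LCC.
#' @export
largest_connected_component <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop("empty network")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest lexicographic member id wins
    first_member <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1L))
    best <- best[order(first_member)][1L]
  }
  keep <- igraph::V(g)[comp$membership == best]
  sub <- igraph::induced_subgraph(g, keep)
  message("largest connected component: ", igraph::vcount(sub), " of ",
          igraph::vcount(g), " nodes (", comp$no, " component(s))")
  structure(list(graph = sub, n_dropped_self = net$n_dropped_self,
                 n_dropped_dup = net$n_dropped_dup),
            class = "background_network")
}

#' Partition network nodes into degree bins
#'
#' Nodes are sorted by degree and grouped into contiguous bins of at least
#' \code{min_bin_size} nodes; nodes of equal degree are never split across
#' bins, and a trailing undersized bin is merged into its predecessor. The
#' binning is the basis for degree-preserving permutation sampling: a random
#' replacement for a node is drawn from the node's own degree bin, which
#' matches the degree distribution of a reference set without requiring exact
#' degree matches for high-degree hubs.
#'
#' @param net a \code{background_network}.
#' @param min_bin_size minimum nodes per bin (default 100).
#' @return an object of class \code{degree_binning}: list with \code{bins}
#'   (each a list with \code{degree_range} and \code{nodes}) and
#'   \code{bin_of} (named integer: node id -> bin index).
#' @export
build_degree_bins <- function(net, min_bin_size = 100L) {
  stopifnot(min_bin_size >= 1L)
  deg <- node_degrees(net)
  n <- length(deg)
  if (min_bin_size > n) stop("min_bin_size exceeds node count")
  ord <- order(deg, names(deg))
  deg_sorted <- deg[ord]
  # group by distinct degree, then accumulate groups into bins
  groups <- split(names(deg_sorted), factor(deg_sorted, levels = unique(deg_sorted)))
  bins <- list()
  cur_nodes <- character(0)
  cur_degs <- integer(0)
  for (gi in seq_along(groups)) {
    cur_nodes <- c(cur_nodes, groups[[gi]])
    cur_degs <- c(cur_degs, as.integer(names(groups)[gi]))
    if (length(cur_nodes) >= min_bin_size) {
      bins[[length(bins) + 1L]] <- list(degree_range = range(cur_degs),
                                        nodes = cur_nodes)
      cur_nodes <- character(0); cur_degs <- integer(0)
    }
  }
  if (length(cur_nodes)) {
    if (length(bins)) {
      last <- bins[[length(bins)]]
      bins[[length(bins)]] <- list(
        degree_range = range(c(last$degree_range, cur_degs)),
        nodes = c(last$nodes, cur_nodes))
    } else {
      bins[[1L]] <- list(degree_range = range(cur_degs), nodes = cur_nodes)
    }
  }
  bin_of <- integer(n)
  names(bin_of) <- character(n)
  i <- 1L
  for (bi in seq_along(bins)) {
    ids <- bins[[bi]]$nodes
    idx <- seq.int(i, i + length(ids) - 1L)
    bin_of[idx] <- bi
    names(bin_of)[idx] <- ids
    i <- i + length(ids)
  }
  structure(list(bins = bins, bin_of = bin_of, min_bin_size = min_bin_size),
            class = "degree_binning")
}

#' @export
print.degree_binning <- function(x, ...) {
  cat("degree_binning:", length(x$bins), "bin(s), min size", x$min_bin_size, "\n")
  for (b in x$bins) {
    cat(sprintf("  degree %d-%d: %d nodes\n", b$degree_range[1L],
                b$degree_range[2L], length(b$nodes)))
  }
  invisible(x)
}
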