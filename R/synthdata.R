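#' Generate a synthetic metabolite-protein background network
#'
#' Emulates the topology of a merged interactome: a scale-free(ish)
#' protein-protein layer grown by preferential attachment, plus a
#' metabolite-enzyme layer in which each metabolite is wired to 1-8 protein
#' "enzymes" chosen with degree-biased probability (metabolite-metabolite
#' edges never occur). The result is simple and connected.
#'
#' @param n_proteins,n_metabolites node counts (each at least 10).
#' @param attachment edges added per new protein in the preferential-
#'   attachment growth (default 3).
#' @param seed integer RNG seed; the generator is a pure function of its
#'   parameters and seed.
#' @return a \code{background_network} with protein ids \code{P0001...} and
#'   metabolite ids \code{cpd:M0001...}.
#' @export
generate_network <- function(n_proteins = 1800L, n_metabolites = 200L,
                             attachment = 3L, seed = NULL) {
  if (n_proteins < 10L || n_metabolites < 10L) {
    stop("need at least 10 proteins and 10 metabolites")
  }
  stopifnot(attachment >= 1L)
  with_seed(seed, {
    g <- igraph::sample_pa(n_proteins, m = attachment, directed = FALSE)
    g <- igraph::simplify(g)
    pid <- sprintf("P%04d", seq_len(n_proteins))
    ppi <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(from = pid[ppi[, 1L]], to = pid[ppi[, 2L]],
                        stringsAsFactors = FALSE)
    deg <- igraph::degree(g)
    mid <- sprintf("cpd:M%04d", seq_len(n_metabolites))
    met_edges <- lapply(seq_len(n_metabolites), function(i) {
      k <- sample.int(8L, 1L)
      enz <- sample.int(n_proteins, k, prob = deg)
      data.frame(from = mid[i], to = pid[enz], stringsAsFactors = FALSE)
    })
    all_edges <- rbind(edges, do.call(rbind, met_edges))
    kinds <- c(stats::setNames(rep("protein", n_proteins), pid),
               stats::setNames(rep("metabolite", n_metabolites), mid))
    background_network(all_edges, kinds = kinds)
  })
}

#' Plant a connected module in a network
#'
#' Grows a random connected subgraph of the requested size by repeated
#' neighbor expansion from a random seed node; the next member is drawn with
#' probability proportional to its number of edges into the current set, so
#' well-connected neighborhoods are preferred. When the network contains
#' metabolites and \code{size > 1}, the expansion is retried (up to 25
#' times) until the module contains at least one metabolite, mirroring the
#' mixed protein/metabolite composition of real disease modules.
#'
#' @param net a \code{background_network}.
#' @param size module size (default 60; must not exceed the node count).
#' @param seed integer RNG seed.
#' @return character vector of planted node ids (induces a connected
#'   subgraph).
#' @export
plant_module <- function(net, size = 60L, seed = NULL) {
  ids <- network_nodes(net)
  if (size > length(ids)) stop("module size exceeds network size")
  if (size < 1L) stop("size must be at least 1")
  kinds <- node_kinds(net)
  g <- net$graph
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  with_seed(seed, {
    grow_once <- function() {
      start <- sample.int(length(ids), 1L)
      members <- start
      in_set <- logical(length(ids)); in_set[start] <- TRUE
      # multiset frontier: multiplicity = number of edges into the set
      frontier <- adj[[start]]
      while (length(members) < size) {
        frontier <- frontier[!in_set[frontier]]
        if (!length(frontier)) break   # cannot happen on a connected graph
        nxt <- frontier[sample.int(length(frontier), 1L)]
        members <- c(members, nxt)
        in_set[nxt] <- TRUE
        frontier <- c(frontier, adj[[nxt]])
      }
      members
    }
    want_metab <- size > 1L && any(kinds == "metabolite")
    for (attempt in seq_len(25L)) {
      members <- grow_once()
      if (length(members) == size &&
          (!want_metab || any(kinds[ids[members]] == "metabolite"))) break
    }
    sort(ids[members])
  })
}

#' Densify a planted module to disease-module edge density
#'
#' Disease modules are denser than random subgraphs of the interactome --
#' that excess interconnectivity is precisely the signal the
#' connectivity-significance test of the growth algorithm detects. A module
#' planted by plain neighbor expansion in a sparse scale-free background is
#' nearly tree-like (mean within-module degree about 2) and therefore
#' carries no connectivity signal. This step adds random edges between
#' non-adjacent module members until the induced subgraph reaches
#' \code{mean_degree} (default 4, the edge density observed in published
#' metabolite-protein disease modules), turning the planted set into a
#' planted dense subgraph, the canonical module-recovery benchmark.
#'
#' @param net a \code{background_network}.
#' @param nodes planted module node ids.
#' @param mean_degree target mean within-module degree (default 4).
#' @param seed integer RNG seed.
#' @return the augmented \code{background_network} (unchanged when the
#'   induced subgraph already meets the target).
#' @export
densify_module <- function(net, nodes, mean_degree = 4, seed = NULL) {
  ids <- network_nodes(net)
  if (!all(nodes %in% ids)) stop("module nodes must be in the network")
  with_seed(seed, {
    g <- net$graph
    target_edges <- ceiling(mean_degree * length(nodes) / 2)
    cur <- igraph::ecount(igraph::induced_subgraph(g, nodes))
    if (cur < target_edges) {
      pairs <- t(utils::combn(nodes, 2L))
      have <- apply(pairs, 1L, function(p) igraph::are_adjacent(g, p[1L], p[2L]))
      free <- pairs[!have, , drop = FALSE]
      n_add <- min(target_edges - cur, nrow(free))
      add <- free[sample.int(nrow(free), n_add), , drop = FALSE]
      g <- igraph::add_edges(g, t(add))
    }
    structure(list(graph = g, n_dropped_self = net$n_dropped_self,
                   n_dropped_dup = net$n_dropped_dup),
              class = "background_network")
  })
}

#' Simulate two-group omics tables with programmed effects
#'
#' Generates log-normal intensity tables for a gene (transcript) layer and a
#' metabolite layer over \code{n_per_group} control and case samples each.
#' Every planted network node carries exactly one feature (feature id = node
#' id) whose case group is shifted by \code{effect_log2fc} on the log2 scale
#' with a random sign; remaining background features map to distinct
#' non-planted nodes of the matching kind and carry no effect. Per-sample
#' noise is Gaussian on the log2 scale with standard deviation \code{sigma}.
#' The metabolite layer carries a VIP surrogate (absolute standardized mean
#' difference of the log2 values), scaled so programmed effects exceed 1.
#'
#' @param net a \code{background_network}.
#' @param planted planted node ids (see \code{\link{plant_module}}).
#' @param n_per_group samples per group (default 6).
#' @param effect_log2fc programmed absolute log2 fold change (default 1.8).
#' @param sigma log2-scale noise standard deviation (default 0.25).
#' @param n_gene_features,n_metab_features total features per layer
#'   (defaults 500 and 150).
#' @param seed integer RNG seed.
#' @return list with \code{genes} and \code{metabolites} (both
#'   \code{omics_table}) and \code{truth} (list: planted_nodes,
#'   effect_log2fc per planted feature, generator parameters).
#' @export
simulate_omics <- function(net, planted, n_per_group = 6L,
                           effect_log2fc = 1.8, sigma = 0.25,
                           n_gene_features = 500L, n_metab_features = 150L,
                           seed = NULL) {
  kinds <- node_kinds(net)
  if (!all(planted %in% names(kinds))) stop("planted nodes must be in the network")
  planted_prot <- planted[kinds[planted] == "protein"]
  planted_met <- planted[kinds[planted] == "metabolite"]
  free_prot <- setdiff(names(kinds)[kinds == "protein"], planted)
  free_met <- setdiff(names(kinds)[kinds == "metabolite"], planted)
  if (n_gene_features < length(planted_prot) ||
      n_metab_features < length(planted_met)) {
    stop("feature counts smaller than the planted node counts")
  }
  if (n_gene_features - length(planted_prot) > length(free_prot) ||
      n_metab_features - length(planted_met) > length(free_met)) {
    stop("not enough background nodes for the requested feature counts")
  }
  groups <- rep(c("control", "case"), each = n_per_group)
  names(groups) <- c(sprintf("ctrl_%02d", seq_len(n_per_group)),
                     sprintf("case_%02d", seq_len(n_per_group)))
  with_seed(seed, {
    make_layer <- function(planted_ids, free_ids, n_features) {
      bg <- sample(free_ids, n_features - length(planted_ids))
      feats <- c(planted_ids, bg)
      base <- stats::rnorm(length(feats), mean = 10, sd = 2)
      eff <- numeric(length(feats))
      eff[seq_along(planted_ids)] <-
        sample(c(-1, 1), length(planted_ids), replace = TRUE) * effect_log2fc
      log2m <- outer(base, rep(0, length(groups))) +
        outer(eff, as.numeric(groups == "case")) +
        matrix(stats::rnorm(length(feats) * length(groups), sd = sigma),
               nrow = length(feats))
      m <- 2^log2m
      dimnames(m) <- list(feats, names(groups))
      list(values = m, effect = stats::setNames(eff, feats))
    }
    gene <- make_layer(planted_prot, free_prot, n_gene_features)
    met <- make_layer(planted_met, free_met, n_metab_features)
    # VIP surrogate: |standardized mean difference| of log2 intensities
    smd <- function(m) {
      lm2 <- log2(m)
      case <- groups == "case"
      dbar <- rowMeans(lm2[, case, drop = FALSE]) -
        rowMeans(lm2[, !case, drop = FALSE])
      sp <- sqrt((apply(lm2[, case, drop = FALSE], 1L, stats::var) +
                  apply(lm2[, !case, drop = FALSE], 1L, stats::var)) / 2)
      abs(dbar) / pmax(sp, 1e-8)
    }
    vip <- smd(met$values)
    # scale so that programmed effects sit comfortably above the VIP > 1 gate
    vip <- vip / max(1, effect_log2fc / sigma / 4)
    genes <- omics_table(gene$values, groups)
    mets <- omics_table(met$values, groups, vip = vip)
    truth <- list(
      planted_nodes = sort(planted),
      effect_log2fc = c(gene$effect[gene$effect != 0], met$effect[met$effect != 0]),
      params = list(n_per_group = n_per_group, effect_log2fc = effect_log2fc,
                    sigma = sigma, n_gene_features = n_gene_features,
                    n_metab_features = n_metab_features, seed = seed)
    )
    list(genes = genes, metabolites = mets, truth = truth)
  })
}

#' Generate a synthetic drug library at controlled distance from a module
#'
#' Proximal drugs draw at least 80 percent of their targets from the planted
#' module's proteins and the remainder from the module's first-order protein
#' neighbors, so their closest distance to the module is at most 0.2.
#' Distal drugs draw degree-matched protein targets from nodes at graph
#' distance 2 or more from the module, so every distance term is at least 2.
#'
#' @param net a \code{background_network}.
#' @param planted planted module node ids.
#' @param n_proximal,n_distal library composition (defaults 20 and 80).
#' @param targets_min,targets_max per-drug target-count range (default 2-6).
#' @param seed integer RNG seed.
#' @return list with \code{drugs} (data.frame drug_id, drug_name, target_id),
#'   \code{proximal_drugs}, \code{distal_drugs} (id vectors).
#' @export
generate_drug_library <- function(net, planted, n_proximal = 20L,
                                  n_distal = 80L, targets_min = 2L,
                                  targets_max = 6L, seed = NULL) {
  stopifnot(targets_min >= 1L, targets_max >= targets_min)
  kinds <- node_kinds(net)
  g <- net$graph
  planted <- intersect(planted, names(kinds))
  mod_prot <- planted[kinds[planted] == "protein"]
  if (length(mod_prot) < targets_max) {
    stop("planted module too small to supply drug targets")
  }
  # distance-1 shell and eligible distal pool (proteins only)
  d_to_mod <- igraph::distances(g, v = planted)
  dmin <- apply(d_to_mod, 2L, min)
  names(dmin) <- igraph::V(g)$name
  shell1_prot <- names(dmin)[dmin == 1 & kinds[names(dmin)] == "protein"]
  distal_pool <- names(dmin)[dmin >= 2 & kinds[names(dmin)] == "protein"]
  if (length(distal_pool) < targets_max) stop("no distal protein pool available")
  bins <- build_degree_bins(net, min_bin_size = min(100L, floor(length(kinds) / 4)))
  with_seed(seed, {
    rows <- list()
    prox_ids <- sprintf("DPX%03d", seq_len(n_proximal))
    dist_ids <- sprintf("DDS%03d", seq_len(n_distal))
    for (i in seq_len(n_proximal)) {
      t <- sample(seq.int(targets_min, targets_max), 1L)
      n_out <- t - ceiling(0.8 * t)
      outside <- if (n_out > 0L && length(shell1_prot)) {
        sample(shell1_prot, min(n_out, length(shell1_prot)))
      } else character(0L)
      tgt <- c(sample(mod_prot, t - length(outside)), outside)
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = prox_ids[i], drug_name = sprintf("proximal_%02d", i),
        target_id = unique(tgt), stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_distal)) {
      t <- sample(seq.int(targets_min, targets_max), 1L)
      # degree-match against a module-like reference, restricted to the
      # distal pool so hubs adjacent to the module never leak in
      ref <- sample(mod_prot, t)
      cand <- sample_degree_matched(net, ref, bins)
      tgt <- cand[cand %in% distal_pool]
      if (length(tgt) < t) {
        tgt <- c(tgt, sample(setdiff(distal_pool, tgt), t - length(tgt)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = dist_ids[i], drug_name = sprintf("distal_%02d", i),
        target_id = unique(tgt[seq_len(t)]), stringsAsFactors = FALSE)
    }
    list(drugs = do.call(rbind, rows), proximal_drugs = prox_ids,
         distal_drugs = dist_ids)
  })
}

#' Generate and optionally write a complete synthetic input bundle
#'
#' One call produces every input the pipeline consumes: background network
#' edge list and node kinds, gene and metabolite tables with group labels
#' and VIP surrogate, a drug library, and the ground truth (planted module,
#' programmed effects, proximal/distal drug labels, full parameter record).
#'
#' @param out_dir directory to write the bundle to (created if needed);
#'   \code{NULL} returns the objects without writing.
#' @param seed master RNG seed; per-stage child seeds are derived from it.
#' @param n_proteins,n_metabolites,attachment see
#'   \code{\link{generate_network}}.
#' @param module_size planted module size (default 60).
#' @param module_mean_degree target within-module edge density handed to
#'   \code{\link{densify_module}} (default 4).
#' @param n_per_group,effect_log2fc,sigma,n_gene_features,n_metab_features
#'   see \code{\link{simulate_omics}}.
#' @param n_proximal,n_distal see \code{\link{generate_drug_library}}.
#' @return (invisibly when writing) list with \code{net}, \code{planted},
#'   \code{omics}, \code{drugs} and \code{truth}; when \code{out_dir} is
#'   given, the files edges.tsv, node_kinds.tsv, genes.tsv, metabolites.tsv,
#'   groups.tsv, vip.tsv, drugs.tsv and truth.json are written there.
#' @export
synth_bundle <- function(out_dir = NULL, seed = 1L, n_proteins = 1800L,
                         n_metabolites = 200L, attachment = 3L,
                         module_size = 60L, module_mean_degree = 4,
                         n_per_group = 6L,
                         effect_log2fc = 1.8, sigma = 0.25,
                         n_gene_features = 500L, n_metab_features = 150L,
                         n_proximal = 20L, n_distal = 80L) {
  net <- generate_network(n_proteins, n_metabolites, attachment,
                          seed = derive_seed(seed, "network"))
  net <- suppressMessages(largest_connected_component(net))
  planted <- plant_module(net, module_size, seed = derive_seed(seed, "module"))
  net <- densify_module(net, planted, module_mean_degree,
                        seed = derive_seed(seed, "module") + 1L)
  om <- simulate_omics(net, planted, n_per_group, effect_log2fc, sigma,
                       n_gene_features, n_metab_features,
                       seed = derive_seed(seed, "omics"))
  dl <- generate_drug_library(net, planted, n_proximal, n_distal,
                              seed = derive_seed(seed, "drugs"))
  truth <- c(om$truth, list(
    proximal_drugs = dl$proximal_drugs,
    distal_drugs = dl$distal_drugs,
    network_params = list(n_proteins = n_proteins,
                          n_metabolites = n_metabolites,
                          attachment = attachment,
                          module_size = module_size,
                          module_mean_degree = module_mean_degree),
    master_seed = seed))
  out <- list(net = net, planted = planted, omics = om, drugs = dl$drugs,
              truth = truth)
  if (is.null(out_dir)) return(out)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ed <- igraph::as_data_frame(net$graph, what = "edges")[, 1:2]
  # headerless two-column edge list, the format load_edge_list expects
  utils::write.table(ed, file.path(out_dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  kv <- node_kinds(net)
  write_tsv_plain(data.frame(id = names(kv), kind = unname(kv)),
                  file.path(out_dir, "node_kinds.tsv"))
  write_omics_layer(om$genes, file.path(out_dir, "genes.tsv"))
  write_omics_layer(om$metabolites, file.path(out_dir, "metabolites.tsv"))
  write_tsv_plain(data.frame(sample = colnames(om$genes$values),
                             group = om$genes$groups),
                  file.path(out_dir, "groups.tsv"))
  write_tsv_plain(data.frame(id = names(om$metabolites$vip),
                             vip = unname(om$metabolites$vip)),
                  file.path(out_dir, "vip.tsv"))
  write_tsv_plain(dl$drugs, file.path(out_dir, "drugs.tsv"))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Write one omics layer as a TSV feature table
#' @param tab an \code{omics_table}.
#' @param path output TSV (first column \code{feature}, then samples).
#' @export
write_omics_layer <- function(tab, path) {
  df <- data.frame(feature = rownames(tab$values), tab$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Read a truth.json written by \code{\link{synth_bundle}}
#' @param path truth.json path.
#' @return the truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
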