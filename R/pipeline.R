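#' Assemble a full run configuration
#'
#' Collects the input paths, thresholds and sizes governing an end-to-end
#' screen. Defaults follow the published analysis constants (metabolite
#' filter |FC| > 1.2, p < 0.05, VIP > 1; gene filter |FC| > 2, FDR < 0.01;
#' module-growth alpha 0.01; top 1 percent of modules pooled; candidate rule
#' z < -2.5 and p < 0.01) at desk scale (10,000 modules, 1,000
#' permutations); \code{interactome_scale = TRUE} raises the ensemble to 100,000
#' modules.
#'
#' @param edges,node_kinds,genes,metabolites,groups,vip,drugs input file
#'   paths (vip may be \code{NULL}).
#' @param out_dir output directory.
#' @param seed master RNG seed; per-stage child seeds are derived from it
#'   and echoed in the run manifest.
#' @param fc_metab,p_metab,vip_thresh metabolite filter thresholds.
#' @param fc_gene,fdr_gene gene filter thresholds.
#' @param gene_test per-gene test, see \code{\link{differential_genes}}.
#' @param alpha,n_modules,max_module_size,top_module_frac,node_frac,variant
#'   module-growth and consensus parameters.
#' @param n_perm,z_thresh,p_thresh,min_targets,randomize screen parameters.
#' @param min_bin_size degree-bin resolution for permutation sampling.
#' @param interactome_scale use the interactome-scale ensemble/permutation counts.
#' @return a \code{run_config} list.
#' @export
run_config <- function(edges, node_kinds, genes, metabolites, groups,
                       vip = NULL, drugs, out_dir, seed = 1L,
                       fc_metab = 1.2, p_metab = 0.05, vip_thresh = 1.0,
                       fc_gene = 2.0, fdr_gene = 0.01,
                       gene_test = "moderated_t",
                       alpha = 0.01, n_modules = 10000L,
                       max_module_size = 500L, top_module_frac = 0.01,
                       node_frac = 1.0, variant = "sqrt",
                       n_perm = 1000L, z_thresh = -2.5, p_thresh = 0.01,
                       min_targets = 1L, randomize = "targets-only",
                       min_bin_size = 100L, interactome_scale = FALSE) {
  if (interactome_scale) n_modules <- 100000L
  cfg <- list(edges = edges, node_kinds = node_kinds, genes = genes,
              metabolites = metabolites, groups = groups, vip = vip,
              drugs = drugs, out_dir = out_dir, seed = as.integer(seed),
              fc_metab = fc_metab, p_metab = p_metab, vip_thresh = vip_thresh,
              fc_gene = fc_gene, fdr_gene = fdr_gene, gene_test = gene_test,
              alpha = alpha, n_modules = as.integer(n_modules),
              max_module_size = as.integer(max_module_size),
              top_module_frac = top_module_frac, node_frac = node_frac,
              variant = variant, n_perm = as.integer(n_perm),
              z_thresh = z_thresh, p_thresh = p_thresh,
              min_targets = as.integer(min_targets), randomize = randomize,
              min_bin_size = as.integer(min_bin_size))
  stopifnot(cfg$fc_metab > 0, cfg$fc_gene > 0,
            cfg$p_metab > 0, cfg$p_metab < 1,
            cfg$fdr_gene > 0, cfg$fdr_gene < 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$top_module_frac > 0, cfg$top_module_frac <= 1,
            cfg$node_frac > 0, cfg$node_frac <= 1,
            cfg$n_perm >= 100L, cfg$n_modules >= 1L)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of \code{\link{run_config}}; relative input
#' paths are resolved against the config file's directory.
#'
#' @param path config file (.yaml/.yml needs the \pkg{yaml} package,
#'   otherwise JSON).
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  for (k in c("edges", "node_kinds", "genes", "metabolites", "groups",
              "vip", "drugs")) {
    if (!is.null(vals[[k]]) && !grepl("^/", vals[[k]])) {
      vals[[k]] <- file.path(base, vals[[k]])
    }
  }
  do.call(run_config, vals)
}

#' Validate the input files of a run configuration
#'
#' Schema checks every input: file existence, column counts, group balance,
#' id consistency and the rate of drug targets that fail to map onto the
#' network. Problems are split into fatal errors and warnings.
#'
#' @param config a \code{run_config}.
#' @return list with \code{errors}, \code{warnings} (character vectors) and
#'   \code{summary} (named counts: nodes, edges, features per layer, drugs,
#'   unmapped-target rate).
#' @export
validate_inputs <- function(config) {
  errors <- character(0L)
  warns <- character(0L)
  summary <- list()
  need <- c("edges", "node_kinds", "genes", "metabolites", "groups", "drugs")
  for (k in need) {
    if (is.null(config[[k]]) || !file.exists(config[[k]])) {
      errors <- c(errors, paste0("missing input file for '", k, "': ",
                                 config[[k]] %||% "<unset>"))
    }
  }
  if (length(errors)) {
    return(list(errors = errors, warnings = warns, summary = summary))
  }
  net <- try(suppressWarnings(
    load_edge_list(config$edges, node_kinds = config$node_kinds)), silent = TRUE)
  if (inherits(net, "try-error")) {
    errors <- c(errors, paste("edge list failed to load:",
                              conditionMessage(attr(net, "condition"))))
    return(list(errors = errors, warnings = warns, summary = summary))
  }
  summary$nodes <- unname(network_size(net)["nodes"])
  summary$edges <- unname(network_size(net)["edges"])
  for (layer in c("genes", "metabolites")) {
    tab <- try(read_omics_table(config[[layer]], config$groups,
                                vip_path = if (layer == "metabolites") config$vip),
               silent = TRUE)
    if (inherits(tab, "try-error")) {
      errors <- c(errors, paste0(layer, " table invalid: ",
                                 conditionMessage(attr(tab, "condition"))))
    } else {
      summary[[paste0("n_", layer)]] <- nrow(tab$values)
      bal <- table(tab$groups)
      summary[[paste0(layer, "_groups")]] <- paste(names(bal), bal,
                                                   sep = "=", collapse = ", ")
    }
  }
  drugs <- try(read_drug_targets(config$drugs), silent = TRUE)
  if (inherits(drugs, "try-error")) {
    errors <- c(errors, paste("drug table invalid:",
                              conditionMessage(attr(drugs, "condition"))))
  } else {
    summary$n_drugs <- length(drugs)
    targets <- unique(unlist(lapply(drugs, `[[`, "targets")))
    unmapped <- mean(!targets %in% network_nodes(net))
    summary$unmapped_target_rate <- round(unmapped, 4)
    if (unmapped > 0.2) {
      warns <- c(warns, sprintf("%.0f%% of drug targets do not map to the network",
                                100 * unmapped))
    }
  }
  list(errors = errors, warnings = warns, summary = summary)
}

#' Run the full disease-module and drug-proximity screen
#'
#' End-to-end pipeline: load and restrict the background network to its
#' largest connected component; call differential metabolites and genes;
#' build node scores; grow the module ensemble and assemble the consensus
#' module; screen the drug library by permutation-normalized network
#' proximity. Writes differential tables, the consensus module (node and
#' edge TSV), the ranked drug table and a JSON run manifest (parameter echo,
#' derived stage seeds, stage timings, package version) into
#' \code{config$out_dir}. A fixed seed makes every output byte-identical
#' across reruns.
#'
#' @param config a \code{run_config} (or path to a YAML/JSON config).
#' @return (invisibly) list with \code{net}, \code{gene_results},
#'   \code{metab_results}, \code{scores}, \code{ensemble}, \code{consensus},
#'   \code{screen} and \code{manifest}.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  rep_ <- validate_inputs(config)
  if (length(rep_$errors)) {
    stop("input validation failed:\n  ", paste(rep_$errors, collapse = "\n  "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }

  net <- tick("network", {
    n <- suppressWarnings(load_edge_list(config$edges,
                                         node_kinds = config$node_kinds))
    suppressMessages(largest_connected_component(n))
  })
  metab <- tick("differential_metabolites", {
    tab <- read_omics_table(config$metabolites, config$groups,
                            vip_path = config$vip)
    differential_metabolites(tab, config$fc_metab, config$p_metab,
                             config$vip_thresh)
  })
  genes <- tick("differential_genes", {
    tab <- read_omics_table(config$genes, config$groups)
    differential_genes(tab, config$fc_gene, config$fdr_gene,
                       test = config$gene_test)
  })
  scores <- tick("node_scores",
                 suppressMessages(build_node_scores(net, genes, metab)))
  ens <- tick("ensemble", build_ensemble(
    net, scores, n_modules = config$n_modules, alpha = config$alpha,
    seed = derive_seed(config$seed, "module"),
    max_size = config$max_module_size, variant = config$variant))
  cons <- tick("consensus", consensus_module(
    ens, net, top_module_frac = config$top_module_frac,
    node_frac = config$node_frac))
  screen <- tick("screen", {
    drugs <- read_drug_targets(config$drugs)
    bins <- build_degree_bins(net, config$min_bin_size)
    suppressMessages(screen_drugs(
      net, drugs, cons$nodes, bins = bins, z_thresh = config$z_thresh,
      p_thresh = config$p_thresh, n_perm = config$n_perm,
      min_targets = config$min_targets, randomize = config$randomize,
      seed = derive_seed(config$seed, "screen")))
  })

  write_differential(metab, file.path(config$out_dir, "differential_metabolites.tsv"))
  write_differential(genes, file.path(config$out_dir, "differential_genes.tsv"))
  write_consensus(cons, scores,
                  file.path(config$out_dir, "module_nodes.tsv"),
                  file.path(config$out_dir, "module_edges.tsv"))
  screen_out <- screen
  for (col in c("d_obs", "mu_rand", "sigma_rand", "z")) {
    screen_out[[col]] <- formatC(screen_out[[col]], format = "g", digits = 10)
  }
  screen_out$p_perm <- formatC(screen$p_perm, format = "g", digits = 10)
  write_tsv_plain(screen_out, file.path(config$out_dir, "drug_screen.tsv"))
  manifest <- list(
    package = "modprox",
    version = as.character(utils::packageVersion("modprox")),
    seed = config$seed,
    stage_seeds = list(module = derive_seed(config$seed, "module"),
                       screen = derive_seed(config$seed, "screen")),
    parameters = config[setdiff(names(config), "out_dir")],
    input_summary = rep_$summary,
    n_differential_metabolites = sum(metab$selected),
    n_differential_genes = sum(genes$selected),
    consensus_nodes = length(cons$nodes),
    consensus_edges = cons$n_edges,
    n_candidates = sum(screen$candidate),
    timings_sec = as.list(timings)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(net = net, gene_results = genes, metab_results = metab,
                 scores = scores, ensemble = ens, consensus = cons,
                 screen = screen, manifest = manifest))
}
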