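#' Two-group omics feature table
#'
#' Container for a features-by-samples intensity (or normalized expression)
#' matrix with a control/case group label per sample and an optional VIP
#' (variable importance in projection, from PLS-DA) column for the metabolite
#' layer. VIP is consumed as an input, never computed here.
#'
#' Zeros in the matrix are imputed with half the smallest positive value in
#' the table so that linear-scale fold changes are always defined.
#'
#' @param values numeric matrix or data.frame, features in rows (rownames are
#'   feature ids), samples in columns.
#' @param groups character/factor of \code{"control"}/\code{"case"} per
#'   sample, or a named vector matched to column names.
#' @param vip optional named numeric vector of VIP scores per feature.
#' @return an object of class \code{omics_table}.
#' @export
omics_table <- function(values, groups, vip = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) stop("feature ids required as rownames")
  if (!is.null(names(groups))) {
    if (!all(colnames(m) %in% names(groups))) {
      stop("group labels missing for some samples")
    }
    groups <- groups[colnames(m)]
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) stop("one group label per sample required")
  if (!all(groups %in% c("control", "case"))) {
    stop("group labels must be 'control' or 'case'")
  }
  if (sum(groups == "control") < 2L || sum(groups == "case") < 2L) {
    stop("need at least 2 samples per group")
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("intensities must be finite and nonnegative")
  }
  if (any(m == 0)) {
    m[m == 0] <- min(m[m > 0]) / 2
  }
  if (!is.null(vip)) {
    if (is.null(names(vip))) stop("vip must be named by feature id")
    vip <- vip[rownames(m)]
    names(vip) <- rownames(m)
  }
  structure(list(values = m, groups = groups, vip = vip),
            class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat("omics_table:", nrow(x$values), "features x", ncol(x$values),
      "samples (", sum(x$groups == "control"), "control /",
      sum(x$groups == "case"), "case );",
      if (is.null(x$vip)) "no VIP column" else "with VIP column", "\n")
  invisible(x)
}

#' Read an omics table from TSV files
#'
#' @param path feature table TSV: first column feature id, remaining columns
#'   samples.
#' @param groups_path two-column TSV sample id / group
#'   (\code{control}|\code{case}).
#' @param vip_path optional two-column TSV feature id / VIP.
#' @return an \code{omics_table}.
#' @export
read_omics_table <- function(path, groups_path, vip_path = NULL) {
  df <- read_tsv_plain(path, header = TRUE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  gdf <- read_tsv_plain(groups_path, header = FALSE)
  if (identical(tolower(as.character(gdf[1L, 2L])), "group")) gdf <- gdf[-1L, ]
  groups <- stats::setNames(as.character(gdf[[2L]]), as.character(gdf[[1L]]))
  vip <- NULL
  if (!is.null(vip_path)) {
    vdf <- read_tsv_plain(vip_path, header = FALSE)
    if (is.na(suppressWarnings(as.numeric(vdf[1L, 2L])))) vdf <- vdf[-1L, ]
    vip <- stats::setNames(as.numeric(vdf[[2L]]), as.character(vdf[[1L]]))
  }
  omics_table(m, groups, vip)
}

#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) p-value
#'
#' Exact enumeration of the rank-sum null when both groups have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y numeric vectors, at least 2 observations each.
#' @return two-sided p-value.
#' @export
mann_whitney_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 8L && length(y) <= 8L && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Standard step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}.
#' @return vector of adjusted values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

fold_changes <- function(tab) {
  m <- tab$values
  case <- tab$groups == "case"
  fc <- rowMeans(m[, case, drop = FALSE]) / rowMeans(m[, !case, drop = FALSE])
  data.frame(id = rownames(m), fc = unname(fc), log2fc = unname(log2(fc)),
             stringsAsFactors = FALSE)
}

wilcoxon_pvalues <- function(tab) {
  case <- tab$groups == "case"
  apply(tab$values, 1L, function(v) mann_whitney_p(v[case], v[!case]))
}

moderated_t_pvalues <- function(tab) {
  design <- cbind(Intercept = 1, case = as.integer(tab$groups == "case"))
  fit <- limma::eBayes(limma::lmFit(log2(tab$values), design))
  fit$p.value[, "case"]
}

differential_result <- function(fc_df, p, q, vip, selected) {
  out <- data.frame(id = fc_df$id, fc = fc_df$fc, log2fc = fc_df$log2fc,
                    p = unname(p), q = unname(q),
                    vip = if (is.null(vip)) NA_real_ else unname(vip),
                    selected = unname(selected), stringsAsFactors = FALSE)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Differential metabolite screen
#'
#' A metabolite is selected when all of: VIP > \code{vip_thresh}, absolute
#' linear fold change (case mean / control mean) exceeds \code{fc_thresh} in
#' either direction, and two-sided Mann-Whitney U p-value is below
#' \code{p_thresh}. When the table carries no VIP column, the VIP criterion
#' is skipped with a warning.
#'
#' @param table an \code{omics_table} (metabolite layer).
#' @param fc_thresh linear fold-change threshold (default 1.2).
#' @param p_thresh Mann-Whitney p threshold (default 0.05).
#' @param vip_thresh VIP threshold (default 1.0).
#' @return a \code{differential_result} data.frame with columns id, fc,
#'   log2fc, p, q, vip, selected.
#' @export
differential_metabolites <- function(table, fc_thresh = 1.2, p_thresh = 0.05,
                                     vip_thresh = 1.0) {
  stopifnot(inherits(table, "omics_table"))
  fc_df <- fold_changes(table)
  p <- wilcoxon_pvalues(table)
  q <- bh_fdr(p)
  vip <- table$vip
  sel <- abs(fc_df$log2fc) > log2(fc_thresh) & p < p_thresh
  if (is.null(vip)) {
    warning("no VIP column; VIP criterion skipped")
  } else {
    sel <- sel & !is.na(vip) & vip > vip_thresh
  }
  differential_result(fc_df, p, q, vip, sel)
}

#' Differential gene screen
#'
#' A gene is selected when its absolute linear fold change exceeds
#' \code{fc_thresh} and its BH-adjusted p-value (FDR) is below
#' \code{fdr_thresh}. The per-gene test is pluggable: the default is the
#' moderated t-statistic (empirical-Bayes shrunken variance, via
#' \pkg{limma}, on log2 intensities), which retains power at small group
#' sizes; \code{test = "wilcoxon"} substitutes the rank-sum test, whose
#' discreteness puts a floor of \code{2/choose(n1+n2, n1)} on attainable
#' p-values and therefore limits FDR resolution at small n.
#'
#' @param table an \code{omics_table} (transcript layer).
#' @param fc_thresh linear fold-change threshold (default 2).
#' @param fdr_thresh FDR threshold on BH-adjusted p (default 0.01).
#' @param test per-feature test: \code{"moderated_t"} (default) or
#'   \code{"wilcoxon"}.
#' @return a \code{differential_result} data.frame.
#' @export
differential_genes <- function(table, fc_thresh = 2.0, fdr_thresh = 0.01,
                               test = c("moderated_t", "wilcoxon")) {
  stopifnot(inherits(table, "omics_table"))
  test <- match.arg(test)
  fc_df <- fold_changes(table)
  p <- switch(test,
              moderated_t = moderated_t_pvalues(table),
              wilcoxon = wilcoxon_pvalues(table))
  q <- bh_fdr(p)
  sel <- abs(fc_df$log2fc) > log2(fc_thresh) & q < fdr_thresh
  differential_result(fc_df, p, q, vip = NULL, selected = sel)
}

#' Write a differential result table to TSV
#' @param result a \code{differential_result}.
#' @param path output file.
#' @export
write_differential <- function(result, path) {
  write_tsv_plain(as.data.frame(result), path)
}

#' Node scores for disease-module growth
#'
#' Maps selected differential features onto background-network nodes and
#' assigns each node the absolute log2 fold change of its feature, s(i) =
#' |log2 FC|; every unscored network node gets s(i) = 0. When a gene and a
#' metabolite map to the same node, the larger score wins. The global mean
#' score mu is taken over ALL network nodes (zeros included), so mu is the
#' background mean against which module scores are centred.
#'
#' @param net a \code{background_network}.
#' @param gene_results,metab_results \code{differential_result} tables (either
#'   may be \code{NULL}).
#' @param feature_map optional two-column data.frame (feature id, node id);
#'   by default feature ids are taken to be node ids. Features that map to no
#'   network node are dropped with a message.
#' @return an object of class \code{node_scores}: list with \code{scores}
#'   (named numeric over all network nodes) and \code{mu}.
#' @export
build_node_scores <- function(net, gene_results = NULL, metab_results = NULL,
                              feature_map = NULL) {
  ids <- network_nodes(net)
  s <- stats::setNames(numeric(length(ids)), ids)
  map_one <- function(res) {
    if (is.null(res)) return(NULL)
    sel <- res[res$selected, , drop = FALSE]
    if (!nrow(sel)) return(NULL)
    node <- sel$id
    if (!is.null(feature_map)) {
      fm <- stats::setNames(as.character(feature_map[[2L]]),
                            as.character(feature_map[[1L]]))
      mapped <- fm[node]
      node <- ifelse(is.na(mapped), node, mapped)
    }
    keep <- node %in% ids
    if (any(!keep)) {
      message(sum(!keep), " selected feature(s) do not map to network nodes; dropped")
    }
    data.frame(node = node[keep], score = abs(sel$log2fc)[keep],
               stringsAsFactors = FALSE)
  }
  hits <- rbind(map_one(gene_results), map_one(metab_results))
  if (is.null(hits) || !nrow(hits)) {
    stop("no selected features map to the network: no signal to grow modules")
  }
  agg <- tapply(hits$score, hits$node, max)
  s[names(agg)] <- as.numeric(agg)
  structure(list(scores = s, mu = mean(s)), class = "node_scores")
}

#' @export
print.node_scores <- function(x, ...) {
  cat("node_scores:", sum(x$scores > 0), "of", length(x$scores),
      "nodes scored; mu =", signif(x$mu, 4), "\n")
  invisible(x)
}
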