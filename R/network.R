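# Per-group lipid-protein correlation networks.
#
# Edges are Pearson correlations over the group's samples between every
# (protein, lipid) pair; the dual filter keeps pairs that correlate strongly
# (|r| > 0.5, p < 0.002, both strict) AND whose designated endpoint(s) are
# significantly dysregulated versus the reference (differential p < 0.05).

#' Two-sided p-value of a Pearson correlation via the t tail
#'
#' `t = r sqrt(n-2) / sqrt(1-r^2)` with `n - 2` degrees of freedom.
#' @param r correlation coefficient(s).
#' @param n sample size.
#' @export
correlation_pvalue <- function(r, n) {
  stopifnot(n > 2)
  r <- pmin(1, pmax(-1, r))
  p <- 2 * stats::pt(-abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps)), n - 2)
  ifelse(abs(r) == 1, 0, p)
}

#' All protein x lipid Pearson correlations within one group
#'
#' @param table imputed `lpn_quant` (no missing cells).
#' @param design a [group_design()].
#' @param group group whose samples are correlated (needs n >= 5).
#' @return data.frame(protein, lipid, group, r, p, q, n); q is BH over the
#'   group's full protein x lipid family. Zero-variance features are excluded
#'   with a warning.
#' @export
pairwise_correlations <- function(table, design, group) {
  samp <- group_samples(design, group)
  n <- length(samp)
  if (n < 5L) stop("group '", group, "' has fewer than 5 samples")
  v <- table$values[samp, , drop = FALSE]
  if (anyNA(v)) stop("correlations require an imputed table (no missing cells)")
  prot <- layer_features(table, "protein"); lip <- layer_features(table, "lipid")
  sds <- apply(v, 2, stats::sd)
  flat <- names(sds)[sds == 0]
  if (length(flat)) {
    warning("zero-variance feature(s) in group ", group, " excluded: ",
            paste(flat, collapse = ", "))
    prot <- setdiff(prot, flat); lip <- setdiff(lip, flat)
  }
  if (!length(prot) || !length(lip))
    return(data.frame(protein = character(), lipid = character(), group = character(),
                      r = numeric(), p = numeric(), q = numeric(), n = integer()))
  R <- stats::cor(v[, prot, drop = FALSE], v[, lip, drop = FALSE])
  out <- data.frame(protein = rep(prot, times = length(lip)),
                    lipid = rep(lip, each = length(prot)),
                    group = group, r = as.vector(R),
                    p = as.vector(correlation_pvalue(R, n)),
                    n = n, stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  out[, c("protein", "lipid", "group", "r", "p", "q", "n")]
}

#' Dual-filter correlation edges into a lipid-protein network
#'
#' An edge survives iff `|r| > r_min` AND `p < p_corr_max` (both strict) AND
#' the endpoint(s) designated by `endpoint_rule` have differential p <
#' `p_diff_max` versus the reference in the same group. Surviving edges define
#' the node set.
#'
#' @param edges output of [pairwise_correlations()].
#' @param diff a [differential_analysis()] result covering the same group.
#' @param r_min,p_corr_max strong-correlation thresholds (defaults 0.5, 0.002).
#' @param p_diff_max dysregulation threshold (default 0.05).
#' @param endpoint_rule which endpoints must be dysregulated: `"either"`
#'   (default), `"lipid"`, or `"both"`.
#' @param table optional `lpn_quant` supplying lipid classes for node
#'   annotation.
#' @return An object of class `lpn_network`: list(group, nodes, edges).
#' @export
dual_filter <- function(edges, diff, r_min = 0.5, p_corr_max = 0.002,
                        p_diff_max = 0.05,
                        endpoint_rule = c("either", "lipid", "both"),
                        table = NULL) {
  endpoint_rule <- match.arg(endpoint_rule)
  grp <- unique(edges$group)
  if (length(grp) > 1L) stop("edges must come from a single group")
  dsub <- diff[diff$group %in% grp, ]
  pdiff <- stats::setNames(dsub$p, dsub$feature_id)
  lp <- unname(pdiff[edges$lipid]); pp <- unname(pdiff[edges$protein])
  lp[is.na(lp)] <- 1; pp[is.na(pp)] <- 1
  dys <- switch(endpoint_rule,
                either = lp < p_diff_max | pp < p_diff_max,
                lipid = lp < p_diff_max,
                both = lp < p_diff_max & pp < p_diff_max)
  keep <- abs(edges$r) > r_min & edges$p < p_corr_max & dys
  kept <- edges[keep, , drop = FALSE]
  kept <- kept[order(kept$protein, kept$lipid), , drop = FALSE]
  rownames(kept) <- NULL
  cls <- if (!is.null(table))
    stats::setNames(table$feature_meta$lipid_class, table$feature_meta$feature_id)
  else stats::setNames(character(0), character(0))
  prot_ids <- sort(unique(kept$protein)); lip_ids <- sort(unique(kept$lipid))
  nodes <- rbind(
    data.frame(id = prot_ids, type = rep("protein", length(prot_ids)),
               lipid_class = rep(NA_character_, length(prot_ids)),
               stringsAsFactors = FALSE),
    data.frame(id = lip_ids, type = rep("lipid", length(lip_ids)),
               lipid_class = if (length(lip_ids)) unname(cls[lip_ids]) else character(0),
               stringsAsFactors = FALSE))
  structure(list(group = if (length(grp)) grp else NA_character_,
                 nodes = nodes, edges = kept),
            class = "lpn_network")
}

#' @export
print.lpn_network <- function(x, ...) {
  cat(sprintf("lpn_network[%s]: %d proteins, %d lipids, %d edges\n",
              x$group, sum(x$nodes$type == "protein"),
              sum(x$nodes$type == "lipid"), nrow(x$edges)))
  invisible(x)
}

#' Hub proteins ranked by lipid degree
#'
#' Proteins sorted by the number of connected lipid species (descending, ties
#' broken alphabetically), with per-lipid-class edge counts when class
#' annotation is available.
#' @param net a `lpn_network`.
#' @export
hub_table <- function(net) {
  if (!nrow(net$edges))
    return(data.frame(protein = character(), degree = integer()))
  deg <- table(net$edges$protein)
  out <- data.frame(protein = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  cls <- net$nodes$lipid_class[match(net$edges$lipid, net$nodes$id)]
  if (!all(is.na(cls))) {
    byclass <- table(net$edges$protein, cls)
    out <- cbind(out, as.data.frame.matrix(byclass)[out$protein, , drop = FALSE])
  }
  out <- out[order(-out$degree, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network in Cytoscape-readable formats
#'
#' SIF (`protein corr_pos|corr_neg lipid`), GraphML (with r/p/q/lipid-class
#' attributes, via igraph), or a full edge TSV. Rows are emitted in stable
#' (protein, lipid) order.
#' @param net a `lpn_network`.
#' @param path output file.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    lines <- if (nrow(e))
      sprintf("%s\t%s\t%s", e$protein, ifelse(e$r >= 0, "corr_pos", "corr_neg"), e$lipid)
    else character(0)
    writeLines(lines, path)
  } else if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("protein", "lipid", "r", "p", "q")], directed = FALSE,
      vertices = net$nodes)
    igraph::E(g)$interaction <- ifelse(e$r >= 0, "corr_pos", "corr_neg")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network edge list written by [export_network()]
#' @param path file to read.
#' @param format `"graphml"` or `"tsv"`.
#' @return data.frame of edges with attributes (graphml/tsv).
#' @export
import_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv")
    return(utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE))
  g <- igraph::read_graph(path, format = "graphml")
  df <- igraph::as_data_frame(g, what = "edges")
  names(df)[1:2] <- c("protein", "lipid")
  df
}

# ---- over-representation analysis ------------------------------------------

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, member ids.
#' @param path GMT file.
#' @return named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional descriptions (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query and the set, with the supplied
#' universe as population (sets are intersected with the universe first); BH
#' adjustment across sets.
#'
#' @param query character set of proteins of interest (must lie within the
#'   universe).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character background set.
#' @return data.frame(set, overlap, set_size, universe_size, p, q,
#'   overlap_ids).
#' @export
ora_enrichment <- function(query, gene_sets, universe) {
  query <- unique(query); universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe); k <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    ov <- intersect(query, s)
    p <- stats::phyper(length(ov) - 1L, length(s), N - length(s), k, lower.tail = FALSE)
    data.frame(set = nm, overlap = length(ov), set_size = length(s),
               universe_size = N, p = p,
               overlap_ids = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$set), c("set", "overlap", "set_size", "universe_size",
                               "p", "q", "overlap_ids")]
}
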