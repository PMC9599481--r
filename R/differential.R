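# Differential abundance versus the normolipidemic reference.
#
# Per-species two-sided Wilcoxon rank-sum tests (exact enumeration for small
# untied samples, tie-corrected normal approximation otherwise), Kruskal-
# Wallis and one-way ANOVA across all groups, Benjamini-Hochberg FDR, and the
# reshaped volcano / Venn / z-score outputs.

# Two-sample rank-sum test. Exact branch enumerates all C(n1+n2, n1) rank
# assignments (used when total n <= 12 and there are no ties); otherwise a
# normal approximation with tie correction and, by default, a continuity
# correction. Without the continuity correction the squared z equals the
# two-group Kruskal-Wallis statistic.
ranksum_test <- function(x, y, exact = NULL, correct = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 2L || n2 < 2L) stop("rank-sum test needs >= 2 observations per group")
  r <- rank(c(x, y))
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L)
    return(list(p = 1, statistic = n1 * n2 / 2, exact = FALSE, degenerate = TRUE))
  if (is.null(exact)) exact <- (N <= 12L) && !ties
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (exact) {
    if (ties) stop("exact enumeration requires untied data")
    sums <- colSums(matrix(r[utils::combn(N, n1)], nrow = n1))
    p <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
  } else {
    tab <- table(r)
    tiecor <- sum(tab^3 - tab) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tiecor))
    dev <- U - n1 * n2 / 2
    if (correct) dev <- dev - sign(dev) * 0.5
    p <- 2 * stats::pnorm(-abs(dev / sigma))
  }
  list(p = p, statistic = U, exact = exact, degenerate = FALSE)
}

#' Wilcoxon rank-sum p-value of one group versus the reference
#'
#' @param values named numeric vector of per-sample concentrations.
#' @param design a [group_design()].
#' @param group non-reference group to compare.
#' @return Two-sided p-value; attributes `exact` and `degenerate` (all values
#'   identical across both groups gives p = 1 with the degeneracy flag).
#' @export
wilcoxon_vs_reference <- function(values, design, group) {
  ref <- design_reference(design)
  res <- ranksum_test(values[group_samples(design, group)],
                      values[group_samples(design, ref)])
  structure(res$p, exact = res$exact, degenerate = res$degenerate)
}

#' Kruskal-Wallis test across all groups
#'
#' Chi-square approximation with tie correction.
#' @inheritParams wilcoxon_vs_reference
#' @export
kruskal_wallis <- function(values, design) {
  g <- design$group[match(names(values), design$sample_id)]
  ok <- !is.na(values) & !is.na(g)
  v <- values[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L || any(table(g) < 2L)) stop(">= 2 groups with >= 2 samples required")
  N <- length(v); r <- rank(v)
  Rg <- tapply(r, g, sum); ng <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  tab <- table(r)
  C <- 1 - sum(tab^3 - tab) / (N^3 - N)
  if (C == 0) return(structure(1, degenerate = TRUE))
  stats::pchisq(H / C, df = nlevels(g) - 1L, lower.tail = FALSE)
}

#' Classic one-way ANOVA F-test p-value
#' @inheritParams wilcoxon_vs_reference
#' @export
anova_oneway <- function(values, design) {
  g <- design$group[match(names(values), design$sample_id)]
  ok <- !is.na(values) & !is.na(g)
  v <- values[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L || any(table(g) < 2L)) stop(">= 2 groups with >= 2 samples required")
  N <- length(v); k <- nlevels(g)
  gm <- tapply(v, g, mean); ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  if (ssw == 0) return(structure(NA_real_, degenerate = TRUE))
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j` over the sorted p-values, capped at 1;
#' order-preserving.
#' @param p numeric vector of p-values in \[0, 1\]; NA/NaN rejected.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("bh_fdr: p-values must be finite (no NA/NaN)")
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  q[order(o)]
}

#' Log2 fold change of a group's mean over the reference mean
#' @inheritParams wilcoxon_vs_reference
#' @return log2 ratio of arithmetic means; NA with a `flagged` attribute when
#'   the reference mean is 0.
#' @export
fold_change <- function(values, design, group) {
  ref <- design_reference(design)
  mg <- mean(values[group_samples(design, group)], na.rm = TRUE)
  mr <- mean(values[group_samples(design, ref)], na.rm = TRUE)
  if (!is.finite(mr) || mr == 0) return(structure(NA_real_, flagged = "reference mean zero"))
  log2(mg / mr)
}

#' Differential abundance of every feature versus the reference group
#'
#' Per (feature, non-reference group): log2 fold change of arithmetic means,
#' two-sided rank-sum p, BH q, and a direction call (`up`/`down` when
#' `p <= alpha`, `ns` otherwise). BH families default to each (group x omics
#' layer) combination.
#'
#' @param table imputed `lpn_quant`.
#' @param design a [group_design()].
#' @param alpha significance level for the direction call (default 0.05).
#' @param fdr_by family for BH adjustment: `"group_layer"` (default),
#'   `"group"`, or `"global"`.
#' @return data.frame(feature_id, layer, group, log2_fc, p, q, direction).
#' @export
differential_analysis <- function(table, design, alpha = 0.05,
                                  fdr_by = c("group_layer", "group", "global")) {
  fdr_by <- match.arg(fdr_by)
  check_design_covers(table, design)
  ref <- design_reference(design)
  groups <- setdiff(levels(design$group), ref)
  fm <- table$feature_meta
  ref_rows <- group_samples(design, ref)
  out <- list()
  for (g in groups) {
    g_rows <- group_samples(design, g)
    res <- lapply(colnames(table$values), function(f) {
      x <- table$values[g_rows, f]; y <- table$values[ref_rows, f]
      rt <- ranksum_test(x, y)
      mr <- mean(y, na.rm = TRUE)
      fc <- if (is.finite(mr) && mr > 0) log2(mean(x, na.rm = TRUE) / mr) else NA_real_
      c(fc = fc, p = rt$p)
    })
    res <- do.call(rbind, res)
    out[[g]] <- data.frame(feature_id = colnames(table$values),
                           layer = fm$layer, group = g,
                           log2_fc = res[, "fc"], p = res[, "p"],
                           stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  fam <- switch(fdr_by,
                group_layer = interaction(d$group, d$layer, drop = TRUE),
                group = factor(d$group),
                global = factor(rep(1, nrow(d))))
  d$q <- stats::ave(d$p, fam, FUN = bh_fdr)
  d$direction <- ifelse(d$p > alpha | d$log2_fc == 0 | is.na(d$log2_fc), "ns",
                        ifelse(d$log2_fc > 0, "up", "down"))
  d
}

#' Volcano-plot table
#' @param diff a [differential_analysis()] result.
#' @param alpha flagging threshold; features with `p <= alpha` are flagged.
#' @return data.frame(feature_id, group, log2_fc, neg_log10_p, significant).
#' @export
volcano_table <- function(diff, alpha = 0.05) {
  data.frame(feature_id = diff$feature_id, group = diff$group,
             log2_fc = diff$log2_fc, neg_log10_p = -log10(diff$p),
             significant = diff$p <= alpha, stringsAsFactors = FALSE)
}

#' Venn partition of significant features across the non-reference groups
#'
#' Partitions the features called in `direction` in at least one group into
#' the nonempty group-membership combinations (15 cells for four groups);
#' every feature lands in exactly one cell.
#'
#' @param diff a [differential_analysis()] result.
#' @param direction `"up"` or `"down"`.
#' @return list with `sets` (named list, combination label like `"HC+HL"` ->
#'   feature ids) and `counts`.
#' @export
venn_sets <- function(diff, direction = c("up", "down")) {
  direction <- match.arg(direction)
  groups <- unique(diff$group)
  sig <- lapply(groups, function(g)
    diff$feature_id[diff$group == g & diff$direction == direction])
  names(sig) <- groups
  feats <- unique(unlist(sig))
  membership <- vapply(feats, function(f)
    paste(groups[vapply(sig, function(s) f %in% s, TRUE)], collapse = "+"), "")
  sets <- split(feats, membership)
  list(sets = sets, counts = vapply(sets, length, 0L))
}

#' Z-scores of group means against the grand mean
#'
#' Per feature, `z_g = (mean_g - mean of group means) / sd of group means`;
#' each feature's row of z-scores has mean 0. Zero-spread rows are returned
#' as all-zero and flagged.
#'
#' @param values_matrix samples x features numeric matrix (or a `lpn_quant`).
#' @param design a [group_design()].
#' @return features x groups z-score matrix with attribute `flat_features`.
#' @export
group_mean_zscores <- function(values_matrix, design) {
  if (inherits(values_matrix, "lpn_quant")) values_matrix <- values_matrix$values
  if (nlevels(design$group) < 2L) stop(">= 2 groups required")
  gm <- sapply(levels(design$group), function(g)
    colMeans(values_matrix[group_samples(design, g), , drop = FALSE], na.rm = TRUE))
  ctr <- gm - rowMeans(gm)
  sdv <- apply(gm, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  z <- ctr / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  structure(z, flat_features = rownames(gm)[flat])
}

#' Hierarchical clustering of a z-score matrix
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage
#' (`ward.D2`) of rows and columns; ordering is deterministic for a given
#' input (hclust resolves ties by merge order over the label order).
#'
#' @param zmatrix numeric matrix (e.g. from [group_mean_zscores()]).
#' @return list(row_hclust, col_hclust, row_order, col_order).
#' @export
hierarchical_cluster <- function(zmatrix) {
  stopifnot(is.matrix(zmatrix), all(is.finite(zmatrix)))
  rh <- stats::hclust(stats::dist(zmatrix), method = "ward.D2")
  ch <- stats::hclust(stats::dist(t(zmatrix)), method = "ward.D2")
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(zmatrix)[rh$order],
       col_order = colnames(zmatrix)[ch$order])
}

#' Group comparison of lipid class totals and protein concentrations
#'
#' Reproduces the study's summary-table layout: per lipid class (total
#' concentration) and per protein, the group means with min/max, the one-way
#' ANOVA p-value, and BH-adjusted p across the family (classes and proteins
#' adjusted separately).
#'
#' @param table imputed `lpn_quant`.
#' @param design a [group_design()].
#' @return data.frame with one row per class/protein.
#' @export
class_comparison <- function(table, design) {
  check_design_covers(table, design)
  blocks <- list(lipid_class = class_totals(table),
                 protein = table$values[, layer_features(table, "protein"), drop = FALSE])
  out <- list()
  for (what in names(blocks)) {
    m <- blocks[[what]]
    if (!ncol(m)) next
    rows <- lapply(colnames(m), function(f) {
      v <- stats::setNames(m[, f], rownames(m))
      cells <- lapply(levels(design$group), function(g) {
        x <- v[group_samples(design, g)]
        sprintf("%.2f (%.2f/%.2f)", mean(x, na.rm = TRUE),
                min(x, na.rm = TRUE), max(x, na.rm = TRUE))
      })
      names(cells) <- levels(design$group)
      data.frame(feature = f, kind = what, as.data.frame(cells),
                 p_anova = as.numeric(anova_oneway(v, design)),
                 stringsAsFactors = FALSE)
    })
    b <- do.call(rbind, rows)
    b$p_adj <- bh_fdr(b$p_anova)
    out[[what]] <- b
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
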