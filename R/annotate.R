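# Lipid species name parsing and fatty-acyl saturation categorization.
#
# Name grammar: CLASS '(' [P-|O-] C:D { '/' C:D } [ '-FA' C:D ] ')'
#   PC(18:1/16:1)      two annotated acyl chains, totals are their sums
#   PE(P-16:0/18:1)    plasmalogen (ether) first chain
#   LPC(18:2)          single annotated chain (= totals)
#   TAG(52:2-FA16:0)   class totals plus one identified fatty acid
#
# Saturation categories: a species with an odd number of total FA carbons is
# ODD regardless of everything else; otherwise the deciding double-bond count
# d (the annotated FA with the most double bonds, or the totals when chains
# are not broken out, as for Lipidyzer TAG names) maps to SFA_MUFA (d <= 1),
# DUFA (d == 2) or PUFA (d >= 3). The sphingoid backbone of SM/CER species is
# implicit and ignored; names carry the N-acyl chain only.

#' Saturation category labels
#' @export
SATURATION_LEVELS <- c("ODD", "SFA_MUFA", "DUFA", "PUFA")

LIPID_NAME_RE <- "^([A-Za-z]+)\\((P-|O-)?(\\d+):(\\d+)((?:/\\d+:\\d+)*)(-FA\\d+:\\d+)?\\)$"

#' Parse lipid species names
#'
#' @param names character vector of species names following the grammar above.
#' @return data.frame with one row per name: `raw_name`, `lipid_class`,
#'   `total_carbons`, `total_double_bonds`, `n_chains`, `chains` (list column
#'   of 2-column matrices, NULL when only totals are known), `ether_flag`
#'   (`"none"`, `"P"` or `"O"`), `fa_carbons`/`fa_double_bonds` (known FA of
#'   TAG-style names, NA otherwise).
#' @export
parse_lipid_name <- function(names) {
  stopifnot(is.character(names))
  m <- regmatches(names, regexec(LIPID_NAME_RE, names))
  rows <- lapply(seq_along(names), function(i) {
    g <- m[[i]]
    if (!length(g)) stop("unparseable lipid name: '", names[i], "'")
    cls <- g[2]
    if (!cls %in% LIPID_CLASSES) stop("unknown lipid class in name: '", names[i], "'")
    ether <- if (g[3] == "") "none" else substr(g[3], 1, 1)
    c1 <- as.integer(g[4]); d1 <- as.integer(g[5])
    more <- g[6]; fa <- g[7]
    if (nzchar(more) && nzchar(fa))
      stop("name mixes chain list and '-FA' totals notation: '", names[i], "'")
    if (nzchar(fa)) {
      fd <- as.integer(strsplit(sub("^-FA", "", fa), ":", fixed = TRUE)[[1]])
      if (fd[1] >= c1 || fd[2] > d1)
        stop("known FA inconsistent with totals in '", names[i], "'")
      list(raw_name = names[i], lipid_class = cls, total_carbons = c1,
           total_double_bonds = d1, n_chains = 0L, chains = list(NULL),
           ether_flag = ether, fa_carbons = fd[1], fa_double_bonds = fd[2])
    } else {
      ch <- matrix(c(c1, d1), ncol = 2)
      if (nzchar(more)) {
        extra <- strsplit(strsplit(sub("^/", "", more), "/", fixed = TRUE)[[1]], ":", fixed = TRUE)
        ch <- rbind(ch, t(vapply(extra, as.integer, integer(2))))
      }
      colnames(ch) <- c("carbons", "double_bonds")
      if (any(ch[, 1] <= 0)) stop("chain with zero carbons in '", names[i], "'")
      list(raw_name = names[i], lipid_class = cls,
           total_carbons = sum(ch[, 1]), total_double_bonds = sum(ch[, 2]),
           n_chains = nrow(ch), chains = list(ch), ether_flag = ether,
           fa_carbons = NA_integer_, fa_double_bonds = NA_integer_)
    }
  })
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[setdiff(names(r), "chains")], stringsAsFactors = FALSE)))
  out$chains <- lapply(rows, function(r) r$chains[[1]])
  out
}

#' Categorize species by fatty-acyl saturation
#'
#' ODD when the total FA carbon count is odd (taking precedence over all
#' double-bond rules); otherwise by the deciding double-bond count: the
#' maximum over annotated chains when chains are known, else the total count
#' (the documented convention for TAG totals-plus-one-FA names, where the
#' maximal per-chain count is not recoverable).
#'
#' @param x character vector of names or a [parse_lipid_name()] data.frame.
#' @return factor with levels `r toString(SATURATION_LEVELS)`.
#' @export
categorize_saturation <- function(x) {
  if (is.character(x)) x <- parse_lipid_name(x)
  d <- vapply(seq_len(nrow(x)), function(i) {
    ch <- x$chains[[i]]
    if (!is.null(ch)) max(ch[, 2]) else x$total_double_bonds[i]
  }, 0L)
  cat <- ifelse(x$total_carbons %% 2L == 1L, "ODD",
         ifelse(d <= 1L, "SFA_MUFA", ifelse(d == 2L, "DUFA", "PUFA")))
  factor(cat, levels = SATURATION_LEVELS)
}

#' Annotate the lipid features of a table
#'
#' @param table a `lpn_quant`.
#' @return data.frame(feature_id, lipid_class, total_carbons,
#'   total_double_bonds, category) for the lipid layer.
#' @export
annotate_features <- function(table) {
  lip <- layer_features(table, "lipid")
  p <- parse_lipid_name(lip)
  data.frame(feature_id = lip, lipid_class = p$lipid_class,
             total_carbons = p$total_carbons,
             total_double_bonds = p$total_double_bonds,
             category = categorize_saturation(p), stringsAsFactors = FALSE)
}

#' Per-sample lipid class total concentrations
#'
#' Class totals are the sums of member species concentrations (units
#' preserved); classes present in the metadata but without members sum to 0.
#' Missing cells are ignored in the sums.
#' @param table a `lpn_quant`.
#' @return samples x classes numeric matrix.
#' @export
class_totals <- function(table) {
  fm <- table$feature_meta
  lip <- fm$layer == "lipid"
  classes <- sort(unique(fm$lipid_class[lip]))
  out <- sapply(classes, function(cl) {
    cols <- fm$feature_id[lip & fm$lipid_class == cl]
    rowSums(table$values[, cols, drop = FALSE], na.rm = TRUE)
  })
  matrix(out, nrow = nrow(table$values),
         dimnames = list(rownames(table$values), classes))
}

#' Saturation sub-class %Abundance per sample and lipid class
#'
#' Within each lipid class and sample, species concentrations are summed by
#' saturation category and divided by the class total, yielding percentages
#' that sum to 100. A zero class total makes the four percentages undefined
#' (`NA`, flagged).
#'
#' @param table a `lpn_quant` (imputed or not; missing cells are ignored).
#' @return Long data.frame(sample_id, lipid_class, category, abundance_pct).
#' @export
subclass_abundance <- function(table) {
  ann <- annotate_features(table)
  tot <- class_totals(table)
  out <- list()
  for (cl in colnames(tot)) {
    for (cat in SATURATION_LEVELS) {
      cols <- ann$feature_id[ann$lipid_class == cl & ann$category == cat]
      s <- rowSums(table$values[, cols, drop = FALSE], na.rm = TRUE)
      pct <- ifelse(tot[, cl] > 0, 100 * s / tot[, cl], NA_real_)
      out[[paste(cl, cat)]] <- data.frame(
        sample_id = rownames(table$values), lipid_class = cl,
        category = cat, abundance_pct = pct, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$category <- factor(res$category, levels = SATURATION_LEVELS)
  res
}

#' Group summary of %Abundance values relative to the reference group
#'
#' Group means with t-based confidence intervals per (group, class, category),
#' and the difference of each group mean from the reference group mean.
#' Singleton groups get `NA` intervals.
#'
#' @param abund output of [subclass_abundance()].
#' @param design a [group_design()].
#' @param conf confidence level (default 0.95).
#' @return data.frame(group, lipid_class, category, mean_pct, ci_lo, ci_hi,
#'   diff_vs_ref).
#' @export
abundance_group_summary <- function(abund, design, conf = 0.95) {
  ref <- design_reference(design)
  abund$group <- design$group[match(abund$sample_id, design$sample_id)]
  if (anyNA(abund$group)) stop("abundance table contains samples absent from design")
  key <- interaction(abund$lipid_class, abund$category, drop = FALSE)
  rows <- list()
  for (k in levels(key)) {
    sub <- abund[key == k, ]
    ref_mean <- mean(sub$abundance_pct[sub$group == ref], na.rm = TRUE)
    for (g in levels(design$group)) {
      x <- sub$abundance_pct[sub$group == g]
      x <- x[!is.na(x)]
      n <- length(x); m <- if (n) mean(x) else NA_real_
      half <- if (n >= 2L) stats::qt(1 - (1 - conf) / 2, n - 1L) * stats::sd(x) / sqrt(n)
              else NA_real_
      rows[[paste(k, g)]] <- data.frame(
        group = g, lipid_class = sub$lipid_class[1],
        category = as.character(sub$category[1]), mean_pct = m,
        ci_lo = m - half, ci_hi = m + half, diff_vs_ref = m - ref_mean,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$category <- factor(res$category, levels = SATURATION_LEVELS)
  res
}
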