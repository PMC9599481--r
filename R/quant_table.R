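# Core containers: concentration table and group design.

#' Recognized lipid class codes
#'
#' Cholesteryl esters (CE), ceramides (CER) and their hexosyl/lactosyl forms
#' (HCER, LCER), diacyl- and triacylglycerols (DAG, TAG), free fatty acids
#' (FFA), phosphatidylcholines/-ethanolamines (PC, PE) and their lyso forms
#' (LPC, LPE), and sphingomyelins (SM). LCER appears in quantified species
#' lists even though it is absent from the class census, so it is accepted as
#' a valid code.
#' @export
LIPID_CLASSES <- c("CE", "CER", "DAG", "FFA", "HCER", "LCER",
                   "LPC", "LPE", "PC", "PE", "SM", "TAG")

#' Construct a concentration table
#'
#' A `lpn_quant` holds a samples x features matrix of nonnegative
#' concentrations (NA marks a missing measurement) plus per-feature metadata:
#' the omics layer (`"lipid"` or `"protein"`), the lipid class for lipid
#' features, and units (nmol/mL for lipids, nmol/L for proteins).
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#' @param feature_meta data.frame with columns `feature_id`, `layer`,
#'   `lipid_class` (NA for proteins) and `units`, one row per feature.
#' @return An object of class `lpn_quant`.
#' @export
quant_table <- function(values, feature_meta) {
  stopifnot(is.matrix(values), is.data.frame(feature_meta))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample rownames and feature colnames")
  req <- c("feature_id", "layer", "lipid_class", "units")
  miss <- setdiff(req, names(feature_meta))
  if (length(miss)) stop("feature_meta lacks columns: ", paste(miss, collapse = ", "))
  feature_meta <- feature_meta[match(colnames(values), feature_meta$feature_id), req]
  x <- structure(list(values = values, feature_meta = feature_meta),
                 class = "lpn_quant")
  validate_quant(x)
  x
}

validate_quant <- function(x) {
  v <- x$values; fm <- x$feature_meta
  if (anyDuplicated(rownames(v))) stop("duplicate sample ids: ",
    paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v))) stop("duplicate feature ids: ",
    paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (anyNA(fm$feature_id)) {
    stop("feature(s) present in data but absent from metadata: ",
         paste(colnames(v)[is.na(fm$feature_id)], collapse = ", "))
  }
  neg <- which(v < 0, arr.ind = TRUE)
  if (nrow(neg)) stop(sprintf("negative concentration at sample '%s', feature '%s'",
                              rownames(v)[neg[1, 1]], colnames(v)[neg[1, 2]]))
  bad_layer <- !fm$layer %in% c("lipid", "protein")
  if (any(bad_layer)) stop("unknown layer for feature '", fm$feature_id[which(bad_layer)[1]],
                           "': ", fm$layer[which(bad_layer)[1]])
  lip <- fm$layer == "lipid"
  if (any(lip & (is.na(fm$lipid_class) | !fm$lipid_class %in% LIPID_CLASSES)))
    stop("lipid feature without a valid lipid_class: ",
         fm$feature_id[which(lip & (is.na(fm$lipid_class) | !fm$lipid_class %in% LIPID_CLASSES))[1]])
  invisible(x)
}

#' @export
print.lpn_quant <- function(x, ...) {
  fm <- x$feature_meta
  cat(sprintf("lpn_quant: %d samples x %d features (%d lipid, %d protein), %d missing cells\n",
              nrow(x$values), ncol(x$values),
              sum(fm$layer == "lipid"), sum(fm$layer == "protein"),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.lpn_quant <- function(x) dim(x$values)

#' Subset a concentration table by samples and/or features
#' @param x a `lpn_quant`.
#' @param samples,features character vectors of ids to retain (NULL = all).
#' @export
subset_quant <- function(x, samples = NULL, features = NULL) {
  s <- samples %||% rownames(x$values)
  f <- features %||% colnames(x$values)
  quant_table(x$values[s, f, drop = FALSE],
              x$feature_meta[x$feature_meta$feature_id %in% f, , drop = FALSE])
}

#' Feature ids belonging to one omics layer
#' @param x a `lpn_quant`.
#' @param layer `"lipid"` or `"protein"`.
#' @export
layer_features <- function(x, layer = c("lipid", "protein")) {
  layer <- match.arg(layer)
  x$feature_meta$feature_id[x$feature_meta$layer == layer]
}

#' Construct a sample-to-group design
#'
#' @param sample_ids character sample ids.
#' @param groups character/factor group labels, one per sample.
#' @param reference reference group (default `"NL"`, normolipidemic).
#' @return `lpn_design`: data.frame(sample_id, group) with a `reference`
#'   attribute; group levels follow the canonical HC/HT/HL/HG/NL order where
#'   applicable, otherwise order of first appearance.
#' @export
group_design <- function(sample_ids, groups, reference = "NL") {
  stopifnot(length(sample_ids) == length(groups))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in design")
  groups <- as.character(groups)
  lev <- if (all(unique(groups) %in% GROUP_LEVELS))
    intersect(GROUP_LEVELS, unique(groups)) else unique(groups)
  if (!reference %in% lev) stop("reference group '", reference, "' absent from design")
  if (sum(groups == reference) < 2L) stop("reference group needs >= 2 samples")
  d <- data.frame(sample_id = as.character(sample_ids),
                  group = factor(groups, levels = lev),
                  stringsAsFactors = FALSE)
  structure(d, reference = reference, class = c("lpn_design", "data.frame"))
}

#' Reference group of a design
#' @param design a `lpn_design`.
#' @export
design_reference <- function(design) attr(design, "reference")

#' Sample ids of one group
#' @param design a `lpn_design`.
#' @param group group label.
#' @export
group_samples <- function(design, group) design$sample_id[design$group == group]

check_design_covers <- function(table, design) {
  missing <- setdiff(rownames(table$values), design$sample_id)
  if (length(missing)) stop("samples without group assignment: ",
                            paste(missing, collapse = ", "))
  invisible(TRUE)
}

# ---- delimited-text I/O -----------------------------------------------------

#' Read a wide concentration table with its feature metadata
#'
#' The data file is delimited text with sample ids in the first column and one
#' column per feature; empty cells are missing values. The metadata file maps
#' `feature_id` to `layer`, `lipid_class` and `units`.
#'
#' @param path data file.
#' @param meta_path metadata file.
#' @param delim field delimiter (default comma).
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, meta_path, delim = ",") {
  raw <- utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                           na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("data file needs a sample-id column plus >= 1 feature")
  ids <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  meta <- utils::read.table(meta_path, sep = delim, header = TRUE, check.names = FALSE,
                            na.strings = c("", "NA"), stringsAsFactors = FALSE)
  quant_table(vals, meta)
}

#' Write a concentration table and its metadata as delimited text
#' @param x a `lpn_quant`.
#' @param path,meta_path output files.
#' @param delim field delimiter.
#' @export
write_quant_table <- function(x, path, meta_path, delim = ",") {
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE, na = "")
  utils::write.table(x$feature_meta, meta_path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(c(path, meta_path))
}

#' Read / write a two-column sample,group design file
#' @param path design file (CSV: sample,group).
#' @param reference reference group label.
#' @param delim field delimiter.
#' @export
read_design <- function(path, reference = "NL", delim = ",") {
  d <- utils::read.table(path, sep = delim, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("design file needs sample and group columns")
  group_design(d[[1L]], d[[2L]], reference = reference)
}

#' @rdname read_design
#' @param design a `lpn_design` to write.
#' @export
write_design <- function(design, path, delim = ",") {
  utils::write.table(data.frame(sample = design$sample_id, group = design$group),
                     path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
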