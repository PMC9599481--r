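# Bootstrap-forest predictor screening.
#
# Repeated cycles: each cycle draws a bootstrap resample of the training
# samples, fits a small ensemble of Gini-impurity classification trees (each
# tree on a bootstrap of the cycle's resample, with random mtry feature
# subsampling), accumulates per-feature impurity-decrease importance, and
# records the per-cycle top features by contribution share. Pool = the
# features most frequently selected across cycles. Tree internals (tree
# count, depth) follow documented conventions since the original screening
# tool does not publish its own.

gini_node <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best threshold split of one feature; returns impurity decrease (weighted by
# node fraction of the root) and threshold, or NULL if no valid split.
best_split_feature <- function(x, Yoh, parent_gini, n_root) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cum <- apply(Yoh[ord, , drop = FALSE], 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
  tot <- cum[n, ]
  valid <- which(xs[-n] < xs[-1L])
  if (!length(valid)) return(NULL)
  nl <- valid
  gl <- 1 - rowSums((cum[valid, , drop = FALSE] / nl)^2)
  right <- sweep(-cum[valid, , drop = FALSE], 2, tot, `+`)
  nr <- n - nl
  gr <- 1 - rowSums((right / nr)^2)
  dec <- parent_gini - (nl * gl + nr * gr) / n
  i <- which.max(dec)
  list(decrease = dec[i] * n / n_root,
       threshold = (xs[valid[i]] + xs[valid[i] + 1L]) / 2)
}

# Grow one tree on (X, y); accumulates importance into env$imp (named vector).
grow_tree <- function(X, y_int, K, mtry, max_depth, min_node, env) {
  recurse <- function(idx, depth) {
    counts <- tabulate(y_int[idx], K)
    g <- gini_node(counts)
    if (depth >= max_depth || length(idx) < min_node || g == 0) return()
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    Yoh <- diag(K)[y_int[idx], , drop = FALSE]
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      sp <- best_split_feature(X[idx, f], Yoh, g, nrow(X))
      if (!is.null(sp) && (is.null(best) || sp$decrease > best$decrease)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best) || best$decrease <= 0) return()
    env$imp[best_f] <- env$imp[best_f] + best$decrease
    go_left <- X[idx, best_f] <= best$threshold
    left <- idx[go_left]
    right <- idx[!go_left]
    if (length(left) >= 2L) recurse(left, depth + 1L)
    if (length(right) >= 2L) recurse(right, depth + 1L)
  }
  recurse(seq_len(nrow(X)), 0L)
}

# Importance (impurity-decrease totals) of one forest fit.
forest_importance <- function(X, y, n_trees, mtry, max_depth, min_node) {
  y_int <- as.integer(y); K <- nlevels(y)
  env <- new.env()
  env$imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  n <- nrow(X)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(X[idx, , drop = FALSE], y_int[idx], K, mtry, max_depth, min_node, env)
  }
  env$imp
}

#' Repeated bootstrap-forest predictor screening
#'
#' @param X samples x features numeric matrix (training data only).
#' @param y factor of class labels (>= 2 classes).
#' @param cycles number of screening cycles (default 100).
#' @param per_cycle_top features recorded per cycle by contribution share
#'   (default 20).
#' @param pool_size size of the final predictor pool (default 20).
#' @param n_trees,max_depth,min_node,mtry forest conventions per cycle
#'   (defaults 25 trees, depth 4, minimum node 5, `mtry = floor(sqrt(p))`).
#' @param seed integer seed; each cycle uses a derived sub-seed.
#' @return An object of class `lpn_screen`: data.frame `result` (feature,
#'   frequency, mean_contribution, ordered by frequency then contribution) and
#'   character `pool` (top `pool_size`, sorted by mean contribution as the
#'   search entry order).
#' @export
screen_predictors <- function(X, y, cycles = 100L, per_cycle_top = 20L,
                              pool_size = 20L, n_trees = 25L, max_depth = 4L,
                              min_node = 5L, mtry = NULL, seed = 1L) {
  y <- droplevels(as.factor(y))
  stopifnot(is.matrix(X), nrow(X) == length(y), nlevels(y) >= 2L, cycles >= 1L)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  p <- ncol(X)
  freq <- stats::setNames(numeric(p), colnames(X))
  contrib <- stats::setNames(numeric(p), colnames(X))
  n <- nrow(X)
  for (cy in seq_len(cycles)) {
    with_seed(sub_seed(seed, paste0("cycle", cy)), {
      idx <- sample.int(n, n, replace = TRUE)
      imp <- forest_importance(X[idx, , drop = FALSE], y[idx], n_trees, mtry,
                               max_depth, min_node)
      share <- if (sum(imp) > 0) imp / sum(imp) else imp
      top <- head(order(-share, seq_len(p)), min(per_cycle_top, p))
      freq[top] <- freq[top] + 1
      contrib <- contrib + share
    })
  }
  mean_contrib <- contrib / cycles
  res <- data.frame(feature = colnames(X), frequency = unname(freq),
                    mean_contribution = unname(mean_contrib),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$frequency, -res$mean_contribution, res$feature), ]
  rownames(res) <- NULL
  pool <- head(res$feature, min(pool_size, p))
  # entry order for the greedy search: by estimated relative contribution
  pool <- pool[order(-mean_contrib[pool])]
  structure(list(result = res, pool = pool, cycles = cycles), class = "lpn_screen")
}

#' @export
print.lpn_screen <- function(x, ...) {
  cat(sprintf("lpn_screen: pool of %d features from %d cycles; top: %s\n",
              length(x$pool), x$cycles,
              paste(head(x$pool, 5), collapse = ", ")))
  invisible(x)
}
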