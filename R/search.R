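# Train/test splitting and the greedy "leading predictor" model search.
#
# For each pool member taken as leading predictor, forward selection adds the
# unused pool feature whose addition maximizes the selection metric, accepting
# only strict improvements; the overall winner is chosen by selection
# accuracy, then macro AUC, then smaller predictor set, then pool order. The
# selection metric is 5-fold CV accuracy on the training set by default
# ("cv"); the "paper" mode scores candidate models on the held-out test set
# during the search, replicating the original procedure (and its leakage) and
# is labeled as such.

#' Stratified train/test split
#'
#' Per-group training counts are obtained by largest-remainder rounding so the
#' training total equals `round(n * train_fraction)`; remainder ties break by
#' group level order. The non-stratified mode draws a simple random sample of
#' that size.
#'
#' @param design a [group_design()] (every group needs >= 2 samples).
#' @param train_fraction fraction of samples to train on, in (0, 1).
#' @param stratified stratify by group (default TRUE).
#' @param seed integer seed.
#' @return list(train, test) of sample ids; disjoint, union = all samples.
#' @export
split_train_test <- function(design, train_fraction = 0.70, stratified = TRUE,
                             seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  ng <- table(design$group)
  if (any(ng < 2L)) stop("every group needs >= 2 samples to split")
  n <- nrow(design)
  total <- round(n * train_fraction)
  if (total >= n || total < 1L) stop("train_fraction yields an empty train or test set")
  train <- with_seed(sub_seed(seed, "split"), {
    if (stratified) {
      tg <- as.numeric(ng) * train_fraction
      base <- floor(tg)
      extra <- total - sum(base)
      if (extra > 0) {
        give <- head(order(-(tg - base), seq_along(tg)), extra)
        base[give] <- base[give] + 1
      } else if (extra < 0) {
        take <- head(order(tg - base, seq_along(tg)), -extra)
        base[take] <- base[take] - 1
      }
      unlist(lapply(seq_along(levels(design$group)), function(i) {
        ids <- group_samples(design, levels(design$group)[i])
        sample(ids, base[i])
      }))
    } else sample(design$sample_id, total)
  })
  list(train = sort(train), test = sort(setdiff(design$sample_id, train)))
}

# Stratified k-fold assignment (named by sample position).
cv_fold_assignment <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Selection-metric scorer with memoization over predictor sets.
make_set_scorer <- function(X, y, train_ids, test_ids, selection_mode, folds,
                            ann_opts, seed) {
  cache <- new.env(parent = emptyenv())
  ytr <- y[train_ids]
  fold <- if (selection_mode == "cv")
    cv_fold_assignment(droplevels(ytr), folds, sub_seed(seed, "folds"))
  function(predictors) {
    key <- paste(sort(predictors), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    Xtr <- X[train_ids, predictors, drop = FALSE]
    res <- if (selection_mode == "cv") {
      P <- matrix(NA_real_, length(train_ids), nlevels(y),
                  dimnames = list(train_ids, levels(y)))
      for (f in seq_len(folds)) {
        in_f <- fold == f
        if (!any(in_f) || length(unique(ytr[!in_f])) < 2L) next
        m <- train_ann(Xtr[!in_f, , drop = FALSE], droplevels(ytr[!in_f]),
                       hidden_nodes = ann_opts$hidden_nodes,
                       lambda = ann_opts$lambda, restarts = ann_opts$restarts,
                       maxit = ann_opts$maxit, seed = sub_seed(seed, paste0("fold", f)))
        P[in_f, m$levels] <- predict(m, Xtr[in_f, , drop = FALSE])
      }
      P[is.na(P)] <- 0
      pred <- factor(levels(y)[max.col(P, ties.method = "first")], levels = levels(y))
      list(accuracy = mean(pred == ytr),
           macro_auc = mean(vapply(levels(y), function(cl)
             auc_ovr(P[, cl], ytr == cl), 0), na.rm = TRUE))
    } else {
      m <- train_ann(Xtr, droplevels(ytr), hidden_nodes = ann_opts$hidden_nodes,
                     lambda = ann_opts$lambda, restarts = ann_opts$restarts,
                     maxit = ann_opts$maxit, seed = sub_seed(seed, "papermode"))
      ev <- evaluate_model(m, X[test_ids, predictors, drop = FALSE], y[test_ids])
      list(accuracy = ev$accuracy, macro_auc = ev$macro_auc)
    }
    cache[[key]] <- res
    res
  }
}

#' Greedy leading-predictor search over Gaussian-node MLPs
#'
#' @param pool ordered predictor pool (a `lpn_screen` or character vector,
#'   most important first).
#' @param X samples x features matrix with sample rownames.
#' @param y class labels named by sample (or aligned to `X` rows).
#' @param split list(train, test) of sample ids from [split_train_test()]
#'   (`test` may be NULL in cv mode; it is then never touched).
#' @param selection_mode `"cv"` (default; 5-fold CV accuracy on the training
#'   set) or `"paper"` (held-out test accuracy, replicating the original
#'   search's use of the test set during selection).
#' @param folds CV folds for mode `"cv"`.
#' @param max_size largest predictor set considered (>= 1).
#' @param hidden_nodes,lambda,restarts,maxit passed to [train_ann()].
#' @param seed integer seed fixing folds and every fit.
#' @return An object of class `lpn_search`: `traces` (per leading predictor:
#'   accepted sets with selection accuracies, non-decreasing by
#'   construction), `best` (predictors, accuracy, macro_auc, leader), and
#'   `curve` (best accepted selection accuracy per predictor-set size).
#' @export
greedy_leading_search <- function(pool, X, y, split,
                                  selection_mode = c("cv", "paper"),
                                  folds = 5L, max_size = NULL,
                                  hidden_nodes = 5L, lambda = 1e-3,
                                  restarts = 2L, maxit = 200L, seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  if (inherits(pool, "lpn_screen")) pool <- pool$pool
  stopifnot(length(pool) >= 1L)
  max_size <- max_size %||% length(pool)
  if (max_size < 1L) stop("max_size must be >= 1")
  if (is.null(names(y))) names(y) <- rownames(X)
  y <- factor(as.character(y[rownames(X)]))
  names(y) <- rownames(X)
  if (selection_mode == "paper" && is.null(split$test))
    stop("paper mode requires a test set")
  scorer <- make_set_scorer(X, y, split$train, split$test, selection_mode,
                            folds, list(hidden_nodes = hidden_nodes,
                                        lambda = lambda, restarts = restarts,
                                        maxit = maxit), seed)
  traces <- list()
  best <- NULL
  for (li in seq_along(pool)) {
    leader <- pool[li]
    S <- leader
    sc <- scorer(S)
    steps <- data.frame(step = 0L, added = leader, accuracy = sc$accuracy,
                        macro_auc = sc$macro_auc, set = paste(S, collapse = "+"),
                        stringsAsFactors = FALSE)
    repeat {
      if (length(S) >= max_size) break
      cand <- setdiff(pool, S)
      if (!length(cand)) break
      cand_sc <- lapply(cand, function(f) scorer(c(S, f)))
      acc <- vapply(cand_sc, `[[`, 0, "accuracy")
      i <- which.max(acc)  # ties resolve to pool order
      if (acc[i] <= sc$accuracy + 1e-12) break
      S <- c(S, cand[i]); sc <- cand_sc[[i]]
      steps <- rbind(steps, data.frame(step = nrow(steps), added = cand[i],
                                       accuracy = sc$accuracy,
                                       macro_auc = sc$macro_auc,
                                       set = paste(S, collapse = "+"),
                                       stringsAsFactors = FALSE))
    }
    traces[[leader]] <- list(leader = leader, predictors = S, steps = steps,
                             accuracy = sc$accuracy, macro_auc = sc$macro_auc)
    better <- is.null(best) ||
      sc$accuracy > best$accuracy + 1e-12 ||
      (abs(sc$accuracy - best$accuracy) <= 1e-12 &&
         (sc$macro_auc > best$macro_auc + 1e-12 ||
            (abs(sc$macro_auc - best$macro_auc) <= 1e-12 &&
               length(S) < length(best$predictors))))
    if (better) best <- list(predictors = S, accuracy = sc$accuracy,
                             macro_auc = sc$macro_auc, leader = leader)
  }
  sizes <- unlist(lapply(traces, function(tr) seq_len(nrow(tr$steps))))
  accs <- unlist(lapply(traces, function(tr) tr$steps$accuracy))
  curve <- tapply(accs, sizes, max)
  structure(list(traces = traces, best = best, selection_mode = selection_mode,
                 curve = data.frame(n_predictors = as.integer(names(curve)),
                                    best_accuracy = as.numeric(curve))),
            class = "lpn_search")
}

#' @export
print.lpn_search <- function(x, ...) {
  cat(sprintf("lpn_search (%s): best set of %d predictors, selection accuracy %.3f\n",
              x$selection_mode, length(x$best$predictors), x$best$accuracy))
  cat("  ", paste(x$best$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' End-to-end classification stage
#'
#' Split, screen predictors on the training partition, run the greedy
#' leading-predictor search, fit the final model on the full training set and
#' evaluate on train and test. All stage seeds derive from the master seed.
#'
#' @param table imputed `lpn_quant`.
#' @param design a [group_design()].
#' @param train_fraction,stratified split parameters.
#' @param cycles,per_cycle_top,pool_size,n_trees,max_depth screening
#'   parameters (see [screen_predictors()]).
#' @param selection_mode,folds,max_size search parameters (see
#'   [greedy_leading_search()]).
#' @param hidden_nodes,lambda,restarts,maxit MLP parameters.
#' @param seed master seed.
#' @return list(split, screening, search, model, train_eval, test_eval,
#'   curve).
#' @export
run_classification_stage <- function(table, design, train_fraction = 0.70,
                                     stratified = TRUE, cycles = 100L,
                                     per_cycle_top = 20L, pool_size = 20L,
                                     n_trees = 25L, max_depth = 4L,
                                     selection_mode = "cv", folds = 5L,
                                     max_size = NULL, hidden_nodes = 5L,
                                     lambda = 1e-3, restarts = 3L,
                                     maxit = 300L, seed = 1L) {
  check_design_covers(table, design)
  if (anyNA(table$values)) stop("classification requires an imputed table")
  y <- stats::setNames(as.character(design$group), design$sample_id)
  y <- factor(y[rownames(table$values)], levels = levels(design$group))
  names(y) <- rownames(table$values)
  split <- split_train_test(design, train_fraction, stratified,
                            seed = sub_seed(seed, "split"))
  lpn_log("classify", sprintf("split train=%d test=%d", length(split$train),
                              length(split$test)))
  X <- table$values
  screening <- screen_predictors(X[split$train, , drop = FALSE],
                                 droplevels(y[split$train]), cycles = cycles,
                                 per_cycle_top = per_cycle_top,
                                 pool_size = pool_size, n_trees = n_trees,
                                 max_depth = max_depth,
                                 seed = sub_seed(seed, "screen"))
  lpn_log("classify", sprintf("pool=%s", paste(screening$pool, collapse = ",")))
  search <- greedy_leading_search(screening, X, y, split,
                                  selection_mode = selection_mode,
                                  folds = folds, max_size = max_size,
                                  hidden_nodes = hidden_nodes, lambda = lambda,
                                  restarts = restarts, maxit = maxit,
                                  seed = sub_seed(seed, "search"))
  model <- train_ann(X[split$train, search$best$predictors, drop = FALSE],
                     droplevels(y[split$train]), hidden_nodes = hidden_nodes,
                     lambda = lambda, restarts = max(restarts, 3L),
                     maxit = maxit, seed = sub_seed(seed, "final"))
  train_eval <- evaluate_model(model, X[split$train, search$best$predictors, drop = FALSE],
                               y[split$train])
  test_eval <- evaluate_model(model, X[split$test, search$best$predictors, drop = FALSE],
                              y[split$test])
  lpn_log("classify", sprintf("train_acc=%.3f test_acc=%.3f",
                              train_eval$accuracy, test_eval$accuracy))
  list(split = split, screening = screening, search = search, model = model,
       train_eval = train_eval, test_eval = test_eval, curve = search$curve,
       seed = seed)
}
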