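test_that("stratified split uses largest-remainder rounding", {
  # full cohort: 146 samples -> 102 train / 44 test
  gs <- cohort_group_sizes()
  d <- group_design(sprintf("s%03d", 1:146), rep(names(gs), gs))
  sp <- split_train_test(d, 0.70, seed = 1)
  expect_length(sp$train, 102L)
  expect_length(sp$test, 44L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), d$sample_id)
  # per-group counts follow largest-remainder arithmetic
  grp <- d$group[match(sp$train, d$sample_id)]
  expect_identical(as.integer(table(grp)), c(25L, 22L, 20L, 20L, 15L))
  # 10 samples, two groups of 5 at 0.70 -> 7 train split (4, 3) by label order
  d2 <- group_design(sprintf("t%02d", 1:10), rep(c("A", "B"), each = 5),
                     reference = "A")
  sp2 <- split_train_test(d2, 0.70, seed = 9)
  cnt <- table(d2$group[match(sp2$train, d2$sample_id)])
  expect_identical(as.integer(cnt), c(4L, 3L))
  # determinism
  expect_identical(split_train_test(d, 0.70, seed = 5),
                   split_train_test(d, 0.70, seed = 5))
  expect_error(split_train_test(d2, 0.999), "empty")
})

test_that("screening finds planted informative features and honors contracts", {
  sep <- separable_matrix(n_per_group = 20, n_inform = 3, n_noise = 20,
                          sep = 3, seed = 4)
  sc <- screen_predictors(sep$X, sep$y, cycles = 20, per_cycle_top = 5,
                          pool_size = 5, n_trees = 12, max_depth = 3, seed = 2)
  expect_true(all(sep$informative %in% sc$pool))
  expect_true(all(sc$result$frequency >= 0 & sc$result$frequency <= 20))
  # cycles = 1 reduces to a single forest's top-k
  sc1 <- screen_predictors(sep$X, sep$y, cycles = 1, per_cycle_top = 5,
                           pool_size = 5, n_trees = 12, max_depth = 3, seed = 2)
  expect_identical(sort(unique(sc1$result$frequency)), c(0, 1))
  expect_identical(sum(sc1$result$frequency), 5)
  # pool invariant to feature column order
  perm <- rev(seq_len(ncol(sep$X)))
  sc_perm <- screen_predictors(sep$X[, perm], sep$y, cycles = 20,
                               per_cycle_top = 5, pool_size = 5, n_trees = 12,
                               max_depth = 3, seed = 2)
  expect_true(all(sep$informative %in% sc_perm$pool))
  # constant features are tolerated with zero importance
  Xc <- cbind(sep$X, const = 1)
  scc <- screen_predictors(Xc, sep$y, cycles = 3, per_cycle_top = 5,
                           pool_size = 5, n_trees = 8, max_depth = 3, seed = 2)
  expect_identical(scc$result$frequency[scc$result$feature == "const"], 0)
})

test_that("pure-noise labels yield near-uniform selection frequencies", {
  withr::with_seed(6, {
    X <- matrix(rnorm(80 * 30), 80, dimnames = list(NULL, sprintf("f%02d", 1:30)))
    y <- factor(rep(c("a", "b"), each = 40))
  })
  sc <- screen_predictors(X, y, cycles = 30, per_cycle_top = 10, pool_size = 10,
                          n_trees = 10, max_depth = 3, seed = 8)
  # no feature should dominate: top frequency well below the cycle count
  expect_lt(max(sc$result$frequency), 0.8 * 30)
})

test_that("the Gaussian-node MLP fits separable data and is reproducible", {
  withr::with_seed(2, {
    X <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
               matrix(rnorm(40, 5, 0.3), ncol = 2))
    colnames(X) <- c("a", "b"); rownames(X) <- sprintf("s%02d", 1:40)
    y <- factor(rep(c("lo", "hi"), each = 20))
  })
  m <- train_ann(X, y, restarts = 4, seed = 3)
  expect_equal(evaluate_model(m, X, y)$accuracy, 1.0)
  # deterministic under (seed, restarts)
  m2 <- train_ann(X, y, restarts = 4, seed = 3)
  expect_identical(m$W1, m2$W1)
  expect_identical(predict(m, X), predict(m2, X))
  # duplicated predictor cannot hurt training accuracy beyond fit tolerance
  Xd <- cbind(X, a2 = X[, "a"])
  md <- train_ann(Xd, y, restarts = 4, seed = 3)
  expect_gte(evaluate_model(md, Xd, y)$accuracy,
             evaluate_model(m, X, y)$accuracy - 0.05)
  # guards
  expect_error(train_ann(X, factor(rep("one", 40))), "2 classes")
  X[1, 1] <- NA
  expect_error(train_ann(X, y), "non-finite")
})

test_that("evaluation: confusion identity, AUC vs brute-force pair counting", {
  # hand example: positives (0.9, 0.8), negatives (0.7, 0.85) -> AUC 0.75
  expect_equal(auc_ovr(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # brute-force oracle with half-credit ties on random small instances
  brute_auc <- function(s, pos) {
    ps <- s[pos]; ns <- s[!pos]
    mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(4:20, 1)
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (any(pos) && any(!pos))
        expect_equal(auc_ovr(s, pos), brute_auc(s, pos), tolerance = 1e-12)
    }
  })
  # random scores hover near AUC 0.5
  withr::with_seed(33, {
    aucs <- replicate(200, auc_ovr(runif(30), rep(c(TRUE, FALSE), 15)))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
  # perfect classifier
  sep <- separable_matrix(n_per_group = 10, n_inform = 2, n_noise = 1,
                          sep = 8, seed = 10)
  m <- train_ann(sep$X[, sep$informative], sep$y, restarts = 4, seed = 1)
  ev <- evaluate_model(m, sep$X[, sep$informative], sep$y)
  expect_identical(as.integer(rowSums(ev$confusion)),
                   as.integer(table(sep$y)))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / length(sep$y))
  # absent class flagged
  keep <- sep$y != "NL"
  ev2 <- evaluate_model(m, sep$X[keep, sep$informative], sep$y[keep])
  expect_identical(ev2$absent_classes, "NL")
  expect_true(is.na(ev2$auc["NL"]))
})

test_that("greedy search honors its contracts on a small pool", {
  sep <- separable_matrix(n_per_group = 12, n_inform = 2, n_noise = 2,
                          sep = 3, seed = 14)
  d <- group_design(rownames(sep$X), as.character(sep$y))
  sp <- split_train_test(d, 0.7, seed = 2)
  # pool of size 1 -> degenerate single-predictor model
  s1 <- greedy_leading_search("inf01", sep$X, sep$y, sp, folds = 3,
                              restarts = 1, maxit = 80, seed = 5)
  expect_identical(s1$best$predictors, "inf01")
  # pool of 4: traces are acceptance-monotone, best >= best single
  s4 <- greedy_leading_search(colnames(sep$X), sep$X, sep$y, sp, folds = 3,
                              restarts = 1, maxit = 80, seed = 5)
  singles <- vapply(s4$traces, function(tr) tr$steps$accuracy[1], 0)
  for (tr in s4$traces) expect_true(all(diff(tr$steps$accuracy) > 0))
  expect_gte(s4$best$accuracy, max(singles))
  expect_error(greedy_leading_search(colnames(sep$X), sep$X, sep$y, sp,
                                     max_size = 0), "max_size")
})

test_that("cv selection mode never touches the test samples", {
  sep <- separable_matrix(n_per_group = 10, n_inform = 2, n_noise = 1,
                          sep = 3, seed = 18)
  d <- group_design(rownames(sep$X), as.character(sep$y))
  sp <- split_train_test(d, 0.7, seed = 3)
  # structural guarantee: with test = NULL the cv search still runs
  s <- greedy_leading_search(colnames(sep$X)[1:3], sep$X, sep$y,
                             list(train = sp$train, test = NULL),
                             folds = 3, restarts = 1, maxit = 80, seed = 7)
  expect_s3_class(s, "lpn_search")
  expect_error(greedy_leading_search(colnames(sep$X)[1:3], sep$X, sep$y,
                                     list(train = sp$train, test = NULL),
                                     selection_mode = "paper"), "test set")
})

test_that("end-to-end classification stage is deterministic", {
  co <- generate_cohort(synthetic_config(
    group_sizes = c(HC = 10, HT = 10, NL = 10),
    n_species_per_class = c(CE = 4, TAG = 4), n_proteins = 3,
    effect_table = rbind(data.frame(target = "CE", group = "HC", shift = 4),
                         data.frame(target = "TAG", group = "HT", shift = 4)),
    missing_rate = 0, seed = 91))
  args <- list(table = co$table, design = co$design, cycles = 4, pool_size = 3,
               per_cycle_top = 3, n_trees = 6, max_depth = 3, folds = 3,
               restarts = 1, maxit = 60, max_size = 2, seed = 11)
  r1 <- do.call(run_classification_stage, args)
  r2 <- do.call(run_classification_stage, args)
  expect_identical(r1$search$best, r2$search$best)
  expect_identical(r1$train_eval$confusion, r2$train_eval$confusion)
  expect_true(all(c("n_predictors", "best_accuracy") %in% names(r1$curve)))
})
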