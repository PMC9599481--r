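# Small multilayer perceptron with Gaussian hidden activation.
#
# One fully connected hidden layer of H units with activation
# g(z) = exp(-z^2) on the affine pre-activation, softmax-normalized class
# outputs, fit by minimizing multinomial cross-entropy plus a small ridge
# penalty on the weights, best-of-restarts BFGS. Predictors are standardized
# with training-set mean/sd (constant columns get scale 1).

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

pack_theta <- function(W1, b1, W2, b2) c(W1, b1, W2, b2)
unpack_theta <- function(theta, p, H, K) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(p * H)], p, H); i <- i + p * H
  b1 <- theta[i + seq_len(H)]; i <- i + H
  W2 <- matrix(theta[i + seq_len(H * K)], H, K); i <- i + H * K
  b2 <- theta[i + seq_len(K)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

ann_forward <- function(Xs, par) {
  Z1 <- sweep(Xs %*% par$W1, 2, par$b1, `+`)
  A <- exp(-Z1^2)
  Z2 <- sweep(A %*% par$W2, 2, par$b2, `+`)
  list(Z1 = Z1, A = A, P = softmax_rows(Z2))
}

#' Train a Gaussian-node MLP classifier
#'
#' @param X samples x predictors numeric matrix (training data).
#' @param y factor of class labels (>= 2 classes present).
#' @param hidden_nodes hidden layer width (default 5).
#' @param lambda ridge penalty on weights (default 1e-3).
#' @param restarts random restarts, best kept by penalized training loss
#'   (default 3).
#' @param maxit BFGS iteration cap per restart (default 300).
#' @param seed integer seed; restart r uses a derived sub-seed, so fits are
#'   deterministic under (seed, restarts).
#' @return An object of class `lpn_ann` with weights, standardization
#'   parameters, class levels and the attained loss.
#' @export
train_ann <- function(X, y, hidden_nodes = 5L, lambda = 1e-3, restarts = 3L,
                      maxit = 300L, seed = 1L) {
  y <- droplevels(as.factor(y))
  stopifnot(is.matrix(X), nrow(X) == length(y), restarts >= 1L, hidden_nodes >= 1L)
  if (!all(is.finite(X))) stop("non-finite values in predictor matrix")
  if (nlevels(y) < 2L) stop("y must contain >= 2 classes")
  n <- nrow(X); p <- ncol(X); H <- as.integer(hidden_nodes); K <- nlevels(y)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  Yoh <- diag(K)[as.integer(y), , drop = FALSE]

  obj <- function(theta) {
    par <- unpack_theta(theta, p, H, K)
    fw <- ann_forward(Xs, par)
    ll <- -sum(Yoh * log(pmax(fw$P, 1e-12))) / n
    ll + lambda / 2 * (sum(par$W1^2) + sum(par$W2^2))
  }
  grad <- function(theta) {
    par <- unpack_theta(theta, p, H, K)
    fw <- ann_forward(Xs, par)
    dZ2 <- (fw$P - Yoh) / n
    gW2 <- crossprod(fw$A, dZ2) + lambda * par$W2
    gb2 <- colSums(dZ2)
    dA <- dZ2 %*% t(par$W2)
    dZ1 <- dA * (-2 * fw$Z1 * fw$A)
    gW1 <- crossprod(Xs, dZ1) + lambda * par$W1
    gb1 <- colSums(dZ1)
    pack_theta(gW1, gb1, gW2, gb2)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(sub_seed(seed, paste0("restart", r)), {
      # pre-activations near +-0.7: inside the informative flank of exp(-z^2)
      pack_theta(matrix(stats::rnorm(p * H, 0, 0.6 / sqrt(p)), p, H),
                 stats::rnorm(H, 0, 0.7),
                 matrix(stats::rnorm(H * K, 0, 0.5), H, K),
                 numeric(K))
    })
    fit <- stats::optim(init, obj, grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- unpack_theta(best$par, p, H, K)
  structure(list(W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
                 center = ctr, scale = scl, levels = levels(y),
                 predictors = colnames(X), hidden_nodes = H, lambda = lambda,
                 loss = best$value, seed = seed, restarts = restarts),
            class = "lpn_ann")
}

#' Predict class probabilities or labels from a fitted `lpn_ann`
#' @param object a [train_ann()] fit.
#' @param newdata samples x predictors matrix (same columns as training).
#' @param type `"prob"` for the class-probability matrix, `"class"` for the
#'   argmax labels (ties resolve to the first class level).
#' @param ... unused.
#' @export
predict.lpn_ann <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.null(object$predictors) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$predictors, drop = FALSE]
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  P <- ann_forward(Xs, object)$P
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")], levels = object$levels)
}

#' One-vs-rest AUC from scores
#'
#' Rank-based Mann-Whitney formulation; tied score pairs count 1/2.
#' @param scores numeric scores for the positive class.
#' @param positive logical mask of positives.
#' @export
auc_ovr <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a fitted classifier
#'
#' Confusion matrix from argmax probabilities, overall accuracy
#' (trace/total), and per-class one-vs-rest AUC from each class's predicted
#' probability. Classes absent from `y` get `NA` AUC (flagged).
#'
#' @param model a `lpn_ann`.
#' @param X samples x predictors matrix.
#' @param y true labels.
#' @return An object of class `lpn_eval`: list(confusion, accuracy, auc,
#'   macro_auc).
#' @export
evaluate_model <- function(model, X, y) {
  y <- factor(as.character(y), levels = model$levels)
  P <- predict(model, X, type = "prob")
  pred <- factor(model$levels[max.col(P, ties.method = "first")],
                 levels = model$levels)
  cm <- table(truth = y, predicted = pred)
  auc <- vapply(model$levels, function(cl) auc_ovr(P[, cl], y == cl), 0)
  structure(list(confusion = cm, accuracy = sum(diag(cm)) / length(y),
                 auc = auc, macro_auc = mean(auc, na.rm = TRUE),
                 absent_classes = model$levels[!model$levels %in% y]),
            class = "lpn_eval")
}

#' @export
print.lpn_eval <- function(x, ...) {
  cat(sprintf("lpn_eval: accuracy %.3f, macro AUC %.3f\n", x$accuracy, x$macro_auc))
  print(x$confusion)
  invisible(x)
}
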