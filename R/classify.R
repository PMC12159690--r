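#' Vectorize the strict lower triangle of a deviation matrix
#'
#' Row-major order: row i contributes columns j < i, so an m x m matrix
#' yields a vector of length `m(m-1)/2` ordered (2,1), (3,1), (3,2),
#' (4,1), ... [lower_triangle_matrix()] inverts the operation (up to the
#' zero diagonal).
#'
#' @param dev A `deviation_matrix` or bare square matrix.
#' @return Numeric vector of length `m(m-1)/2`.
#' @export
vectorize_lower_triangle <- function(dev) {
  z <- if (inherits(dev, "deviation_matrix")) dev$z else as.matrix(dev)
  tz <- t(z)
  tz[upper.tri(tz)]  # column-major upper triangle of t(z) == row-major lower of z
}

#' @rdname vectorize_lower_triangle
#' @param v Vector as produced by `vectorize_lower_triangle`.
#' @param labels Optional region labels for the reconstructed matrix.
#' @export
lower_triangle_matrix <- function(v, labels = NULL) {
  m <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (m != round(m)) stop("vector length is not m(m-1)/2 for integer m")
  z <- matrix(0, m, m)
  tz <- t(z)
  tz[upper.tri(tz)] <- v
  z <- t(tz)
  z <- z + t(z)
  if (!is.null(labels)) dimnames(z) <- list(labels, labels)
  z
}

#' Build a classification feature set from deviation matrices
#'
#' Either the vectorized strict lower triangles of the (by default raw,
#' unthresholded) z-matrices (`kind = "edges"`, m(m-1)/2 features) or the
#' per-subject RED vectors (`kind = "red"`, m features).
#'
#' @param devs List of `deviation_matrix` objects.
#' @param labels Class label per subject (factor or coercible).
#' @param kind `"edges"` or `"red"`.
#' @param thresholded For `kind = "edges"`: vectorize thresholded
#'   matrices instead of raw ones.
#' @param tau Threshold used when `thresholded = TRUE` or `kind = "red"`.
#' @return List of class `feature_set` with `X`, `y`, `feature_kind`.
#' @export
deviation_features <- function(devs, labels, kind = c("edges", "red"),
                               thresholded = FALSE, tau = 4.13) {
  kind <- match.arg(kind)
  y <- factor(labels)
  if (length(y) != length(devs)) stop("labels and deviation list differ in length")
  if (!nlevels(y) %in% c(2, 3)) stop("need 2 or 3 classes")
  X <- if (kind == "edges") {
    src <- if (thresholded) lapply(devs, function(d) threshold_deviation(d, tau)$zt) else devs
    do.call(rbind, lapply(src, vectorize_lower_triangle))
  } else {
    red(lapply(devs, threshold_deviation, tau = tau))
  }
  rownames(X) <- vapply(devs, function(d) d$subject_id, character(1))
  if (any(!is.finite(X))) stop("non-finite feature values")
  structure(list(X = X, y = y, feature_kind = kind), class = "feature_set")
}

# Stratified fold assignment: within each class, shuffled then dealt
# round-robin. Errors when a class has fewer members than folds.
stratified_folds <- function(y, folds, seed = NULL) {
  with_seed(seed, {
    assign <- integer(length(y))
    for (lev in levels(y)) {
      idx <- which(y == lev)
      if (length(idx) < folds)
        stop(sprintf("class '%s' has %d subjects, fewer than %d folds; use fewer folds",
                     lev, length(idx), folds))
      assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

# Fit a binary linear SVM on (a row representation of) the training
# features; returns a scoring function oriented so that higher scores
# favour the FIRST of the two class levels (orientation calibrated on
# the training decisions, never on test data).
binary_svm <- function(X_tr, y_tr, cost) {
  fit <- e1071::svm(X_tr, y_tr, kernel = "linear", cost = cost, scale = FALSE)
  dec_tr <- attr(stats::predict(fit, X_tr, decision.values = TRUE),
                 "decision.values")[, 1]
  lev <- levels(y_tr)
  orient <- mean(dec_tr[y_tr == lev[1]]) - mean(dec_tr[y_tr == lev[2]])
  orient <- if (orient >= 0) 1 else -1
  list(score = function(X_new) {
    orient * attr(stats::predict(fit, X_new, decision.values = TRUE),
                  "decision.values")[, 1]
  })
}

# Row representation of the fold-standardized features. When there are
# more features than subjects the linear SVM depends on the data only
# through the gram matrix K = Xs Xs', so Xs is replaced by an n x n
# factor R with R R' = K — the identical SVM, much cheaper per fit.
# Standardization uses training-row statistics only.
fold_representation <- function(X, tr) {
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (ncol(Xs) > nrow(Xs)) {
    e <- eigen(tcrossprod(Xs), symmetric = TRUE)
    Xs <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  }
  Xs
}

# Rank (Mann-Whitney) AUC: probability that a score from the positive
# group exceeds one from the negative group (ties count 1/2).
rank_auc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  np <- length(scores_pos); nn <- length(scores_neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# One fold of the linear-SVM pipeline. X is the raw feature matrix;
# standardization uses training-fold statistics only. Returns test-fold
# predictions and pairwise AUCs. `R` may be a precomputed fold
# representation from fold_representation() (fast path used by the
# permutation test, valid because standardization and the gram factor do
# not depend on labels).
svm_fold <- function(X, y, tr, te, cost, smote, smote_k, smote_seed, R = NULL) {
  lev <- levels(y)
  if (is.null(R)) R <- fold_representation(X, tr)

  y_tr <- y[tr]
  if (smote) {
    # convex interpolation commutes with the gram factorization, so SMOTE
    # in the row representation equals SMOTE in feature space for the
    # linear kernel
    bal <- smote_balance(R[tr, , drop = FALSE], y_tr, k = smote_k,
                         seed = smote_seed)
    R_tr <- bal$X; y_tr <- bal$y
  } else {
    R_tr <- R[tr, , drop = FALSE]
  }
  R_te <- R[te, , drop = FALSE]

  pairs <- utils::combn(lev, 2, simplify = FALSE)
  scores <- matrix(NA_real_, length(te), length(pairs))
  votes <- matrix(0L, length(te), length(lev), dimnames = list(NULL, lev))
  aucs <- numeric(length(pairs))
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    sub <- which(y_tr %in% pr)
    ysub <- droplevels(factor(y_tr[sub], levels = pr))
    mdl <- binary_svm(R_tr[sub, , drop = FALSE], ysub, cost)
    sc <- mdl$score(R_te)
    scores[, pi] <- sc
    winner <- ifelse(sc >= 0, pr[1], pr[2])
    for (j in seq_along(te)) votes[j, winner[j]] <- votes[j, winner[j]] + 1L
    te_in <- which(y[te] %in% pr)
    if (length(unique(y[te][te_in])) == 2) {
      aucs[pi] <- rank_auc(sc[te_in][y[te][te_in] == pr[1]],
                           sc[te_in][y[te][te_in] == pr[2]])
    } else aucs[pi] <- NA_real_
  }
  # one-vs-one majority vote; ties broken by total oriented margin
  pred <- character(length(te))
  for (j in seq_along(te)) {
    v <- votes[j, ]
    top <- names(v)[v == max(v)]
    if (length(top) == 1) pred[j] <- top
    else {
      margin <- sapply(top, function(cl) {
        s <- 0
        for (pi in seq_along(pairs)) {
          pr <- pairs[[pi]]
          if (cl == pr[1]) s <- s + scores[j, pi]
          if (cl == pr[2]) s <- s - scores[j, pi]
        }
        s
      })
      pred[j] <- top[which.max(margin)]
    }
  }
  list(pred = factor(pred, levels = lev), truth = y[te], aucs = aucs)
}

# Per-class recalls and one-vs-rest specificities from a prediction.
fold_metrics <- function(pred, truth) {
  lev <- levels(truth)
  recall <- vapply(lev, function(cl) {
    n <- sum(truth == cl)
    if (n == 0) NA_real_ else sum(pred == cl & truth == cl) / n
  }, numeric(1))
  spec <- vapply(lev, function(cl) {
    n <- sum(truth != cl)
    if (n == 0) NA_real_ else sum(pred != cl & truth != cl) / n
  }, numeric(1))
  c(balanced_accuracy = mean(recall, na.rm = TRUE),
    sensitivity = unname(if (length(lev) == 2) recall[1] else mean(recall, na.rm = TRUE)),
    specificity = unname(if (length(lev) == 2) spec[1] else mean(spec, na.rm = TRUE)))
}

#' Linear-SVM classification with stratified cross-validation
#'
#' Linear support-vector machine (margin parameter `cost = 1`) evaluated
#' by stratified 5-fold cross-validation: each fold holds out 20% of the
#' subjects for testing and trains on the remaining 80%. Features are
#' z-score standardized with training-fold statistics only; optional
#' SMOTE class balancing is likewise applied inside training folds only.
#' Multiclass problems use a one-vs-one strategy with majority voting;
#' AUC is the (macro-averaged over class pairs, for 3 classes) rank AUC
#' of the pairwise decision values. Reported metrics are averaged over
#' folds; for two classes the first factor level is treated as the
#' positive class for sensitivity/specificity.
#'
#' @param x Feature matrix (subjects x features) or a
#'   [deviation_features()] `feature_set` (then `y` is taken from it).
#' @param y Class labels (ignored when `x` is a feature set).
#' @param folds Number of CV folds (default 5).
#' @param cost SVM margin parameter C (default 1).
#' @param smote Apply SMOTE inside training folds.
#' @param smote_k SMOTE neighbour count (default 5).
#' @param mode `"cv"` (default) or `"split"` for a single fixed
#'   stratified 80/20 train/test split.
#' @param seed Integer seed (fold assignment, SMOTE draws).
#' @return An object of class `classification_report` with
#'   `balanced_accuracy`, `auc`, `sensitivity`, `specificity`,
#'   `per_fold`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 5), 20, 2))
#' y <- rep(c("a", "b"), each = 20)
#' svm_classify(X, y, seed = 1)
#' @export
svm_classify <- function(x, y = NULL, folds = 5, cost = 1, smote = FALSE,
                         smote_k = 5, mode = c("cv", "split"), seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "feature_set")) { y <- x$y; x <- x$X }
  y <- factor(y)
  x <- as.matrix(x)
  if (min(table(y)) < 4) stop("need at least 4 subjects per class")
  fold_id <- stratified_folds(y, folds, seed = seed)
  fold_set <- if (mode == "cv") seq_len(folds) else 1L
  per <- vector("list", length(fold_set))
  for (f in fold_set) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    res <- svm_fold(x, y, tr, te, cost, smote, smote_k,
                    smote_seed = substream_seed(if (is.null(seed)) 0 else seed, f))
    mets <- fold_metrics(res$pred, res$truth)
    per[[f]] <- c(mets, auc = mean(res$aucs, na.rm = TRUE))
  }
  per_fold <- do.call(rbind, per)
  rownames(per_fold) <- paste0("fold", fold_set)
  out <- as.list(colMeans(per_fold, na.rm = TRUE))
  names(out) <- c("balanced_accuracy", "sensitivity", "specificity", "auc")
  out$per_fold <- as.data.frame(per_fold)
  out$n_classes <- nlevels(y)
  out$folds <- folds
  out$mode <- mode
  structure(out, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Linear SVM (%s, %d classes): balanced accuracy %.3f, AUC %.3f\n",
              if (x$mode == "cv") sprintf("%d-fold CV", x$folds) else "80/20 split",
              x$n_classes, x$balanced_accuracy, x$auc))
  cat(sprintf("sensitivity %.3f, specificity %.3f\n", x$sensitivity, x$specificity))
  if (!is.null(x$permutation_p))
    cat(sprintf("permutation p = %.4g (%d label permutations)\n",
                x$permutation_p, x$n_perm))
  invisible(x)
}

#' Label-permutation null for the SVM pipeline
#'
#' Re-runs the cross-validated SVM with randomly permuted class labels
#' and compares the observed balanced accuracy against the null
#' distribution, with the add-one empirical p-value
#' `(1 + #{null >= observed}) / (1 + n_perm)`. The fold partition is
#' fixed once from the observed labels; feature standardization does not
#' depend on labels, so the per-fold feature representations are
#' precomputed and reused across permutations (the result is identical
#' to a full re-run). SMOTE synthesis does depend on labels and is
#' re-drawn inside every permutation.
#'
#' @inheritParams svm_classify
#' @param n_perm Number of label permutations (default 1000).
#' @return A `classification_report` with `permutation_p` and
#'   `null_accuracies` added.
#' @export
svm_permutation_test <- function(x, y = NULL, n_perm = 1000, folds = 5,
                                 cost = 1, smote = FALSE, smote_k = 5,
                                 seed = NULL) {
  if (inherits(x, "feature_set")) { y <- x$y; x <- x$X }
  y <- factor(y)
  x <- as.matrix(x)
  obs <- svm_classify(x, y, folds = folds, cost = cost, smote = smote,
                      smote_k = smote_k, seed = seed)
  fold_id <- stratified_folds(y, folds, seed = seed)

  reps <- lapply(seq_len(folds), function(f)
    fold_representation(x, which(fold_id != f)))
  run_once <- function(yy, perm_index) {
    accs <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- which(fold_id == f); tr <- which(fold_id != f)
      res <- svm_fold(x, yy, tr, te, cost, smote, smote_k,
                      smote_seed = substream_seed(if (is.null(seed)) 0 else seed,
                                                  perm_index, f),
                      R = reps[[f]])
      accs[f] <- fold_metrics(res$pred, res$truth)["balanced_accuracy"]
    }
    mean(accs)
  }
  null_acc <- with_seed(if (is.null(seed)) NULL else substream_seed(seed, 77),
    vapply(seq_len(n_perm), function(b) run_once(sample(y), b), numeric(1)))
  out <- obs
  out$permutation_p <- (1 + sum(null_acc >= obs$balanced_accuracy)) / (1 + n_perm)
  out$n_perm <- n_perm
  out$null_accuracies <- null_acc
  out
}

#' SMOTE class balancing
#'
#' Oversamples every minority class up to the majority class size by
#' interpolating between a randomly chosen minority sample and one of its
#' `k` nearest minority-class neighbours (Euclidean distance): each
#' synthetic point is `x_i + u * (x_j - x_i)` with `u ~ U(0, 1)`. Already
#' balanced input is returned unchanged. Intended to be applied inside
#' training folds only; [svm_classify()] does this when `smote = TRUE`.
#'
#' @param X Feature matrix.
#' @param y Class labels.
#' @param k Number of nearest neighbours (default 5); each minority class
#'   must have more than `k` members.
#' @param seed Integer seed.
#' @return List with augmented `X` and `y` (synthetic rows appended).
#' @export
smote_balance <- function(X, y, k = 5, seed = NULL) {
  y <- factor(y)
  X <- as.matrix(X)
  counts <- table(y)
  target <- max(counts)
  if (all(counts == target)) return(list(X = X, y = y))
  with_seed(seed, {
    add_X <- list(); add_y <- character(0)
    for (lev in names(counts)[counts < target]) {
      idx <- which(y == lev)
      if (length(idx) <= k)
        stop(sprintf("class '%s' has %d samples, not more than k = %d; use a smaller k",
                     lev, length(idx), k))
      Xm <- X[idx, , drop = FALSE]
      D <- as.matrix(stats::dist(Xm))
      diag(D) <- Inf
      need <- target - length(idx)
      parents <- sample(length(idx), need, replace = TRUE)
      for (s in seq_len(need)) {
        i <- parents[s]
        nb <- order(D[i, ])[seq_len(k)]
        j <- nb[sample.int(k, 1)]
        u <- runif(1)
        add_X[[length(add_X) + 1]] <- Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
        add_y <- c(add_y, lev)
      }
    }
    list(X = rbind(X, do.call(rbind, add_X)),
         y = factor(c(as.character(y), add_y), levels = levels(y)))
  })
}

#' ROC curve coordinates
#'
#' False/true positive rates over all score thresholds, for a binary
#' problem where higher scores favour the positive class.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical or two-level factor; `TRUE`/first level =
#'   positive.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_coordinates <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[1]
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  tpr <- cumsum(labels) / sum(labels)
  fpr <- cumsum(!labels) / sum(!labels)
  data.frame(threshold = c(Inf, scores[ord]), fpr = c(0, fpr), tpr = c(0, tpr))
}
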