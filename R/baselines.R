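#' Train the band-power SVM (PSD_SVM)
#'
#' Radial-basis-kernel SVM on the combined three-band feature matrix
#' (59 channels x 3 bands = 177 features on the standard montage),
#' one-vs-one for multi-class, features standardised by the fit.
#'
#' @param features numeric matrix, windows in rows; in combined-band mode
#'   the width must be 177.
#' @param labels character labels.
#' @param expect_width expected feature width (177 by default; `NULL`
#'   disables the check, e.g. for full-band features).
#' @param cost,gamma SVM hyperparameters; defaults are the conventional
#'   `cost = 1`, `gamma = 1 / (ncol * var)` heuristic (e1071's scaled
#'   default).
#' @return A fitted `e1071::svm` object.
#' @export
train_psd_svm <- function(features, labels, expect_width = 177,
                          cost = 1, gamma = NULL) {
  features <- as.matrix(features)
  if (!is.null(expect_width) && ncol(features) != expect_width) {
    stop("expected ", expect_width, " features (channels x bands), got ",
         ncol(features))
  }
  if (length(unique(labels)) < 2L) stop("single-class input")
  if (any(table(labels) < 2L)) stop("need >= 2 samples per class")
  args <- list(x = features, y = factor(labels), kernel = "radial",
               cost = cost, scale = TRUE)
  if (!is.null(gamma)) args$gamma <- gamma
  do.call(e1071::svm, args)
}

baseline_methods <- function() {
  c("decision_tree", "discriminant_analysis", "naive_bayes", "svm_rbf",
    "knn", "shallow_nn")
}

fit_baseline <- function(method, x, y, seed = 1) {
  y <- factor(y)
  switch(method,
    decision_tree = rpart::rpart(y ~ ., data = data.frame(x, y = y),
                                 method = "class"),
    discriminant_analysis = MASS::lda(x, grouping = y),
    naive_bayes = e1071::naiveBayes(x, y),
    svm_rbf = e1071::svm(x, y, kernel = "radial", scale = TRUE),
    knn = list(kind = "knn", x = x, y = y, k = 5),
    shallow_nn = {
      set.seed(seed)
      # one hidden layer of 64 units, the classic shallow-ANN baseline
      nnet::nnet(x, class.ind(y), size = 64, softmax = TRUE,
                 maxit = 200, MaxNWts = 1e6, trace = FALSE)
    },
    stop("unknown method: ", method))
}

predict_baseline <- function(method, model, x) {
  switch(method,
    decision_tree = as.character(
      predict(model, newdata = data.frame(x), type = "class")),
    discriminant_analysis = as.character(predict(model, x)$class),
    naive_bayes = as.character(predict(model, x)),
    svm_rbf = as.character(predict(model, x)),
    knn = as.character(class::knn(model$x, x, model$y, k = model$k)),
    shallow_nn = colnames(predict(model, x))[
      max.col(predict(model, x), ties.method = "first")],
    stop("unknown method: ", method))
}

class.ind <- function(y) {
  y <- factor(y)
  m <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' Compare six classical classifiers across the seven tasks
#'
#' Stratified k-fold cross-validated accuracy of decision tree, linear
#' discriminant analysis, naive Bayes, RBF SVM, kNN and a shallow neural
#' network, for each classification task (class-subset code fv ... fvac).
#'
#' @param features windows x features matrix.
#' @param labels character labels (all four states for the full table).
#' @param tasks task codes (default [all_tasks()]).
#' @param k folds (default 5).
#' @param seed RNG seed (folds and any stochastic fits).
#' @param methods methods to include (default all six).
#' @return data.frame with columns `method`, `task`, `accuracy` (mean
#'   out-of-fold accuracy in `[0, 1]`); per-fold accuracies in attribute
#'   `"folds"` (data.frame method, task, fold, accuracy).
#' @export
compare_classifiers <- function(features, labels, tasks = all_tasks(),
                                k = 5, seed = 1,
                                methods = baseline_methods()) {
  stopifnot(all(methods %in% baseline_methods()))
  features <- as.matrix(features)
  fold_rows <- list()
  for (task in tasks) {
    cls <- task_classes(task)
    if (!all(cls %in% labels)) stop("task ", task, " needs classes ",
                                    paste(cls, collapse = ", "))
    sel <- labels %in% cls
    x <- features[sel, , drop = FALSE]
    y <- labels[sel]
    folds <- stratified_folds(y, k, seed)
    for (method in methods) {
      for (f in seq_len(k)) {
        tr <- folds != f
        model <- fit_baseline(method, x[tr, , drop = FALSE], y[tr],
                              seed = seed + f)
        pred <- predict_baseline(method, model, x[!tr, , drop = FALSE])
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          method = method, task = task, fold = f,
          accuracy = mean(pred == y[!tr]), stringsAsFactors = FALSE)
      }
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  agg <- stats::aggregate(accuracy ~ method + task, data = folds_df,
                          FUN = mean)
  agg <- agg[order(match(agg$method, methods),
                   match(agg$task, tasks)), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "folds") <- folds_df
  agg
}

#' Full-band vs three-band feature comparison
#'
#' Cross-validated RBF-SVM accuracy for (a) the full 0-50 Hz PSD feature
#' set (every bin x channel, dB-normalised) and (b) the combined
#' theta/alpha/beta band features (177-dim), on identical folds. Both
#' arms use the same kernel machine (C-SVC, `C = 1`,
#' `gamma = 1 / (n_features * mean feature variance)` computed on the
#' training fold); the pairwise squared distances are cached per arm so
#' repeated fold sweeps stay cheap.
#'
#' @param windows list of [window_sample()] objects, or a precomputed
#'   list as returned with `return_features = TRUE` (reusable across
#'   seeds).
#' @param labels labels; defaults to the window labels.
#' @param k folds.
#' @param seed RNG seed (shared folds for the two arms).
#' @param return_features also return the cached feature/distance
#'   structures for reuse.
#' @return List with `full` and `bands` (mean out-of-fold accuracies in
#'   `[0, 1]`) and `difference` (`bands - full`); with
#'   `return_features = TRUE` also `cache`.
#' @export
full_vs_band_features <- function(windows, labels = NULL, k = 5,
                                  seed = 1, return_features = FALSE) {
  if (is.list(windows) && !is.null(windows$d2_full)) {
    cache <- windows
    if (is.null(labels)) labels <- cache$labels
  } else {
    if (is.null(labels)) labels <- window_labels(windows)
    fb <- feature_matrix(windows, mode = "full")$x
    bb <- feature_matrix(windows, mode = "bands")$x
    sqd <- function(x) {
      g <- tcrossprod(x); s <- diag(g)
      pmax(outer(s, s, "+") - 2 * g, 0)
    }
    cache <- list(d2_full = sqd(fb), d2_bands = sqd(bb),
                  var_full = fb, var_bands = bb, labels = labels)
  }
  folds <- stratified_folds(labels, k, seed)
  y <- factor(labels)
  acc_arm <- function(d2, x) {
    d <- ncol(x)
    mean(vapply(seq_len(k), function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      gamma <- 1 / (d * mean(apply(x[tr, , drop = FALSE], 2, stats::var)))
      K <- exp(-gamma * d2)
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr]), y[tr],
                         type = "C-svc", C = 1)
      sv <- kernlab::SVindex(m)
      pred <- kernlab::predict(m, kernlab::as.kernelMatrix(
        K[te, tr, drop = FALSE][, sv, drop = FALSE]))
      mean(as.character(pred) == as.character(y[te]))
    }, numeric(1)))
  }
  full <- acc_arm(cache$d2_full, cache$var_full)
  bands <- acc_arm(cache$d2_bands, cache$var_bands)
  out <- list(full = full, bands = bands, difference = bands - full)
  if (return_features) out$cache <- cache
  out
}
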