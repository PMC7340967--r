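# Performance metrics, ROC/AUC, stratified cross-validation and grid search.

#' Two-class performance metrics
#'
#' Sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient from true and predicted labels. With N+ positives of which
#' N-+ are predicted negative, and N- negatives of which N+- are predicted
#' positive: Sn = 1 - N-+/N+, Sp = 1 - N+-/N-, Acc = 1 - (N-+ + N+-)/(N+ + N-),
#' and MCC is the standard contingency-table correlation. A zero MCC
#' denominator (a degenerate margin) yields MCC = 0 with a warning.
#'
#' @param truth,predicted label vectors over \{"positive","negative"\};
#'   `truth` must contain both classes.
#' @return List with `Sn`, `Sp`, `Acc`, `MCC` and the confusion counts
#'   `n_pos`, `n_neg`, `miscl_pos` (N-+), `miscl_neg` (N+-).
#' @export
#' @examples
#' compute_metrics(rep(c("positive", "negative"), each = 10),
#'                 rep(c("positive", "negative"), times = 10))
compute_metrics <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  n_pos <- sum(truth == "positive")
  n_neg <- sum(truth == "negative")
  if (n_pos == 0L || n_neg == 0L)
    stop("metrics undefined: truth must contain both classes")
  miscl_pos <- sum(truth == "positive" & predicted == "negative")
  miscl_neg <- sum(truth == "negative" & predicted == "positive")
  tp <- n_pos - miscl_pos; fn <- miscl_pos
  tn <- n_neg - miscl_neg; fp <- miscl_neg
  den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (den == 0) {
    warning("MCC denominator is zero; reporting MCC = 0")
    mcc <- 0
  } else {
    mcc <- (tp * tn - fp * fn) / sqrt(den)
  }
  list(Sn = 1 - miscl_pos / n_pos,
       Sp = 1 - miscl_neg / n_neg,
       Acc = 1 - (miscl_pos + miscl_neg) / (n_pos + n_neg),
       MCC = mcc,
       n_pos = n_pos, n_neg = n_neg,
       miscl_pos = miscl_pos, miscl_neg = miscl_neg)
}

#' ROC curve and AUC
#'
#' Threshold sweep over decision scores in descending order (tied scores
#' share one threshold step); AUC by the trapezoidal rule, which equals the
#' normalized Mann-Whitney U statistic. Constant scores give the chance
#' diagonal (AUC 0.5) with a warning.
#'
#' @param scores numeric decision values, higher = more positive.
#' @param truth label vector over \{"positive","negative"\}.
#' @return List with `points` (data.frame `FPR`, `TPR` from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth == "positive")
  n_neg <- sum(truth == "negative")
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: both classes must be present")
  if (length(unique(scores)) == 1L)
    warning("constant decision scores; ROC is the chance diagonal (AUC 0.5)")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  is_pos <- truth[ord] == "positive"
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(is_pos)[keep] / n_pos)
  fpr <- c(0, cumsum(!is_pos)[keep] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds, separately within each class so
#' fold class balance matches the dataset. Deterministic for a fixed seed.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return Integer fold vector in `1..k`.
#' @export
make_folds <- function(labels, k = 10L, seed = NULL) {
  if (k < 2L) stop("need at least 2 folds")
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has ", length(idx),
           " samples, fewer than folds (", k, ")")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# assemble an evaluation report object
new_eval <- function(protocol, metrics, per_fold, roc, auc, folds = NULL,
                     config = NULL, spec_name = NULL, n = NULL) {
  out <- list(protocol = protocol, metrics = metrics, per_fold = per_fold,
              roc = roc, auc = auc, folds = folds, config = config,
              spec_name = spec_name, n = n)
  class(out) <- "m5c_eval"
  out
}

#' Stratified k-fold cross-validation
#'
#' Splits the labeled windows into `k` stratified folds, trains on `k - 1`
#' and evaluates on the held-out fold, repeating until every fold has been
#' tested once; reported Sn/Sp/Acc/MCC are the means over the k test folds,
#' and the pooled held-out decision scores give one ROC/AUC. In the default
#' leakage-safe mode (`psp_fit = "per_fold"`), propensity matrices feeding
#' the PSNP/PSDP/PSTP encoders are refit on each training fold only;
#' `"global"` fits them once on the full dataset before splitting, which
#' leaks label information into the features and typically inflates CV
#' accuracy.
#'
#' `x` may also be a precomputed [fuse()] feature matrix (with labels), in
#' which case the columns are taken as-is and no propensity refitting is
#' possible.
#'
#' @param x an [rna_windows] dataset with positive and negative labels, or
#'   a `feature_matrix`.
#' @param features a [feature_spec], preset name or encoder shorthand
#'   vector (ignored when `x` is already a feature matrix).
#' @param classifier a [classifier_config()] or algorithm name.
#' @param folds number of folds k.
#' @param seed seed controlling fold assignment and stochastic backends.
#' @param psp_fit `"per_fold"` (leakage-safe, default) or `"global"`.
#' @param scale min-max scale features to [0, 1], fit on each training fold.
#' @return An object of class `m5c_eval`: mean `metrics`, a `per_fold`
#'   table, pooled `roc` points and `auc`, and the fold assignment.
#' @export
#' @examples
#' d <- generate_windows(generator_model(delta = 0.2), 60, 60, seed = 1)
#' cv <- cross_validate(d, "Kmer", classifier = "gaussian_nb",
#'                      folds = 3, seed = 1)
#' cv$metrics$Acc
cross_validate <- function(x, features = "BEST",
                           classifier = classifier_config("svm_rbf"),
                           folds = 10L, seed = 1L,
                           psp_fit = c("per_fold", "global"),
                           scale = FALSE) {
  psp_fit <- match.arg(psp_fit)
  config <- as_classifier_config(classifier)
  if (inherits(x, "feature_matrix")) {
    labels <- attr(x, "labels")
    feats <- unclass(x)
    get_fold_matrices <- function(train_idx, test_idx) {
      list(train = feats[train_idx, , drop = FALSE],
           test = feats[test_idx, , drop = FALSE])
    }
    spec_name <- "precomputed"
  } else {
    stopifnot(inherits(x, "rna_windows"))
    labels <- x$label
    spec <- as_feature_spec(features)
    spec_name <- spec$name
    needs_psp <- any(vapply(spec$entries, function(e)
      !is.null(encoder_registry()[[e$id]]$needs), logical(1)))
    fitted_global <- if (needs_psp && psp_fit == "global") fit_psp_set(x)
    # fit-free encoder blocks never depend on the training split: compute once
    static <- !vapply(spec$entries, function(e)
      !is.null(encoder_registry()[[e$id]]$needs), logical(1))
    static_blocks <- lapply(which(static), function(i)
      encode_entry(x, spec$entries[[i]], NULL))
    names(static_blocks) <- as.character(which(static))
    get_fold_matrices <- function(train_idx, test_idx) {
      fitted <- if (!needs_psp) NULL
        else if (psp_fit == "global") fitted_global
        else fit_psp_set(x[train_idx, ])
      assemble <- function(idx) {
        blocks <- lapply(seq_along(spec$entries), function(i) {
          if (static[i]) static_blocks[[as.character(i)]][idx, , drop = FALSE]
          else encode_entry(x[idx, ], spec$entries[[i]], fitted)
        })
        do.call(cbind, blocks)
      }
      list(train = assemble(train_idx), test = assemble(test_idx))
    }
  }
  if (!all(labels %in% c("positive", "negative")))
    stop("cross-validation needs fully labeled positive/negative data")
  fold <- make_folds(labels, k = folds, seed = seed)
  per_fold <- vector("list", folds)
  pooled_scores <- numeric(length(labels))
  pooled_pred <- character(length(labels))
  for (f in seq_len(folds)) {
    train_idx <- which(fold != f)
    test_idx <- which(fold == f)
    m <- get_fold_matrices(train_idx, test_idx)
    scaler <- if (scale) fit_scaler(m$train)
    xtr <- if (scale) apply_scaler(m$train, scaler) else m$train
    xte <- if (scale) apply_scaler(m$test, scaler) else m$test
    backend <- train_backend(config, xtr, labels[train_idx],
                             seed = seed + f)
    pred <- backend_predict(backend, xte)
    pooled_pred[test_idx] <- pred
    pooled_scores[test_idx] <- backend_score(backend, xte)
    mt <- compute_metrics(labels[test_idx], pred)
    per_fold[[f]] <- data.frame(fold = f, Sn = mt$Sn, Sp = mt$Sp,
                                Acc = mt$Acc, MCC = mt$MCC)
  }
  per_fold <- do.call(rbind, per_fold)
  roc <- roc_curve(pooled_scores, labels)
  metrics <- as.list(colMeans(per_fold[, c("Sn", "Sp", "Acc", "MCC")]))
  new_eval(protocol = sprintf("%d-fold cross-validation", folds),
           metrics = metrics, per_fold = per_fold,
           roc = roc$points, auc = roc$auc, folds = fold,
           config = config, spec_name = spec_name, n = length(labels))
}

#' @export
print.m5c_eval <- function(x, ...) {
  cat("Evaluation (", x$protocol, ")", sep = "")
  if (!is.null(x$spec_name)) cat(", features: ", x$spec_name, sep = "")
  if (!is.null(x$config)) cat(", classifier: ", x$config$algorithm, sep = "")
  cat("\n")
  cat(sprintf("  n = %d | Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f  AUC %.4f\n",
              x$n, x$metrics$Sn, x$metrics$Sp, x$metrics$Acc,
              x$metrics$MCC, x$auc))
  invisible(x)
}

#' ROC plot for an evaluation report
#'
#' @param x an `m5c_eval` from [cross_validate()] or [evaluate()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.m5c_eval <- function(x, ...) {
  graphics::plot(x$roc$FPR, x$roc$TPR, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Scalar metrics as JSON, per-fold metrics and ROC points as TSV.
#'
#' @param report an `m5c_eval`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_eval_report <- function(report, dir, prefix = "eval") {
  stopifnot(inherits(report, "m5c_eval"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_metrics.json", "_per_fold.tsv",
                                           "_roc.tsv")))
  jsonlite::write_json(
    c(report$metrics, list(AUC = report$auc, n = report$n,
                           protocol = report$protocol,
                           features = report$spec_name,
                           classifier = report$config$algorithm %||% NA)),
    paths[1L], auto_unbox = TRUE, digits = NA)
  if (!is.null(report$per_fold))
    utils::write.table(report$per_fold, paths[2L], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(report$roc, paths[3L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Hyperparameter grid search by cross-validated accuracy
#'
#' Evaluates classifier parameter settings by stratified k-fold CV accuracy
#' over the same fold assignment (fixed seed) and returns the best
#' configuration. `mode = "full"` evaluates the Cartesian product of the
#' grid; `mode = "axiswise"` optimizes one parameter at a time in the order
#' given, holding the others at their current best -- far fewer fits on
#' larger grids. Ties are broken toward the smaller parameter values, in
#' grid order (for an SVM grid `list(C = ..., gamma = ...)`: smaller C,
#' then smaller gamma).
#'
#' @param x dataset or feature matrix, as in [cross_validate()].
#' @param grid named list of parameter value vectors.
#' @param features,classifier,folds,seed,psp_fit,scale as in
#'   [cross_validate()].
#' @param mode `"full"` or `"axiswise"`.
#' @return List with `best` (a [classifier_config()]), `best_acc`, and the
#'   full `trace` data.frame of evaluated cells.
#' @export
grid_search <- function(x, grid, features = "BEST",
                        classifier = classifier_config("svm_rbf"),
                        folds = 10L, seed = 1L, mode = c("full", "axiswise"),
                        psp_fit = c("per_fold", "global"), scale = FALSE) {
  mode <- match.arg(mode)
  psp_fit <- match.arg(psp_fit)
  base <- as_classifier_config(classifier)
  if (!length(grid) || !all(lengths(grid) >= 1L))
    stop("grid must be a non-empty named list of parameter values")
  eval_cell <- function(params) {
    cfg <- base
    cfg$params[names(params)] <- params
    cv <- cross_validate(x, features = features, classifier = cfg,
                         folds = folds, seed = seed, psp_fit = psp_fit,
                         scale = scale)
    cv$metrics$Acc
  }
  trace <- list()
  record <- function(params, acc)
    trace[[length(trace) + 1L]] <<- data.frame(params, Acc = acc)
  if (mode == "full") {
    cells <- expand.grid(grid, stringsAsFactors = FALSE)
    cells <- cells[do.call(order, cells), , drop = FALSE]  # tie-break order
    accs <- vapply(seq_len(nrow(cells)), function(i) {
      acc <- eval_cell(as.list(cells[i, , drop = FALSE]))
      record(cells[i, , drop = FALSE], acc)
      acc
    }, numeric(1))
    best_params <- as.list(cells[which.max(accs), , drop = FALSE])
    best_acc <- max(accs)
  } else {
    current <- lapply(grid, function(v) sort(v)[1L])
    best_acc <- -Inf
    for (p in names(grid)) {
      vals <- sort(grid[[p]])
      accs <- vapply(vals, function(v) {
        params <- current
        params[[p]] <- v
        acc <- eval_cell(params)
        record(data.frame(params), acc)
        acc
      }, numeric(1))
      current[[p]] <- vals[which.max(accs)]
      best_acc <- max(accs)
    }
    best_params <- current
  }
  best <- base
  best$params[names(best_params)] <- best_params
  list(best = best, best_acc = best_acc,
       trace = do.call(rbind, trace))
}
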