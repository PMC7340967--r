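# Classifier backends and the user-facing model interface.

#' Classifier configuration
#'
#' Algorithm defaults follow common practice for this task: SVM with RBF
#' kernel at C = 1 and gamma = "scale" (1 / (n_features * var(X)), the
#' scikit-learn rule; the tuned setting reported for this model family is
#' C = 1.5 with default gamma); random forest with 100 trees; AdaBoost with
#' 50 depth-1 tree stumps; Gaussian naive Bayes with no parameters.
#'
#' @param algorithm one of `"svm_rbf"`, `"random_forest"`, `"adaboost"`,
#'   `"gaussian_nb"`.
#' @param ... parameter overrides: `C`, `gamma` (svm); `ntree` (rf);
#'   `n_rounds`, `maxdepth` (adaboost).
#' @return An object of class `classifier_config`.
#' @export
#' @examples
#' classifier_config("svm_rbf", C = 1.5)
classifier_config <- function(algorithm = c("svm_rbf", "random_forest",
                                            "adaboost", "gaussian_nb"),
                              ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm_rbf = list(C = 1, gamma = "scale"),
    random_forest = list(ntree = 100L),
    adaboost = list(n_rounds = 50L, maxdepth = 1L),
    gaussian_nb = list())
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for ", algorithm, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  out <- list(algorithm = algorithm, params = defaults)
  class(out) <- "classifier_config"
  out
}

as_classifier_config <- function(x, ...) {
  if (inherits(x, "classifier_config")) return(x)
  classifier_config(x, ...)
}

#' @export
print.classifier_config <- function(x, ...) {
  p <- if (length(x$params))
    paste(names(x$params), vapply(x$params, format, character(1)),
          sep = " = ", collapse = ", ")
  else "(no parameters)"
  cat("Classifier: ", x$algorithm, " [", p, "]\n", sep = "")
  invisible(x)
}

# min-max scaler, fit on training features only
fit_scaler <- function(x) {
  list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}
apply_scaler <- function(x, scaler) {
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  sweep(sweep(x, 2L, scaler$min), 2L, rng, `/`)
}

# ---- backends ---------------------------------------------------------------
# Each backend trains on a numeric matrix with labels in
# {"positive","negative"} and exposes class predictions plus a decision
# score oriented so that larger means more positive.

train_backend <- function(config, x, labels, seed = 1L) {
  y <- factor(labels, levels = c("negative", "positive"))
  set.seed(seed)
  model <- switch(config$algorithm,
    svm_rbf = {
      g <- config$params$gamma
      if (identical(g, "scale")) {
        v <- mean((x - mean(x))^2)
        g <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
      }
      e1071::svm(x = x, y = y, kernel = "radial",
                 cost = config$params$C, gamma = g, scale = FALSE)
    },
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = config$params$ntree),
    adaboost = fit_adaboost(x, y, n_rounds = config$params$n_rounds,
                            maxdepth = config$params$maxdepth),
    gaussian_nb = {
      keep <- apply(x, 2L, function(col) stats::var(col) > 0)
      if (!any(keep)) stop("all features constant; naive Bayes undefined")
      list(nb = e1071::naiveBayes(x = x[, keep, drop = FALSE], y = y),
           keep = keep)
    })
  structure(list(algorithm = config$algorithm, model = model),
            class = "m5c_backend")
}

backend_predict <- function(backend, x) {
  out <- switch(backend$algorithm,
    svm_rbf = as.character(stats::predict(backend$model, x)),
    random_forest = as.character(stats::predict(backend$model, x)),
    adaboost = ifelse(predict_adaboost(backend$model, x) > 0,
                      "positive", "negative"),
    gaussian_nb = as.character(stats::predict(
      backend$model$nb, x[, backend$model$keep, drop = FALSE])))
  out
}

backend_score <- function(backend, x) {
  switch(backend$algorithm,
    svm_rbf = {
      dv <- attr(stats::predict(backend$model, x, decision.values = TRUE),
                 "decision.values")
      # orient the signed margin toward the positive class
      if (grepl("^positive", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
    },
    random_forest = stats::predict(backend$model, x,
                                   type = "prob")[, "positive"],
    adaboost = predict_adaboost(backend$model, x),
    gaussian_nb = stats::predict(backend$model$nb,
                                 x[, backend$model$keep, drop = FALSE],
                                 type = "raw")[, "positive"])
}

# Discrete AdaBoost (SAMME with two classes) over weighted rpart stumps.
fit_adaboost <- function(x, y, n_rounds = 50L, maxdepth = 1L) {
  yy <- ifelse(y == "positive", 1, -1)
  n <- length(yy)
  df <- data.frame(.y = factor(yy, levels = c(-1, 1)), x,
                   check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = -1,
                               minsplit = 2L, minbucket = 1L, xval = 0L)
  wts <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = wts,
                        method = "class", control = ctrl)
    h <- as.numeric(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(wts * (h != yy))
    if (err >= 0.5) break                 # weak learner no better than chance
    used <- used + 1L
    stumps[[used]] <- fit
    if (err <= 0) {                       # perfect stump: finite capped weight
      alphas[used] <- 10
      break
    }
    alphas[used] <- 0.5 * log((1 - err) / err)
    wts <- wts * exp(-alphas[used] * yy * h)
    wts <- wts / sum(wts)
  }
  if (used == 0L) {
    # no usable weak learner: fall back to the majority class margin
    maj <- if (mean(yy) >= 0) 1 else -1
    return(list(stumps = list(), alphas = numeric(0), fallback = maj))
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
       fallback = NULL)
}

predict_adaboost <- function(model, x) {
  if (!length(model$stumps))
    return(rep(model$fallback * 1e-6, nrow(x)))
  df <- data.frame(x, check.names = FALSE)
  score <- numeric(nrow(x))
  for (m in seq_along(model$stumps)) {
    h <- as.numeric(as.character(
      stats::predict(model$stumps[[m]], df, type = "class")))
    score <- score + model$alphas[m] * h
  }
  score
}

# ---- model interface --------------------------------------------------------

#' Fit an m5C site prediction model
#'
#' The headline fitting function: encodes labeled training windows with a
#' feature combination (default the 287-feature "BEST" preset: PSP + Kmer +
#' PseEIIP + PC-PseDNC), fits any required position-specific propensity
#' matrices on the training data, and trains a classifier backend. The
#' returned object carries everything needed to encode and score new
#' windows.
#'
#' @param data an [rna_windows] training set with positive and negative
#'   labels.
#' @param features a [feature_spec], preset name (see [preset_names()]) or
#'   character vector of encoder shorthands.
#' @param classifier a [classifier_config()] or algorithm name.
#' @param ... parameter overrides when `classifier` is a name (e.g.
#'   `C = 1.5`).
#' @param scale min-max scale features to [0, 1] (recorded in the model).
#' @param seed seed for stochastic backends.
#' @return An object of class `m5c_fit`.
#' @export
#' @examples
#' train <- generate_windows(generator_model(delta = 0.15), 100, 100, seed = 1)
#' fit <- m5c_fit(train, features = "Kmer", classifier = "gaussian_nb")
#' fit
m5c_fit <- function(data, features = "BEST", classifier = "svm_rbf", ...,
                    scale = FALSE, seed = 1L) {
  stopifnot(inherits(data, "rna_windows"))
  config <- as_classifier_config(classifier, ...)
  spec <- as_feature_spec(features)
  needs_psp <- any(vapply(spec$entries, function(e)
    !is.null(encoder_registry()[[e$id]]$needs), logical(1)))
  fitted <- if (needs_psp) fit_psp_set(data)
  fm <- fuse(data, spec, fitted = fitted)
  scaler <- if (scale) fit_scaler(fm)
  xtr <- if (scale) apply_scaler(unclass(fm), scaler) else unclass(fm)
  backend <- train_backend(config, xtr, data$label, seed = seed)
  out <- list(spec = spec, fitted = fitted, scaler = scaler,
              backend = backend, config = config,
              width = attr(data, "width"),
              feature_names = colnames(fm),
              class_counts = class_counts(data),
              seed = seed, call = match.call())
  class(out) <- "m5c_fit"
  out
}

encode_newdata <- function(object, newdata) {
  if (is.character(newdata) && length(newdata) == 1L && file.exists(newdata))
    newdata <- read_windows(newdata, width = object$width,
                            strict_center = FALSE)
  if (is.character(newdata))
    newdata <- rna_windows(newdata, width = object$width,
                           strict_center = FALSE)
  stopifnot(inherits(newdata, "rna_windows"))
  if (attr(newdata, "width") != object$width)
    stop("window length ", attr(newdata, "width"),
         " does not match the model's ", object$width)
  fm <- fuse(newdata, object$spec, fitted = object$fitted)
  x <- unclass(fm)
  if (!is.null(object$scaler)) x <- apply_scaler(x, object$scaler)
  list(x = x, windows = newdata)
}

#' Predict m5C sites with a fitted model
#'
#' @param object an [m5c_fit()] model.
#' @param newdata an [rna_windows] dataset, a character vector of window
#'   sequences, or a FASTA file path.
#' @param type `"class"` for positive/negative labels, `"score"` for the
#'   decision value (higher = more likely methylated).
#' @param ... unused.
#' @return Character label vector or numeric score vector, named by window
#'   id.
#' @export
predict.m5c_fit <- function(object, newdata, type = c("class", "score"),
                            ...) {
  type <- match.arg(type)
  enc <- encode_newdata(object, newdata)
  out <- if (type == "class") backend_predict(object$backend, enc$x)
         else backend_score(object$backend, enc$x)
  stats::setNames(out, enc$windows$id)
}

#' Independent-test evaluation of a fitted model
#'
#' Scores a disjoint labeled test set with a model trained on the full
#' training split and reports Sn/Sp/Acc/MCC and ROC/AUC.
#'
#' @param object an [m5c_fit()] model.
#' @param test a labeled [rna_windows] dataset.
#' @return An `m5c_eval` report.
#' @export
evaluate <- function(object, test) {
  stopifnot(inherits(object, "m5c_fit"))
  enc <- encode_newdata(object, test)
  pred <- backend_predict(object$backend, enc$x)
  scores <- backend_score(object$backend, enc$x)
  mt <- compute_metrics(enc$windows$label, pred)
  roc <- roc_curve(scores, enc$windows$label)
  new_eval(protocol = "independent test",
           metrics = mt[c("Sn", "Sp", "Acc", "MCC")],
           per_fold = NULL, roc = roc$points, auc = roc$auc,
           config = object$config, spec_name = object$spec$name,
           n = nrow(enc$windows))
}

#' @export
print.m5c_fit <- function(x, ...) {
  cat("m5C site prediction model\n")
  cat("  features  : ", x$spec$name, " (", length(x$feature_names),
      " columns)\n", sep = "")
  cat("  classifier: ", x$config$algorithm, "\n", sep = "")
  cat(sprintf("  trained on: %d positive / %d negative windows of length %d\n",
              x$class_counts["positive"], x$class_counts["negative"],
              x$width))
  invisible(x)
}

#' @export
summary.m5c_fit <- function(object, ...) {
  print(object)
  cat("\nEncoders:\n")
  for (e in object$spec$entries) {
    p <- if (length(e$params))
      paste0(" (", paste(names(e$params),
                         vapply(e$params, format, character(1)),
                         sep = "=", collapse = ", "), ")")
    else ""
    cat("  - ", e$id, p, "\n", sep = "")
  }
  print(object$config)
  if (!is.null(object$fitted))
    cat("Propensity matrices fitted on the training data (k = 1, 2, 3)\n")
  if (!is.null(object$scaler))
    cat("Min-max feature scaling recorded in the model\n")
  invisible(object)
}
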