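test_that("metrics reproduce hand-computed values and degenerate cases", {
  truth <- rep(c("positive", "negative"), each = 10)
  # 2 positives predicted negative, 3 negatives predicted positive
  pred <- truth
  pred[1:2] <- "negative"
  pred[11:13] <- "positive"
  m <- compute_metrics(truth, pred)
  expect_equal(m$Sn, 0.8)
  expect_equal(m$Sp, 0.7)
  expect_equal(m$Acc, 0.75)
  expect_equal(m$MCC, chou_mcc(10, 10, 2, 3), tolerance = 1e-12)
  expect_equal(m$MCC, oracle_metrics(truth, pred)$MCC, tolerance = 1e-12)
  # perfect and degenerate predictors
  expect_equal(compute_metrics(truth, truth)[c("Sn", "Sp", "Acc", "MCC")],
               list(Sn = 1, Sp = 1, Acc = 1, MCC = 1))
  expect_warning(allpos <- compute_metrics(truth, rep("positive", 20)),
                 "MCC denominator")
  expect_equal(allpos$Sn, 1)
  expect_equal(allpos$Sp, 0)
  expect_equal(allpos$MCC, 0)
  expect_error(compute_metrics(rep("positive", 5), rep("positive", 5)),
               "both classes")
})

test_that("metrics agree with the contingency oracle on random cases", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pred <- sample(c("positive", "negative"), n, replace = TRUE)
    got <- suppressWarnings(compute_metrics(truth, pred))
    want <- oracle_metrics(truth, pred)
    expect_equal(got$Sn, want$Sn)
    expect_equal(got$Sp, want$Sp)
    expect_equal(got$Acc, want$Acc)
    expect_equal(got$MCC, want$MCC, tolerance = 1e-12)
    expect_true(got$MCC >= -1 && got$MCC <= 1)
    # the algebraic rewriting in terms of misclassification counts agrees
    den <- (1 + (got$miscl_neg - got$miscl_pos) / got$n_pos) *
      (1 + (got$miscl_pos - got$miscl_neg) / got$n_neg)
    if (den > 0 && abs(want$MCC) > 0)
      expect_equal(got$MCC,
                   chou_mcc(got$n_pos, got$n_neg, got$miscl_pos,
                            got$miscl_neg), tolerance = 1e-12)
  }
})

test_that("ROC/AUC equals the Mann-Whitney statistic, including ties", {
  # perfectly ranked and reversed rankings
  truth <- rep(c("positive", "negative"), each = 5)
  expect_equal(roc_curve(c(6:10, 1:5), truth)$auc, 1)
  expect_equal(roc_curve(c(1:5, 6:10), truth)$auc, 0)
  # hand-enumerated 6-score case with one tie: pairs (3x3): pos {5,3,2},
  # neg {4,3,1} -> wins 5>4,5>3,5>1,3>1,2>1 = 5, tie 3==3 = 0.5 -> 5.5/9
  s <- c(5, 3, 2, 4, 3, 1)
  t6 <- rep(c("positive", "negative"), each = 3)
  r <- roc_curve(s, t6)
  expect_equal(r$auc, 5.5 / 9, tolerance = 1e-12)
  expect_equal(r$auc, oracle_auc(s, t6), tolerance = 1e-12)
  # curve geometry
  expect_equal(r$points$FPR[1], 0)
  expect_equal(r$points$TPR[1], 0)
  expect_equal(unname(tail(as.matrix(r$points), 1)), cbind(1, 1))
  expect_true(all(diff(r$points$FPR) >= 0))
  # constant scores give the chance diagonal with a warning
  expect_warning(rc <- roc_curve(rep(2, 10), truth), "constant")
  expect_equal(rc$auc, 0.5)
})

test_that("AUC matches the U-statistic and pROC on random score sets", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    truth <- c("positive", "negative",
               sample(c("positive", "negative"), n - 2, replace = TRUE))
    scores <- sample(seq(-2, 2, by = 0.25), n, replace = TRUE)  # forces ties
    got <- suppressWarnings(roc_curve(scores, truth)$auc)
    expect_equal(got, oracle_auc(scores, truth), tolerance = 1e-12)
    pr <- suppressMessages(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("negative", "positive"),
      direction = "<")))
    expect_equal(got, as.numeric(pr), tolerance = 1e-12)
  }
})

test_that("fold assignment is stratified, complete and seed-stable", {
  labels <- rep(c("positive", "negative"), c(55, 45))
  f1 <- make_folds(labels, k = 10, seed = 3)
  f2 <- make_folds(labels, k = 10, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(labels, k = 10, seed = 4)))
  expect_true(all(table(f1) >= 9 & table(f1) <= 11))
  for (k in 1:10) {
    npos <- sum(labels[f1 == k] == "positive")
    expect_true(npos %in% 5:6)  # stratified within one unit
  }
  expect_error(make_folds(rep(c("positive", "negative"), c(3, 50)), k = 5),
               "fewer")
})

test_that("cross-validation equals an explicit leave-one-out style oracle", {
  # folds = per-class size, so each fold holds out one positive and one
  # negative; re-run the same protocol by hand with direct e1071 calls
  d <- rand_labeled(10, 10, seed = 66)
  # plant a weak signal so predictions are non-trivial
  cfg <- classifier_config("svm_rbf", C = 1)
  fm <- fuse(d, "Kmer")
  # two-sample test folds can yield a degenerate MCC margin; that warning
  # is expected here
  cv <- suppressWarnings(
    cross_validate(fm, classifier = cfg, folds = 10, seed = 5))
  labels <- d$label
  fold <- make_folds(labels, k = 10, seed = 5)
  expect_identical(cv$folds, fold)
  x <- unclass(fm)
  per_fold_acc <- vapply(1:10, function(f) {
    tr <- fold != f
    y <- factor(labels[tr], levels = c("negative", "positive"))
    v <- mean((x[tr, ] - mean(x[tr, ]))^2)
    fit <- e1071::svm(x = x[tr, ], y = y, kernel = "radial", cost = 1,
                      gamma = 1 / (ncol(x) * v), scale = FALSE)
    pred <- as.character(predict(fit, x[!tr, , drop = FALSE]))
    mean(pred == labels[!tr])
  }, numeric(1))
  expect_equal(cv$per_fold$Acc, per_fold_acc, tolerance = 1e-12)
  expect_equal(cv$metrics$Acc, mean(per_fold_acc), tolerance = 1e-12)
})

test_that("separable data is learned and permuted labels are not", {
  strong <- generate_windows(generator_model(delta = 0.4), 40, 40, seed = 2)
  cv <- cross_validate(strong, "Kmer", classifier = "gaussian_nb",
                       folds = 5, seed = 1)
  expect_gt(cv$metrics$Acc, 0.9)
  # permutation null: accuracy compatible with chance over repeats
  base <- generate_windows(generator_model(delta = 0.3), 30, 30, seed = 3)
  accs <- vapply(1:8, function(r) {
    perm <- base
    set.seed(100 + r)
    perm$label <- sample(perm$label)
    suppressWarnings(
      cross_validate(perm, "Kmer", classifier = "gaussian_nb",
                     folds = 5, seed = r)$metrics$Acc)
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), max(3 * se, 0.12))
})

test_that("evaluation reports serialize to JSON and TSV", {
  d <- generate_windows(generator_model(delta = 0.3), 30, 30, seed = 8)
  cv <- cross_validate(d, "Kmer", classifier = "gaussian_nb",
                       folds = 5, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_eval_report(cv, dir, prefix = "cv")
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$Acc, cv$metrics$Acc, tolerance = 1e-9)
  roc <- read.delim(paths[3])
  expect_equal(nrow(roc), nrow(cv$roc))
})

test_that("grid search returns the brute-force argmax with ordered tie-breaks", {
  d <- generate_windows(generator_model(delta = 0.25), 25, 25, seed = 4)
  fm <- fuse(d, "Kmer")
  grid <- list(C = c(0.5, 2), gamma = c(0.01, 0.1))
  gs <- grid_search(fm, grid, classifier = "svm_rbf", folds = 5, seed = 9)
  expect_equal(nrow(gs$trace), 4L)
  # brute-force re-evaluation of all four cells
  accs <- apply(expand.grid(C = grid$C, gamma = grid$gamma), 1, function(p) {
    cross_validate(fm, classifier = classifier_config(
      "svm_rbf", C = p["C"], gamma = p["gamma"]),
      folds = 5, seed = 9)$metrics$Acc
  })
  expect_equal(gs$best_acc, max(accs), tolerance = 1e-12)
  got <- cross_validate(fm, classifier = gs$best, folds = 5,
                        seed = 9)$metrics$Acc
  expect_equal(got, max(accs), tolerance = 1e-12)
  # single-point grid returns that point
  gs1 <- grid_search(fm, list(C = 1.5), classifier = "svm_rbf",
                     folds = 5, seed = 9)
  expect_equal(gs1$best$params$C, 1.5)
  # axis-wise mode evaluates |C| + |gamma| cells, not the product
  gsa <- grid_search(fm, grid, classifier = "svm_rbf", folds = 5, seed = 9,
                     mode = "axiswise")
  expect_equal(nrow(gsa$trace), 4L)  # 2 + 2
  expect_error(grid_search(fm, list()), "non-empty")
})
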