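# Training, validation and ensemble voting of the three operon-pair
# classifiers (random forest, single-hidden-layer neural network, RBF SVM).

FEATURES <- c("igr_length", "cu_score", "diff_expr", "igr_expr")

#' Training configuration
#'
#' @param test_fraction Fraction of pairs held out as the test set (default
#'   0.30).
#' @param cv_folds Folds of the cross-validation (default 5).
#' @param cv_repeats Number of repeated cross-validation runs (default 10,
#'   i.e. a 10 x 5 protocol).
#' @param seed Master seed; every split, fold and refit derives its own seed
#'   from it.
#' @param models Model families to train, subset of `"RF"`, `"NN"`, `"SVM"`.
#' @param feature_subset Features used, subset of `igr_length`, `cu_score`,
#'   `diff_expr`, `igr_expr`.
#' @param nn_size_grid Hidden-unit grid for the neural network.
#' @param svm_cost_grid,svm_gamma_grid RBF SVM grids.
#' @param rf_trees Trees in the random forest.
#' @return A list of class `train_config`.
#' @export
train_config <- function(test_fraction = 0.30, cv_folds = 5L,
                         cv_repeats = 10L, seed = 1L,
                         models = c("RF", "NN", "SVM"),
                         feature_subset = FEATURES,
                         nn_size_grid = c(2L, 4L, 6L, 8L),
                         svm_cost_grid = c(0.1, 1, 10, 100),
                         svm_gamma_grid = c(0.01, 0.1, 1),
                         rf_trees = 500L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  if (cv_folds < 2L) stopf("cv_folds must be >= 2")
  stopifnot(all(models %in% c("RF", "NN", "SVM")),
            all(feature_subset %in% FEATURES), length(feature_subset) >= 1L)
  structure(list(test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats), seed = as.integer(seed),
                 models = models, feature_subset = feature_subset,
                 nn_size_grid = nn_size_grid, svm_cost_grid = svm_cost_grid,
                 svm_gamma_grid = svm_gamma_grid,
                 rf_trees = as.integer(rf_trees)),
            class = "train_config")
}

label_factor <- function(label) factor(label, levels = c("NOP", "OP"))

#' Stratified holdout split
#'
#' Randomly holds out `cfg$test_fraction` of the rows as a test set,
#' stratified by label, seeded from `cfg$seed`. Train and test are disjoint
#' and exhaustive.
#'
#' @param table Feature table with a `label` column of OP/NOP values.
#' @param cfg [train_config()].
#' @return List with elements `train` and `test`.
#' @export
split_holdout <- function(table, cfg = train_config()) {
  y <- label_factor(table$label)
  if (any(tabulate(y, 2L) < 2L)) stopf("each class needs at least 2 members")
  set.seed(derive_seed(cfg$seed, 101))
  test_idx <- unlist(lapply(levels(y), function(lv) {
    ii <- which(y == lv)
    sample(ii, round(length(ii) * cfg$test_fraction))
  }))
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

standardize_fit <- function(x) {
  list(center = colMeans(x),
       scale = pmax(apply(x, 2, stats::sd), 1e-12))
}
standardize_apply <- function(x, st) {
  scale(as.matrix(x), center = st$center, scale = st$scale)
}

fit_one <- function(kind, x, y, pars, seed) {
  set.seed(seed)
  switch(kind,
    RF = randomForest::randomForest(x, y, ntree = pars$ntree),
    NN = nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2, drop = FALSE],
                    size = pars$size, decay = 0.01, maxit = 300,
                    entropy = TRUE, trace = FALSE),
    SVM = e1071::svm(x, y, kernel = "radial", cost = pars$cost,
                     gamma = pars$gamma, probability = TRUE, scale = FALSE))
}

prob_one <- function(kind, fit, x) {
  switch(kind,
    RF = unname(stats::predict(fit, x, type = "prob")[, "OP"]),
    NN = as.numeric(stats::predict(fit, x)),
    SVM = {
      pr <- stats::predict(fit, x, probability = TRUE)
      unname(attr(pr, "probabilities")[, "OP"])
    })
}

#' Train one operon-pair classifier
#'
#' Fits the requested model family on an OP/NOP feature table. NN and SVM
#' features are standardized with statistics fitted on the training data
#' only, and hyperparameters (hidden units for NN; cost and kernel width for
#' SVM) are chosen by grid search on an internal stratified 70/30 holdout of
#' the training data, then the winner is refit on the full training set. The
#' random forest uses raw features and no grid; its error is estimated
#' internally on out-of-bag data.
#'
#' @param train_table Feature table with OP/NOP labels.
#' @param model_kind `"RF"`, `"NN"` or `"SVM"`.
#' @param cfg [train_config()].
#' @return An object of class `operon_classifier` mapping features to an OP
#'   probability via [predict.operon_classifier()].
#' @export
train_model <- function(train_table, model_kind = c("RF", "NN", "SVM"),
                        cfg = train_config()) {
  model_kind <- match.arg(model_kind)
  feats <- cfg$feature_subset
  y <- label_factor(train_table$label)
  if (nlevels(droplevels(y)) < 2L) stopf("training data has a single class")
  x <- as.matrix(train_table[, feats, drop = FALSE])
  st <- NULL
  if (model_kind == "RF") {
    fit <- fit_one("RF", x, y, list(ntree = cfg$rf_trees),
                   derive_seed(cfg$seed, 11))
    chosen <- list(ntree = cfg$rf_trees)
  } else {
    st <- standardize_fit(x)
    xs <- standardize_apply(x, st)
    grid <- if (model_kind == "NN") {
      data.frame(size = cfg$nn_size_grid)
    } else {
      expand.grid(cost = cfg$svm_cost_grid, gamma = cfg$svm_gamma_grid)
    }
    if (nrow(grid) > 1L) {
      set.seed(derive_seed(cfg$seed, 12))
      val_idx <- unlist(lapply(levels(y), function(lv) {
        ii <- which(y == lv)
        sample(ii, max(1L, round(length(ii) * 0.3)))
      }))
      acc <- vapply(seq_len(nrow(grid)), function(g) {
        f <- fit_one(model_kind, xs[-val_idx, , drop = FALSE], y[-val_idx],
                     as.list(grid[g, , drop = FALSE]),
                     derive_seed(cfg$seed, 13, g))
        pr <- prob_one(model_kind, f, xs[val_idx, , drop = FALSE])
        mean((pr > 0.5) == (y[val_idx] == "OP"))
      }, numeric(1))
      chosen <- as.list(grid[which.max(acc), , drop = FALSE])
    } else chosen <- as.list(grid[1, , drop = FALSE])
    fit <- fit_one(model_kind, xs, y, chosen, derive_seed(cfg$seed, 14))
  }
  structure(list(kind = model_kind, fit = fit, standardize = st,
                 features = feats, hyperparameters = chosen,
                 seed = cfg$seed),
            class = "operon_classifier")
}

#' Predict OP probability or class for gene pairs
#'
#' @param object An `operon_classifier` from [train_model()].
#' @param newdata Feature table (only the model's feature columns are used).
#' @param type `"prob"` for the OP probability, `"class"` for the OP/NOP call
#'   at threshold 0.5.
#' @param ... Unused.
#' @return Numeric vector of probabilities or character vector of classes.
#' @export
predict.operon_classifier <- function(object, newdata,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  if (!is.null(object$standardize)) x <- standardize_apply(x, object$standardize)
  p <- prob_one(object$kind, object$fit, x)
  if (type == "prob") p else ifelse(p > 0.5, "OP", "NOP")
}

#' Confusion counts of OP/NOP calls
#' @param truth,pred Character vectors of OP/NOP labels (OP is the positive
#'   class).
#' @return Named list `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(truth, pred) {
  list(tp = sum(truth == "OP" & pred == "OP"),
       fn = sum(truth == "OP" & pred == "NOP"),
       fp = sum(truth == "NOP" & pred == "OP"),
       tn = sum(truth == "NOP" & pred == "NOP"))
}

#' Evaluation metrics from confusion counts
#'
#' Computes TPR = TP/(TP+FN), PPV = TP/(TP+FP), the historically printed
#' `fpr_paper` = FP/(FP+FN) alongside the standard `fpr_standard` =
#' FP/(FP+TN) (both are reported; they answer different questions and the
#' non-standard form appears in the operon literature), error rate
#' (FP+FN)/total and accuracy (TP+TN)/total. Ratios with a zero denominator
#' are returned as `NaN`, never as 0.
#'
#' @param counts Named list/vector with `tp`, `fn`, `fp`, `tn`.
#' @return Named list of the six metrics.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  total <- tp + fn + fp + tn
  if (total == 0) stopf("empty confusion counts")
  rat <- function(num, den) if (den == 0) NaN else num / den
  list(tpr = rat(tp, tp + fn),
       ppv = rat(tp, tp + fp),
       fpr_paper = rat(fp, fp + fn),
       fpr_standard = rat(fp, fp + tn),
       error_rate = (fp + fn) / total,
       accuracy = (tp + tn) / total)
}

#' ROC points from continuous OP scores
#' @param scores Numeric OP scores.
#' @param labels OP/NOP truth labels.
#' @return data.frame of `(fpr, tpr)` points from (0,0) to (1,1), fpr being
#'   the standard FP/(FP+TN).
#' @export
roc_points <- function(scores, labels) {
  pos <- labels == "OP"
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  cut <- which(!duplicated(s, fromLast = TRUE))    # last index of each score
  tpr <- c(0, cumsum(p)[cut] / n1, 1)
  fpr <- c(0, cumsum(!p)[cut] / n0, 1)
  data.frame(fpr = fpr, tpr = tpr)
}

#' Area under the ROC curve
#'
#' `method = "rank"` uses the Mann-Whitney statistic with midranks;
#' `method = "trapezoid"` integrates [roc_points()]. The two agree to
#' numerical precision.
#'
#' @param scores Numeric OP scores.
#' @param labels OP/NOP truth labels.
#' @param method `"rank"` (default) or `"trapezoid"`.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels, method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  pos <- labels == "OP"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes")
  if (method == "rank") {
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    rp <- roc_points(scores, labels)
    sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + utils::tail(rp$tpr, -1)) / 2)
  }
}

# stratified fold assignment; guarantees both classes in every training part
fold_assignment <- function(y, k, seed) {
  for (attempt in 0:9) {
    set.seed(derive_seed(seed, 31, attempt))
    fold <- integer(length(y))
    for (lv in levels(y)) {
      ii <- which(y == lv)
      fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      nlevels(droplevels(y[fold != f])) == 2L, logical(1)))
    if (ok) return(fold)
  }
  stopf("could not build folds with both classes in every training part")
}

#' Repeated k-fold cross-validation of the three classifiers
#'
#' NN and SVM are evaluated by `cv_repeats` repetitions of seeded stratified
#' `cv_folds`-fold cross-validation (default 10 x 5); per repeat, the fold
#' confusion counts are summed and turned into metrics, and the held-out
#' scores of all folds are pooled into one ROC per model. The random forest
#' estimates its error internally on out-of-bag data, so instead of folding
#' it is refit `cv_repeats` times and the out-of-bag predictions of each
#' refit provide the metrics and pooled scores.
#'
#' @param table Feature table with OP/NOP labels.
#' @param cfg [train_config()].
#' @return An `evaluation_report`: per model a list with `runs` (per-repeat
#'   metric data.frame), `mean_accuracy`, `sd_accuracy`, `auc`, `roc`
#'   (pooled ROC points) and `pooled` (scores + labels).
#' @export
cross_validate <- function(table, cfg = train_config()) {
  y <- label_factor(table$label)
  report <- list()
  for (m in cfg$models) {
    runs <- vector("list", cfg$cv_repeats)
    sc_all <- numeric(0); lab_all <- character(0)
    for (rep_i in seq_len(cfg$cv_repeats)) {
      if (m == "RF") {
        cfg_r <- cfg; cfg_r$seed <- derive_seed(cfg$seed, 41, rep_i)
        fit <- train_model(table, "RF", cfg_r)
        oob_prob <- unname(stats::predict(fit$fit, type = "prob")[, "OP"])
        pred <- ifelse(oob_prob > 0.5, "OP", "NOP")
        cc <- confusion_counts(as.character(y), pred)
        sc <- oob_prob; lb <- as.character(y)
      } else {
        fold <- fold_assignment(y, cfg$cv_folds, derive_seed(cfg$seed, 42, rep_i))
        cc <- list(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
        sc <- numeric(nrow(table)); lb <- as.character(y)
        for (f in seq_len(cfg$cv_folds)) {
          tr <- table[fold != f, , drop = FALSE]
          te <- table[fold == f, , drop = FALSE]
          cfg_f <- cfg; cfg_f$seed <- derive_seed(cfg$seed, 43, rep_i, f)
          fit <- train_model(tr, m, cfg_f)
          pr <- predict(fit, te, type = "prob")
          sc[fold == f] <- pr
          cf <- confusion_counts(te$label, ifelse(pr > 0.5, "OP", "NOP"))
          cc <- Map(`+`, cc, cf)
        }
      }
      runs[[rep_i]] <- c(list(run = rep_i), compute_metrics(cc),
                         cc[c("tp", "fn", "fp", "tn")])
      sc_all <- c(sc_all, sc); lab_all <- c(lab_all, lb)
    }
    runs_df <- do.call(rbind, lapply(runs, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    report[[m]] <- list(
      runs = runs_df,
      mean_accuracy = mean(runs_df$accuracy),
      sd_accuracy = stats::sd(runs_df$accuracy),
      auc = compute_auc(sc_all, lab_all, method = "rank"),
      roc = roc_points(sc_all, lab_all),
      pooled = list(scores = sc_all, labels = lab_all))
  }
  structure(report, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  for (m in names(x))
    cat(sprintf("%-4s mean accuracy %.3f (sd %.3f), AUC %.3f over %d runs\n",
                m, x[[m]]$mean_accuracy, x[[m]]$sd_accuracy, x[[m]]$auc,
                nrow(x[[m]]$runs)))
  invisible(x)
}

#' One-dimensional sensitivity analysis of feature importance
#'
#' Varies one feature at a time over a grid of `levels` values spanning its
#' observed range while holding the other features at their training means,
#' and records the model's OP probability at each grid point. The importance
#' of a feature is the variance of these responses; normalized importances
#' sum to one.
#'
#' @param model An `operon_classifier`, or a function mapping a feature
#'   data.frame to a numeric score.
#' @param table Feature table defining the observed ranges and means.
#' @param levels Grid points per feature (default 7).
#' @param features Features to scan (default: the model's features, or the
#'   four standard features for a function model).
#' @return data.frame `feature`, `importance` (response variance),
#'   `normalized`.
#' @export
sensitivity_importance <- function(model, table, levels = 7L,
                                   features = NULL) {
  if (is.null(features)) {
    features <- if (inherits(model, "operon_classifier")) model$features
                else FEATURES
  }
  score_fun <- if (inherits(model, "operon_classifier")) {
    function(nd) predict(model, nd, type = "prob")
  } else model
  mu <- colMeans(table[, features, drop = FALSE])
  imp <- vapply(features, function(f) {
    lo <- min(table[[f]]); hi <- max(table[[f]])
    grid <- seq(lo, hi, length.out = levels)
    nd <- as.data.frame(as.list(mu))[rep(1L, levels), , drop = FALSE]
    nd[[f]] <- grid
    stats::var(score_fun(nd))
  }, numeric(1))
  total <- sum(imp)
  data.frame(feature = features, importance = unname(imp),
             normalized = if (total > 0) unname(imp) / total
                          else rep(0, length(imp)),
             stringsAsFactors = FALSE)
}

#' Simple majority vote of the three classifiers
#'
#' A gene pair is tagged OP when at least two of the three class calls are
#' OP; with three voters no tie is possible.
#'
#' @param rf_class,nn_class,svm_class Character vectors of OP/NOP calls, one
#'   per pair.
#' @return data.frame `rf_class`, `nn_class`, `svm_class`, `final_class`.
#' @export
vote <- function(rf_class, nn_class, svm_class) {
  n <- length(rf_class)
  if (length(nn_class) != n || length(svm_class) != n)
    stopf("vote needs equal-length calls from all three models")
  calls <- cbind(rf_class, nn_class, svm_class)
  if (anyNA(calls) || !all(calls %in% c("OP", "NOP")))
    stopf("missing or invalid model output in vote")
  n_op <- rowSums(calls == "OP")
  data.frame(rf_class = rf_class, nn_class = nn_class, svm_class = svm_class,
             final_class = ifelse(n_op >= 2, "OP", "NOP"),
             stringsAsFactors = FALSE)
}

#' Train the three models and vote on unlabeled pairs
#'
#' Convenience wrapper used by the pipeline: trains RF, NN and SVM on the
#' OP/NOP rows of a feature table and applies the majority vote to a table
#' of pairs to classify (typically the POP/EGP rows).
#'
#' @param train_table Feature table with OP/NOP labels.
#' @param predict_table Feature table of pairs to classify.
#' @param cfg [train_config()].
#' @return List with `models` (named list of classifiers) and `votes`
#'   (the [vote()] data.frame with `pair_id` and per-model OP probabilities).
#' @export
vote_predictions <- function(train_table, predict_table,
                             cfg = train_config()) {
  models <- lapply(stats::setNames(c("RF", "NN", "SVM"),
                                   c("RF", "NN", "SVM")),
                   function(m) train_model(train_table, m, cfg))
  if (nrow(predict_table) == 0L) {
    v <- data.frame(pair_id = character(), rf_class = character(),
                    nn_class = character(), svm_class = character(),
                    final_class = character(), rf_prob = numeric(),
                    nn_prob = numeric(), svm_prob = numeric(),
                    stringsAsFactors = FALSE)
    return(list(models = models, votes = v))
  }
  probs <- lapply(models, function(m) predict(m, predict_table, type = "prob"))
  cls <- lapply(probs, function(p) ifelse(p > 0.5, "OP", "NOP"))
  v <- vote(cls$RF, cls$NN, cls$SVM)
  v <- cbind(pair_id = predict_table$pair_id, v,
             rf_prob = probs$RF, nn_prob = probs$NN, svm_prob = probs$SVM,
             stringsAsFactors = FALSE)
  list(models = models, votes = v)
}

#' Cross-validate pre-registered feature subsets
#'
#' Runs [cross_validate()] once per feature subset with the same master seed,
#' so folds are identical across subsets and accuracies are paired. The
#' default subsets are: all four features; genomic only (`igr_length`,
#' `cu_score`); transcriptomic only (`diff_expr`, `igr_expr`); genomic plus
#' `igr_expr`; genomic plus `diff_expr`. A subset requested twice is computed
#' once and reported twice.
#'
#' @param table Feature table with OP/NOP labels.
#' @param cfg [train_config()].
#' @param subsets Named list of feature-name vectors.
#' @return data.frame `subset`, `model`, `mean_accuracy`, `sd_accuracy`.
#' @export
evaluate_feature_subsets <- function(table, cfg = train_config(),
                                     subsets = NULL) {
  if (is.null(subsets)) {
    subsets <- list(
      all = FEATURES,
      genomic = c("igr_length", "cu_score"),
      transcriptomic = c("diff_expr", "igr_expr"),
      genomic_igr_expr = c("igr_length", "cu_score", "igr_expr"),
      genomic_diff_expr = c("igr_length", "cu_score", "diff_expr"))
  }
  if (any(lengths(subsets) == 0L)) stopf("empty feature subset")
  sig <- vapply(subsets, function(s) paste(sort(s), collapse = "+"),
                character(1))
  cache <- list()
  out <- list()
  for (i in seq_along(subsets)) {
    if (is.null(cache[[sig[i]]])) {
      cfg_s <- cfg; cfg_s$feature_subset <- subsets[[i]]
      cache[[sig[i]]] <- cross_validate(table, cfg_s)
    }
    rep_i <- cache[[sig[i]]]
    out[[i]] <- data.frame(subset = names(subsets)[i] %||% sig[i],
                           model = names(rep_i),
                           mean_accuracy = vapply(rep_i, `[[`, numeric(1),
                                                  "mean_accuracy"),
                           sd_accuracy = vapply(rep_i, `[[`, numeric(1),
                                                "sd_accuracy"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-dataset accuracy comparison by bootstrap t-test
#'
#' Tests a fitted classifier on seeded bootstrap samples (size
#' `fraction` of the table, drawn with replacement) of its own dataset and
#' of a second dataset, and compares the two accuracy vectors with a Welch
#' two-sample t-test.
#'
#' @param model A fitted `operon_classifier`.
#' @param table_a Dataset the model was trained on (or an i.i.d. draw of it).
#' @param table_b The other dataset (same feature schema).
#' @param n_bootstrap Number of bootstrap samples per dataset (default 50).
#' @param fraction Bootstrap sample size as a fraction of the table (default
#'   0.70).
#' @param seed Seed for the bootstrap draws.
#' @return List `mean_accuracy_a`, `mean_accuracy_b`, `p_value`,
#'   `accuracy_a`, `accuracy_b`.
#' @export
cross_dataset_test <- function(model, table_a, table_b, n_bootstrap = 50L,
                               fraction = 0.70, seed = 1L) {
  if (nrow(table_a) < 10L || nrow(table_b) < 10L)
    stopf("tables too small for bootstrap (< 10 pairs)")
  boot_acc <- function(tbl, off) {
    vapply(seq_len(n_bootstrap), function(b) {
      set.seed(derive_seed(seed, off, b))
      ii <- sample(nrow(tbl), round(fraction * nrow(tbl)), replace = TRUE)
      s <- tbl[ii, , drop = FALSE]
      mean(predict(model, s, type = "class") == s$label)
    }, numeric(1))
  }
  acc_a <- boot_acc(table_a, 61)
  acc_b <- boot_acc(table_b, 62)
  # degenerate case: both accuracy vectors constant (e.g. a perfectly
  # separable table) — equal means are maximally consistent, unequal ones
  # maximally inconsistent
  p <- tryCatch(stats::t.test(acc_a, acc_b)$p.value,
                error = function(e)
                  if (isTRUE(all.equal(mean(acc_a), mean(acc_b)))) 1 else 0)
  list(mean_accuracy_a = mean(acc_a), mean_accuracy_b = mean(acc_b),
       p_value = p, accuracy_a = acc_a, accuracy_b = acc_b)
}
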