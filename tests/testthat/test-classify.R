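test_that("holdout split is stratified, seeded and exhaustive", {
  tbl <- simulate_pair_features(100, 100, seed = 3)
  cfg <- train_config(seed = 7)
  sp <- split_holdout(tbl, cfg)
  expect_equal(nrow(sp$test), 60L)
  expect_equal(sum(sp$test$label == "OP"), 30L)
  expect_equal(sort(c(sp$train$pair_id, sp$test$pair_id)), sort(tbl$pair_id))
  sp2 <- split_holdout(tbl, cfg)
  expect_identical(sp$test$pair_id, sp2$test$pair_id)
  expect_error(train_config(test_fraction = 0), "test_fraction")
})

test_that("all three models separate a separable table and are deterministic", {
  tbl <- simulate_pair_features(80, 80, seed = 5)
  cfg <- train_config(seed = 11, cv_repeats = 2)
  for (m in c("RF", "NN", "SVM")) {
    fit <- train_model(tbl, m, cfg)
    acc <- mean(predict(fit, tbl, type = "class") == tbl$label)
    expect_gt(acc, 0.97)
    fit2 <- train_model(tbl, m, cfg)
    expect_equal(predict(fit, tbl, type = "prob"),
                 predict(fit2, tbl, type = "prob"))
  }
  one_class <- tbl[tbl$label == "OP", ]
  expect_error(train_model(one_class, "RF", cfg), "single class")
})

test_that("evaluation metrics match direct arithmetic and flag zero denominators", {
  m <- compute_metrics(list(tp = 9, fn = 1, fp = 2, tn = 8))
  expect_equal(m$tpr, 0.9)
  expect_equal(m$ppv, 9 / 11)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$error_rate, 0.15)
  expect_equal(m$fpr_paper, 2 / 3)
  expect_equal(m$fpr_standard, 0.2)

  perfect <- compute_metrics(list(tp = 5, fn = 0, fp = 0, tn = 5))
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$error_rate, 0)

  z <- compute_metrics(list(tp = 3, fn = 1, fp = 0, tn = 0))
  expect_true(is.nan(z$fpr_standard))
  expect_error(compute_metrics(list(tp = 0, fn = 0, fp = 0, tn = 0)), "empty")
})

test_that("accuracy and error rate are complementary in every report", {
  tbl <- simulate_pair_features(40, 40, seed = 13)
  cfg <- train_config(seed = 2, cv_repeats = 2, models = c("RF", "SVM"))
  rep_ <- cross_validate(tbl, cfg)
  for (m in names(rep_))
    expect_equal(rep_[[m]]$runs$accuracy + rep_[[m]]$runs$error_rate,
                 rep(1, nrow(rep_[[m]]$runs)))
})

test_that("ROC is monotone and rank AUC equals trapezoid AUC", {
  set.seed(17)
  for (i in 1:10) {
    lab <- sample(c("OP", "NOP"), 60, replace = TRUE, prob = c(.5, .5))
    sc <- rnorm(60) + (lab == "OP") * runif(1, 0, 2)
    sc[sample(60, 10)] <- round(sc[sample(60, 10)], 1)  # induce ties
    rp <- roc_points(sc, lab)
    expect_true(all(diff(rp$fpr) >= 0))
    expect_true(all(diff(rp$tpr) >= 0))
    expect_equal(compute_auc(sc, lab, "rank"),
                 compute_auc(sc, lab, "trapezoid"), tolerance = 1e-9)
  }
})

test_that("cross-validation is perfect on separable data and stores consistent counts", {
  tbl <- simulate_pair_features(40, 40, seed = 19)
  tbl$igr_expr <- ifelse(tbl$label == "OP", 10, 0)   # force exact separation
  cfg <- train_config(seed = 3, cv_repeats = 2, models = "RF")
  rep_ <- cross_validate(tbl, cfg)
  expect_equal(rep_$RF$mean_accuracy, 1)
  expect_equal(rep_$RF$sd_accuracy, 0)
  expect_equal(rep_$RF$auc, 1)
  # metrics recomputed from the stored confusion counts equal the aggregates
  r <- rep_$RF$runs
  for (k in seq_len(nrow(r)))
    expect_equal(compute_metrics(as.list(r[k, c("tp", "fn", "fp", "tn")]))$accuracy,
                 r$accuracy[k])
})

test_that("sensitivity importance is zero for ignored features and exact for linear models", {
  tbl <- simulate_pair_features(50, 50, seed = 23)
  ignore_cu <- function(nd) 0.1 * nd$igr_expr + 0.01 * nd$diff_expr
  si <- sensitivity_importance(ignore_cu, tbl, levels = 7)
  expect_equal(si$importance[si$feature == "cu_score"], 0)
  expect_equal(si$importance[si$feature == "igr_length"], 0)

  const <- function(nd) rep(0.5, nrow(nd))
  si0 <- sensitivity_importance(const, tbl)
  expect_equal(si0$importance, rep(0, 4))
  expect_equal(si0$normalized, rep(0, 4))

  b <- 0.37
  lin <- function(nd) b * nd$igr_length
  si1 <- sensitivity_importance(lin, tbl, levels = 7)
  g <- seq(min(tbl$igr_length), max(tbl$igr_length), length.out = 7)
  expect_equal(si1$importance[si1$feature == "igr_length"],
               b^2 * sum((g - mean(g))^2) / 6, tolerance = 1e-9)
})

test_that("majority voting reproduces the 2-of-3 rule over all 8 combinations", {
  combos <- expand.grid(rf = c("NOP", "OP"), nn = c("NOP", "OP"),
                        svm = c("NOP", "OP"), stringsAsFactors = FALSE)
  v <- vote(combos$rf, combos$nn, combos$svm)
  n_op <- rowSums(combos == "OP")
  expect_equal(v$final_class, ifelse(n_op >= 2, "OP", "NOP"))
  expect_error(vote(c("OP", NA), c("OP", "OP"), c("NOP", "OP")), "missing")
  expect_error(vote("OP", c("OP", "NOP"), "OP"), "equal-length")
})

test_that("feature-subset evaluation ranks informative subsets first", {
  tbl <- simulate_pair_features(80, 80, seed = 29, informative = "diff_expr")
  cfg <- train_config(seed = 4, cv_repeats = 2, models = "RF")
  res <- evaluate_feature_subsets(tbl, cfg,
    subsets = list(genomic = c("igr_length", "cu_score"),
                   transcriptomic = c("diff_expr", "igr_expr"),
                   genomic2 = c("cu_score", "igr_length")))
  acc <- stats::setNames(res$mean_accuracy, res$subset)
  expect_gt(acc["transcriptomic"], acc["genomic"] + 0.2)
  # duplicate subset (order-insensitive) is reported identically
  expect_equal(unname(acc["genomic"]), unname(acc["genomic2"]))
  expect_error(evaluate_feature_subsets(tbl, cfg, subsets = list(character(0))),
               "empty")
})

test_that("cross-dataset bootstrap t-test is reproducible and detects inversion", {
  tbl_a <- simulate_pair_features(100, 100, seed = 31)
  fit <- train_model(tbl_a, "RF", train_config(seed = 5))
  tbl_inv <- simulate_pair_features(100, 100, seed = 37)
  tbl_inv$label <- ifelse(tbl_inv$label == "OP", "NOP", "OP")
  res <- cross_dataset_test(fit, tbl_a, tbl_inv, seed = 6)
  expect_lt(res$mean_accuracy_b, 0.5)
  expect_lt(res$p_value, 1e-6)
  res2 <- cross_dataset_test(fit, tbl_a, tbl_inv, seed = 6)
  expect_equal(res$p_value, res2$p_value)
  expect_error(cross_dataset_test(fit, tbl_a[1:5, ], tbl_inv, seed = 1),
               "too small")
})
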