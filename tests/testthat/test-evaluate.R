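test_that("confusion metrics reproduce the defining formulas", {
  # a perfectly predicted small class among 629 records
  m <- binary_metrics(5, 624, 0, 0)
  expect_equal(unname(m[c("Sn", "Sp", "MCC")]), c(1, 1, 1))
  # fully balanced random confusion has zero correlation
  expect_equal(binary_metrics(25, 25, 25, 25)[["MCC"]], 0)
  # half-sensitivity case with no false positives
  m3 <- binary_metrics(3, 623, 0, 3)
  expect_equal(m3[["Sn"]], 0.5)
  expect_equal(m3[["MCC"]], (3 * 623) / sqrt(3 * 6 * 623 * 626),
               tolerance = 1e-12)
  expect_equal(m3[["MCC"]], 0.7054, tolerance = 1e-4)
  expect_error(binary_metrics(0, 0, 0, 0), "empty")
})

test_that("metrics agree with the brute-force oracle on random tuples", {
  set.seed(11)
  for (i in 1:200) {
    cnt <- rmultinom(1, sample(10:400, 1), runif(4, 0.05, 1))[, 1]
    if (sum(cnt) == 0) next
    got <- binary_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    want <- oracle_binary_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rank-statistic AUC behaves as an ROC area", {
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(roc_auc(truth, c(rep(1, 10), rep(0, 10))), 1)
  expect_equal(roc_auc(truth, c(rep(0, 10), rep(1, 10))), 0)
  expect_true(is.na(roc_auc(rep(TRUE, 5), 1:5)))
  set.seed(12)
  t2 <- runif(2000) < 0.5
  s2 <- runif(2000)
  expect_lt(abs(roc_auc(t2, s2) - 0.5), 0.03)
  # invariance under strictly monotone transforms
  s3 <- rnorm(200); t3 <- runif(200) < plogis(s3)
  expect_equal(roc_auc(t3, s3), roc_auc(t3, exp(s3)), tolerance = 1e-12)
  # cross-check against an independent implementation
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(t3, s3),
               as.numeric(pROC::auc(pROC::roc(t3, s3, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("the multiclass report scores exact label-set equality", {
  truth <- list("plastid", c("cytoplasm", "nucleus"), "vacuole")
  pred_ok <- truth
  r <- multiclass_report(truth, pred_ok)
  expect_equal(unname(r$overall["acc_combined"]), 1)
  expect_true(all(r$per_location$MCC == 1))
  # predicting only one member of a dual label is incorrect
  pred_half <- list("plastid", "cytoplasm", "vacuole")
  r2 <- multiclass_report(truth, pred_half)
  expect_equal(unname(r2$overall["acc_multi"]), 0)
  expect_equal(unname(r2$overall["acc_combined"]), 2 / 3)
  expect_error(multiclass_report(list("plastid"), list("lysosome")),
               "outside")
})

test_that("subtotal aggregation reproduces the benchmark arithmetic", {
  # 592 single-label records with 506 correct; 37 dual-label with 26
  single_ok <- 506; single_n <- 592; multi_ok <- 26; multi_n <- 37
  truth <- c(rep(list("plastid"), single_n),
             rep(list(c("cytoplasm", "nucleus")), multi_n))
  pred <- c(rep(list("plastid"), single_ok),
            rep(list("vacuole"), single_n - single_ok),
            rep(list(c("cytoplasm", "nucleus")), multi_ok),
            rep(list("cytoplasm"), multi_n - multi_ok))
  r <- multiclass_report(truth, pred)
  expect_equal(unname(r$overall["acc_single"]), 506 / 592)
  expect_equal(unname(r$overall["acc_multi"]), 26 / 37)
  expect_equal(unname(r$overall["acc_combined"]), 532 / 629)
  expect_equal(round(100 * unname(r$overall["acc_combined"]), 2), 84.58)
  # overall accuracy is the weighted mean of the subtotals
  expect_equal(unname(r$overall["acc_combined"]),
               (single_n * r$overall[["acc_single"]] +
                  multi_n * r$overall[["acc_multi"]]) / (single_n + multi_n))
})

test_that("cross-validation is stratified, deterministic and leak-free", {
  fx <- make_fixture("tiny")
  tab <- extract_table(fx$dataset, table_provider(fx$scores))
  sets <- label_sets(fx$dataset)
  expect_error(cross_validate(tab, sets, folds = 1), ">= 2")
  cv1 <- cross_validate(tab, sets, ensemble_config(seed = 1), folds = 5,
                        seed = 3)
  cv2 <- cross_validate(tab, sets, ensemble_config(seed = 1), folds = 5,
                        seed = 3)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$ensemble_accuracy, cv2$ensemble_accuracy)
  # leave-one-out boundary on the 22-record toy runs to completion
  cvl <- cross_validate(tab, sets, ensemble_config(seed = 1),
                        folds = nrow(tab), seed = 1)
  expect_equal(cvl$report$n, nrow(tab))
  # every record is scored exactly once, out of fold
  expect_equal(sort(unique(cv1$folds)), 1:5)
})

test_that("in-fold selection trains on the selected subset only", {
  fx <- make_fixture("tiny")
  tab <- extract_table(fx$dataset, table_provider(fx$scores))
  sets <- label_sets(fx$dataset)
  cv <- cross_validate(tab, sets, ensemble_config(seed = 1), folds = 3,
                       seed = 2, selection = "oner", top_n = 30)
  expect_equal(cv$report$n, nrow(tab))
  expect_true(all(lengths(cv$predictions) >= 1))
})

test_that("one-vs-rest Pearson analysis ranks indicator-like features first", {
  set.seed(14)
  n <- 400
  y <- sample(compartment_labels(), n, replace = TRUE)
  sets <- as.list(y)
  ind <- as.numeric(y == "nucleus")
  X <- data.frame(exact = ind, neg = -ind, noise = runif(n), const = 1)
  r <- suppressWarnings(pcc_feature_analysis(X, sets, "nucleus", top_n = 4))
  expect_equal(r$feature[1:2], c("exact", "neg"))
  expect_equal(r$pcc[r$feature == "exact"], 1, tolerance = 1e-12)
  expect_equal(r$pcc[r$feature == "neg"], -1, tolerance = 1e-12)
  expect_equal(r$pcc[r$feature == "const"], 0)
  # pure-noise features stay near zero at large n
  set.seed(15)
  big <- data.frame(noise = runif(5000))
  yb <- as.list(sample(c("nucleus", "cytoplasm"), 5000, replace = TRUE))
  rb <- pcc_feature_analysis(big, yb, "nucleus", top_n = 1)
  expect_lt(abs(rb$pcc[1]), 0.05)
})
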