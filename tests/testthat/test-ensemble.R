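# small labeled feature table built once for the ensemble tests
tiny_env <- new.env()
tiny_data <- function() {
  if (is.null(tiny_env$tab)) {
    fx <- make_fixture("tiny")
    tiny_env$tab <- extract_table(fx$dataset, table_provider(fx$scores))
    tiny_env$sets <- label_sets(fx$dataset)
  }
  list(tab = tiny_env$tab, sets = tiny_env$sets)
}

test_that("average voting is the unweighted componentwise mean", {
  v <- c(0.7, 0.2, 0.1)
  expect_equal(average_vote(v, v, v), v)
  a <- c(0.6, 0.4, 0); b <- c(0.2, 0.8, 0); d <- c(0.4, 0.6, 0)
  expect_equal(average_vote(a, b, d), c(0.4, 0.6, 0))
  # consensus of valid distributions is a distribution, and the vote is
  # permutation-equivariant in its three inputs
  set.seed(1)
  ps <- lapply(1:3, function(i) { x <- runif(11); x / sum(x) })
  expect_equal(sum(do.call(average_vote, ps)), 1, tolerance = 1e-12)
  expect_equal(do.call(average_vote, ps),
               do.call(average_vote, ps[c(3, 1, 2)]))
  expect_error(average_vote(a, b, c(0.5, 0.5)), "mismatch")
})

test_that("label decisions follow the runner-up threshold rule", {
  cons <- setNames(c(0.9, 0.05, rep(0.05 / 9, 9)), compartment_labels())
  expect_equal(decide_labels(cons, 0.30), "plastid")
  cons2 <- setNames(c(0.45, 0.40, rep(0.15 / 9, 9)), compartment_labels())
  expect_equal(decide_labels(cons2, 0.30),
               c("plastid", "cytoplasm"))
  expect_equal(decide_labels(cons2, 1.0), "plastid")
  # rank-2 ties break by canonical compartment order
  cons3 <- setNames(rep(0, 11), compartment_labels())
  cons3[c("nucleus", "cytoplasm", "golgi")] <- c(0.4, 0.3, 0.3)
  expect_equal(decide_labels(cons3, 0.30), c("nucleus", "cytoplasm"))
})

test_that("dual-labeled records duplicate into both classes for training", {
  tr <- plantloc:::.training_rows(
    list("plastid", c("cytoplasm", "nucleus")), "duplicate")
  expect_equal(tr$rows, c(1, 2, 2))
  expect_equal(tr$y, c("plastid", "cytoplasm", "nucleus"))
  trp <- plantloc:::.training_rows(
    list("plastid", c("cytoplasm", "nucleus")), "pair-class")
  expect_equal(trp$y, c("plastid", "cytoplasm+nucleus"))
})

test_that("training is deterministic and recovers its training labels", {
  d <- tiny_data()
  m1 <- train_ensemble(d$tab, d$sets, ensemble_config(seed = 5))
  m2 <- train_ensemble(d$tab, d$sets, ensemble_config(seed = 5))
  p1 <- predict_ensemble(m1, d$tab)
  p2 <- predict_ensemble(m2, d$tab)
  expect_equal(p1$consensus, p2$consensus, tolerance = 1e-12)
  # overfit sanity: training records get their own labels back
  expect_equal(label_key(p1$labels), label_key(d$sets))
  # consensus equals the average of the three reported base vectors
  expect_equal(p1$consensus,
               (p1$base$knn + p1$base$rf + p1$base$xgb) / 3,
               tolerance = 1e-12)
  expect_equal(unname(rowSums(p1$consensus)), rep(1, nrow(d$tab)),
               tolerance = 1e-9)
})

test_that("class enforcement and feature checks raise clear errors", {
  d <- tiny_data()
  expect_error(
    train_ensemble(d$tab, d$sets, classes = compartment_labels()),
    "absent from training")
  m <- train_ensemble(d$tab, d$sets)
  expect_error(predict_ensemble(m, d$tab[, 1:100]), "missing from input")
  expect_error(train_ensemble(d$tab, rep(list(character(0)), nrow(d$tab))),
               "no label")
})

test_that("a feature-subset model trains and predicts on that subset only", {
  d <- tiny_data()
  sel <- select_top(oner_rank(d$tab, label_key(d$sets)), 25)
  m <- train_ensemble(d$tab, d$sets, features = sel$selected)
  expect_equal(m$features, sel$selected)
  pr <- predict_ensemble(m, d$tab)
  expect_length(pr$labels, nrow(d$tab))
  expect_error(train_ensemble(d$tab, d$sets, features = "no_such"),
               "not in table")
})

test_that("the pair-class policy trains and collapses to 11 compartments", {
  set.seed(31)
  fx <- generate_synthetic(synthetic_config(
    n_per_class = c(cytoplasm = 12, nucleus = 12, plastid = 12,
                    mitochondrion = 12),
    n_dual = c(cyto_nucleus = 6, mito_plastid = 6), seed = 31))
  tab <- extract_table(fx$dataset, table_provider(fx$scores))
  sets <- label_sets(fx$dataset)
  m <- train_ensemble(tab, sets,
                      ensemble_config(multilabel_policy = "pair-class",
                                      seed = 2))
  pr <- predict_ensemble(m, tab)
  expect_true(all(colnames(pr$consensus) %in% compartment_labels()))
  expect_equal(unname(rowSums(pr$consensus)), rep(1, nrow(tab)),
               tolerance = 1e-9)
  expect_true(all(lengths(pr$labels) %in% 1:2))
})

test_that("models persist to a directory and reload intact", {
  d <- tiny_data()
  m <- train_ensemble(d$tab, d$sets, ensemble_config(seed = 9))
  dir <- file.path(tempdir(), "mdl")
  save_ensemble(m, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  m2 <- load_ensemble(dir)
  expect_equal(predict_ensemble(m2, d$tab)$consensus,
               predict_ensemble(m, d$tab)$consensus, tolerance = 1e-12)
})

test_that("prediction tables carry one or two labels plus probabilities", {
  d <- tiny_data()
  m <- train_ensemble(d$tab, d$sets)
  out <- prediction_table(predict_ensemble(m, d$tab))
  expect_equal(nrow(out), nrow(d$tab))
  expect_true(all(c("id", "label1", "label2") %in% names(out)))
  expect_true(all(out$label1 %in% compartment_labels()))
})
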