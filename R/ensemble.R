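# The heterogeneous average-voting ensemble: inverse-distance-weighted
# k-nearest neighbours (k = 12), random forest (100 trees) and gradient
# boosted trees (50 rounds, depth 5, eta 0.1, multiclass log-loss), each
# producing a class-probability vector; the consensus is their unweighted
# mean. Single- vs dual-label calls are decided on the consensus
# distribution: the top class always, plus the runner-up when its
# consensus probability reaches the decision threshold theta.

#' Ensemble configuration
#'
#' Defaults are the base-learner settings the workflow fixes: KNN k = 12
#' with inverse-distance weighting, 100 random-forest trees, and XGBoost
#' with 50 rounds, max depth 5, eta 0.1, multiclass log-loss.
#'
#' @param knn_k neighbours for KNN.
#' @param rf_estimators random-forest tree count.
#' @param xgb_rounds,xgb_max_depth,xgb_eta XGBoost parameters.
#' @param theta dual-label decision threshold on the runner-up consensus
#'   probability (in (0, 1]; 1 forces single-label output).
#' @param multilabel_policy `"duplicate"` (default: dual-labeled training
#'   records appear once per constituent class) or `"pair-class"` (pairs
#'   are distinct training classes, collapsed back at prediction).
#' @param seed integer seed for the stochastic learners.
#' @return validated config list.
#' @export
ensemble_config <- function(knn_k = 12L, rf_estimators = 100L,
                            xgb_rounds = 50L, xgb_max_depth = 5L,
                            xgb_eta = 0.1, theta = 0.30,
                            multilabel_policy = c("duplicate", "pair-class"),
                            seed = 1L) {
  multilabel_policy <- match.arg(multilabel_policy)
  stopifnot(knn_k >= 1, rf_estimators >= 1, xgb_rounds >= 1,
            theta > 0, theta <= 1)
  list(knn_k = as.integer(knn_k), rf_estimators = as.integer(rf_estimators),
       xgb_rounds = as.integer(xgb_rounds),
       xgb_max_depth = as.integer(xgb_max_depth), xgb_eta = xgb_eta,
       theta = theta, multilabel_policy = multilabel_policy,
       seed = as.integer(seed))
}

# expand training rows according to the multilabel policy; returns
# list(rows = row indices into X, y = single-class factor labels)
.training_rows <- function(label_list, policy) {
  rows <- integer(0); y <- character(0)
  for (i in seq_along(label_list)) {
    s <- label_list[[i]]
    if (!length(s)) stop("record ", i, " has no label")
    if (policy == "duplicate" || length(s) == 1) {
      rows <- c(rows, rep(i, length(s)))
      y <- c(y, s)
    } else {
      rows <- c(rows, i)
      y <- c(y, paste(s, collapse = "+"))
    }
  }
  list(rows = rows, y = y)
}

#' Train the three base classifiers
#'
#' @param X feature table (data.frame with optional `id` column, or
#'   matrix); rows aligned with `labels`.
#' @param labels list of per-record label sets (1 or 2 compartments), or a
#'   character vector of single labels.
#' @param config an [ensemble_config()].
#' @param features optional feature-name subset to train on (e.g. a
#'   selection result's `selected`); default all columns.
#' @param classes optional class universe to enforce; an error lists any
#'   enforced class absent from the training labels.
#' @return an `plantloc_ensemble` model object.
#' @export
train_ensemble <- function(X, labels, config = ensemble_config(),
                           features = NULL, classes = NULL) {
  X <- .as_feature_matrix(X)
  if (is.character(labels)) labels <- as.list(labels)
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(X))
    if (length(miss)) stop("feature(s) not in table: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  if (!all(is.finite(X))) stop("non-finite feature values in training data")
  tr <- .training_rows(labels, config$multilabel_policy)
  present <- unique(tr$y)
  if (!is.null(classes)) {
    miss <- setdiff(classes, present)
    if (length(miss)) stop("class(es) absent from training data: ",
                           paste(miss, collapse = ", "))
  }
  class_order <- c(COMPARTMENTS,
                   vapply(DUAL_CLASSES, paste, "", collapse = "+"))
  cls <- intersect(class_order, present)
  extra <- setdiff(present, class_order)
  if (length(extra)) stop("unknown training class(es): ",
                          paste(extra, collapse = ", "))
  yf <- factor(tr$y, levels = cls)
  if (any(table(yf) < 2)) stop("class(es) with < 2 training rows: ",
                               paste(names(which(table(yf) < 2)),
                                     collapse = ", "))
  Xt <- X[tr$rows, , drop = FALSE]
  mu <- colMeans(Xt)
  sdv <- apply(Xt, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Zt <- sweep(sweep(Xt, 2, mu), 2, sdv, "/")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  rf <- randomForest::randomForest(Xt, yf, ntree = config$rf_estimators)
  xgb <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(cls),
                  max_depth = config$xgb_max_depth, eta = config$xgb_eta,
                  eval_metric = "mlogloss", nthread = 1),
    data = xgboost::xgb.DMatrix(Xt, label = as.integer(yf) - 1L),
    nrounds = config$xgb_rounds, verbose = 0)
  structure(list(
    knn = list(Z = Zt, y = yf, k = config$knn_k),
    rf = rf, xgb = xgb,
    classes = cls, features = colnames(X),
    scaling = list(mu = mu, sd = sdv),
    config = config,
    meta = list(seed = config$seed, n_records = length(labels),
                n_training_rows = nrow(Xt), date = "unset")),
    class = "plantloc_ensemble")
}

# inverse-distance-weighted KNN class probabilities
.knn_proba <- function(knn, Z) {
  k <- min(knn$k, nrow(knn$Z))
  cls <- levels(knn$y)
  out <- matrix(0, nrow(Z), length(cls), dimnames = list(NULL, cls))
  tZ <- t(knn$Z)
  for (i in seq_len(nrow(Z))) {
    d <- sqrt(colSums((tZ - Z[i, ])^2))
    nn <- order(d)[seq_len(k)]
    w <- 1 / (d[nn] + 1e-8)
    for (j in seq_len(k))
      out[i, as.character(knn$y[nn[j]])] <-
        out[i, as.character(knn$y[nn[j]])] + w[j]
    out[i, ] <- out[i, ] / sum(out[i, ])
  }
  out
}

#' Average voting consensus
#'
#' Unweighted componentwise mean of class-probability vectors (or
#' identically shaped matrices).
#'
#' @param p_knn,p_rf,p_xgb non-negative probability vectors/matrices
#'   summing to 1 per row.
#' @return consensus of the same shape.
#' @export
average_vote <- function(p_knn, p_rf, p_xgb) {
  if (is.null(dim(p_knn))) {
    p_knn <- rbind(p_knn); p_rf <- rbind(p_rf); p_xgb <- rbind(p_xgb)
    drop1 <- TRUE
  } else drop1 <- FALSE
  if (!all(dim(p_knn) == dim(p_rf)) || !all(dim(p_knn) == dim(p_xgb)))
    stop("probability inputs have mismatched dimensions")
  out <- (p_knn + p_rf + p_xgb) / 3
  if (drop1) out[1, ] else out
}

#' Decide the output label set from a consensus distribution
#'
#' The top-probability class is always called; the runner-up is added iff
#' its consensus probability is at least `theta`. Rank-2 ties break by
#' canonical compartment order.
#'
#' @param consensus named probability vector over compartments.
#' @param theta dual-label threshold.
#' @return character vector of 1 or 2 compartment codes.
#' @export
decide_labels <- function(consensus, theta = 0.30) {
  cls <- names(consensus)
  ord <- order(-consensus, match(cls, COMPARTMENTS))
  out <- cls[ord[1]]
  if (length(cls) > 1 && theta < 1 && consensus[ord[2]] >= theta)
    out <- c(out, cls[ord[2]])
  out
}

# collapse pair-class probabilities back onto the 11 compartments
.collapse_pairs <- function(P) {
  single <- intersect(colnames(P), COMPARTMENTS)
  pairs <- setdiff(colnames(P), single)
  out <- P[, single, drop = FALSE]
  for (pc in pairs) {
    parts <- strsplit(pc, "+", fixed = TRUE)[[1]]
    for (q in parts) out[, q] <- out[, q] + P[, pc] / length(parts)
  }
  out / rowSums(out)
}

#' Predict class probabilities and label calls
#'
#' @param model a trained `plantloc_ensemble`.
#' @param X feature table covering the model's fit-time feature list (an
#'   error names any missing feature).
#' @param theta optional override of the dual-label threshold.
#' @return a `plantloc_predictions` list: `ids`, `consensus` (n x classes
#'   matrix), `base` (per-model probability matrices), `labels` (list of
#'   decided label sets).
#' @export
predict_ensemble <- function(model, X, theta = NULL) {
  ids <- if (is.data.frame(X) && "id" %in% names(X)) X$id else
    as.character(seq_len(nrow(X)))
  Xm <- .as_feature_matrix(X)
  miss <- setdiff(model$features, colnames(Xm))
  if (length(miss)) stop("feature(s) missing from input: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  Xm <- Xm[, model$features, drop = FALSE]
  Z <- sweep(sweep(Xm, 2, model$scaling$mu), 2, model$scaling$sd, "/")
  p_knn <- .knn_proba(model$knn, Z)
  p_rf <- stats::predict(model$rf, Xm, type = "prob")[, model$classes,
                                                      drop = FALSE]
  p_xgb <- stats::predict(model$xgb, Xm)
  if (is.null(dim(p_xgb)))
    p_xgb <- matrix(p_xgb, ncol = length(model$classes), byrow = TRUE)
  colnames(p_xgb) <- model$classes
  p_xgb <- p_xgb / rowSums(p_xgb)   # exact renormalization (float32 sums)
  if (model$config$multilabel_policy == "pair-class") {
    p_knn <- .collapse_pairs(p_knn)
    p_rf <- .collapse_pairs(p_rf)
    p_xgb <- .collapse_pairs(p_xgb)
  }
  cons <- average_vote(p_knn, p_rf, p_xgb)
  th <- if (is.null(theta)) model$config$theta else theta
  labels <- lapply(seq_len(nrow(cons)), function(i)
    decide_labels(cons[i, ], th))
  structure(list(ids = ids, consensus = cons,
                 base = list(knn = p_knn, rf = p_rf, xgb = p_xgb),
                 labels = labels, theta = th),
            class = "plantloc_predictions")
}

#' Predict localization for raw protein records
#'
#' Extracts the model's fit-time features from the sequences (with the
#' given external-score provider) and runs [predict_ensemble()].
#'
#' @param model a trained `plantloc_ensemble`.
#' @param dataset a `plantloc_dataset` of query records.
#' @param provider external-score provider function.
#' @param params a [descriptor_params()].
#' @param homology optional homology codes per id (see
#'   [go_homology_codes()]).
#' @inheritParams predict_ensemble
#' @return a `plantloc_predictions`.
#' @export
predict_records <- function(model, dataset, provider,
                            params = descriptor_params(), homology = NULL,
                            theta = NULL) {
  tab <- extract_table(dataset, provider, params, homology)
  predict_ensemble(model, tab, theta)
}

#' Format predictions as a table
#'
#' @param pred a `plantloc_predictions`.
#' @return data.frame with id, label1, label2 (NA when single) and one
#'   probability column per class.
#' @export
prediction_table <- function(pred) {
  l1 <- vapply(pred$labels, `[`, "", 1)
  l2 <- vapply(pred$labels, function(s) if (length(s) > 1) s[2] else
    NA_character_, "")
  cbind(data.frame(id = pred$ids, label1 = l1, label2 = l2,
                   stringsAsFactors = FALSE),
        as.data.frame(pred$consensus))
}

#' Persist / restore an ensemble model
#'
#' The model directory holds a JSON config plus binary base-model
#' artifacts (run-time only; not a text interchange format).
#'
#' @param model a `plantloc_ensemble`.
#' @param dir model directory.
#' @name model_io
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = model$config, classes = model$classes,
         features = model$features, meta = model$meta),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname model_io
#' @param dir model directory.
#' @export
load_ensemble <- function(dir) {
  m <- readRDS(file.path(dir, "model.rds"))
  if (!inherits(m, "plantloc_ensemble")) stop("not an ensemble model: ", dir)
  m
}
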