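# Performance evaluation: one-vs-rest confusion metrics (accuracy,
# sensitivity, specificity, Matthews correlation), rank-statistic AUC,
# stratified cross-validation with in-fold feature selection, per-location
# report tables, and the one-vs-rest Pearson feature analysis.

#' Binary confusion metrics
#'
#' ACC = (TP+TN)/total, Sn = TP/(TP+FN), Sp = TN/(TN+FP),
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); the MCC is
#' 0 when any denominator factor vanishes (standard convention), and Sn/Sp
#' are NA when their denominator is 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (total > 0).
#' @return named numeric vector (ACC, Sn, Sp, MCC).
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total <= 0) stop("empty confusion matrix")
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) /
    sqrt(den)
  c(ACC = (tp + tn) / total,
    Sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    Sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    MCC = mcc)
}

#' Rank-statistic AUC
#'
#' The area under the ROC curve computed as the normalized Mann-Whitney
#' statistic with midranks for ties; invariant under strictly monotone
#' score transforms.
#'
#' @param truth logical (or 0/1) one-vs-rest labels.
#' @param score numeric scores (higher = more positive).
#' @return AUC in `[0, 1]`, or NA if only one class is present.
#' @export
roc_auc <- function(truth, score) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# one-vs-rest confusion counts for one class over label SETS
.ovr_counts <- function(class, truth_sets, pred_sets) {
  tpos <- vapply(truth_sets, function(s) class %in% s, logical(1))
  ppos <- vapply(pred_sets, function(s) class %in% s, logical(1))
  c(tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
    fp = sum(!tpos & ppos), fn = sum(tpos & !ppos))
}

#' Multiclass / multilabel performance report
#'
#' A record is counted correct iff its predicted label set equals its true
#' label set exactly. The report carries per-location rows (single-location
#' classes and the dual-location pair classes), subtotal rows for
#' single-label, multilabel and all records, plus one-vs-rest MCC and
#' (when scores are given) AUC per compartment, where a dual-labeled
#' record is a positive of both its compartments.
#'
#' @param truth,predicted aligned lists of label sets.
#' @param scores optional consensus probability matrix (n x 11, columns
#'   named by compartment) for AUC.
#' @return a `plantloc_report` list: `per_location` data.frame, `overall`
#'   accuracies, `ovr` per-compartment one-vs-rest metrics.
#' @export
multiclass_report <- function(truth, predicted, scores = NULL) {
  stopifnot(length(truth) == length(predicted))
  all_lab <- unique(unlist(c(truth, predicted)))
  bad <- setdiff(all_lab, COMPARTMENTS)
  if (length(bad)) stop("label(s) outside the class universe: ",
                        paste(bad, collapse = ", "))
  tkey <- label_key(truth)
  pkey <- label_key(predicted)
  correct <- tkey == pkey
  single <- lengths(truth) == 1
  keys <- c(COMPARTMENTS, vapply(DUAL_CLASSES, paste, "", collapse = "+"))
  rows <- lapply(keys, function(k) {
    n <- sum(tkey == k)
    if (n == 0) return(NULL)
    ok <- sum(correct[tkey == k])
    data.frame(location = k, n = n, correct = ok,
               percent = 100 * ok / n, stringsAsFactors = FALSE)
  })
  per_loc <- do.call(rbind, rows)
  ovr <- t(vapply(COMPARTMENTS, function(cl) {
    cnt <- .ovr_counts(cl, truth, predicted)
    m <- binary_metrics(cnt[["tp"]], cnt[["tn"]], cnt[["fp"]], cnt[["fn"]])
    auc <- if (!is.null(scores) && cl %in% colnames(scores))
      roc_auc(vapply(truth, function(s) cl %in% s, logical(1)),
              scores[, cl]) else NA_real_
    c(cnt, m, AUC = auc)
  }, numeric(9)))
  per_loc$MCC <- NA_real_
  for (i in seq_len(nrow(per_loc))) {
    loc <- per_loc$location[i]
    if (loc %in% COMPARTMENTS) per_loc$MCC[i] <- ovr[loc, "MCC"]
    else {
      parts <- strsplit(loc, "+", fixed = TRUE)[[1]]
      pos <- tkey == loc
      ok2 <- pkey == tkey
      cnt <- c(tp = sum(pos & ok2), tn = sum(!pos & !(pkey == loc)),
               fp = sum(!pos & pkey == loc), fn = sum(pos & !ok2))
      per_loc$MCC[i] <- binary_metrics(cnt[[1]], cnt[[2]], cnt[[3]],
                                       cnt[[4]])[["MCC"]]
    }
  }
  overall <- c(
    acc_single = if (any(single)) mean(correct[single]) else NA_real_,
    acc_multi = if (any(!single)) mean(correct[!single]) else NA_real_,
    acc_combined = mean(correct))
  structure(list(per_location = per_loc, overall = overall, ovr = ovr,
                 macro_auc = if (!is.null(scores))
                   mean(ovr[, "AUC"], na.rm = TRUE) else NA_real_,
                 n = length(truth),
                 n_single = sum(single), n_multi = sum(!single),
                 correct_single = sum(correct[single]),
                 correct_multi = sum(correct[!single])),
            class = "plantloc_report")
}

#' @export
print.plantloc_report <- function(x, ...) {
  cat("plantloc performance report (n =", x$n, ")\n")
  print(x$per_location, row.names = FALSE)
  cat(sprintf("single: %d/%d (%.2f%%)  multi: %d/%d (%.2f%%)  all: %d/%d (%.2f%%)\n",
              x$correct_single, x$n_single, 100 * x$overall["acc_single"],
              x$correct_multi, x$n_multi, 100 * x$overall["acc_multi"],
              x$correct_single + x$correct_multi, x$n,
              100 * x$overall["acc_combined"]))
  if (!is.na(x$macro_auc)) cat(sprintf("macro AUC: %.3f\n", x$macro_auc))
  invisible(x)
}

#' Write a report as TSV (per-location layout) and JSON
#'
#' @param report a `plantloc_report`.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @export
write_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(report$per_location, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(per_location = report$per_location,
           overall = as.list(report$overall),
           ovr = as.data.frame(report$ovr), macro_auc = report$macro_auc),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# stratified fold assignment over label-set keys
.stratified_folds <- function(keys, folds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fold <- integer(length(keys))
  small <- character(0)
  for (k in unique(keys)) {
    idx <- sample(which(keys == k))
    if (length(idx) < folds) small <- c(small, k)
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (length(small))
    warning("class(es) with fewer members than folds (stratification ",
            "degrades): ", paste(small, collapse = ", "))
  fold
}

#' Stratified cross-validation of the full pipeline
#'
#' Splits records into stratified folds (by label set), then runs feature
#' selection (optional) and ensemble training inside each training fold
#' only, scoring pooled out-of-fold predictions. Also reports the CV
#' accuracy of each base model alone (its probability vectors passed
#' through the same label-decision rule).
#'
#' @param features feature table from [extract_table()].
#' @param labels list of label sets aligned with the table rows.
#' @param config an [ensemble_config()].
#' @param folds number of folds (default 10; must be >= 2).
#' @param seed integer seed (fold assignment; also offsets model seeds).
#' @param selection `"none"` (default), `"relieff"`, `"oner"` or
#'   `"cfs_ga"`.
#' @param top_n subset size for the ranking selectors (default 95).
#' @param ga_params passed to [cfs_ga_search()] when selection is
#'   `"cfs_ga"` (its seed defaults to `seed`).
#' @return list: `report` (a `plantloc_report` with AUC), `base_accuracy`
#'   (named consensus-rule accuracies of knn/rf/xgb alone),
#'   `ensemble_accuracy`, `folds` (assignment), `predictions`.
#' @export
cross_validate <- function(features, labels, config = ensemble_config(),
                           folds = 10L, seed = 1L, selection = "none",
                           top_n = 95L, ga_params = list()) {
  if (folds < 2) stop("folds must be >= 2")
  n <- length(labels)
  stopifnot(nrow(features) == n)
  keys <- label_key(labels)
  fold <- .stratified_folds(keys, folds, seed)
  cons <- matrix(0, n, length(COMPARTMENTS),
                 dimnames = list(NULL, COMPARTMENTS))
  pred_sets <- vector("list", n)
  base_sets <- list(knn = vector("list", n), rf = vector("list", n),
                    xgb = vector("list", n))
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- fold == f
    feats <- NULL
    if (selection != "none") {
      Xtr <- features[tr, , drop = FALSE]
      ytr <- keys[tr]
      sel <- switch(selection,
        relieff = select_top(relieff(Xtr, ytr, seed = seed + f),
                             min(top_n, ncol(.as_feature_matrix(Xtr)))),
        oner = select_top(oner_rank(Xtr, ytr),
                          min(top_n, ncol(.as_feature_matrix(Xtr)))),
        cfs_ga = cfs_ga_search(Xtr, ytr,
                               utils::modifyList(list(seed = seed + f),
                                                 ga_params)),
        stop("unknown selection method: ", selection))
      feats <- sel$selected
    }
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_ensemble(features[tr, , drop = FALSE], labels[tr],
                            cfg, features = feats)
    pr <- predict_ensemble(model, features[te, , drop = FALSE])
    cons[te, colnames(pr$consensus)] <- pr$consensus
    for (m in names(base_sets)) {
      P <- pr$base[[m]]
      for (j in seq_len(nrow(P))) {
        i <- which(te)[j]
        base_sets[[m]][[i]] <- decide_labels(P[j, ], pr$theta)
      }
    }
    for (j in seq_len(sum(te)))
      pred_sets[[which(te)[j]]] <- pr$labels[[j]]
  }
  report <- multiclass_report(labels, pred_sets, cons)
  base_acc <- vapply(base_sets, function(ps)
    mean(label_key(ps) == keys), numeric(1))
  list(report = report, base_accuracy = base_acc,
       ensemble_accuracy = unname(report$overall["acc_combined"]),
       folds = fold, predictions = pred_sets, consensus = cons)
}

#' One-vs-rest Pearson correlation feature analysis
#'
#' For a target compartment, correlates every feature with the one-vs-rest
#' class indicator (a dual-labeled record containing the target counts as
#' positive) and returns the strongest `top_n` features by absolute
#' correlation. Zero-variance features get correlation 0 with a warning.
#'
#' @param features feature table.
#' @param labels list of label sets.
#' @param target_class compartment code.
#' @param top_n how many features to report (default 20).
#' @return data.frame (feature, pcc) sorted by decreasing `|pcc|`.
#' @export
pcc_feature_analysis <- function(features, labels, target_class,
                                 top_n = 20L) {
  target_class <- normalize_compartment(target_class)
  X <- .as_feature_matrix(features)
  ind <- vapply(labels, function(s) target_class %in% s, logical(1))
  if (!any(ind)) stop("target class absent from labels: ", target_class)
  pcc <- numeric(ncol(X))
  zv <- apply(X, 2, stats::sd) == 0
  if (any(zv)) warning(sum(zv), " zero-variance feature(s) set to PCC 0")
  pcc[!zv] <- suppressWarnings(
    as.vector(stats::cor(X[, !zv, drop = FALSE], as.numeric(ind))))
  names(pcc) <- colnames(X)
  ord <- order(-abs(pcc), seq_along(pcc))
  data.frame(feature = colnames(X)[ord[seq_len(min(top_n, length(ord)))]],
             pcc = pcc[ord[seq_len(min(top_n, length(ord)))]],
             row.names = NULL, stringsAsFactors = FALSE)
}
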