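# Feature selection: ReliefF weighting, OneR ranking, and CFS subset
# merit searched with a genetic algorithm. All methods operate on a
# numeric feature matrix/table plus a categorical label vector, and are
# deterministic given their seed. Selection must be run on training rows
# only; cross_validate() enforces that by construction.

.as_feature_matrix <- function(X) {
  if (is.data.frame(X)) {
    if ("id" %in% names(X)) X <- X[setdiff(names(X), "id")]
    X <- as.matrix(X)
  }
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

.selection_result <- function(method, weights, selected, params) {
  structure(list(method = method, weights = weights, selected = selected,
                 params = params),
            class = "plantloc_selection")
}

#' ReliefF multiclass feature weighting
#'
#' Instance-based weighting: for each sampled instance, features are
#' rewarded for separating it from its k nearest misses of each other
#' class (weighted by class priors) and penalized for differing from its k
#' nearest hits. Features are internally scaled to `[0, 1]`; distances are
#' Manhattan. Weights lie in `[-1, 1]`; a constant feature gets weight 0.
#'
#' @param X feature table (data.frame with optional `id` column, or
#'   matrix).
#' @param y class labels (factor or character).
#' @param k_neighbors neighbors per class (default 10; reduced with a
#'   warning for classes with fewer members).
#' @param n_samples number of sampled instances (default: all).
#' @param seed integer seed (used when subsampling instances).
#' @return a `plantloc_selection` with per-feature weights, ranked.
#' @export
relieff <- function(X, y, k_neighbors = 10L, n_samples = NULL, seed = 1L) {
  X <- .as_feature_matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("ReliefF needs at least 2 classes")
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1      # constant features contribute zero diff
  Z <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  prior <- table(y) / n
  counts <- table(y)
  if (any(counts - 1 < k_neighbors))
    warning("k reduced for class(es) with < k+1 members: ",
            paste(names(counts)[counts - 1 < k_neighbors], collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  samp <- if (is.null(n_samples) || n_samples >= n) seq_len(n) else
    sort(sample.int(n, n_samples))
  D <- as.matrix(stats::dist(Z, method = "manhattan"))
  W <- numeric(p)
  for (i in samp) {
    ci <- y[i]
    for (cl in levels(y)) {
      members <- which(y == cl & seq_len(n) != i)
      if (!length(members)) next
      k <- min(k_neighbors, length(members))
      nn <- members[order(D[i, members])[seq_len(k)]]
      diffs <- colMeans(abs(Z[nn, , drop = FALSE] -
                              matrix(Z[i, ], k, p, byrow = TRUE)))
      if (cl == ci) W <- W - diffs / length(samp)
      else W <- W + (prior[[cl]] / (1 - prior[[ci]])) * diffs / length(samp)
    }
  }
  names(W) <- colnames(X)
  ord <- order(-W, seq_along(W))
  .selection_result("relieff", W, colnames(X)[ord],
                    list(k_neighbors = k_neighbors,
                         n_samples = length(samp), seed = seed))
}

# equal-frequency discretization into at most n_bins bins; features with
# fewer distinct values than bins keep one bin per distinct value
.discretize <- function(x, n_bins = 10L) {
  ux <- unique(x)
  if (length(ux) <= n_bins) return(match(x, sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

#' OneR univariate feature ranking
#'
#' Each feature is discretized (equal-frequency, `n_bins`), a one-rule
#' classifier (majority class per bin) is built, and the feature's score
#' is that rule's training accuracy.
#'
#' @inheritParams relieff
#' @param n_bins number of bins (default 10).
#' @return a `plantloc_selection` with per-feature scores, ranked.
#' @export
oner_rank <- function(X, y, n_bins = 10L) {
  X <- .as_feature_matrix(X)
  y <- factor(y)
  n <- nrow(X)
  scores <- vapply(seq_len(ncol(X)), function(j) {
    b <- .discretize(X[, j], n_bins)
    correct <- 0
    for (bin in unique(b)) {
      tab <- table(y[b == bin])
      correct <- correct + max(tab)
    }
    correct / n
  }, numeric(1))
  names(scores) <- colnames(X)
  ord <- order(-scores, seq_along(scores))
  .selection_result("oner", scores, colnames(X)[ord],
                    list(n_bins = n_bins))
}

# symmetric uncertainty of two discrete vectors
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.sym_uncertainty <- function(a, b) {
  ha <- .entropy(table(a) / length(a))
  hb <- .entropy(table(b) / length(b))
  if (ha + hb == 0) return(0)
  hab <- .entropy(table(a, b) / length(a))
  2 * (ha + hb - hab) / (ha + hb)
}

# memoized correlation context for CFS
.cfs_context <- function(X, y, n_bins = 10L) {
  X <- .as_feature_matrix(X)
  y <- factor(y)
  disc <- apply(X, 2, .discretize, n_bins = n_bins)
  rcf <- vapply(seq_len(ncol(X)),
                function(j) .sym_uncertainty(disc[, j], y), numeric(1))
  names(rcf) <- colnames(X)
  env <- new.env(parent = emptyenv())
  rff <- function(i, j) {
    key <- paste0(min(i, j), ":", max(i, j))
    v <- env[[key]]
    if (is.null(v)) {
      v <- .sym_uncertainty(disc[, i], disc[, j])
      env[[key]] <- v
    }
    v
  }
  list(features = colnames(X), rcf = rcf, rff = rff)
}

.merit_from_context <- function(subset_idx, ctx) {
  k <- length(subset_idx)
  if (k == 0) return(-Inf)
  rcf <- mean(ctx$rcf[subset_idx])
  if (k == 1) return(rcf)
  s <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k)
    s <- s + ctx$rff(subset_idx[a], subset_idx[b])
  rff <- s / (k * (k - 1) / 2)
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' CFS merit of a feature subset
#'
#' Hall's correlation-based feature selection merit
#' \eqn{k \bar r_{cf} / \sqrt{k + k(k-1) \bar r_{ff}}} with feature-class
#' and feature-feature correlations measured by symmetric uncertainty on
#' equal-frequency-discretized variables. A zero-variance feature has zero
#' correlation with everything.
#'
#' @inheritParams relieff
#' @param subset character vector of feature names (non-empty).
#' @param n_bins discretization bins.
#' @return the merit (numeric scalar).
#' @export
cfs_merit <- function(subset, X, y, n_bins = 10L) {
  if (!length(subset)) stop("subset must be non-empty")
  ctx <- .cfs_context(X, y, n_bins)
  idx <- match(subset, ctx$features)
  if (anyNA(idx)) stop("unknown feature(s): ",
                       paste(subset[is.na(idx)], collapse = ", "))
  .merit_from_context(idx, ctx)
}

#' CFS with genetic search
#'
#' Bitmask genetic algorithm maximizing the CFS merit: tournament
#' selection (size 2), uniform crossover, per-bit mutation, elitism 1.
#' With elitism the best merit is non-decreasing across generations.
#' `generations = 0` returns the best subset of the random initial
#' population. Fully reproducible from `seed`.
#'
#' @inheritParams relieff
#' @param ga_params list with `pop_size` (50), `generations` (100),
#'   `crossover_p` (0.6), `mutation_p` (0.02), `seed` (required).
#' @param n_bins discretization bins.
#' @return a `plantloc_selection`; `weights` is the 0/1 membership vector
#'   and `params$merit` the achieved merit.
#' @export
cfs_ga_search <- function(X, y, ga_params = list(), n_bins = 10L) {
  gp <- utils::modifyList(list(pop_size = 50L, generations = 100L,
                               crossover_p = 0.6, mutation_p = 0.02,
                               seed = NULL), ga_params)
  if (is.null(gp$seed)) stop("cfs_ga_search requires ga_params$seed")
  ctx <- .cfs_context(X, y, n_bins)
  p <- length(ctx$features)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(gp$seed))
  pop <- matrix(stats::runif(gp$pop_size * p) < 0.5, gp$pop_size, p)
  fitness <- function(mask) .merit_from_context(which(mask), ctx)
  fit <- apply(pop, 1, fitness)
  for (g in seq_len(gp$generations)) {
    newpop <- matrix(FALSE, gp$pop_size, p)
    best <- which.max(fit)
    newpop[1, ] <- pop[best, ]      # elitism
    for (s in seq(2, gp$pop_size)) {
      pick <- function() {
        cand <- sample.int(gp$pop_size, 2)
        cand[which.max(fit[cand])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      child <- if (stats::runif(1) < gp$crossover_p) {
        m <- stats::runif(p) < 0.5
        ifelse(m, pa, pb)
      } else pa
      flip <- stats::runif(p) < gp$mutation_p
      child[flip] <- !child[flip]
      newpop[s, ] <- child
    }
    pop <- newpop
    fit <- apply(pop, 1, fitness)
  }
  best <- which.max(fit)
  mask <- pop[best, ]
  w <- as.numeric(mask)
  names(w) <- ctx$features
  .selection_result("cfs_ga", w, ctx$features[mask],
                    c(gp, list(merit = fit[best], n_bins = n_bins)))
}

#' Truncate a ranking-based selection to its top n features
#'
#' Ties are broken by schema (column) order.
#'
#' @param result a ranking `plantloc_selection` (relieff or oner).
#' @param n number of features to keep.
#' @return a truncated `plantloc_selection`.
#' @export
select_top <- function(result, n) {
  if (!inherits(result, "plantloc_selection"))
    stop("not a selection result")
  if (result$method == "cfs_ga")
    stop("select_top applies to ranking methods (relieff, oner)")
  if (n <= 0) stop("n must be >= 1")
  avail <- length(result$weights)
  if (n > avail) {
    warning("n = ", n, " exceeds ", avail, " features; keeping all")
    n <- avail
  }
  ord <- order(-result$weights, seq_along(result$weights))
  result$selected <- names(result$weights)[ord][seq_len(n)]
  result$params$top_n <- n
  result
}

#' Serialize a selection result to JSON
#'
#' @param result a `plantloc_selection`.
#' @param path output path.
#' @export
write_selection <- function(result, path) {
  jsonlite::write_json(
    list(method = result$method, params = result$params,
         weights = as.list(result$weights), selected = result$selected),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
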