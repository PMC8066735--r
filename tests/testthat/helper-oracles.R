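# Independent brute-force oracles for the descriptor and metric families.
# These are written as plain double loops over the definitions, sharing
# only the residue constant tables with the package, so they provide an
# implementation-independent check.

.oracle_props <- function() {
  h1 <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
          H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
          P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
          W = 0.81, Y = 0.26)
  h2 <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
          H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
          P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
          W = -3.4, Y = -2.3)
  m <- c(A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.1, G = 1.0,
         H = 81.1, I = 57.1, K = 72.1, L = 57.1, M = 75.1, N = 58.0,
         P = 41.1, Q = 72.0, R = 100.1, S = 31.0, T = 45.0, V = 43.1,
         W = 130.2, Y = 107.1)
  std <- function(v) (v - mean(v)) / sd(v)
  list(std(h1), std(h2), std(m))
}

# Chou type-I PseAAC by direct summation
oracle_pseaac_type1 <- function(s, lambda, w) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  props <- .oracle_props()
  theta <- numeric(lambda)
  for (k in 1:lambda) {
    acc <- 0
    for (i in 1:(L - k)) {
      t0 <- 0
      for (p in props) t0 <- t0 + (p[ch[i + k]] - p[ch[i]])^2 / 3
      acc <- acc + t0
    }
    theta[k] <- acc / (L - k)
  }
  f <- numeric(20); names(f) <- sort(unique(names(props[[1]])))
  for (a in names(f)) f[a] <- sum(ch == a) / L
  den <- sum(f) + w * sum(theta)
  unname(c(f / den, w * theta / den))
}

# serial (type-II) PseAAC: per-property product correlation factors
oracle_pseaac_serial <- function(s, lambda, w, nprops = 3) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  props <- .oracle_props()[seq_len(nprops)]
  tau <- numeric(0)
  for (k in 1:lambda) for (p in props) {
    acc <- 0
    for (i in 1:(L - k)) acc <- acc + p[ch[i]] * p[ch[i + k]]
    tau <- c(tau, acc / (L - k))
  }
  f <- numeric(20); names(f) <- sort(unique(names(props[[1]])))
  for (a in names(f)) f[a] <- sum(ch == a) / L
  den <- sum(f) + w * sum(tau)
  unname(c(f / den, w * tau / den))
}

# Geary autocorrelation coefficient by direct loops
oracle_geary <- function(s, prop, nlag) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  p <- (prop - mean(prop)) / sd(prop)
  x <- p[ch]
  xb <- mean(x)
  den <- sum((x - xb)^2)
  out <- numeric(nlag)
  for (k in 1:nlag) {
    if (den == 0) { out[k] <- 1; next }
    num <- 0
    for (i in 1:(L - k)) num <- num + (x[i] - x[i + k])^2
    out[k] <- ((L - 1) * num) / (2 * (L - k) * den)
  }
  out
}

# sequence-order-coupling numbers by direct double loop
oracle_socn <- function(s, dm, nlag) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  tau <- numeric(nlag)
  for (d in 1:nlag) {
    acc <- 0
    for (i in 1:(L - d)) acc <- acc + dm[ch[i], ch[i + d]]^2
    tau[d] <- acc
  }
  tau
}

# instability index: direct dipeptide-weight summation
oracle_instability <- function(s, diwv) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  acc <- 0
  for (i in 1:(L - 1)) acc <- acc + diwv[ch[i], ch[i + 1]]
  10 / L * acc
}

# Henderson-Hasselbalch net charge written out directly (EMBOSS pK set)
oracle_charge <- function(s, pH) {
  ch <- strsplit(s, "")[[1]]
  pk <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, H = 6.5,
          K = 10.8, R = 12.5, Y = 10.1)
  pos <- 1 / (1 + 10^(pH - pk["Nterm"]))
  for (a in c("K", "R", "H"))
    pos <- pos + sum(ch == a) / (1 + 10^(pH - pk[a]))
  neg <- 1 / (1 + 10^(pk["Cterm"] - pH))
  for (a in c("D", "E", "C", "Y"))
    neg <- neg + sum(ch == a) / (1 + 10^(pk[a] - pH))
  unname(pos - neg)
}

# isoelectric point by fine grid scan of the charge curve
oracle_pi_grid <- function(s, step = 0.001) {
  grid <- seq(0, 14, by = step)
  q <- vapply(grid, function(p) oracle_charge(s, p), numeric(1))
  grid[which.min(abs(q))]
}

# binary confusion metrics from expanded 0/1 vectors via table()
oracle_binary_metrics <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  acc <- mean(truth == pred)
  sn <- if (sum(truth == 1) > 0) mean(pred[truth == 1] == 1) else NA
  sp <- if (sum(truth == 0) > 0) mean(pred[truth == 0] == 0) else NA
  num <- as.numeric(tp) * tn - as.numeric(fp) * fn
  den <- sqrt(as.numeric(tp + fp)) * sqrt(tp + fn) * sqrt(tn + fp) *
    sqrt(tn + fn)
  mcc <- if (den == 0) 0 else num / den
  c(ACC = acc, Sn = sn, Sp = sp, MCC = mcc)
}

rel_err <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s < 1e-12, d, d / s)
}
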