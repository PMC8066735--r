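# shared fixtures: random sequences and small labeled feature tables

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# n random sequences with lengths uniform in [lo, hi], reproducible
random_sequences <- function(n, lo = 15, hi = 500, seed = 1) {
  set.seed(seed)
  lens <- sample(lo:hi, n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
}

# a small 2-class feature table: f_signal encodes the class (plus noise),
# f_noise is pure noise
toy_table <- function(n = 60, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  y <- rep(c("cytoplasm", "nucleus"), length.out = n)
  f_signal <- as.numeric(y == "nucleus") + rnorm(n, sd = noise_sd)
  f_noise <- runif(n)
  list(X = data.frame(f_signal = f_signal, f_noise = f_noise), y = y)
}

# 10-feature toy with 3 informative features and 7 noise features
planted_table <- function(n = 80, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  ind <- as.numeric(y == "b")
  X <- as.data.frame(matrix(runif(n * 10), n, 10,
                            dimnames = list(NULL, paste0("f", 1:10))))
  X$f1 <- ind + rnorm(n, sd = 0.1)
  X$f2 <- -ind + rnorm(n, sd = 0.1)
  X$f3 <- 2 * ind + rnorm(n, sd = 0.15)
  list(X = X, y = y, informative = c("f1", "f2", "f3"))
}

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
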