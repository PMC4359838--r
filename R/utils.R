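# internal helpers shared across modules

# x * log2(x) with the 0 log 0 = 0 convention
xlog2x <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  dim(out) <- dim(x)
  out
}

# Deterministic sub-seed derivation: every stage/candidate seed is a pure
# function of (master seed, tag string), kept below 2^31.
derive_seed <- function(seed, tag) {
  v <- utf8ToInt(as.character(tag))
  h <- sum(v * (seq_along(v) %% 97L + 1L)) %% 32452843
  as.integer((abs(as.numeric(seed)) %% 1e6 * 69991 + h * 131) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# row-normalize a nonnegative matrix (rows summing to 0 become uniform)
row_normalize <- function(m) {
  s <- rowSums(m)
  zero <- s <= 0
  if (any(zero)) {
    m[zero, ] <- 1
    s[zero] <- ncol(m)
  }
  m / s
}

stop_lantree <- function(msg, class) {
  stop(structure(class = c(class, "lantree_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# plug-in mutual information (bits) between all pairs of binary columns
empirical_mi_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p1 <- colMeans(X)
  p11 <- crossprod(X) / n
  p10 <- outer(p1, rep(1, length(p1))) - p11
  p01 <- t(p10)
  p00 <- 1 - p11 - p10 - p01
  term <- function(pab, pa, pb) {
    num <- pab
    den <- outer(pa, pb)
    out <- matrix(0, nrow(num), ncol(num))
    pos <- num > 0 & den > 0
    out[pos] <- num[pos] * log2(num[pos] / den[pos])
    out
  }
  mi <- term(p11, p1, p1) + term(p10, p1, 1 - p1) +
    term(p01, 1 - p1, p1) + term(p00, 1 - p1, 1 - p1)
  mi[mi < 0] <- 0
  diag(mi) <- 0
  dimnames(mi) <- list(colnames(X), colnames(X))
  mi
}
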