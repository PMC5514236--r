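# deterministic sub-seed derivation: mixes integer keys into [1, 2^31 - 2]
# via a multiplicative-congruential hash (all arithmetic stays below 2^53,
# so exact in doubles)
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647
  x <- 11
  for (k in keys) {
    x <- (x * 69069 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(x %% (m - 1) + 1)
}

# central finite difference of a vector/matrix-valued function,
# relative step `rel` with absolute floor `floor`
fd_step <- function(x, rel = 1e-5, floor = 1e-8) {
  max(abs(x) * rel, floor)
}

central_diff <- function(fn, x, i, rel = 1e-5, floor = 1e-8) {
  h <- fd_step(x[i], rel, floor)
  xp <- x; xp[i] <- x[i] + h
  xm <- x; xm[i] <- x[i] - h
  (fn(xp) - fn(xm)) / (2 * h)
}

# symmetrize and, if needed, clip eigenvalues to make a matrix PSD;
# returns list(mat, repaired)
nearest_psd <- function(m, eps = 1e-10) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  if (all(ev$values >= 0)) return(list(mat = m, repaired = FALSE))
  vals <- pmax(ev$values, eps)
  list(mat = ev$vectors %*% (vals * t(ev$vectors)), repaired = TRUE)
}

log_det_pd <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  2 * sum(log(diag(ch)))
}

# log determinant via LU: stays finite for near-singular PSD matrices
# (no underflow), -Inf when the determinant is not strictly positive
log_det <- function(m) {
  if (any(!is.finite(m))) return(-Inf)
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0 || !is.finite(d$modulus)) return(-Inf)
  as.numeric(d$modulus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
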