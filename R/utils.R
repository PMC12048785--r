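# internal numerical helpers

# log(sum(exp(x))) rows of a matrix, guarded against overflow
row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx + log(rowSums(exp(m - mx)))
}

# effects-coding basis: K x (K-1) matrix Z with u = Z %*% theta, colSums(Z) = 0.
# The last item's utility is minus the sum of the others.
effects_basis <- function(K) {
  rbind(diag(K - 1L), rep(-1, K - 1L))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# derive independent per-stage seeds from one user seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
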