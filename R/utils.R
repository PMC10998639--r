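# Small numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow; abs/arithmetic instead of pmax keeps
# it cheap on large dense matrices
softplus <- function(x) {
  a <- abs(x)
  0.5 * (x + a) + log1p(exp(-a))
}

# Row-wise softmax of a dense nodes x k matrix.
row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Index of the row-wise maximum, lowest index on ties (the tie rule used for
# label prediction and reliability agreement).
argmax_first <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  max.col(m, ties.method = "first")
}

# Squared column norms without densifying sparse input.
col_means_sds <- function(x) {
  n <- nrow(x)
  mu <- Matrix::colSums(x) / n
  ex2 <- Matrix::colSums(x^2) / n
  v <- pmax(ex2 - mu^2, 0)
  list(mean = as.numeric(mu), sd = sqrt(as.numeric(v)))
}

as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else x
}

stop_validation <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
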