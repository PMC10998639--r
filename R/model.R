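# Parallel VGAE building blocks: symmetric adjacency normalization, the
# two-layer GCN encoder, reparameterization, the four loss terms and the
# inner-product decoder. The exported functions are the reference
# definitions of each operation; the training loop in train.R uses an
# internal logits-stable fast path whose agreement with these definitions
# (and with naive dense oracles) is covered by the test suite.

#' Symmetrically normalized adjacency for GCN propagation
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree matrix of
#' `A + I`.
#'
#' @param a a `CellGraph` or symmetric sparse adjacency matrix.
#' @return A symmetric sparse matrix.
#' @export
normalize_adjacency <- function(a) {
  if (is(a, "CellGraph")) a <- a$adjacency
  n <- nrow(a)
  ai <- a + Matrix::Diagonal(n)
  dh <- 1 / sqrt(Matrix::rowSums(ai))
  Matrix::Diagonal(x = dh) %*% ai %*% Matrix::Diagonal(x = dh)
}

# Glorot-uniform weight initialization.
glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# The hidden GCN layer gets Glorot-uniform weights (ReLU needs the
# symmetry broken); the mu / log-sigma heads are plain linear maps and are
# zero-initialized. With Adam each parameter moves at most ~lr per step,
# so over a few hundred epochs the total movement is comparable to the
# Glorot scale of a head — random head initialization would have to be
# unlearned first, which slows convergence seed-dependently and, for the
# single-layer variant, contaminates the weights read out as
# peak-importance scores. Zero heads start at a uniform label indicator
# and learn signal only.
init_branch_params <- function(n_features, d, k, single_layer = FALSE) {
  if (single_layer) {
    list(W1 = NULL, Wmu = matrix(0, n_features, k),
         Wls = matrix(0, n_features, k))
  } else {
    list(W1 = glorot(n_features, d), Wmu = matrix(0, d, k),
         Wls = matrix(0, d, k))
  }
}

#' GCN encoder of one VGAE branch
#'
#' Two-layer form: `H = ReLU(Ahat X W1)`, `mu = Ahat H Wmu`,
#' `logsigma = Ahat H Wls` — a shared first layer feeding separate mean and
#' log-sd heads. The single-layer form maps the input directly to the
#' latent space: `mu = Ahat X Wmu`, `logsigma = Ahat X Wls`. No biases.
#'
#' @param ahat normalized adjacency ([normalize_adjacency()]).
#' @param x node feature matrix (nodes x features).
#' @param weights list with `W1`, `Wmu`, `Wls` (use `W1 = NULL` for the
#'   single-layer form).
#' @return List with dense `mu` and `logsigma` (nodes x k).
#' @export
encode <- function(ahat, x, weights) {
  ax <- ahat %*% x
  if (is.null(weights$W1)) {
    mu <- as_dense(ax %*% weights$Wmu)
    ls <- as_dense(ax %*% weights$Wls)
  } else {
    h <- pmax(as_dense(ax %*% weights$W1), 0)
    ah <- as_dense(ahat %*% h)
    mu <- ah %*% weights$Wmu
    ls <- ah %*% weights$Wls
  }
  if (any(!is.finite(mu)) || any(!is.finite(ls))) {
    stop("non-finite encoder output; check inputs/learning rate")
  }
  list(mu = mu, logsigma = ls)
}

#' Reparameterization draw
#'
#' `Z = exp(logsigma) * N + mu` with `N` standard normal. Pass `noise` for
#' an explicit draw, `seed` for a reproducible internal draw, or neither
#' for evaluation mode (`Z = mu`).
#'
#' @param mu,logsigma dense matrices of equal shape.
#' @param noise optional standard-normal matrix of the same shape.
#' @param seed optional seed for an internal draw.
#' @return Dense matrix `Z`.
#' @export
reparameterize <- function(mu, logsigma, noise = NULL, seed = NULL) {
  stopifnot(all(dim(mu) == dim(logsigma)))
  if (is.null(noise)) {
    if (is.null(seed)) return(mu)
    noise <- withr::with_seed(seed,
      matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
  }
  mu + exp(logsigma) * noise
}

#' KL divergence loss of the two VGAE branches
#'
#' `-1/2 * sum(1 + 2 log(sigma) - mu^2 - sigma^2)` over all latent entries
#' of both branches; with `mode = "mean"` (the default) each branch's sum
#' is divided by its node count so loss magnitudes are comparable across
#' dataset sizes.
#'
#' @param mu_h,sigma_h hybrid-branch mean and standard deviation
#'   (nodes x k; sigma, not log-sigma).
#' @param mu_atac,sigma_atac ATAC branch; omit to score a single branch.
#' @param mode `"mean"` (per-node) or `"sum"` (raw sum).
#' @return Non-negative scalar.
#' @export
kl_loss <- function(mu_h, sigma_h, mu_atac = NULL, sigma_atac = NULL,
                    mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  one <- function(mu, sg) {
    if (any(sg <= 0)) stop_validation("sigma must be positive")
    tot <- 0.5 * sum(mu^2 + sg^2 - 1 - 2 * log(sg))
    if (mode == "mean") tot / nrow(as.matrix(mu)) else tot
  }
  l <- one(mu_h, sigma_h)
  if (!is.null(mu_atac)) l <- l + one(mu_atac, sigma_atac)
  l
}

#' Anchor alignment loss
#'
#' Mean over anchors of the norm of the difference between the two latent
#' views of the same ATAC anchor cell: its row in the hybrid-branch latent
#' and its row in the ATAC-branch latent.
#'
#' @param z_h hybrid-branch latent (nodes x k).
#' @param z_atac ATAC-branch latent (n2 x k).
#' @param hybrid_rows,atac_rows equal-length index vectors: the hybrid node
#'   row and ATAC row of each anchor.
#' @param norm `"l2"` (Euclidean, default) or `"l1"`.
#' @return Non-negative scalar.
#' @export
alignment_loss <- function(z_h, z_atac, hybrid_rows, atac_rows,
                           norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  if (length(hybrid_rows) == 0L) stop_validation("empty anchor set")
  stopifnot(length(hybrid_rows) == length(atac_rows))
  diff <- z_h[hybrid_rows, , drop = FALSE] - z_atac[atac_rows, , drop = FALSE]
  per <- if (norm == "l2") sqrt(rowSums(diff^2)) else rowSums(abs(diff))
  mean(per)
}

#' Inner-product decoder
#'
#' `Ghat = sigmoid(Z Z')`: an N x N symmetric matrix of edge
#' probabilities in (0, 1).
#'
#' @param z_m merged latent matrix (nodes x k).
#' @return Dense N x N matrix.
#' @export
decode <- function(z_m) {
  z_m <- as.matrix(z_m)
  if (any(!is.finite(z_m))) stop_validation("non-finite latent matrix")
  sigmoid(tcrossprod(z_m))
}

#' Graph reconstruction loss (binary cross-entropy)
#'
#' Entry-wise BCE of the decoded edge probabilities against the merged
#' graph over all `N^2` entries. The default `"weighted"` mode applies the
#' standard VGAE class weighting — positives weighted by
#' `(N^2 - E) / E` and the total scaled by `N^2 / (2 (N^2 - E))` — because
#' unweighted BCE on a sparse graph is dominated by the empty entries.
#' `"unweighted"` is the plain mean over `N^2` entries.
#'
#' @param g binary adjacency (matrix or `CellGraph`).
#' @param g_hat decoded probabilities, same shape.
#' @param mode `"weighted"` or `"unweighted"`.
#' @param eps probabilities are clipped to `[eps, 1 - eps]` before logs.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(g, g_hat, mode = c("weighted", "unweighted"),
                                eps = 1e-7) {
  mode <- match.arg(mode)
  if (is(g, "CellGraph")) g <- g$adjacency
  g <- as_dense(g)
  g_hat <- as_dense(g_hat)
  stopifnot(all(dim(g) == dim(g_hat)))
  n2 <- length(g)
  e <- sum(g)
  p <- pmin(pmax(g_hat, eps), 1 - eps)
  if (mode == "weighted") {
    if (e == 0 || e == n2) stop_validation("degenerate graph for weighted BCE")
    pw <- (n2 - e) / e
    nrm <- n2 / (2 * (n2 - e))
  } else {
    pw <- 1
    nrm <- 1
  }
  nrm * sum(pw * g * (-log(p)) + (1 - g) * (-log(1 - p))) / n2
}

#' Reference-cell classification loss
#'
#' Cross-entropy of the softmax label indicator against the one-hot
#' reference labels, averaged over the `n1` reference cells. Target-cell
#' rows do not contribute.
#'
#' @param zhat_m label indicator matrix (N x k, rows sum to 1).
#' @param y one-hot matrix (n1 x k) of reference labels.
#' @param reference_indices rows of `zhat_m` holding the reference cells.
#' @return Scalar loss.
#' @export
classification_loss <- function(zhat_m, y, reference_indices) {
  stopifnot(length(reference_indices) == nrow(y))
  p <- zhat_m[reference_indices, , drop = FALSE]
  -sum(y * log(pmax(p, 1e-12))) / nrow(y)
}

#' Total training loss
#'
#' `L = L1 + L2 + lambda * L_ali + L_rna`.
#'
#' @param l1,l2,l_ali,l_rna component losses.
#' @param lambda alignment weight (default 1).
#' @return Scalar.
#' @export
total_loss <- function(l1, l2, l_ali, l_rna, lambda = 1) {
  stopifnot(is.finite(l1), is.finite(l2), is.finite(l_ali), is.finite(l_rna))
  l1 + l2 + lambda * l_ali + l_rna
}
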