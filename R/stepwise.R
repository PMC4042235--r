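# Stepwise-forward descriptor selection.
#
# Greedy forward search: starting from the empty set, each step adds the
# descriptor whose inclusion maximizes the leave-one-out cross-validated q2
# of the fitted linear model on the training set, stopping at the descriptor
# cap or when no addition improves q2. With as many latent components as
# descriptors PLS equals ordinary least squares, so during the search LOO q2
# is computed with the exact hat-matrix identity (PRESS residual
# e_i / (1 - h_ii)) instead of n refits.

# exact LOO q2 of an OLS fit with intercept
loo_q2_ols <- function(X, y) {
  X1 <- cbind(1, X)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1)) return(-Inf)           # redundant column: never preferred
  h <- rowSums(qr.Q(qrx)^2)
  if (any(h > 1 - 1e-10)) return(-Inf)
  e <- qr.resid(qrx, y)
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Stepwise-forward descriptor selection
#'
#' @param m descriptor_matrix.
#' @param train [split_spec()]; selection uses training compounds only.
#' @param max_descriptors cap on the number of descriptors in the final
#'   equation (default 4).
#' @return character vector of selected descriptor names (in selection
#'   order), with the per-step q2 trace in the `q2_trace` attribute. Ties
#'   are broken toward the lower column index, so the result is
#'   deterministic for a fixed matrix.
#' @export
stepwise_forward_select <- function(m, train, max_descriptors = 4L) {
  stopifnot(max_descriptors >= 1)
  tr <- training_matrix(m, train)
  X <- tr$X; y <- tr$y
  if (ncol(X) < 1) stop("no candidate descriptor columns")
  if (nrow(X) < max_descriptors + 2)
    stop("need at least max_descriptors + 2 training compounds (have ", nrow(X), ")")
  sel <- forward_select_matrix(X, y, max_descriptors)
  if (length(sel$selected) == 0) stop("no descriptor improves on the empty model")
  out <- colnames(X)[sel$selected]
  attr(out, "q2_trace") <- stats::setNames(sel$trace, out)
  out
}

# greedy core on raw matrices; returns integer column indices.
# Candidate scoring uses the exact rank-one update of the OLS fit: with Q an
# orthonormal basis of [1, X_selected], the model extended by column x has
# residual e = e_base - z (z'e_base)/|z|^2 and leverage h = h_base +
# z_i^2/|z|^2, where z = x - QQ'x. This scores all candidates with matrix
# products instead of one QR factorization each; the result is identical to
# loo_q2_ols per candidate.
forward_select_matrix <- function(X, y, max_descriptors) {
  n <- nrow(X)
  sst <- sum((y - mean(y))^2)
  selected <- integer(0)
  trace <- numeric(0)
  best_q2 <- -Inf
  while (length(selected) < max_descriptors) {
    base <- qr(cbind(1, X[, selected, drop = FALSE]))
    Q <- qr.Q(base)
    hB <- rowSums(Q^2)
    eB <- as.numeric(qr.resid(base, y))
    cand <- setdiff(seq_len(ncol(X)), selected)
    if (length(cand) == 0) break
    Xc <- X[, cand, drop = FALSE]
    Z <- Xc - Q %*% crossprod(Q, Xc)
    zn2 <- colSums(Z^2)
    inv <- ifelse(zn2 > 1e-10, 1 / zn2, 0)
    coefs <- as.numeric(crossprod(Z, eB)) * inv
    E <- eB - sweep(Z, 2, coefs, `*`)
    H <- hB + sweep(Z^2, 2, inv, `*`)
    bad <- zn2 <= 1e-10 | col_maxs(H) > 1 - 1e-10
    press <- colSums((E / (1 - H))^2)
    q2s <- 1 - press / sst
    q2s[bad] <- -Inf
    k <- which.max(q2s)                     # first max = lowest column index
    if (!(q2s[k] > best_q2 + 1e-12)) break  # no improvement: stop early
    best_q2 <- q2s[k]
    selected <- c(selected, cand[k])
    trace <- c(trace, best_q2)
  }
  list(selected = selected, trace = trace)
}

col_maxs <- function(M) apply(M, 2, max)
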