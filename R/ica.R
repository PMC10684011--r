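#' Fixed-point independent component analysis
#'
#' Compact symmetric fixed-point ICA with the tanh contrast: rows of `x`
#' are centred and whitened (PCA), an orthogonal unmixing matrix is
#' estimated by fixed-point iteration with symmetric decorrelation, and
#' the mixing matrix is recovered for back-projection. Deterministic for
#' a fixed seed.
#'
#' @param x Numeric matrix, channels x samples.
#' @param n_comp Number of components (default: number of channels).
#' @param seed RNG seed for the orthogonal initialisation.
#' @param maxit,tol Iteration controls.
#' @param attempts Re-initialisations tried on non-convergence.
#' @param on_fail `"warn"`: after all attempts, return the best iterate
#'   seen with a warning (non-Gaussianity can be rotationally flat on
#'   noise-dominated subspaces, where the fixed point has no attractor);
#'   `"error"`: fail instead.
#' @return List: `S` (components x samples source estimates), `A`
#'   (channels x components mixing), `W` (components x channels
#'   unmixing), `center`, `converged`.
#' @export
fast_ica <- function(x, n_comp = nrow(x), seed = 1, maxit = 200,
                     tol = 1e-4, attempts = 3, on_fail = c("warn", "error")) {
  on_fail <- match.arg(on_fail)
  x <- as.matrix(x)
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  n_comp <- min(n_comp, sum(pos))
  K <- diag(1 / sqrt(eg$values[seq_len(n_comp)]), n_comp) %*%
    t(eg$vectors[, seq_len(n_comp), drop = FALSE])
  z <- K %*% xc
  n <- ncol(z)
  sym_decor <- function(w) {
    s <- eigen(tcrossprod(w), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), n_comp) %*%
      t(s$vectors) %*% w
  }
  converged <- FALSE
  best_w <- NULL; best_delta <- Inf
  for (att in seq_len(attempts)) {
    set.seed(seed + att - 1)
    w <- sym_decor(matrix(stats::rnorm(n_comp^2), n_comp))
    for (it in seq_len(maxit)) {
      wz <- w %*% z
      g <- tanh(wz)
      gp <- rowMeans(1 - g^2)
      w1 <- sym_decor(tcrossprod(g, z) / n - gp * w)
      delta <- max(abs(abs(rowSums(w1 * w)) - 1))
      w <- w1
      if (delta < best_delta) { best_delta <- delta; best_w <- w }
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) break
  }
  if (!converged) {
    if (on_fail == "error")
      stop("ICA failed to converge after ", attempts, " initialisations")
    warning("ICA did not reach tol = ", tol, " after ", attempts,
            " initialisations; using the best iterate (delta = ",
            signif(best_delta, 3), ")")
    w <- best_w
  }
  W <- w %*% K                                   # components x channels
  A <- t(W) %*% solve(tcrossprod(W))             # channels x components
  list(S = W %*% xc, A = A, W = W, center = ctr, converged = converged)
}
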