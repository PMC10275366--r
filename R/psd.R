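## Nearest-positive-semidefinite repair of a correlation matrix by iterated
## eigenvalue clipping (floor eigenvalues at `tol`) and rescaling to a unit
## diagonal.  Returns the repaired matrix; callers decide whether the
## perturbation is acceptable.
nearest_psd <- function(R, tol = 1e-8, maxit = 200L) {
  X <- (R + t(R)) / 2
  for (i in seq_len(maxit)) {
    e <- eigen(X, symmetric = TRUE)
    if (min(e$values) >= -tol) break
    vals <- pmax(e$values, tol)
    X <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(X))
    X <- X / (d %o% d)
    X <- (X + t(X)) / 2
  }
  diag(X) <- 1
  dimnames(X) <- dimnames(R)
  X
}
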