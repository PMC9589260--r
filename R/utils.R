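# internal numeric helpers

#' Numerically stable logistic sigmoid
#'
#' Computes `1 / (1 + exp(-x))` elementwise without overflow for large
#' negative arguments.
#'
#' @param x Numeric vector, matrix or array of finite values.
#' @return Object of the same shape with entries in `[0, 1]`.
#' @export
#' @examples
#' sigmoid(0)            # 0.5
#' sigmoid(c(-5, 5))     # sums to 1
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# inverse sigmoid; input must lie strictly inside (0, 1)
logit <- function(p) log(p) - log1p(-p)

# map a matrix affinely into (eps, 1 - eps); constant matrices map to 0.5
squash_unit <- function(m, eps = 1e-4) {
  mn <- min(m)
  mx <- max(m)
  if (mx - mn < .Machine$double.eps) {
    return(array(0.5, dim = dim(m)))
  }
  eps + (1 - 2 * eps) * (m - mn) / (mx - mn)
}

# Moore-Penrose least squares solve for Z minimizing ||T - Z H||_F^2
ls_right_solve <- function(T, H, ridge = 1e-10) {
  G <- H %*% t(H)
  diag(G) <- diag(G) + ridge * mean(diag(G))
  T %*% t(H) %*% solve(G)
}

# least squares solve for H minimizing ||T - Z H||_F^2
ls_left_solve <- function(Z, T, ridge = 1e-10) {
  G <- crossprod(Z)
  diag(G) <- diag(G) + ridge * mean(diag(G))
  solve(G, crossprod(Z, T))
}

frob2 <- function(m) sum(m * m)

# deterministic sign convention for an SVD: the entry of largest magnitude
# in each right singular vector is made positive
fix_svd_signs <- function(sv) {
  for (j in seq_len(ncol(sv$v))) {
    v <- sv$v[, j]
    m <- which.max(abs(v))
    if (v[m] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  sv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# formats doubles so that read-back is bit-identical
format_full <- function(x) sprintf("%.17g", x)

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("pdjdsnmf_validation_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("pdjdsnmf_numeric_error", "error")))
}
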