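# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort warn inform .data
#' @importFrom stats optim setNames lm coef sd
#' @importFrom utils head tail modifyList
#' @importFrom Rcpp sourceCpp
#' @useDynLib polarflux, .registration = TRUE
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# numeric tolerance used for "strictly positive flux" style comparisons
FLUX_TOL <- 1e-9

# nullspace of a matrix via SVD; returns a matrix whose columns span ker(A)
nullspace <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  s <- svd(A, nu = 0, nv = ncol(A))
  rank <- sum(s$d > tol * max(s$d, 1))
  if (rank == ncol(A)) {
    matrix(numeric(0), nrow = ncol(A), ncol = 0)
  } else {
    s$v[, (rank + 1L):ncol(A), drop = FALSE]
  }
}

mat_rank <- function(A, tol = 1e-10) {
  if (length(A) == 0L || nrow(A) == 0L || ncol(A) == 0L) return(0L)
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > tol * max(d, 1))
}

# scale a flux vector so its largest absolute entry is 1
normalize_mode <- function(v) {
  m <- max(abs(v))
  if (m == 0) v else v / m
}

# constrained least squares: min ||t(A) %*% w - b||^2, w >= 0, optionally sum(w) = 1.
# A has one row per candidate point, columns = coordinates. Solved with
# quadprog; a tiny ridge keeps D positive definite when points are affinely
# dependent. Returns list(w, fitted, residual).
convex_lsq <- function(A, b, sum_to_one = TRUE, ridge = 1e-10) {
  n <- nrow(A)
  D <- A %*% t(A) + diag(ridge, n)
  d <- as.numeric(A %*% b)
  Amat <- if (sum_to_one) cbind(rep(1, n), diag(n)) else diag(n)
  bvec <- if (sum_to_one) c(1, rep(0, n)) else rep(0, n)
  meq <- if (sum_to_one) 1L else 0L
  sol <- quadprog::solve.QP(D, d, Amat, bvec, meq = meq)
  w <- pmax(sol$solution, 0)
  if (sum_to_one && sum(w) > 0) w <- w / sum(w)
  fitted <- as.numeric(t(A) %*% w)
  list(w = w, fitted = fitted, residual = sqrt(sum((b - fitted)^2)))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
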