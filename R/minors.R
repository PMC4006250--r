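# Minors of (sI - K) evaluated at real or complex arguments. Tridiagonal
# corner minors use the three-term continuant recurrences; everything else
# goes through a dense complex LU determinant (base `det()` is real-only).

cdet <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(1 + 0i)
  A <- matrix(as.complex(A), n, n)
  d <- 1 + 0i
  for (k in seq_len(max(n - 1L, 0L))) {
    idx <- k:n
    p <- idx[which.max(Mod(A[idx, k]))]
    if (Mod(A[p, k]) == 0) return(0 + 0i)
    if (p != k) {
      A[c(k, p), ] <- A[c(p, k), ]
      d <- -d
    }
    piv <- A[k, k]
    d <- d * piv
    if (k < n) {
      rows <- (k + 1L):n
      A[rows, ] <- A[rows, ] - outer(A[rows, k] / piv, A[k, ])
    }
  }
  d * A[n, n]
}

#' Minor evaluator for the shifted inner rate matrix
#'
#' Evaluates the \eqn{(i, j)}-minor of \eqn{sI - \tilde K} (the determinant
#' of the submatrix after deleting row `i` and column `j`) at arbitrary real
#' or complex `s`. For a tridiagonal inner matrix the two corner minors
#' \eqn{M_{1,1}} and \eqn{M_{m,m}} -- the ones entering the first-return
#' CDFs -- are computed by the three-term continuant recurrence; any other
#' request (bypass systems) uses direct determinant evaluation.
#'
#' @param K an `inner_rate_matrix` or a plain square matrix.
#' @param i,j row and column to delete (1-based).
#' @return A `minor_evaluator`; call [minor_eval()] on it.
#' @export
minor_evaluator <- function(K, i, j) {
  M <- if (inherits(K, "inner_rate_matrix")) K$matrix else K
  m <- nrow(M)
  stopifnot(i >= 1L, i <= m, j >= 1L, j <= m)
  tri <- all(M[abs(row(M) - col(M)) > 1L] == 0)
  corner <- if (tri && i == 1L && j == 1L) "11"
    else if (tri && i == m && j == m) "mm"
    else "general"
  structure(list(matrix = M, i = i, j = j, corner = corner, m = m),
            class = "minor_evaluator")
}

#' @rdname minor_evaluator
#' @param ev a `minor_evaluator`.
#' @param s evaluation point (real or complex scalar).
#' @export
minor_eval <- function(ev, s) {
  stopifnot(inherits(ev, "minor_evaluator"), length(s) == 1L, is.finite(Re(s)))
  M <- ev$matrix
  m <- ev$m
  if (m == 1L) return(1 + 0i)      # empty determinant convention
  if (ev$corner == "11") {
    # trailing continuant over indices 2..m of A = sI - K
    q2 <- 0 + 0i; q1 <- 1 + 0i     # q_{i+2}, q_{i+1}
    for (i in m:2) {
      qi <- (s - M[i, i]) * q1 -
        (if (i < m) (-M[i, i + 1]) * (-M[i + 1, i]) * q2 else 0)
      q2 <- q1; q1 <- qi
    }
    return(q1)
  }
  if (ev$corner == "mm") {
    p0 <- 1 + 0i; pm1 <- 0 + 0i    # p_{i-1}, p_{i-2}
    for (i in seq_len(m - 1L)) {
      pi_ <- (s - M[i, i]) * p0 -
        (if (i > 1L) (-M[i - 1, i]) * (-M[i, i - 1]) * pm1 else 0)
      pm1 <- p0; p0 <- pi_
    }
    return(p0)
  }
  A <- diag(m) * s - M
  cdet(A[-ev$i, -ev$j, drop = FALSE])
}
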