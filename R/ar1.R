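#' Separable AR1 x AR1 plot correlation
#'
#' First-order autoregressive correlation in the row and column directions
#' of a field grid: plots at row-lag a and column-lag b have correlation
#' `rho_row^a * rho_col^b`. The object is a structured operator - dense
#' materialisation, solves and log-determinants exploit the Kronecker
#' factorisation (the AR1 inverse is tridiagonal), so large grids never
#' require a dense inverse.
#'
#' @param rho_row,rho_col Autocorrelations, `abs(rho) < 1`.
#' @param rows,columns Grid dimensions.
#' @return An object of class `ar1_kron` with fields `rho_row`, `rho_col`,
#'   `rows`, `columns`.
#' @export
ar1_kron_correlation <- function(rho_row, rho_col, rows, columns) {
  stopifnot(abs(rho_row) < 1, abs(rho_col) < 1, rows >= 1, columns >= 1)
  structure(list(rho_row = rho_row, rho_col = rho_col,
                 rows = as.integer(rows), columns = as.integer(columns)),
            class = "ar1_kron")
}

#' Dense AR1 correlation matrix
#' @param rho Autocorrelation, `abs(rho) < 1`.
#' @param n Dimension.
#' @return n x n matrix with entries `rho^|i-j|`.
#' @export
ar1_matrix <- function(rho, n) {
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

# derivative of the dense AR1 matrix wrt rho
ar1_matrix_deriv <- function(rho, n) {
  idx <- seq_len(n)
  lag <- abs(outer(idx, idx, "-"))
  d <- lag * rho^pmax(lag - 1, 0)
  d[lag == 0] <- 0
  d
}

# tridiagonal inverse of the AR1 correlation matrix
ar1_inverse <- function(rho, n) {
  if (n == 1L) return(matrix(1, 1, 1))
  main <- c(1, rep(1 + rho^2, n - 2L), 1)
  Ri <- diag(main)
  for (i in seq_len(n - 1L)) {
    Ri[i, i + 1L] <- -rho
    Ri[i + 1L, i] <- -rho
  }
  Ri / (1 - rho^2)
}

#' Operations on the AR1 x AR1 operator
#'
#' `ar1_kron_dense()` materialises the plot x plot correlation (plots in
#' column-major grid order, row index fastest); `ar1_kron_solve()` applies
#' the inverse to a vector or matrix; `ar1_kron_logdet()` returns the exact
#' log-determinant.
#'
#' @param op An `ar1_kron` operator.
#' @param x Vector/matrix of length `rows * columns` (grid in column-major
#'   order).
#' @return Dense matrix, solved vector/matrix, or scalar log-determinant.
#' @export
ar1_kron_dense <- function(op) {
  kronecker(ar1_matrix(op$rho_col, op$columns), ar1_matrix(op$rho_row, op$rows))
}

#' @rdname ar1_kron_dense
#' @export
ar1_kron_solve <- function(op, x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == op$rows * op$columns)
  Rr <- ar1_inverse(op$rho_row, op$rows)
  Rc <- ar1_inverse(op$rho_col, op$columns)
  out <- apply(x, 2, function(v) {
    V <- matrix(v, op$rows, op$columns)
    as.vector(Rr %*% V %*% t(Rc))
  })
  matrix(out, nrow = op$rows * op$columns)
}

#' @rdname ar1_kron_dense
#' @export
ar1_kron_logdet <- function(op) {
  op$columns * (op$rows - 1L) * log(1 - op$rho_row^2) +
    op$rows * (op$columns - 1L) * log(1 - op$rho_col^2)
}
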