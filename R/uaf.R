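# Universal activation function (UAF): a five-parameter smooth function
# able to morph between standard activations. Each neuron owns one
# parameter row (A, B, C, D, E); with A = 1, B = C = 0, D = -1, E = 0 the
# function is exactly the identity.

# overflow-safe softplus and logistic
.softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
.logistic <- function(z) stats::plogis(z)

#' Universal activation function (scalar form)
#'
#' Computes `ln(1 + exp(A (x + B) - |C| x^2)) - ln(1 + exp(D (x - B))) + E`
#' with an overflow-safe softplus, so the result is finite for any finite
#' input and parameters.
#'
#' @param x input value(s).
#' @param A,B,C,D,E activation parameters (recycled against `x`).
#' @return activation output, same shape as `x`.
#' @export
uaf <- function(x, A, B, C, D, E) {
  z1 <- A * (x + B) - abs(C) * x^2
  z2 <- D * (x - B)
  .softplus(z1) - .softplus(z2) + E
}

#' Universal activation function applied row-wise to a state matrix
#'
#' Row `i` of `X` goes through the UAF with parameter row `i` of `C_eff`.
#' `X` may be a vector (one value per neuron) or an `N x B` matrix whose
#' columns are independent samples.
#'
#' @param X numeric vector of length `N` or `N x B` matrix.
#' @param C_eff `N x 5` parameter matrix with columns A, B, C, D, E.
#' @return object of the same shape as `X`.
#' @export
uaf_vector <- function(X, C_eff) {
  n <- if (is.matrix(X)) nrow(X) else length(X)
  if (nrow(C_eff) != n) stop("uaf_vector: C_eff rows must match X length")
  # per-row parameters recycle down columns for matrix X
  uaf(X, C_eff[, 1L], C_eff[, 2L], C_eff[, 3L], C_eff[, 4L], C_eff[, 5L])
}

#' Partial derivatives of the universal activation function
#'
#' Closed-form derivatives with respect to the input and each of the five
#' parameters, using the logistic of each softplus argument. The
#' subgradient of `|C|` at `C = 0` is taken as 0.
#'
#' @inheritParams uaf
#' @return list of numeric objects `dx`, `dA`, `dB`, `dC`, `dD`, `dE`,
#'   each the shape of `x`.
#' @export
uaf_gradients <- function(x, A, B, C, D, E) {
  z1 <- A * (x + B) - abs(C) * x^2
  z2 <- D * (x - B)
  s1 <- .logistic(z1)
  s2 <- .logistic(z2)
  list(dx = s1 * (A - 2 * abs(C) * x) - s2 * D,
       dA = s1 * (x + B),
       dB = s1 * A + s2 * D,
       dC = -s1 * sign(C) * x^2,
       dD = -s2 * (x - B),
       dE = x * 0 + 1)
}

# Row-parameterized gradients for an N x B state matrix.
.uaf_grad_mat <- function(X, C_eff) {
  uaf_gradients(X, C_eff[, 1L], C_eff[, 2L], C_eff[, 3L],
                C_eff[, 4L], C_eff[, 5L])
}

#' Identity UAF parameter rows
#'
#' @param n number of rows.
#' @return `n x 5` matrix of (1, 0, 0, -1, 0) rows: the exact identity.
#' @export
uaf_identity_params <- function(n) {
  matrix(rep(c(1, 0, 0, -1, 0), each = n), n, 5L,
         dimnames = list(NULL, c("A", "B", "C", "D", "E")))
}
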