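# Internal helpers: polynomial arithmetic (ascending coefficients) and
# small conveniences shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate a polynomial with ascending coefficients
#' @param coef numeric vector c(a0, a1, ..., an) for a0 + a1*x + ... + an*x^n
#' @param x evaluation points
#' @return numeric vector of p(x)
#' @keywords internal
poly_eval <- function(coef, x) {
  out <- rep(coef[length(coef)], length(x))
  if (length(coef) > 1L) {
    for (j in (length(coef) - 1L):1L) out <- out * x + coef[j]
  }
  out
}

# derivative of an ascending-coefficient polynomial
poly_deriv <- function(coef) {
  n <- length(coef)
  if (n <= 1L) return(0)
  coef[-1L] * seq_len(n - 1L)
}

# real roots of the polynomial, dropping numerically-zero leading coefficients
poly_real_roots <- function(coef, imag_tol = 1e-8) {
  scale <- max(abs(coef), 1e-300)
  keep <- which(abs(coef) / scale > 1e-12)
  if (length(keep) == 0L) return(numeric(0))
  coef <- coef[seq_len(max(keep))]
  if (length(coef) <= 1L) return(numeric(0))
  z <- polyroot(coef)
  Re(z[abs(Im(z)) <= imag_tol * pmax(1, abs(Re(z)))])
}

poly_mul <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    idx <- i + seq_along(q) - 1L
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

# substitute x -> c0 + c1 * t into p(x); returns coefficients in t.
# Used to report fits done on conditioned abscissae in the original
# frame-index basis.
poly_affine_subst <- function(coef, c0, c1) {
  out <- numeric(1)
  out[1] <- coef[1]
  pw <- 1
  for (j in seq_along(coef)[-1L]) {
    pw <- poly_mul(pw, c(c0, c1))
    term <- coef[j] * pw
    if (length(term) > length(out)) out <- c(out, numeric(length(term) - length(out)))
    out[seq_along(term)] <- out[seq_along(term)] + term
  }
  out
}

# number of sign changes of a vector, ignoring zeros
n_sign_changes <- function(x, tol = 1e-12) {
  s <- sign(x)
  s <- s[abs(x) > tol]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}
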