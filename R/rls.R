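#' Initialize the RLS inverse-correlation matrix
#'
#' Returns `P(0) = I / alpha`, the starting value of the running estimate of
#' the inverse regularized rate-correlation matrix
#' `P(t) = (alpha I + sum_s r_s r_s^T)^{-1}`. `alpha` acts as a ridge
#' regularizer and as an inverse learning rate.
#'
#' @param alpha Regularization constant, strictly positive.
#' @param n Matrix dimension.
#' @return An n x n numeric matrix.
#' @export
init_P <- function(alpha, n) {
  check_that(is.numeric(alpha) && length(alpha) == 1L && alpha > 0,
             sprintf("alpha must be a positive scalar, got %s",
                     paste(alpha, collapse = ",")))
  diag(1 / alpha, as.integer(n))
}

# shared rank-one Sherman-Morrison downdate; also used per-neuron so that
# the full-connectivity A^i recursion agrees with the shared P bit-for-bit
rank_one_update <- function(P, r) {
  Pr <- as_num(P %*% r)
  denom <- 1 + sum(r * Pr)
  P <- P - tcrossprod(Pr) / denom
  (P + t(P)) / 2  # enforce symmetry against drift
}

#' Rank-one RLS update of the inverse-correlation matrix
#'
#' Applies the Sherman-Morrison downdate
#' `P' = P - (P r)(P r)^T / (1 + r^T P r)`, equivalent to
#' `(P^{-1} + r r^T)^{-1}`. The result is symmetrized to suppress
#' floating-point drift.
#'
#' @param P Symmetric positive-definite matrix.
#' @param r Rate (feature) vector of matching length.
#' @return The updated matrix.
#' @export
rls_update_P <- function(P, r) {
  check_that(all(is.finite(P)) && all(is.finite(r)),
             "non-finite values in RLS update")
  check_that(length(r) == nrow(P) && nrow(P) == ncol(P),
             sprintf("P is %dx%d but r has length %d",
                     nrow(P), ncol(P), length(r)))
  rank_one_update(P, as_num(r))
}

#' A-priori readout error
#'
#' The error `e_-(t) = z(t) - f_out(t)` between the readout computed with the
#' pre-update weights and the target, per output dimension. With this sign
#' convention the minus sign in the weight update reduces the error.
#'
#' @param z Readout vector.
#' @param f_out_t Target vector of the same length.
#' @return Numeric error vector.
#' @export
compute_error <- function(z, f_out_t) {
  check_that(length(z) == length(f_out_t),
             sprintf("readout has length %d but target has length %d",
                     length(z), length(f_out_t)))
  as_num(z) - as_num(f_out_t)
}

#' Delta-rule update of the readout weights
#'
#' Applies `w_out(t) = w_out(t - dt) - (P r) e_-^T`: the pseudogradient
#' `-e_-(t) P(t) r(t)` with the already-updated `P` acting as a
#' direction-dependent learning rate. A single `P` is shared across output
#' dimensions; multi-dimensional targets use the outer product form.
#'
#' @param w_out N x M_out readout matrix.
#' @param e_minus Error vector of length M_out ([compute_error()]).
#' @param P N x N inverse-correlation matrix, updated with `r` this step.
#' @param r Rate vector of length N.
#' @return The updated readout matrix.
#' @export
update_output_weights <- function(w_out, e_minus, P, r) {
  check_that(nrow(w_out) == length(r) && ncol(w_out) == length(e_minus),
             sprintf("w_out is %dx%d but r has length %d and e has length %d",
                     nrow(w_out), ncol(w_out), length(r), length(e_minus)))
  w_out - tcrossprod(as_num(P %*% r), as_num(e_minus))
}

#' Initialize the per-neuron inverse-correlation family
#'
#' For recurrent-weight training each neuron i keeps its own matrix `A^i`
#' over its presynaptic set `B(i)` (the TRUE entries of column i of the
#' mask), initialized to `I / alpha`.
#'
#' @param alpha Regularizer.
#' @param mask N x N logical connectivity mask, `[j, i]` TRUE iff j is
#'   presynaptic to i.
#' @return List with elements `A` (list of |B(i)| x |B(i)| matrices, NULL for
#'   isolated neurons) and `pre` (list of presynaptic index vectors).
#' @export
init_A_family <- function(alpha, mask) {
  N <- ncol(mask)
  pre <- lapply(seq_len(N), function(i) which(mask[, i]))
  A <- lapply(pre, function(b) if (length(b) > 0L) init_P(alpha, length(b)) else NULL)
  list(A = A, pre = pre)
}

#' Per-neuron RLS update of the recurrent weights
#'
#' For a scalar output, each neuron i's incoming weights are trained with its
#' own rank-one recursion restricted to the presynaptic set `B(i)`:
#' `A^i` is downdated with `r[B(i)]`, then
#' `w_R[j, i] <- w_R[j, i] - e_- * (A^i r[B(i)])_j` for `j in B(i)`.
#' Entries outside the mask are never touched. The `A^i` recursion itself is
#' error-independent, so it runs even when `e_minus` is zero.
#'
#' @param w_R N x N recurrent weight matrix.
#' @param A_family Family from [init_A_family()].
#' @param e_minus Scalar a-priori error (recurrent training supports scalar
#'   outputs only).
#' @param r Length-N rate vector.
#' @return List with updated `w_R` and `A_family`.
#' @export
update_recurrent_weights <- function(w_R, A_family, e_minus, r) {
  check_that(length(e_minus) == 1L,
             "recurrent FORCE training supports scalar outputs only")
  check_that(length(A_family$A) == ncol(w_R),
             "A family size does not match w_R")
  e <- as.numeric(e_minus)
  for (i in seq_along(A_family$A)) {
    b <- A_family$pre[[i]]
    if (length(b) == 0L) next
    rb <- r[b]
    A <- rank_one_update(A_family$A[[i]], rb)
    A_family$A[[i]] <- A
    w_R[b, i] <- w_R[b, i] - e * as_num(A %*% rb)
  }
  list(w_R = w_R, A_family = A_family)
}
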