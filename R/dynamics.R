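# Vectorised right-hand side and Jacobian of the energy-scaled circuit.
#
#   dx1/dt = lam * a1 * x1^n / (ta1^n + x1^n)
#          + lam * b1 * tb1^n / (tb1^n + x2^n) - k1 * x1
#   dx2/dt = symmetric with indices swapped.
#
# The activation Hill term at x = 0 is taken as its limit value 0 for every
# n >= 1 (x^n with x = 0, n >= 1 evaluates to 0, so no special-casing is
# needed).  Its derivative at 0 is 0 for n > 1 and a/theta_a for n = 1;
# R's 0^0 == 1 makes the closed-form derivative below cover both cases.

.rhs_vec <- function(x1, x2, p, lam) {
  n <- p$n
  f1 <- lam * p$a1 * x1^n / (p$theta_a1^n + x1^n) +
    lam * p$b1 * p$theta_b1^n / (p$theta_b1^n + x2^n) - p$k1 * x1
  f2 <- lam * p$a2 * x2^n / (p$theta_a2^n + x2^n) +
    lam * p$b2 * p$theta_b2^n / (p$theta_b2^n + x1^n) - p$k2 * x2
  list(f1 = f1, f2 = f2)
}

# Entries of the 2x2 Jacobian, vectorised over states.
# d/dx [a x^n / (t^n + x^n)]   =  a n t^n x^(n-1) / (t^n + x^n)^2
# d/dx [b t^n / (t^n + x^n)]   = -b n t^n x^(n-1) / (t^n + x^n)^2
.jac_vec <- function(x1, x2, p, lam) {
  n <- p$n
  dact <- function(x, a, th) {
    lam * a * n * th^n * x^(n - 1) / (th^n + x^n)^2
  }
  drep <- function(x, b, th) {
    -lam * b * n * th^n * x^(n - 1) / (th^n + x^n)^2
  }
  list(j11 = dact(x1, p$a1, p$theta_a1) - p$k1,
       j12 = drep(x2, p$b1, p$theta_b1),
       j21 = drep(x1, p$b2, p$theta_b2),
       j22 = dact(x2, p$a2, p$theta_a2) - p$k2)
}

#' Time derivatives of the energy-scaled toggle switch
#'
#' Evaluates the governing ODE right-hand side at a state `(x1, x2)`.  Both
#' production terms (conditional self-activation and repressible constitutive
#' expression) are multiplied by the energy scaling factor `lam`; degradation
#' is energy-independent.
#'
#' @param state numeric vector `c(x1, x2)` of non-negative protein levels, or
#'   an m x 2 matrix of states.
#' @param params a [regulatory_params()] object.
#' @param lam energy scaling factor, `lam >= 0` (see [lambda_energy()]).
#' @return numeric vector `c(dx1, dx2)` (or m x 2 matrix), in
#'   concentration/time.
#' @examples
#' toggle_rhs(c(0, 0), regulatory_params(), lam = 1)      # c(1, 1)
#' toggle_rhs(c(0.5, 0.5), regulatory_params(), lam = 1)  # c(0.5, 0.5)
#' @export
toggle_rhs <- function(state, params, lam) {
  stopifnot(inherits(params, "regulatory_params"),
            is.finite(lam), lam >= 0)
  st <- as_state_matrix(state)
  if (any(st < 0)) stop("state components must be non-negative", call. = FALSE)
  f <- .rhs_vec(st[, 1], st[, 2], params, lam)
  out <- cbind(f$f1, f$f2)
  colnames(out) <- c("dx1", "dx2")
  if (is.null(dim(state))) drop(out) else out
}

#' Analytic Jacobian of the toggle-switch dynamics
#'
#' Partial derivatives of [toggle_rhs()] with respect to `(x1, x2)`.  The
#' diagonal combines the self-activation slope with `-k_i`; the off-diagonal
#' entries are the (always non-positive) repression-term derivatives.  At
#' `x = 0` the activation derivative is 0 for `n > 1` and `a / theta_a` for
#' `n = 1` (the limit convention).
#'
#' @inheritParams toggle_rhs
#' @return a 2 x 2 numeric matrix with entry `[i, j] = d(dxi/dt) / dxj`.
#' @export
toggle_jacobian <- function(state, params, lam) {
  stopifnot(inherits(params, "regulatory_params"),
            is.finite(lam), lam >= 0)
  st <- as_state_matrix(state)
  if (nrow(st) != 1L) stop("toggle_jacobian expects a single state", call. = FALSE)
  if (any(st < 0)) stop("state components must be non-negative", call. = FALSE)
  j <- .jac_vec(st[, 1], st[, 2], params, lam)
  matrix(c(j$j11, j$j21, j$j12, j$j22), 2, 2)
}

as_state_matrix <- function(state) {
  if (is.matrix(state)) {
    stopifnot(ncol(state) == 2L)
    st <- state
  } else {
    stopifnot(is.numeric(state), length(state) == 2L)
    st <- matrix(state, 1L, 2L)
  }
  if (any(!is.finite(st))) stop("state must be finite", call. = FALSE)
  st
}

# Real parts of the eigenvalues of the 2x2 Jacobian, vectorised: for each
# state, tr/2 +/- sqrt(disc) with complex pairs contributing Re = tr/2.
# Returns the largest real part per state.
.leading_re_vec <- function(x1, x2, p, lam) {
  j <- .jac_vec(x1, x2, p, lam)
  tr <- j$j11 + j$j22
  det <- j$j11 * j$j22 - j$j12 * j$j21
  disc <- tr * tr / 4 - det
  re <- tr / 2
  pos <- disc > 0
  re[pos] <- re[pos] + sqrt(disc[pos])
  re
}

# Upper bound on steady-state protein levels: x_i <= lam * (a_i + b_i) / k_i.
x_max_bound <- function(params, lam) {
  max(lam * (params$a1 + params$b1) / params$k1,
      lam * (params$a2 + params$b2) / params$k2)
}
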