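#' Relax a batch of initial conditions to rest
#'
#' Integrates the circuit dynamics forward from every row of `x0`
#' simultaneously with a fixed-step classical Runge-Kutta (RK4) scheme,
#' freezing each trajectory once its right-hand-side norm falls below
#' `conv_tol`.  States are projected onto the non-negative quadrant after
#' each step (the quadrant is forward-invariant; projection only absorbs
#' round-off undershoot).  This is the workhorse behind [attractor_of()] and
#' [basin_map()]; batching thousands of trajectories through vectorised
#' arithmetic is what makes basin mapping fast.
#'
#' @param x0 m x 2 matrix of initial conditions (non-negative).
#' @param params a [regulatory_params()] object.
#' @param lam energy scaling factor.
#' @param conv_tol convergence threshold on `||rhs||`.
#' @param t_max maximum integration time per trajectory.
#' @param dt fixed step size; the dynamics are non-stiff with rates of order
#'   one, so the default 0.05 keeps RK4 well inside its stability region.
#' @return list with `states` (m x 2 terminal states), `rhs_norm` (terminal
#'   residual norms) and `converged` (logical).
#' @export
settle <- function(x0, params, lam, conv_tol = 1e-8, t_max = 500, dt = 0.05) {
  stopifnot(inherits(params, "regulatory_params"), lam >= 0, dt > 0)
  x0 <- as_state_matrix_multi(x0)
  if (any(x0 < 0) || any(!is.finite(x0))) {
    stop("initial conditions must be finite and non-negative", call. = FALSE)
  }
  x1 <- x0[, 1]
  x2 <- x0[, 2]
  m <- length(x1)
  f <- .rhs_vec(x1, x2, params, lam)
  rn <- sqrt(f$f1^2 + f$f2^2)
  active <- which(rn >= conv_tol)
  n_steps <- ceiling(t_max / dt)

  for (s in seq_len(n_steps)) {
    if (length(active) == 0L) break
    u1 <- x1[active]; u2 <- x2[active]
    k1 <- .rhs_vec(u1, u2, params, lam)
    k2 <- .rhs_vec(pmax(u1 + dt / 2 * k1$f1, 0), pmax(u2 + dt / 2 * k1$f2, 0),
                   params, lam)
    k3 <- .rhs_vec(pmax(u1 + dt / 2 * k2$f1, 0), pmax(u2 + dt / 2 * k2$f2, 0),
                   params, lam)
    k4 <- .rhs_vec(pmax(u1 + dt * k3$f1, 0), pmax(u2 + dt * k3$f2, 0),
                   params, lam)
    u1 <- pmax(u1 + dt / 6 * (k1$f1 + 2 * k2$f1 + 2 * k3$f1 + k4$f1), 0)
    u2 <- pmax(u2 + dt / 6 * (k1$f2 + 2 * k2$f2 + 2 * k3$f2 + k4$f2), 0)
    x1[active] <- u1
    x2[active] <- u2
    fr <- .rhs_vec(u1, u2, params, lam)
    rr <- sqrt(fr$f1^2 + fr$f2^2)
    rn[active] <- rr
    active <- active[rr >= conv_tol]
  }
  list(states = cbind(x1, x2), rhs_norm = rn, converged = rn < conv_tol)
}
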