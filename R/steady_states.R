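#' Find all steady states of the energy-scaled circuit
#'
#' Locates every root of the governing equations at a given energy level by
#' damped-Newton iteration from a dense grid of starting points covering
#' `[0, margin * x_max]^2`, where `x_max = max_i lam * (a_i + b_i) / k_i`
#' bounds every steady state.  Roots are verified against `residual_tol`,
#' deduplicated, and classified by the real parts of the analytic Jacobian's
#' eigenvalues: a root is `stable` iff its leading real part is below
#' `-stability_eps`.  Marginal (metastable) roots are deliberately labelled
#' `unstable` — they are functionally unstable, since arbitrarily small
#' expression noise moves the system off them — so only robust attractors
#' count as cell fates.
#'
#' @param params a [regulatory_params()] object.
#' @param a_star scaled energy availability (see [lambda_energy()]).
#' @param model an [energy_model()].
#' @param n_starts number of starting points per axis (the start grid has
#'   `n_starts^2` points); at least 15.
#' @param margin multiplicative margin on the steady-state bound used for the
#'   start-grid extent.
#' @param residual_tol maximum Euclidean norm of the right-hand side at an
#'   accepted root.
#' @param dedup_tol minimum Euclidean separation between distinct roots.
#' @param stability_eps half-width of the marginal band around zero for the
#'   leading eigenvalue real part.
#' @param grid_offset small shift applied to the start grid (diagnostic use:
#'   attractor counts must not depend on it).
#' @return An object of class `attractor_set`: a list with `states` (a
#'   data.frame with columns `x1`, `x2`, `stability`, `leading_re`,
#'   `residual`, ordered by decreasing `x1 - x2`), `params`, `a_star`, `lam`,
#'   `model`, and `n_stable`.
#' @examples
#' aset <- find_steady_states(regulatory_params(), a_star = 1)
#' aset$n_stable  # 3: the circuit is tristable at full energy
#' @export
find_steady_states <- function(params, a_star, model = energy_model(),
                               n_starts = 25L, margin = 1.2,
                               residual_tol = 1e-9, dedup_tol = 1e-5,
                               stability_eps = 1e-8, grid_offset = 0) {
  stopifnot(inherits(params, "regulatory_params"), n_starts >= 15L)
  lam <- lambda_energy(a_star, model)
  upper <- max(margin * x_max_bound(params, lam), 1e-3)
  starts <- .start_grid(upper, n_starts, grid_offset)
  sol <- .solve_roots(starts, params, lam, residual_tol = residual_tol)
  if (nrow(sol$states) == 0L) {
    stop("no steady state survived verification at a_star = ", a_star,
         " (numerical failure: a steady state must exist)", call. = FALSE)
  }
  dd <- deduplicate_roots(sol$states, residuals = sol$residual,
                          dedup_tol = dedup_tol)
  x1 <- dd$states[, 1]
  x2 <- dd$states[, 2]
  leading <- .leading_re_vec(x1, x2, params, lam)
  stability <- ifelse(leading < -stability_eps, "stable", "unstable")
  ord <- order(-(x1 - x2), x1)
  states <- data.frame(x1 = x1[ord], x2 = x2[ord],
                       stability = stability[ord],
                       leading_re = leading[ord],
                       residual = dd$residual[ord])
  structure(list(states = states, params = params,
                 a_star = as.numeric(a_star), lam = lam, model = model,
                 n_stable = sum(states$stability == "stable")),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("Attractor set at A* = %g (lambda = %.6g): %d stable / %d total\n",
              x$a_star, x$lam, x$n_stable, nrow(x$states)))
  print(x$states, digits = 6)
  invisible(x)
}

#' Stable members of an attractor set
#'
#' @param aset an `attractor_set` from [find_steady_states()].
#' @return data.frame of the stable rows, in the set's deterministic order.
#' @export
stable_states <- function(aset) {
  stopifnot(inherits(aset, "attractor_set"))
  aset$states[aset$states$stability == "stable", , drop = FALSE]
}

#' @export
as.data.frame.attractor_set <- function(x, ...) {
  cbind(a_star = x$a_star, x$states)
}

#' Classify the stability of a verified steady state
#'
#' Computes the eigenvalues of the analytic Jacobian at a root and labels it
#' `stable` iff the largest eigenvalue real part is below `-eps`.  Marginal
#' states (`|leading_re| <= eps`) are labelled `unstable` (functionally
#' unstable).
#'
#' @param state numeric `c(x1, x2)`, a root of the system.
#' @param params a [regulatory_params()] object.
#' @param lam energy scaling factor.
#' @param eps marginality threshold on the leading real part.
#' @param residual_tol the input is rejected unless `||rhs(state)||` is below
#'   this tolerance.
#' @return list with `stability` (`"stable"` or `"unstable"`) and
#'   `leading_re`.
#' @export
classify_stability <- function(state, params, lam, eps = 1e-8,
                               residual_tol = 1e-9) {
  f <- toggle_rhs(state, params, lam)
  res <- sqrt(sum(f^2))
  if (res > residual_tol) {
    stop("state is not a steady state (residual ", format(res), " > ",
         format(residual_tol), ")", call. = FALSE)
  }
  lead <- .leading_re_vec(state[1], state[2], params, lam)
  list(stability = if (lead < -eps) "stable" else "unstable",
       leading_re = lead)
}

#' Deduplicate near-identical roots
#'
#' Greedy clustering by Euclidean distance: candidates are visited in order
#' of increasing residual, and a candidate is kept iff it is farther than
#' `dedup_tol` from every root already kept, so each cluster is represented
#' by its smallest-residual member.
#'
#' @param roots m x 2 matrix of candidate roots.
#' @param residuals numeric vector of residual norms (defaults to zeros,
#'   keeping input order).
#' @param dedup_tol minimum pairwise separation of the output.
#' @return list with `states` (matrix) and `residual` (vector).
#' @export
deduplicate_roots <- function(roots, residuals = NULL, dedup_tol = 1e-5) {
  stopifnot(dedup_tol > 0)
  roots <- as_state_matrix_multi(roots)
  if (is.null(residuals)) residuals <- rep(0, nrow(roots))
  ord <- order(residuals)
  kept <- matrix(numeric(0), 0, 2)
  kres <- numeric(0)
  for (i in ord) {
    if (nrow(kept) > 0L) {
      d2 <- (kept[, 1] - roots[i, 1])^2 + (kept[, 2] - roots[i, 2])^2
      if (any(d2 <= dedup_tol^2)) next
    }
    kept <- rbind(kept, roots[i, ])
    kres <- c(kres, residuals[i])
  }
  list(states = kept, residual = kres)
}

as_state_matrix_multi <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c(1, 2)])
  if (!is.matrix(x)) x <- matrix(x, ncol = 2, byrow = TRUE)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 2L)
  x
}

#' Identify the attractor a trajectory converges to
#'
#' Integrates the circuit dynamics from `x0` until the right-hand-side norm
#' drops below `conv_tol` (or `t_max` elapses) and matches the terminal point
#' against the stable members of `attractors`.
#'
#' @param x0 numeric `c(x1, x2)` initial condition.
#' @param attractors an `attractor_set` with at least one stable member.
#' @param conv_tol convergence threshold on `||rhs||`.
#' @param t_max maximum integration time.
#' @param dt fixed Runge-Kutta step size.
#' @param match_tol maximum distance between the terminal point and the
#'   matched attractor.
#' @return integer index into `stable_states(attractors)`.
#' @export
attractor_of <- function(x0, attractors, conv_tol = 1e-8, t_max = 500,
                         dt = 0.05, match_tol = 1e-3) {
  stopifnot(inherits(attractors, "attractor_set"))
  stab <- stable_states(attractors)
  if (nrow(stab) == 0L) stop("no stable attractor exists", call. = FALSE)
  out <- settle(matrix(x0, 1, 2), attractors$params, attractors$lam,
                conv_tol = conv_tol, t_max = t_max, dt = dt)
  if (!out$converged[1]) {
    stop("non-convergent: trajectory did not reach ||rhs|| < conv_tol by t_max",
         call. = FALSE)
  }
  d <- sqrt((stab$x1 - out$states[1, 1])^2 + (stab$x2 - out$states[1, 2])^2)
  i <- which.min(d)
  if (d[i] > match_tol) {
    stop("unmatched terminal state: trajectory settled ", format(d[i]),
         " away from the nearest stable attractor", call. = FALSE)
  }
  i
}
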