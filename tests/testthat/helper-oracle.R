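# Independent numerical oracles used across the suite.

# Central finite-difference Jacobian of toggle_rhs.
fd_jacobian <- function(state, params, lam, h = 1e-6) {
  J <- matrix(NA_real_, 2, 2)
  for (j in 1:2) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (toggle_rhs(up, params, lam) - toggle_rhs(dn, params, lam)) /
      (up[j] - dn[j])
  }
  J
}

# Swap the two gene indices of a parameter set.
swap_genes <- function(p) {
  regulatory_params(a1 = p$a2, a2 = p$a1, b1 = p$b2, b2 = p$b1,
                    k1 = p$k2, k2 = p$k1,
                    theta_a1 = p$theta_a2, theta_a2 = p$theta_a1,
                    theta_b1 = p$theta_b2, theta_b2 = p$theta_b1, n = p$n)
}

# Distinct trajectory limits of a dense initial-condition grid: the
# integration-based route to the attractor set, independent of the Newton
# root finder.  Returns terminal states of converged trajectories.
trajectory_limits <- function(params, a_star, model = energy_model(),
                              n_grid = 21, margin = 1.2) {
  lam <- lambda_energy(a_star, model)
  upper <- max(margin * lam * max((params$a1 + params$b1) / params$k1,
                                  (params$a2 + params$b2) / params$k2), 1e-3)
  g <- seq(0, upper, length.out = n_grid)
  out <- settle(as.matrix(expand.grid(g, g)), params, lam)
  list(states = out$states[out$converged, , drop = FALSE],
       frac_converged = mean(out$converged))
}

# Minimum distance from each point of `from` to the nearest row of `to`.
nearest_dist <- function(from, to) {
  d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}
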