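# Multistart root solver for the 2-D circuit: a damped (backtracking) Newton
# iteration run simultaneously on a whole matrix of starting points.  The
# 2x2 Newton step is solved in closed form, iterates are projected onto the
# non-negative quadrant (roots on the axes exist when b = 0 or lam = 0), and
# a step that fails to reduce the residual after repeated halving retires
# that start.  Starts that do not reach the residual tolerance are simply
# dropped; with a grid of starts the surviving set covers all roots.

.solve_roots <- function(x0, params, lam, residual_tol = 1e-9,
                         max_iter = 120L, x_clamp = NULL) {
  x1 <- x0[, 1]
  x2 <- x0[, 2]
  if (is.null(x_clamp)) x_clamp <- 2 * x_max_bound(params, lam) + 1
  f <- .rhs_vec(x1, x2, params, lam)
  res <- sqrt(f$f1^2 + f$f2^2)
  alive <- rep(TRUE, length(x1))
  tol_work <- min(residual_tol, 1e-11)

  for (iter in seq_len(max_iter)) {
    act <- which(alive & res > tol_work)
    if (length(act) == 0L) break
    a1 <- x1[act]; a2 <- x2[act]
    f1 <- f$f1[act]; f2 <- f$f2[act]
    j <- .jac_vec(a1, a2, params, lam)
    det <- j$j11 * j$j22 - j$j12 * j$j21
    sing <- abs(det) < 1e-13
    det[sing] <- ifelse(det[sing] >= 0, 1e-13, -1e-13)
    d1 <- (-f1 * j$j22 + f2 * j$j12) / det
    d2 <- (-f2 * j$j11 + f1 * j$j21) / det
    # cap step length to keep the iteration inside a sane region
    len <- sqrt(d1^2 + d2^2)
    cap <- pmin(1, x_clamp / pmax(len, 1e-300))
    d1 <- d1 * cap
    d2 <- d2 * cap

    alpha <- rep(1, length(act))
    pending <- rep(TRUE, length(act))
    for (bt in 1:8) {
      idx <- which(pending)
      if (length(idx) == 0L) break
      n1 <- pmin(pmax(a1[idx] + alpha[idx] * d1[idx], 0), x_clamp)
      n2 <- pmin(pmax(a2[idx] + alpha[idx] * d2[idx], 0), x_clamp)
      fn <- .rhs_vec(n1, n2, params, lam)
      rn <- sqrt(fn$f1^2 + fn$f2^2)
      ok <- is.finite(rn) & rn < res[act][idx]
      if (any(ok)) {
        g <- act[idx[ok]]
        x1[g] <- n1[ok]; x2[g] <- n2[ok]
        f$f1[g] <- fn$f1[ok]; f$f2[g] <- fn$f2[ok]
        res[g] <- rn[ok]
        pending[idx[ok]] <- FALSE
      }
      alpha[idx[!ok]] <- alpha[idx[!ok]] / 2
    }
    alive[act[pending]] <- FALSE  # stalled starts retire
  }
  keep <- res <= residual_tol
  list(states = cbind(x1, x2)[keep, , drop = FALSE],
       residual = res[keep],
       n_failed = sum(!keep))
}

# Equally spaced grid of starting points over [0, upper]^2.
.start_grid <- function(upper, n_per_axis, offset = 0) {
  g <- seq(0, upper, length.out = n_per_axis) + offset
  g <- pmin(pmax(g, 0), upper)
  as.matrix(expand.grid(x1 = g, x2 = g))
}
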