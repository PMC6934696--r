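test_that("the default circuit is tristable at full energy", {
  aset <- find_steady_states(regulatory_params(), a_star = 1)
  expect_equal(aset$n_stable, 3L)
  expect_equal(nrow(aset$states), 5L)   # 3 attractors + 2 saddles
  stab <- stable_states(aset)
  # symmetric extremes plus the balanced intermediate state
  expect_equal(stab$x1[1], 1.9954, tolerance = 1e-3)
  expect_equal(stab$x2[1], 0.0039, tolerance = 1e-2)
  expect_equal(stab$x1[2], stab$x2[2], tolerance = 1e-8)
  expect_true(all(aset$states$residual < 1e-9))
})

test_that("noncooperative binding collapses the system to one fate", {
  aset <- find_steady_states(regulatory_params(n = 1), a_star = 1)
  expect_equal(aset$n_stable, 1L)
})

test_that("low energy leaves a single attractor near the origin", {
  aset <- find_steady_states(regulatory_params(), a_star = 0)
  expect_equal(aset$n_stable, 1L)
  lam0 <- lambda_energy(0, energy_model())
  expect_true(all(stable_states(aset)[, c("x1", "x2")] <= 2 * lam0 + 1e-6))
})

test_that("roots are bounded, symmetric and exist for random circuits", {
  pars <- random_params(seed = 11, n = 20)
  for (i in seq_along(pars)) {
    p <- pars[[i]]
    aset <- find_steady_states(p, a_star = 0.9, n_starts = 15)
    expect_gte(aset$n_stable, 1L)
    lam <- aset$lam
    b1 <- lam * (p$a1 + p$b1) / p$k1
    b2 <- lam * (p$a2 + p$b2) / p$k2
    expect_true(all(aset$states$x1 <= b1 + 1e-5))
    expect_true(all(aset$states$x2 <= b2 + 1e-5))
    # symmetric parameters: steady-state set closed under (x1,x2) swap
    mirrored <- cbind(aset$states$x2, aset$states$x1)
    own <- cbind(aset$states$x1, aset$states$x2)
    expect_lt(max(nearest_dist(mirrored, own)), 1e-5)
  }
})

test_that("attractor counts are independent of the start-grid offset", {
  p <- regulatory_params()
  for (a_star in c(0.3, 0.5, 0.7, 1)) {
    n0 <- find_steady_states(p, a_star, n_starts = 15)$n_stable
    n1 <- find_steady_states(p, a_star, n_starts = 18,
                             grid_offset = 0.013)$n_stable
    expect_identical(n0, n1)
  }
})

test_that("stability classification follows the Jacobian eigenvalues", {
  p <- regulatory_params()
  # degradation-only system: origin is stable with eigenvalues -k
  cl <- classify_stability(c(0, 0), p, lam = 0)
  expect_identical(cl$stability, "stable")
  expect_equal(cl$leading_re, -1)
  # the symmetric intermediate root of the tristable defaults is stable
  aset <- find_steady_states(p, 1)
  mid <- stable_states(aset)
  mid <- mid[abs(mid$x1 - mid$x2) < 1e-6, ]
  cl <- classify_stability(c(mid$x1, mid$x2), p, lam = aset$lam)
  expect_identical(cl$stability, "stable")
  # non-roots are rejected
  expect_error(classify_stability(c(0.3, 0.3), p, lam = 1), "not a steady state")
})

test_that("deduplication clusters by distance, keeping best residuals", {
  out <- deduplicate_roots(rbind(c(1, 0), c(1 + 1e-8, 0)),
                           residuals = c(1e-12, 1e-10), dedup_tol = 1e-5)
  expect_equal(nrow(out$states), 1L)
  expect_equal(out$residual, 1e-12)  # representative = smallest residual
  out <- deduplicate_roots(rbind(c(1, 0), c(0, 1)), dedup_tol = 1e-5)
  expect_equal(nrow(out$states), 2L)
})

test_that("trajectories identify their attractor and respect symmetry", {
  p <- regulatory_params()
  aset <- find_steady_states(p, 1)
  stab <- stable_states(aset)
  for (i in seq_len(nrow(stab))) {
    expect_identical(attractor_of(c(stab$x1[i], stab$x2[i]), aset), i)
  }
  i_20 <- attractor_of(c(2, 0), aset)
  i_02 <- attractor_of(c(0, 2), aset)
  expect_gt(stab$x1[i_20] - stab$x2[i_20], 1)  # the high-x1 fate
  # mirror starts reach mirror attractors
  expect_equal(c(stab$x1[i_02], stab$x2[i_02]),
               c(stab$x2[i_20], stab$x1[i_20]), tolerance = 1e-8)
  expect_error(attractor_of(c(2, 0), aset, t_max = 1e-3), "non-convergent")
})

test_that("Newton roots agree with an independent Levenberg-Marquardt solver", {
  skip_if_not_installed("minpack.lm")
  p <- regulatory_params()
  aset <- find_steady_states(p, 1)
  lam <- aset$lam
  fn <- function(x) toggle_rhs(pmax(x, 0), p, lam)
  g <- seq(0, 2.4, length.out = 10)
  lm_roots <- NULL
  for (x1 in g) for (x2 in g) {
    s <- minpack.lm::nls.lm(par = c(x1, x2), fn = fn)
    x <- pmax(s$par, 0)
    if (sqrt(sum(toggle_rhs(x, p, lam)^2)) < 1e-9) {
      lm_roots <- rbind(lm_roots, x)
    }
  }
  lm_roots <- deduplicate_roots(lm_roots, dedup_tol = 1e-5)$states
  own <- as.matrix(aset$states[, c("x1", "x2")])
  expect_equal(nrow(lm_roots), nrow(own))
  expect_lt(max(nearest_dist(lm_roots, own)), 1e-6)
  expect_lt(max(nearest_dist(own, lm_roots)), 1e-6)
})

test_that("the batched RK4 integrator matches an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- regulatory_params()
  lam <- lambda_energy(1, energy_model())
  for (x0 in list(c(2, 0.1), c(0.6, 0.9), c(0.2, 2.2))) {
    ode_out <- deSolve::lsoda(
      y = x0, times = c(0, 200),
      func = function(t, y, parms) list(toggle_rhs(pmax(y, 0), p, lam)),
      rtol = 1e-10, atol = 1e-12)
    term_ode <- ode_out[2, 2:3]
    term_rk <- settle(matrix(x0, 1, 2), p, lam)$states[1, ]
    expect_equal(unname(term_rk), unname(term_ode), tolerance = 1e-6)
  }
})

test_that("root finding from an integration-based oracle finds the same fates", {
  # On random circuits the stable roots from multistart Newton must
  # coincide with the distinct limits of dense trajectory bundles.
  pars <- random_params(seed = 42, n = 20)
  set.seed(43)
  a_stars <- runif(20, 0.2, 1)
  for (i in seq_along(pars)) {
    p <- pars[[i]]
    aset <- find_steady_states(p, a_stars[i], n_starts = 15)
    stab <- as.matrix(stable_states(aset)[, c("x1", "x2")])
    tl <- trajectory_limits(p, a_stars[i])
    expect_equal(tl$frac_converged, 1)
    term <- tl$states
    d <- nearest_dist(term, stab)
    matched <- d <= 1e-3
    # every stable root is reached by at least one trajectory
    d_back <- nearest_dist(stab, term[matched, , drop = FALSE])
    expect_lt(max(d_back), 1e-3)
    # unmatched limits are separatrix starts: they sit on unstable roots
    if (any(!matched)) {
      unst <- aset$states[aset$states$stability == "unstable", ]
      expect_gt(nrow(unst), 0)
      d_sep <- nearest_dist(term[!matched, , drop = FALSE],
                            as.matrix(unst[, c("x1", "x2")]))
      expect_lt(max(d_sep), 1e-3)
    }
  }
})
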