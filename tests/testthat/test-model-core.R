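test_that("sigmoid energy scaling matches its closed form and stays in (0,1)", {
  m <- energy_model()
  expect_identical(lambda_energy(0.5, m), 0.5)
  expect_equal(lambda_energy(1, m), 1 / (1 + exp(-8)), tolerance = 1e-12)
  expect_equal(lambda_energy(0, m), 1 / (1 + exp(8)), tolerance = 1e-12)
  grid <- seq(0, 1, by = 1e-3)
  lam <- lambda_energy(grid, m)
  expect_true(all(lam > 0 & lam < 1))
})

test_that("every energy-model kind is strictly increasing on [0,1]", {
  grid <- seq(0, 1, by = 1e-3)
  for (m in list(energy_model("sigmoid"), energy_model("linear"),
                 energy_model("shifted"))) {
    expect_true(all(diff(lambda_energy(grid, m)) > 0), info = m$kind)
  }
})

test_that("linear kind is the identity on [0,1] and clamps outside", {
  m <- energy_model("linear")
  expect_identical(lambda_energy(0.3, m), 0.3)
  expect_warning(out <- lambda_energy(c(-0.5, 1.5), m), "outside")
  expect_identical(out, c(0, 1))
})

test_that("shifted kind is an affine rescale of the sigmoid, exceeding 1", {
  m <- energy_model("shifted", floor = 0.1, ceiling = 1.2)
  sig <- lambda_energy(c(0, 0.5, 1), energy_model())
  expect_equal(lambda_energy(c(0, 0.5, 1), m), 0.1 + 1.1 * sig,
               tolerance = 1e-12)
  expect_gt(lambda_energy(1, m), 1)   # external ATP lifts the ceiling
  expect_gt(lambda_energy(0, m), 0)   # and the floor
  expect_error(energy_model("shifted", floor = -0.1), "floor")
  expect_error(energy_model("shifted", floor = 0.5, ceiling = 0.5), "ceiling")
})

test_that("ATP concentrations map linearly onto the energy axis", {
  expect_equal(map_atp_to_astar(320)$a_star, 0)
  expect_true(map_atp_to_astar(320)$at_boundary)
  expect_equal(map_atp_to_astar(2760)$a_star, 1)
  expect_equal(map_atp_to_astar(1540)$a_star, 0.5)
  low <- map_atp_to_astar(100)
  expect_true(low$sub_critical)
  expect_lt(low$a_star, 0)
  expect_error(map_atp_to_astar(0), "positive")
  expect_error(map_atp_to_astar(-5), "positive")
})

test_that("rhs reproduces hand-evaluated states and the lam = 0 limit", {
  p <- regulatory_params()
  expect_equal(toggle_rhs(c(0, 0), p, lam = 1), c(dx1 = 1, dx2 = 1))
  expect_equal(toggle_rhs(c(0.5, 0.5), p, lam = 1), c(dx1 = 0.5, dx2 = 0.5),
               tolerance = 1e-14)
  st <- c(0.8, 1.7)
  expect_equal(unname(toggle_rhs(st, p, lam = 0)), -c(p$k1, p$k2) * st)
  expect_error(toggle_rhs(c(-0.1, 0.5), p, 1), "non-negative")
  expect_error(toggle_rhs(c(NaN, 0.5), p, 1), "finite")
})

test_that("rhs respects the gene-swap symmetry", {
  set.seed(7)
  for (i in 1:30) {
    p <- random_params(seed = 100 + i, symmetric = FALSE)
    st <- runif(2, 0, 3)
    f <- toggle_rhs(st, p, 0.8)
    f_sw <- toggle_rhs(rev(st), swap_genes(p), 0.8)
    expect_equal(unname(f), unname(rev(f_sw)), tolerance = 1e-12)
  }
})

test_that("flow never exits the non-negative quadrant through the axes", {
  for (i in 1:25) {
    p <- random_params(seed = 200 + i)
    lam <- runif(1)
    f1 <- toggle_rhs(c(0, runif(1, 0, 3)), p, lam)
    f2 <- toggle_rhs(c(runif(1, 0, 3), 0), p, lam)
    expect_gte(f1[1], 0)
    expect_gte(f2[2], 0)
  }
})

test_that("analytic Jacobian agrees with central finite differences", {
  worst <- 0
  for (i in 1:100) {
    p <- random_params(seed = 300 + i, symmetric = FALSE)
    set.seed(1000 + i)
    st <- runif(2, 0.01, 2.5)
    lam <- runif(1, 0.05, 1)
    J <- toggle_jacobian(st, p, lam)
    Jfd <- fd_jacobian(st, p, lam)
    rel <- max(abs(J - Jfd) / pmax(1, abs(J)))
    worst <- max(worst, rel)
  }
  expect_lte(worst, 1e-6)
})

test_that("Jacobian limits and symmetries hold", {
  p <- regulatory_params(k1 = 0.7, k2 = 1.3)
  expect_equal(toggle_jacobian(c(0.4, 1.1), p, lam = 0), diag(c(-0.7, -1.3)))
  p <- regulatory_params()
  J <- toggle_jacobian(c(0.8, 0.8), p, 1)
  expect_equal(J[1, 1], J[2, 2])
  expect_equal(J[1, 2], J[2, 1])
  expect_lte(J[1, 2], 0)  # repression derivative never positive
  # limit convention at the origin: activation slope a/theta_a when n = 1
  p1 <- regulatory_params(n = 1)
  J0 <- toggle_jacobian(c(0, 0), p1, 1)
  expect_equal(J0[1, 1], p1$a1 / p1$theta_a1 - p1$k1, tolerance = 1e-12)
  # and 0 for n > 1
  J0 <- toggle_jacobian(c(0, 0), regulatory_params(), 1)
  expect_equal(J0[1, 1], -1)
})

test_that("parameter construction validates and defaults are canonical", {
  p <- regulatory_params()
  expect_identical(unclass(p),
                   list(a1 = 1, a2 = 1, b1 = 1, b2 = 1, k1 = 1, k2 = 1,
                        theta_a1 = 0.5, theta_a2 = 0.5,
                        theta_b1 = 0.5, theta_b2 = 0.5, n = 4))
  expect_true(is_symmetric(p))
  expect_false(is_symmetric(regulatory_params(a1 = 1, a2 = 2)))
  expect_error(regulatory_params(a1 = -1), "positive")
  expect_error(regulatory_params(k1 = 0), "positive")
  expect_error(regulatory_params(n = 0.5), "n must be")
  expect_error(regulatory_params(b1 = -0.1), "non-negative")
})

test_that("parameter sets round-trip through YAML and JSON configs", {
  p <- regulatory_params(a1 = 1.25, theta_b1 = 0.37, n = 3)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    expect_identical(unclass(read_params(f)), unclass(p))
    unlink(f)
  }
  # defaults round-trip exactly
  f <- tempfile(fileext = ".yaml")
  write_params(regulatory_params(), f)
  expect_identical(unclass(read_params(f)), unclass(regulatory_params()))
  unlink(f)
})
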