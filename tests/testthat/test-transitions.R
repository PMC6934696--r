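test_that("roles are assigned by fate geometry", {
  p <- regulatory_params()
  aset <- find_steady_states(p, 1)
  roles <- assign_roles(aset)
  expect_identical(roles$role, c("high_x1", "intermediate", "high_x2"))
  # monostable set: the single attractor is high_x1 by convention
  aset0 <- find_steady_states(p, 0.2)
  expect_identical(assign_roles(aset0)$role, "high_x1")
})

test_that("four-attractor landscapes include a near-zero fate", {
  p <- regulatory_params(b1 = 0.02)
  aset <- find_steady_states(p, 0.8, n_starts = 15)
  expect_equal(aset$n_stable, 4L)
  roles <- assign_roles(aset)
  expect_setequal(roles$role,
                  c("high_x1", "high_x2", "intermediate", "near_zero"))
  nz <- roles[roles$role == "near_zero", ]
  expect_lt(nz$x1 + nz$x2, 0.1)
})

test_that("a monostable landscape cannot transition", {
  p <- regulatory_params()
  aset <- find_steady_states(p, 0.2)
  bm <- basin_map(p, 0.2, attractors = aset, resolution = 31)
  expect_error(transition_distance(aset, bm), "monostable")
})

test_that("tristable transition uses the indirect route and is symmetric", {
  p <- regulatory_params()
  aset <- find_steady_states(p, 1)
  bm <- basin_map(p, 1, attractors = aset, resolution = 61)
  tr <- transition_distance(aset, bm)
  expect_lte(tr$minimum, tr$direct)
  expect_false(is.na(tr$indirect))
  # symmetric circuit: hopping via the intermediate state is cheaper
  expect_identical(tr$route, "indirect")
  # distance is symmetric under exchanging the extreme fates
  roles <- tr$roles
  h1 <- roles[roles$role == "high_x1", ]
  h2 <- roles[roles$role == "high_x2", ]
  d12 <- energytoggle:::.dist_to_basin(c(h1$x1, h1$x2), h2$index, bm)$distance
  d21 <- energytoggle:::.dist_to_basin(c(h2$x1, h2$x2), h1$index, bm)$distance
  expect_equal(d12, d21, tolerance = 1e-6)
})

test_that("refinement matches the brute-force cell minimum within a diagonal", {
  p <- regulatory_params()
  aset <- find_steady_states(p, 1)
  bm <- basin_map(p, 1, attractors = aset, resolution = 61)
  tr <- transition_distance(aset, bm)
  roles <- tr$roles
  h1 <- roles[roles$role == "high_x1", ]
  h2 <- roles[roles$role == "high_x2", ]
  # brute-force: minimum distance over every cell labelled with the target
  cells <- bm$cells
  sel <- !is.na(cells$label) & cells$label == h2$index
  brute <- min(sqrt((cells$x1_0[sel] - h1$x1)^2 + (cells$x2_0[sel] - h1$x2)^2))
  expect_equal(tr$grid_direct, brute)
  cell_diag <- sqrt(2) * bm$upper / (bm$resolution - 1)
  expect_lte(tr$direct, brute + 1e-12)
  expect_lte(brute - tr$direct, cell_diag)
})

test_that("bistable landscapes only admit the direct route", {
  p <- regulatory_params(a1 = 2)   # central fate destabilised near A* = 0.45
  aset <- find_steady_states(p, 0.45, n_starts = 15)
  expect_equal(aset$n_stable, 2L)
  bm <- basin_map(p, 0.45, attractors = aset, resolution = 41)
  # the diagonal separatrix shows up as boundary cells, never as an error
  expect_gt(bm$n_boundary, 0L)
  tr <- transition_distance(aset, bm)
  expect_true(is.na(tr$indirect))
  expect_identical(tr$route, "direct")
  expect_identical(tr$minimum, tr$direct)
})

test_that("transitions get easier just past the multistability boundary", {
  p <- regulatory_params()
  d <- sapply(c(0.47, 1), function(a_star) {
    aset <- find_steady_states(p, a_star)
    bm <- basin_map(p, a_star, attractors = aset, resolution = 41)
    transition_distance(aset, bm)$minimum
  })
  expect_lt(d[1], d[2])
})

test_that("difficulty grids leave monostable cells undefined", {
  p <- regulatory_params()
  tg <- transition_difficulty_grid(
    p, axis1 = list(name = "b", values = 1),
    axis2 = list(name = "a_star", values = c(0.3, 0.6, 1)),
    resolution = 31)
  expect_true(is.na(tg$min_distance[1, 1]))       # monostable at low energy
  expect_true(all(!is.na(tg$min_distance[1, 2:3])))
  expect_identical(is.na(tg$min_distance), tg$counts < 2L)
  df <- as.data.frame(tg)
  expect_identical(names(df), c("b", "a_star", "min_distance", "route"))
})

test_that("the strongest fates appear at high conditional-promoter activity", {
  cells <- list(c(1, 1), c(2, 0.8), c(3, 1))   # (b, A*) probes
  max_d <- sapply(c(1, 2, 3), function(a) {
    d <- sapply(cells, function(cl) {
      p <- regulatory_params(a1 = a, b1 = cl[1])
      aset <- find_steady_states(p, cl[2], n_starts = 15)
      if (aset$n_stable < 2) return(NA_real_)
      bm <- basin_map(p, cl[2], attractors = aset, resolution = 41)
      transition_distance(aset, bm)$minimum
    })
    max(d, na.rm = TRUE)
  })
  expect_identical(which.max(max_d), 3L)
})
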