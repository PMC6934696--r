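#' Assign phenotypic roles to stable attractors
#'
#' Labels each stable attractor of a set as `high_x1` (the extreme fate with
#' the largest `x1 - x2`), `high_x2` (largest `x2 - x1`), `near_zero` (the
#' attractor minimising `x1 + x2`, provided that sum is below
#' `role_zero_frac * x_max` — the low-expression fate supported at low basal
#' rates), or `intermediate` (everything else, including the symmetric
#' both-genes-on state).  Ties are broken towards larger `x1`.
#'
#' @param attractors an `attractor_set` with at least one stable member.
#' @param role_zero_frac fraction of the steady-state bound below which the
#'   smallest attractor counts as near-zero.
#' @return data.frame with columns `index` (row in
#'   [stable_states()]), `x1`, `x2`, `role`.
#' @export
assign_roles <- function(attractors, role_zero_frac = 0.05) {
  stopifnot(inherits(attractors, "attractor_set"))
  stab <- stable_states(attractors)
  if (nrow(stab) == 0L) stop("no stable attractor exists", call. = FALSE)
  m <- nrow(stab)
  role <- rep("intermediate", m)
  # order by criterion, tie-break on larger x1
  pick <- function(score) order(-score, -stab$x1)[1]
  i_h1 <- pick(stab$x1 - stab$x2)
  i_h2 <- pick(stab$x2 - stab$x1)
  if (m >= 2L && i_h1 == i_h2) {
    stop("degenerate attractor geometry: high_x1 and high_x2 coincide",
         call. = FALSE)
  }
  role[i_h1] <- "high_x1"
  if (m >= 2L) role[i_h2] <- "high_x2"
  rest <- setdiff(seq_len(m), c(i_h1, i_h2))
  if (length(rest) > 0L) {
    tot <- stab$x1[rest] + stab$x2[rest]
    zero_tol <- role_zero_frac * x_max_bound(attractors$params, attractors$lam)
    i_min <- rest[order(tot, -stab$x1[rest])[1]]
    if (stab$x1[i_min] + stab$x2[i_min] < zero_tol) role[i_min] <- "near_zero"
  }
  data.frame(index = seq_len(m), x1 = stab$x1, x2 = stab$x2, role = role)
}

# Terminal-basin label of a single point (NA when the trajectory settles on
# a separatrix / unstable state).
.basin_label_of <- function(pt, attractors, conv_tol = 1e-8, t_max = 500,
                            dt = 0.05, match_tol = 1e-3) {
  tryCatch(attractor_of(pt, attractors, conv_tol = conv_tol, t_max = t_max,
                        dt = dt, match_tol = match_tol),
           error = function(e) NA_integer_)
}

# Shortest distance from a point to the basin with the given label:
# minimum over labelled basin cells, then bisection refinement along the
# segment to the best cell, localising the basin boundary to refine_tol.
.dist_to_basin <- function(pt, target, basin, refine_tol = 1e-4) {
  cells <- basin$cells
  sel <- which(!is.na(cells$label) & cells$label == target)
  if (length(sel) == 0L) return(list(distance = NA_real_, grid_distance = NA_real_))
  d2 <- (cells$x1_0[sel] - pt[1])^2 + (cells$x2_0[sel] - pt[2])^2
  ib <- which.min(d2)
  best <- c(cells$x1_0[sel[ib]], cells$x2_0[sel[ib]])
  grid_d <- sqrt(d2[ib])
  if (grid_d == 0) return(list(distance = 0, grid_distance = 0))
  att <- basin$attractors
  t_lo <- 0
  t_hi <- 1
  while ((t_hi - t_lo) * grid_d > refine_tol) {
    t_mid <- (t_lo + t_hi) / 2
    lab <- .basin_label_of(pt + t_mid * (best - pt), att)
    if (!is.na(lab) && lab == target) t_hi <- t_mid else t_lo <- t_mid
  }
  list(distance = t_hi * grid_d, grid_distance = grid_d)
}

#' Minimum perturbation distance between the extreme attractors
#'
#' Computes the minimum biochemical perturbation (Euclidean distance in the
#' `(x1, x2)` plane) needed to switch the system from the high-`x1` fate to
#' the high-`x2` fate: either directly (the shortest distance from the
#' high-`x1` attractor point into the high-`x2` basin) or indirectly (into
#' the basin of a non-extreme attractor, relaxing to that attractor point,
#' then from there into the high-`x2` basin), minimised over the non-extreme
#' attractors.  Only defined for landscapes with two or more stable
#' attractors — a monostable system cannot transition.
#'
#' @param attractors an `attractor_set` with `n_stable >= 2`.
#' @param basin a [basin_map()] of the same system.
#' @param refine_tol boundary localisation tolerance of the bisection
#'   refinement.
#' @param multi_hop also consider two-intermediate routes in four-attractor
#'   landscapes (off by default; the canonical metric uses a single hop).
#' @return An object of class `transition_result`: list with `direct`,
#'   `indirect` (`NA` when no non-extreme attractor exists), `minimum`,
#'   `route` (`"direct"` or `"indirect"`), `roles`, and `grid_direct` (the
#'   unrefined cell-centre distance, for diagnostics).
#' @export
transition_distance <- function(attractors, basin, refine_tol = 1e-4,
                                multi_hop = FALSE) {
  stopifnot(inherits(attractors, "attractor_set"), inherits(basin, "basin_map"))
  if (attractors$n_stable < 2L) {
    stop("monostable - transition undefined", call. = FALSE)
  }
  roles <- assign_roles(attractors)
  h1 <- roles[roles$role == "high_x1", ]
  h2 <- roles[roles$role == "high_x2", ]
  p_h1 <- c(h1$x1, h1$x2)
  dd <- .dist_to_basin(p_h1, h2$index, basin, refine_tol)
  direct <- dd$distance
  mids <- roles[roles$role %in% c("intermediate", "near_zero"), , drop = FALSE]
  indirect <- NA_real_
  if (nrow(mids) > 0L) {
    legs <- vapply(seq_len(nrow(mids)), function(i) {
      m <- mids[i, ]
      l1 <- .dist_to_basin(p_h1, m$index, basin, refine_tol)$distance
      l2 <- .dist_to_basin(c(m$x1, m$x2), h2$index, basin, refine_tol)$distance
      l1 + l2
    }, numeric(1))
    indirect <- min(legs, na.rm = TRUE)
    if (multi_hop && nrow(mids) >= 2L) {
      for (i in seq_len(nrow(mids))) {
        for (j in seq_len(nrow(mids))) {
          if (i == j) next
          mi <- mids[i, ]; mj <- mids[j, ]
          hop <- .dist_to_basin(p_h1, mi$index, basin, refine_tol)$distance +
            .dist_to_basin(c(mi$x1, mi$x2), mj$index, basin, refine_tol)$distance +
            .dist_to_basin(c(mj$x1, mj$x2), h2$index, basin, refine_tol)$distance
          if (is.finite(hop)) indirect <- min(indirect, hop)
        }
      }
    }
  }
  minimum <- if (is.na(indirect)) direct else min(direct, indirect)
  structure(list(direct = direct, indirect = indirect, minimum = minimum,
                 route = if (!is.na(indirect) && indirect < direct)
                   "indirect" else "direct",
                 roles = roles, grid_direct = dd$grid_distance),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("Transition high_x1 -> high_x2: minimum = %.6g (%s route)\n",
              x$minimum, x$route))
  cat(sprintf("  direct = %.6g, indirect = %s\n", x$direct,
              if (is.na(x$indirect)) "undefined" else format(x$indirect)))
  invisible(x)
}

#' Grid of minimum transition distances over a parameter plane
#'
#' As [attractor_count_grid()], but each node stores the minimum transition
#' distance between the extreme attractors; monostable nodes are undefined
#' (`NA`).
#'
#' @inheritParams attractor_count_grid
#' @param resolution basin-map resolution used at each multistable node.
#' @param refine_tol see [transition_distance()].
#' @return An object of class `transition_grid`: list with `axis1`, `axis2`,
#'   `min_distance` and `route` matrices, plus `counts`.
#' @export
transition_difficulty_grid <- function(params, axis1, axis2,
                                       model = energy_model(), a_star = 1,
                                       resolution = 41L, n_starts = 15L,
                                       refine_tol = 1e-4, ...) {
  v1 <- as.numeric(axis1$values)
  v2 <- as.numeric(axis2$values)
  dist <- matrix(NA_real_, length(v1), length(v2))
  route <- matrix(NA_character_, length(v1), length(v2))
  counts <- matrix(NA_integer_, length(v1), length(v2))
  for (i in seq_along(v1)) {
    p_i <- if (axis1$name == "a_star") params else
      set_param(params, axis1$name, v1[i])
    for (j in seq_along(v2)) {
      p_ij <- if (axis2$name == "a_star") p_i else
        set_param(p_i, axis2$name, v2[j])
      as <- if (axis1$name == "a_star") v1[i] else
        if (axis2$name == "a_star") v2[j] else a_star
      aset <- find_steady_states(p_ij, as, model, n_starts = n_starts, ...)
      counts[i, j] <- aset$n_stable
      if (aset$n_stable >= 2L) {
        bm <- basin_map(p_ij, as, model, resolution = resolution,
                        attractors = aset)
        tr <- transition_distance(aset, bm, refine_tol = refine_tol)
        dist[i, j] <- tr$minimum
        route[i, j] <- tr$route
      }
    }
  }
  structure(list(axis1 = list(name = axis1$name, values = v1),
                 axis2 = list(name = axis2$name, values = v2),
                 min_distance = dist, route = route, counts = counts,
                 params = params, model = model),
            class = "transition_grid")
}

#' @export
as.data.frame.transition_grid <- function(x, ...) {
  df <- expand.grid(axis1 = x$axis1$values, axis2 = x$axis2$values)
  names(df) <- c(x$axis1$name, x$axis2$name)
  df$min_distance <- as.vector(x$min_distance)
  df$route <- as.vector(x$route)
  df
}
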