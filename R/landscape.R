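#' Attractor-count grid over a parameter plane
#'
#' Computes the number of stable steady states at every node of a
#' two-dimensional parameter grid.  Axes are named parameter families
#' (`"a"`, `"b"`, `"k"`, `"theta_a"`, `"theta_b"`, `"n"`, applied to both
#' genes) or `"a_star"` for the energy axis.  Attractor counting is a
#' deterministic property of the dynamics: counts must not depend on the
#' start-grid used by the root solver (see `grid_offset` in
#' [find_steady_states()]).
#'
#' @param params baseline [regulatory_params()]; axis values override it
#'   node by node.
#' @param axis1,axis2 lists `list(name = <string>, values = <numeric>)`.
#' @param model an [energy_model()]; required (as `a_star` axis or fixed
#'   `a_star`) to evaluate lambda.
#' @param a_star fixed energy level used when neither axis is `"a_star"`.
#' @param n_starts starting points per axis for the root solver; landscape
#'   sweeps default to the minimum contract density for speed.
#' @param ... further arguments to [find_steady_states()].
#' @return An object of class `count_grid`: list with `axis1`, `axis2`,
#'   `counts` (matrix, rows = axis1, cols = axis2), `params`, `model`,
#'   `a_star`.
#' @examples
#' \donttest{
#' g <- attractor_count_grid(regulatory_params(),
#'                           axis1 = list(name = "b", values = seq(0, 3, 0.5)),
#'                           axis2 = list(name = "a_star", values = seq(0, 1, 0.2)))
#' table(g$counts)
#' }
#' @export
attractor_count_grid <- function(params, axis1, axis2,
                                 model = energy_model(), a_star = 1,
                                 n_starts = 15L, ...) {
  stopifnot(is.list(axis1), is.list(axis2),
            !is.null(axis1$name), !is.null(axis2$name))
  v1 <- as.numeric(axis1$values)
  v2 <- as.numeric(axis2$values)
  counts <- matrix(NA_integer_, length(v1), length(v2))
  for (i in seq_along(v1)) {
    p_i <- if (axis1$name == "a_star") params else
      set_param(params, axis1$name, v1[i])
    for (j in seq_along(v2)) {
      p_ij <- if (axis2$name == "a_star") p_i else
        set_param(p_i, axis2$name, v2[j])
      as <- if (axis1$name == "a_star") v1[i] else
        if (axis2$name == "a_star") v2[j] else a_star
      aset <- tryCatch(
        find_steady_states(p_ij, as, model, n_starts = n_starts, ...),
        error = function(e) {
          stop("solver failure at (", axis1$name, " = ", v1[i], ", ",
               axis2$name, " = ", v2[j], "): ", conditionMessage(e),
               call. = FALSE)
        })
      counts[i, j] <- aset$n_stable
    }
  }
  structure(list(axis1 = list(name = axis1$name, values = v1),
                 axis2 = list(name = axis2$name, values = v2),
                 counts = counts, params = params, model = model,
                 a_star = a_star),
            class = "count_grid")
}

#' @export
print.count_grid <- function(x, ...) {
  cat(sprintf("Attractor-count grid: %s (%d) x %s (%d)\n",
              x$axis1$name, length(x$axis1$values),
              x$axis2$name, length(x$axis2$values)))
  cat("count distribution:\n")
  print(table(x$counts))
  invisible(x)
}

#' @export
as.data.frame.count_grid <- function(x, ...) {
  df <- expand.grid(axis1 = x$axis1$values, axis2 = x$axis2$values)
  names(df) <- c(x$axis1$name, x$axis2$name)
  df$count <- as.vector(x$counts)
  df
}

#' Plot a count grid as a heatmap
#'
#' @param x a `count_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.count_grid <- function(x, ...) {
  graphics::image(x$axis1$values, x$axis2$values, x$counts,
                  xlab = x$axis1$name, ylab = x$axis2$name,
                  col = grDevices::hcl.colors(max(x$counts), "viridis"), ...)
  invisible(x)
}

#' Low-energy monostability threshold per parameter value
#'
#' For each value on the first axis of an energy landscape, the largest
#' `A*` grid value below which the system is monostable at every smaller
#' grid value — the separatrix between the single-fate and multi-fate
#' regions.  Columns monostable over the whole energy range are flagged and
#' report the top of the range.
#'
#' @param grid a [attractor_count_grid()] result whose second axis is
#'   `"a_star"`.
#' @return data.frame with columns `axis1` (value), `threshold` (`A*`), and
#'   `monostable_everywhere` (logical marker).
#' @export
monostability_threshold <- function(grid) {
  stopifnot(inherits(grid, "count_grid"))
  if (grid$axis2$name != "a_star") {
    stop("second axis must be a_star", call. = FALSE)
  }
  a_vals <- grid$axis2$values
  res <- lapply(seq_along(grid$axis1$values), function(i) {
    row <- grid$counts[i, ]
    first_multi <- which(row > 1L)[1]
    if (is.na(first_multi)) {
      data.frame(axis1 = grid$axis1$values[i], threshold = max(a_vals),
                 monostable_everywhere = TRUE)
    } else {
      data.frame(axis1 = grid$axis1$values[i],
                 threshold = a_vals[first_multi],
                 monostable_everywhere = FALSE)
    }
  })
  out <- do.call(rbind, res)
  names(out)[1] <- grid$axis1$name
  out
}

#' Map the basins of attraction of the (x1, x2) plane
#'
#' Relaxes every node of a regular grid of initial conditions to rest (see
#' [settle()]) and labels it with the index of the stable attractor it
#' reaches.  Nodes that converge onto a separatrix (the terminal point is a
#' functionally unstable state, matched by no stable attractor) are labelled
#' `NA` and counted as `n_boundary`; these are measure-zero start sets such
#' as the symmetric diagonal of a bistable switch.  Nodes that fail to
#' converge at all are counted as `n_undetermined`, and more than 1% of them
#' is an error (it signals inadequate integrator settings).
#'
#' @param params a [regulatory_params()] object.
#' @param a_star energy level.
#' @param model an [energy_model()].
#' @param resolution grid nodes per axis.
#' @param attractors optional precomputed `attractor_set` (found with
#'   default settings when omitted).
#' @param margin extent multiplier on the steady-state bound.
#' @param conv_tol,t_max,dt integrator settings, see [settle()].
#' @param match_tol attractor matching tolerance.
#' @return An object of class `basin_map`: list with `cells` (data.frame
#'   `x1_0`, `x2_0`, `label`), `attractors`, `resolution`, `n_boundary`,
#'   `n_undetermined`.
#' @export
basin_map <- function(params, a_star, model = energy_model(),
                      resolution = 101L, attractors = NULL, margin = 1.2,
                      conv_tol = 1e-8, t_max = 500, dt = 0.05,
                      match_tol = 1e-3) {
  if (is.null(attractors)) {
    attractors <- find_steady_states(params, a_star, model)
  }
  stab <- stable_states(attractors)
  if (nrow(stab) == 0L) stop("no stable attractor exists", call. = FALSE)
  lam <- attractors$lam
  upper <- max(margin * x_max_bound(params, lam), 1e-3)
  g <- seq(0, upper, length.out = resolution)
  cells <- as.matrix(expand.grid(x1_0 = g, x2_0 = g))
  out <- settle(cells, params, lam, conv_tol = conv_tol, t_max = t_max,
                dt = dt)
  label <- rep(NA_integer_, nrow(cells))
  conv <- out$converged
  if (any(conv)) {
    d2 <- outer(out$states[conv, 1], stab$x1, "-")^2 +
      outer(out$states[conv, 2], stab$x2, "-")^2
    best <- max.col(-d2, ties.method = "first")
    ok <- d2[cbind(seq_along(best), best)] <= match_tol^2
    label[which(conv)[ok]] <- best[ok]
  }
  n_undetermined <- sum(!conv)
  n_boundary <- sum(conv) - sum(!is.na(label))
  if (n_undetermined > 0.01 * nrow(cells)) {
    stop(sprintf("%d of %d basin cells undetermined (>1%%): integrator settings inadequate",
                 n_undetermined, nrow(cells)), call. = FALSE)
  }
  structure(list(cells = data.frame(x1_0 = cells[, 1], x2_0 = cells[, 2],
                                    label = label),
                 attractors = attractors, resolution = resolution,
                 upper = upper,
                 n_boundary = n_boundary, n_undetermined = n_undetermined),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("Basin map: %d x %d cells over [0, %.3g]^2, %d stable attractors\n",
              x$resolution, x$resolution, x$upper,
              nrow(stable_states(x$attractors))))
  print(table(x$cells$label, useNA = "ifany"))
  invisible(x)
}

#' @export
as.data.frame.basin_map <- function(x, ...) x$cells

#' Attractor-count grid over a binding-strength axis
#'
#' Convenience wrapper around [attractor_count_grid()] with the first axis a
#' Hill dissociation constant (`theta_a`: activator binding; `theta_b`:
#' inhibitor binding) and the second axis the energy level.
#'
#' @param axis `"theta_a"` or `"theta_b"`.
#' @param values grid of dissociation-constant values.
#' @param params baseline [regulatory_params()].
#' @param a_star_values energy grid.
#' @param model an [energy_model()].
#' @param ... further arguments to [attractor_count_grid()].
#' @return a `count_grid`.
#' @export
scan_theta <- function(axis = c("theta_a", "theta_b"), values,
                       params = regulatory_params(),
                       a_star_values = seq(0, 1, 0.04),
                       model = energy_model(), ...) {
  axis <- match.arg(axis)
  attractor_count_grid(params,
                       axis1 = list(name = axis, values = values),
                       axis2 = list(name = "a_star", values = a_star_values),
                       model = model, ...)
}
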