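#' Bifurcation sweep over energy availability
#'
#' Calls [find_steady_states()] independently at each value of `A*` on a
#' regular grid (no branch continuation: every energy level is solved from
#' scratch, so the stable count at each point is self-contained) and records
#' the full steady-state set, the stable count, and the energy values at
#' which the stable count changes.
#'
#' @param params a [regulatory_params()] object.
#' @param model an [energy_model()].
#' @param a_star_min,a_star_max sweep range.
#' @param step grid step in `A*`; the canonical fine sweep uses `5e-3`.
#' @param ... further arguments passed to [find_steady_states()]
#'   (e.g. `n_starts`).
#' @return An object of class `bifurcation_sweep`: list with
#'   `a_star_values`, `sets` (list of `attractor_set`), `stable_counts`,
#'   `change_points` (the `A*` values at which the count first differs from
#'   the previous grid point), and `states` (long data.frame with columns
#'   `a_star`, `x1`, `x2`, `stability`, `leading_re`, `residual`).
#' @examples
#' \donttest{
#' sw <- sweep_energy(regulatory_params(), step = 0.05)
#' sw$stable_counts
#' }
#' @export
sweep_energy <- function(params, model = energy_model(),
                         a_star_min = 0, a_star_max = 1, step = 5e-3, ...) {
  stopifnot(step > 0, a_star_max > a_star_min)
  a_vals <- seq(a_star_min, a_star_max, by = step)
  sets <- vector("list", length(a_vals))
  for (i in seq_along(a_vals)) {
    sets[[i]] <- tryCatch(
      find_steady_states(params, a_vals[i], model, ...),
      error = function(e) {
        stop("steady-state solve failed at a_star = ", a_vals[i], ": ",
             conditionMessage(e), call. = FALSE)
      })
  }
  counts <- vapply(sets, function(s) s$n_stable, integer(1))
  change <- a_vals[which(diff(counts) != 0) + 1L]
  states <- do.call(rbind, lapply(sets, as.data.frame))
  rownames(states) <- NULL
  structure(list(a_star_values = a_vals, sets = sets,
                 stable_counts = counts, change_points = change,
                 states = states, params = params, model = model),
            class = "bifurcation_sweep")
}

#' @export
print.bifurcation_sweep <- function(x, ...) {
  rle_runs <- count_sequence(x)
  cat(sprintf("Bifurcation sweep: A* in [%g, %g], %d points\n",
              min(x$a_star_values), max(x$a_star_values),
              length(x$a_star_values)))
  cat("stable-count runs:\n")
  print(rle_runs$runs)
  if (rle_runs$reentrant) cat("re-entrant behaviour detected\n")
  invisible(x)
}

#' @export
as.data.frame.bifurcation_sweep <- function(x, ...) x$states

#' Run-length summary of the stable-count sequence
#'
#' Collapses consecutive equal stable counts along a sweep into runs and
#' flags re-entrant behaviour: a count value that reappears in a later,
#' non-adjacent run (e.g. the sequence 1, 3, 2, 3 as energy increases).
#'
#' @param sweep a [sweep_energy()] result, or a plain integer vector of
#'   stable counts (then `a_star_values` may supply the grid).
#' @param a_star_values optional grid matching a plain counts vector.
#' @return list with `runs` (data.frame: `count`, `a_star_start`,
#'   `a_star_end`, `length`) and `reentrant` (logical).
#' @export
count_sequence <- function(sweep, a_star_values = NULL) {
  if (inherits(sweep, "bifurcation_sweep")) {
    counts <- sweep$stable_counts
    a_vals <- sweep$a_star_values
  } else {
    counts <- as.integer(sweep)
    a_vals <- if (is.null(a_star_values)) seq_along(counts) else a_star_values
  }
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  runs <- data.frame(count = r$values,
                     a_star_start = a_vals[starts],
                     a_star_end = a_vals[ends],
                     length = r$lengths)
  list(runs = runs, reentrant = anyDuplicated(r$values) > 0L)
}

#' Separation of the two extreme attractors along a sweep
#'
#' At each energy value with at least two stable attractors, the Euclidean
#' distance between the high-`x1` and high-`x2` attractors (assigned by
#' [assign_roles()]); `NA` where fewer than two stable states exist.
#'
#' @param sweep a [sweep_energy()] result.
#' @return data.frame with columns `a_star` and `separation`.
#' @export
attractor_separation <- function(sweep) {
  stopifnot(inherits(sweep, "bifurcation_sweep"))
  sep <- vapply(sweep$sets, function(aset) {
    stab <- stable_states(aset)
    if (nrow(stab) < 2L) return(NA_real_)
    roles <- assign_roles(aset)
    h1 <- roles[roles$role == "high_x1", ]
    h2 <- roles[roles$role == "high_x2", ]
    sqrt((h1$x1 - h2$x1)^2 + (h1$x2 - h2$x2)^2)
  }, numeric(1))
  data.frame(a_star = sweep$a_star_values, separation = sep)
}

#' Plot a bifurcation sweep
#'
#' Displays the `x2` component of every steady state against `A*`, stable
#' states in blue and (functionally) unstable states in red.
#'
#' @param x a `bifurcation_sweep`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bifurcation_sweep <- function(x, ...) {
  st <- x$states
  col <- ifelse(st$stability == "stable", "blue", "red")
  graphics::plot(st$a_star, st$x2, col = col, pch = 16, cex = 0.4,
                 xlab = "A*", ylab = "x2", ...)
  invisible(x)
}
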