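#' Built-in analysis scenarios
#'
#' Named, self-describing parameter regimes covering the standard study
#' conditions of the energy-scaled toggle switch: the default tristable
#' sweep, the constitutive-rate-by-energy landscape, the panel series over
#' conditional promoter activity, cooperativity and binding-strength scans,
#' the external-ATP (shifted lambda) variant, the high-activity re-entrance
#' scan, and transition-difficulty grids.  Each scenario records a
#' `provenance` note stating whether its parameter values are canonical
#' (printed defaults) or representative values chosen here (marked
#' `"guessed"`), so downstream analyses never silently depend on a guess.
#'
#' @return Named list of `scenario` objects, each a list with `name`,
#'   `type` (`"sweep"`, `"landscape"`, `"basins"` or `"transitions"`),
#'   `params`, `model`, axis/sweep specifications and `provenance`.
#' @examples
#' names(builtin_scenarios())
#' @export
builtin_scenarios <- function() {
  def <- regulatory_params()
  sig <- energy_model()
  sc <- function(name, type, params = def, model = sig, provenance, ...) {
    structure(c(list(name = name, type = type, params = params,
                     model = model, provenance = provenance), list(...)),
              class = "scenario")
  }
  b_axis <- list(name = "b", values = seq(0, 3, length.out = 31))
  e_axis <- list(name = "a_star", values = seq(0, 1, length.out = 26))
  out <- list(
    defaults_sweep = sc("defaults_sweep", "sweep",
      provenance = "canonical default parameter set; fine energy sweep",
      sweep = list(a_star_min = 0, a_star_max = 1, step = 5e-3)),
    b_energy_landscape = sc("b_energy_landscape", "landscape",
      provenance = "canonical landscape: a = 1, b in [0,3] x A* in [0,1]",
      axis1 = b_axis, axis2 = e_axis),
    a_series_panels = sc("a_series_panels", "landscape",
      provenance = paste("panel series over conditional promoter activity;",
                         "a values guessed (spread over the studied range)"),
      a_values = c(0.25, 0.5, 1, 1.5, 2, 3),
      axis1 = b_axis, axis2 = e_axis),
    cooperativity_1 = sc("cooperativity_1", "landscape",
      params = regulatory_params(n = 1),
      provenance = "noncooperative binding n = 1; canonical axes",
      axis1 = b_axis, axis2 = e_axis),
    cooperativity_2 = sc("cooperativity_2", "landscape",
      params = regulatory_params(n = 2),
      provenance = "cooperativity n = 2; canonical axes",
      axis1 = b_axis, axis2 = e_axis),
    cooperativity_3 = sc("cooperativity_3", "landscape",
      params = regulatory_params(n = 3),
      provenance = "cooperativity n = 3; canonical axes",
      axis1 = b_axis, axis2 = e_axis),
    cooperativity_4 = sc("cooperativity_4", "landscape",
      provenance = "default cooperativity n = 4; canonical axes",
      axis1 = b_axis, axis2 = e_axis),
    theta_a_scan = sc("theta_a_scan", "landscape",
      provenance = paste("activator binding-strength scan;",
                         "theta_a range guessed around the default"),
      axis1 = list(name = "theta_a", values = seq(0.1, 1.5, length.out = 15)),
      axis2 = e_axis),
    theta_b_scan = sc("theta_b_scan", "landscape",
      provenance = paste("inhibitor binding-strength scan;",
                         "theta_b range guessed around the default"),
      axis1 = list(name = "theta_b", values = seq(0.1, 1.5, length.out = 15)),
      axis2 = e_axis),
    external_atp = sc("external_atp", "landscape",
      model = energy_model("shifted"),
      provenance = paste("external-ATP shifted lambda; floor/ceiling",
                         "guessed demonstration values 0.1/1.2"),
      axis1 = b_axis, axis2 = e_axis),
    high_a_reentrant = sc("high_a_reentrant", "sweep",
      provenance = paste("re-entrance scan over conditional promoter",
                         "activity; a values guessed in the high range"),
      a_values = c(1.5, 2, 2.5, 3),
      sweep = list(a_star_min = 0, a_star_max = 1, step = 5e-3)),
    transition_grid_a1 = sc("transition_grid_a1", "transitions",
      provenance = "transition-difficulty grid at a = 1; reduced axes guessed",
      axis1 = list(name = "b", values = seq(0.5, 3, length.out = 6)),
      axis2 = list(name = "a_star", values = seq(0.5, 1, length.out = 6))),
    transition_grid_a2 = sc("transition_grid_a2", "transitions",
      params = regulatory_params(a1 = 2),
      provenance = "transition-difficulty grid at a = 2; reduced axes guessed",
      axis1 = list(name = "b", values = seq(0.5, 3, length.out = 6)),
      axis2 = list(name = "a_star", values = seq(0.5, 1, length.out = 6))),
    transition_grid_a3 = sc("transition_grid_a3", "transitions",
      params = regulatory_params(a1 = 3),
      provenance = "transition-difficulty grid at a = 3; reduced axes guessed",
      axis1 = list(name = "b", values = seq(0.5, 3, length.out = 6)),
      axis2 = list(name = "a_star", values = seq(0.5, 1, length.out = 6)))
  )
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s)\n  %s\n", x$name, x$type, x$provenance))
  invisible(x)
}

#' Look up one built-in scenario by name
#'
#' @param name scenario name; unknown names raise an error listing the
#'   available scenarios.
#' @return a `scenario` object.
#' @export
get_scenario <- function(name) {
  sc <- builtin_scenarios()
  if (!name %in% names(sc)) {
    stop("unknown scenario '", name, "'. Available: ",
         paste(names(sc), collapse = ", "), call. = FALSE)
  }
  sc[[name]]
}

#' Seeded random circuit parameters for property testing
#'
#' Draws parameter sets log-uniformly within the studied ranges
#' (`a, b` in `[0.1, 3]`, `k` in `[0.2, 2]`, `theta` in `[0.1, 1.5]`,
#' `n` in `{1, 2, 3, 4}`).  Symmetric by default (index-1 equals index-2);
#' with `symmetric = FALSE` the two genes are drawn independently.  The
#' global RNG state is restored on exit, so draws are reproducible from
#' `seed` without side effects.
#'
#' @param seed integer seed.
#' @param n number of parameter sets to draw.
#' @param ranges named list of ranges `a`, `b`, `k`, `theta` (length-2
#'   numeric, low < high) and `n_hill` (integer candidates).
#' @param symmetric draw one value per parameter family (`TRUE`) or one per
#'   gene (`FALSE`).
#' @return a single [regulatory_params()] if `n == 1`, else a list of them.
#' @export
random_params <- function(seed, n = 1,
                          ranges = list(a = c(0.1, 3), b = c(0.1, 3),
                                        k = c(0.2, 2), theta = c(0.1, 1.5),
                                        n_hill = 1:4),
                          symmetric = TRUE) {
  for (nm in c("a", "b", "k", "theta")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] <= 0 || r[2] <= r[1]) {
      stop("range for '", nm, "' must be positive and increasing", call. = FALSE)
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif_log <- function(r, m) exp(stats::runif(m, log(r[1]), log(r[2])))
  draws <- lapply(seq_len(n), function(i) {
    m <- if (symmetric) 1L else 2L
    a <- runif_log(ranges$a, m)
    b <- runif_log(ranges$b, m)
    k <- runif_log(ranges$k, m)
    ta <- runif_log(ranges$theta, m)
    tb <- runif_log(ranges$theta, m)
    nh <- ranges$n_hill[sample.int(length(ranges$n_hill), 1L)]
    if (symmetric) {
      regulatory_params(a1 = a, b1 = b, k1 = k, theta_a1 = ta,
                        theta_b1 = tb, n = nh)
    } else {
      regulatory_params(a1 = a[1], a2 = a[2], b1 = b[1], b2 = b[2],
                        k1 = k[1], k2 = k[2],
                        theta_a1 = ta[1], theta_a2 = ta[2],
                        theta_b1 = tb[1], theta_b2 = tb[2], n = nh)
    }
  })
  if (n == 1L) draws[[1]] else draws
}
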