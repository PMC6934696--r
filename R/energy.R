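#' Energy-scaling model lambda(A*)
#'
#' Specifies how the scaled free-energy availability `A*` (the ratio of a
#' cell's free energy availability to its maximum, normally in `[0, 1]`)
#' modulates all production rates of the circuit.  Three kinds are supported:
#'
#' * `"sigmoid"` (default): `lambda(A*) = 1 / (1 + exp(-(s1 A* + s2)))`,
#'   the empirically motivated sigmoidal dependence of transcription rate on
#'   ATP, with defaults `s1 = 16`, `s2 = -8` so that `lambda(0.5) = 0.5`.
#' * `"linear"`: `lambda(A*) = A*` clamped to `[0, 1]`.
#' * `"shifted"`: an affine rescale of the same sigmoid,
#'   `floor + (ceiling - floor) * sigmoid(s1 A* + s2)`, modelling uptake of
#'   external ATP: nonzero at `A* = 0` and allowed to exceed 1.  Defaults
#'   `floor = 0.1`, `ceiling = 1.2` are demonstration values.
#'
#' @param kind one of `"sigmoid"`, `"linear"`, `"shifted"`.
#' @param s1 sigmoid steepness (dimensionless).
#' @param s2 sigmoid offset (dimensionless).
#' @param floor lambda at `A* = 0` for the shifted variant; `floor >= 0`.
#' @param ceiling maximum lambda for the shifted variant; `ceiling > floor`.
#' @return An object of class `energy_model`.
#' @examples
#' lambda_energy(0.5, energy_model())            # exactly 0.5
#' lambda_energy(0,   energy_model("shifted"))   # the floor value
#' @export
energy_model <- function(kind = c("sigmoid", "linear", "shifted"),
                         s1 = 16, s2 = -8, floor = NULL, ceiling = NULL) {
  kind <- match.arg(kind)
  if (is.null(floor)) floor <- if (kind == "shifted") 0.1 else 0
  if (is.null(ceiling)) ceiling <- if (kind == "shifted") 1.2 else 1
  stopifnot(is.finite(s1), is.finite(s2), is.finite(floor), is.finite(ceiling))
  if (floor < 0) stop("floor must be >= 0", call. = FALSE)
  if (ceiling <= floor) stop("ceiling must exceed floor", call. = FALSE)
  structure(list(kind = kind, s1 = as.numeric(s1), s2 = as.numeric(s2),
                 floor = as.numeric(floor), ceiling = as.numeric(ceiling)),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("Energy model: %s (s1 = %g, s2 = %g", x$kind, x$s1, x$s2))
  if (x$kind == "shifted") {
    cat(sprintf(", floor = %g, ceiling = %g", x$floor, x$ceiling))
  }
  cat(")\n")
  invisible(x)
}

#' Production-rate scaling factor at a given energy level
#'
#' Evaluates `lambda(A*)` under an [energy_model()].  Vectorised over
#' `a_star`.  The output is strictly increasing in `A*` on `[0, 1]` for every
#' model kind; the sigmoid kind with default `s1`, `s2` is strictly inside
#' `(0, 1)` for all finite `A*` and equals 0.5 exactly at `A* = 0.5`.
#'
#' @param a_star scaled free-energy availability; finite numeric.  Values
#'   outside `[0, 1]` trigger a warning for the sigmoid and linear kinds
#'   (they are expected only when exploring the shifted, external-ATP model).
#' @param model an [energy_model()].
#' @return numeric vector of scaling factors (dimensionless).
#' @export
lambda_energy <- function(a_star, model = energy_model()) {
  stopifnot(inherits(model, "energy_model"), all(is.finite(a_star)))
  if (model$kind != "shifted" && any(a_star < 0 | a_star > 1)) {
    warning("a_star outside [0, 1] under the ", model$kind, " energy model",
            call. = FALSE)
  }
  sig <- function(z) 1 / (1 + exp(-z))
  switch(model$kind,
    sigmoid = sig(model$s1 * a_star + model$s2),
    linear  = pmin(pmax(a_star, 0), 1),
    shifted = model$floor +
      (model$ceiling - model$floor) * sig(model$s1 * a_star + model$s2)
  )
}

#' Map an ATP concentration onto the scaled energy axis
#'
#' Linear map of an intracellular ATP concentration (in micromolar) onto
#' `A* = (conc - lo) / (hi - lo)`.  The default bounds are the observed
#' E. coli range, 320--2760 uM: at the lower bound expression capacity is
#' minimal and below it a cell is considered sub-critical (non-viable), at
#' the upper bound lambda is maximal.
#'
#' @param conc ATP concentration in uM; strictly positive. Vectorised.
#' @param lo,hi concentration bounds in uM mapping to `A* = 0` and `A* = 1`;
#'   `hi > lo > 0`.
#' @return A list with components `a_star` (numeric), `sub_critical`
#'   (logical, `conc < lo`: mapped `A*` is negative, flagged non-viable) and
#'   `at_boundary` (logical, `conc == lo`: exactly at the critical energy).
#' @examples
#' map_atp_to_astar(1540)  # midpoint of the E. coli range -> A* = 0.5
#' @export
map_atp_to_astar <- function(conc, lo = 320, hi = 2760) {
  stopifnot(is.numeric(conc), hi > lo, lo > 0)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("ATP concentration must be finite and strictly positive", call. = FALSE)
  }
  a_star <- (conc - lo) / (hi - lo)
  list(a_star = a_star,
       sub_critical = conc < lo,
       at_boundary = conc == lo)
}
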