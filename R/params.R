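#' Circuit parameters for the two-gene toggle switch
#'
#' Constructs the parameter set of the self-activating, cross-repressing
#' two-gene circuit.  Each gene `i` has a conditional (auto-activated)
#' promoter with maximum rate `a_i`, a constitutive promoter with basal rate
#' `b_i` that is repressed by the other gene's product, a first-order
#' degradation rate `k_i`, and Hill dissociation constants `theta_a_i`
#' (activator) and `theta_b_i` (inhibitor).  A single Hill coefficient `n`
#' sets the cooperativity of all regulatory binding terms.
#'
#' Calling `regulatory_params()` with no arguments returns the canonical
#' default set `a = b = k = 1`, `theta_a = theta_b = 0.5`, `n = 4`, which is
#' tristable at full energy.  Index-2 values default to their index-1
#' counterparts, so supplying e.g. `a1 = 2` yields a symmetric circuit with
#' `a1 = a2 = 2`.
#'
#' @param a1,a2 maximum expression rate of the conditional promoter
#'   (concentration/time), strictly positive.
#' @param b1,b2 basal expression rate of the constitutive promoter
#'   (concentration/time), non-negative.
#' @param k1,k2 first-order degradation rate (1/time), strictly positive.
#' @param theta_a1,theta_a2 activator dissociation constant (concentration).
#' @param theta_b1,theta_b2 inhibitor dissociation constant (concentration).
#' @param n Hill coefficient (dimensionless), `n >= 1`.
#'
#' @return An object of class `regulatory_params`: a named list with the
#'   eleven fields above.
#' @examples
#' p <- regulatory_params()          # canonical defaults, tristable
#' p2 <- regulatory_params(a1 = 2)   # symmetric circuit with a = 2
#' @export
regulatory_params <- function(a1 = 1, a2 = a1, b1 = 1, b2 = b1,
                              k1 = 1, k2 = k1,
                              theta_a1 = 0.5, theta_a2 = theta_a1,
                              theta_b1 = 0.5, theta_b2 = theta_b1,
                              n = 4) {
  p <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, k1 = k1, k2 = k2,
            theta_a1 = theta_a1, theta_a2 = theta_a2,
            theta_b1 = theta_b1, theta_b2 = theta_b2, n = n)
  p <- lapply(p, as.numeric)
  validate_params(p)
  structure(p, class = "regulatory_params")
}

validate_params <- function(p) {
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("all circuit parameters must be finite numeric scalars", call. = FALSE)
  }
  pos <- c("a1", "a2", "k1", "k2", "theta_a1", "theta_a2", "theta_b1", "theta_b2")
  if (any(unlist(p[pos]) <= 0)) {
    stop("rates a, k and dissociation constants theta must be strictly positive",
         call. = FALSE)
  }
  if (p$b1 < 0 || p$b2 < 0) {
    stop("basal rates b must be non-negative", call. = FALSE)
  }
  if (p$n < 1) stop("Hill coefficient n must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.regulatory_params <- function(x, ...) {
  cat("Toggle-switch circuit parameters\n")
  cat(sprintf("  conditional promoter  a = (%g, %g)\n", x$a1, x$a2))
  cat(sprintf("  constitutive promoter b = (%g, %g)\n", x$b1, x$b2))
  cat(sprintf("  degradation           k = (%g, %g)\n", x$k1, x$k2))
  cat(sprintf("  activator theta_a       = (%g, %g)\n", x$theta_a1, x$theta_a2))
  cat(sprintf("  inhibitor theta_b       = (%g, %g)\n", x$theta_b1, x$theta_b2))
  cat(sprintf("  Hill coefficient      n = %g\n", x$n))
  invisible(x)
}

#' Test whether a parameter set is symmetric in the two genes
#'
#' @param params a [regulatory_params()] object.
#' @param tol numeric tolerance for equality of paired fields.
#' @return `TRUE` if every index-1 field equals its index-2 counterpart.
#' @export
is_symmetric <- function(params, tol = 0) {
  stopifnot(inherits(params, "regulatory_params"))
  pairs <- list(c("a1", "a2"), c("b1", "b2"), c("k1", "k2"),
                c("theta_a1", "theta_a2"), c("theta_b1", "theta_b2"))
  all(vapply(pairs, function(pr) {
    abs(params[[pr[1]]] - params[[pr[2]]]) <= tol
  }, logical(1)))
}

# Override one symmetric parameter family ("a", "b", "k", "theta_a",
# "theta_b", "n") or a single named field.  Used by landscape/scenario axes.
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "regulatory_params"))
  p <- unclass(params)
  if (name %in% c("a", "b", "k", "theta_a", "theta_b")) {
    p[[paste0(name, "1")]] <- as.numeric(value)
    p[[paste0(name, "2")]] <- as.numeric(value)
  } else if (name %in% names(p)) {
    p[[name]] <- as.numeric(value)
  } else {
    stop("unknown parameter name: ", name, call. = FALSE)
  }
  validate_params(p)
  structure(p, class = "regulatory_params")
}

#' Read or write circuit parameters as a flat YAML or JSON config
#'
#' Parameter sets serialise to a flat mapping with exactly the field names of
#' [regulatory_params()]; the default set round-trips losslessly.  The format
#' is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param params a [regulatory_params()] object.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a [regulatory_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "regulatory_params"))
  flat <- lapply(unclass(params), as.numeric)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(flat, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  flat <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  do.call(regulatory_params, flat)
}
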