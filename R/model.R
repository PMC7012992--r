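# Model ingredients: i-state space, growth/death rates, Dirac-mixture birth
# law and output weight functions, all held in separated form.

#' Define the individual-state space
#'
#' @param dim number of i-state coordinates (>= 1).
#' @param lower,upper numeric vectors of length `dim`; `upper` entries may be
#'   `Inf`.
#' @param x_b reference/birth point in the closure of the interior.  Defaults
#'   to `lower` when all its entries are finite.
#' @return an `istate_space` object.  Coordinate symbols are `x` for
#'   one-dimensional spaces and `x1`, `x2`, ... otherwise.
#' @export
istate_space <- function(dim = 1L, lower = 0, upper = Inf, x_b = NULL) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1, length(lower) == dim, length(upper) == dim)
  if (any(!is.finite(lower))) stop("lower bounds must be finite")
  if (any(lower >= upper)) stop("each lower bound must be below its upper bound")
  if (is.null(x_b)) {
    x_b <- lower
  }
  stopifnot(length(x_b) == dim)
  if (any(x_b < lower - 1e-12) || any(x_b > upper + 1e-12))
    stop("x_b must lie within the bounds")
  vars <- if (dim == 1) "x" else paste0("x", seq_len(dim))
  structure(list(dim = dim, lower = as.numeric(lower), upper = as.numeric(upper),
                 x_b = as.numeric(x_b), vars = vars),
            class = "istate_space")
}

#' @export
print.istate_space <- function(x, ...) {
  cat(sprintf("<i-state space> dim %d: %s, x_b = (%s)\n", x$dim,
              paste(sprintf("[%g, %g]", x$lower, x$upper), collapse = " x "),
              paste(signif(x$x_b, 6), collapse = ", ")))
  invisible(x)
}

#' Define a birth term of a Dirac-mixture birth law
#'
#' The birth law is a finite sum of terms, each a per-capita rate weight
#' (a separated expression in the parent's i-state and the environment)
#' placing offspring as a point mass at a fixed birth state.
#'
#' @param rate_weight expression (string/symf/sep_expr) for the rate.
#' @param birth_state numeric i-state at which offspring appear.
#' @param atoms atom names used by `rate_weight`.
#' @return a `birth_term` object.
#' @export
birth_term <- function(rate_weight, birth_state, atoms = character(0)) {
  structure(list(rate_weight = normalize_separated(rate_weight, atoms),
                 birth_state = as.numeric(birth_state)),
            class = "birth_term")
}

#' Assemble a physiologically structured population model
#'
#' @param space an [istate_space()].
#' @param atoms list of [env_atom()]s (or character names).
#' @param g growth rate: one expression for dim 1, else a list of `dim`
#'   expressions (strings are parsed; atoms allowed).
#' @param mu death rate expression.
#' @param births list of [birth_term()]s.
#' @param outputs list of output weight-function expressions (the gamma_i).
#'   May use atoms (environment-modulated outputs).
#' @param name optional label.
#' @return a `pspm_model`.
#' @export
pspm_model <- function(space, atoms, g, mu, births = list(), outputs = list(),
                       name = "model") {
  anames <- atom_names(atoms)
  if (!is.list(g) || is_sep(g)) g <- list(g)
  stopifnot(length(g) == space$dim)
  g <- lapply(g, normalize_separated, atoms = anames)
  mu <- normalize_separated(mu, anames)
  if (inherits(births, "birth_term")) births <- list(births)
  outputs <- lapply(outputs, normalize_separated, atoms = anames)
  structure(list(space = space, atoms = anames, g = g, mu = mu,
                 births = births, outputs = outputs, name = name),
            class = "pspm_model")
}

#' @export
print.pspm_model <- function(x, ...) {
  cat(sprintf("<PSPM '%s'> dim %d, atoms: %s\n", x$name, x$space$dim,
              paste(x$atoms, collapse = ", ")))
  cat("  g : ", paste(vapply(x$g, sep_format, character(1)), collapse = " ; "), "\n")
  cat("  mu: ", sep_format(x$mu), "\n")
  for (b in x$births)
    cat(sprintf("  birth at (%s): %s\n", paste(signif(b$birth_state, 6), collapse = ","),
                sep_format(b$rate_weight)))
  cat(sprintf("  %d output weight function(s)\n", length(x$outputs)))
  invisible(x)
}

#' Validate a model's structural invariants
#'
#' Checks that every expression uses only declared atoms and i-state symbols,
#' that birth states lie within the i-state space, and that the growth rate is
#' positive on a sampled grid at a reference atom valuation (so that every
#' i-state is reachable from the birth state).
#'
#' @param model a [pspm_model()].
#' @param reference_valuation named numeric values for the atoms (default: all
#'   equal to 1) at which positivity of `g` is probed.
#' @param n_grid grid points per coordinate for the positivity probe.
#' @return character vector of human-readable diagnostics; empty when valid.
#' @export
validate_model <- function(model, reference_valuation = NULL, n_grid = 25L) {
  diags <- character(0)
  sp <- model$space
  if (is.null(reference_valuation))
    reference_valuation <- stats::setNames(rep(1, length(model$atoms)), model$atoms)
  allowed <- c(model$atoms, sp$vars)
  check_syms <- function(se, what) {
    syms <- unique(unlist(lapply(se$components, function(cp)
      c(names(cp$mono), sf_symbols(cp$x)))))
    bad <- setdiff(syms, allowed)
    if (length(bad))
      diags <<- c(diags, sprintf("%s references undeclared symbol(s): %s",
                                 what, paste(bad, collapse = ", ")))
  }
  for (i in seq_along(model$g)) check_syms(model$g[[i]], sprintf("g[%d]", i))
  check_syms(model$mu, "mu")
  for (i in seq_along(model$outputs)) check_syms(model$outputs[[i]], sprintf("output[%d]", i))
  for (i in seq_along(model$births)) {
    b <- model$births[[i]]
    check_syms(b$rate_weight, sprintf("birth[%d] rate", i))
    if (length(b$birth_state) != sp$dim)
      diags <- c(diags, sprintf("birth[%d] state has wrong dimension", i))
    else if (any(b$birth_state < sp$lower - 1e-12) || any(b$birth_state > sp$upper + 1e-12))
      diags <- c(diags, sprintf("birth[%d] state (%s) lies outside the i-state space",
                                i, paste(signif(b$birth_state, 6), collapse = ",")))
  }
  # positivity of g at the reference valuation (reachability)
  if (!length(diags)) {
    grid <- space_grid(sp, n_grid)
    for (i in seq_along(model$g)) {
      gi <- sep_at_valuation(model$g[[i]], reference_valuation)
      vals <- tryCatch(do.call(sf_fun(gi, sp$vars), grid), error = function(e) NA)
      if (any(!is.finite(vals)))
        diags <- c(diags, sprintf("g[%d] not finite on the probe grid", i))
      else if (sp$dim == 1 && any(vals <= 0))
        diags <- c(diags, sprintf(
          "g is not positive on the i-state space at the reference valuation (min %.3g)",
          min(vals)))
    }
  }
  diags
}

# interior grid (list of coordinate vectors, recycled to a full grid)
space_grid <- function(space, n = 25L) {
  axes <- lapply(seq_len(space$dim), function(i) {
    hi <- if (is.finite(space$upper[i])) space$upper[i] else space$x_b[i] + 1
    seq(space$lower[i] + 1e-9, hi - 1e-9, length.out = n)
  })
  g <- do.call(expand.grid, axes)
  stats::setNames(as.list(g), space$vars)
}

# seeded interior sample points used by independence checks / coefficient
# solves; span default 1 beyond x_b when the upper bound is infinite
space_sample <- function(space, m, seed, span = 1) {
  pts <- withr_seed(seed, {
    lapply(seq_len(space$dim), function(i) {
      hi <- if (is.finite(space$upper[i])) space$upper[i] else space$x_b[i] + span
      lo <- max(space$lower[i], space$x_b[i])
      lo + (hi - lo) * stats::runif(m, 0.02, 0.98)
    })
  })
  stats::setNames(pts, space$vars)
}

# run code with a local RNG seed, restoring the global state afterwards
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
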