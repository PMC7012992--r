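# Separated expressions: finite sums of (environment monomial) x (i-state
# function) terms.  The environment enters all model ingredients only through
# named scalar atoms, and the TEST's linear algebra is exact precisely because
# atoms appear polynomially, so every backward-operator image splits into
# finitely many environment monomials with symbolic i-state parts.

#' Declare an environment atom
#'
#' An atom is an opaque scalar function of the environmental condition E
#' (e.g. a functional response `f(E)` or a background death rate `mu0(E)`).
#' The toolkit never evaluates E itself; it only substitutes numeric values
#' for atoms.
#'
#' @param name identifier (a valid symbol name).
#' @param description free text.
#' @return an object of class `env_atom`.
#' @export
env_atom <- function(name, description = "") {
  stopifnot(is.character(name), length(name) == 1, grepl("^[A-Za-z][A-Za-z0-9_]*$", name))
  structure(list(name = name, description = description), class = "env_atom")
}

#' @export
print.env_atom <- function(x, ...) {
  cat("<env atom>", x$name, if (nzchar(x$description)) paste0("- ", x$description), "\n")
  invisible(x)
}

# ---- monomial helpers ------------------------------------------------------

mono_key <- function(mono) {
  if (!length(mono)) return("1")
  o <- order(names(mono))
  paste0(names(mono)[o], "^", mono[o], collapse = "*")
}

mono_format <- function(mono) {
  if (!length(mono)) return("1")
  o <- order(names(mono))
  paste(ifelse(mono[o] == 1, names(mono)[o],
               paste0(names(mono)[o], "^", mono[o])), collapse = "*")
}

mono_eval <- function(mono, valuation) {
  if (!length(mono)) return(1)
  prod(unlist(valuation)[names(mono)]^mono)
}

mono_mul <- function(a, b) {
  for (nm in names(b)) a[nm] <- (if (nm %in% names(a)) a[[nm]] else 0L) + b[[nm]]
  a <- a[a != 0]
  if (!length(a)) integer(0) else a[order(names(a))]
}

# ---- separated expression --------------------------------------------------

sep_new <- function(components, atoms) {
  structure(list(components = components, atoms = atoms), class = "sep_expr")
}

is_sep <- function(x) inherits(x, "sep_expr")

#' Normalise a symbolic expression into separated form
#'
#' Splits an expression in i-state symbols and environment atoms into a merged
#' list of (environment monomial, i-state function) terms.  Atoms must appear
#' polynomially (default degree cap 2) and must not occur inside exp/log/trig
#' or general-power kernels of i-state quantities.
#'
#' @param expr a string, R language object, `symf`, or an existing separated
#'   expression (returned unchanged up to atom bookkeeping).
#' @param atoms character vector of atom names, or a list of [env_atom()]s.
#' @param degree_cap maximum total atom degree allowed per term.
#' @return an object of class `sep_expr`.
#' @export
normalize_separated <- function(expr, atoms, degree_cap = 2L) {
  anames <- atom_names(atoms)
  if (is_sep(expr)) return(sep_new(expr$components, anames))
  x <- sf_canonical(as_symf(expr))
  comps <- list()
  for (t in x$terms) {
    mono <- integer(0); rest_pow <- numeric(0)
    for (nm in names(t$pow)) {
      f <- sf_factor(nm)
      if (f$kind == "sym" && f$name %in% anames) {
        p <- t$pow[[nm]]
        if (p != round(p) || p < 0)
          stop(pspm_condition("pspm_nonseparable_error", sprintf(
            "atom '%s' appears with non-polynomial power %g", f$name, p)))
        mono[f$name] <- as.integer(p)
      } else {
        if (f$kind != "sym" && any(sf_symbols(f$arg) %in% anames))
          stop(pspm_condition("pspm_nonseparable_error", sprintf(
            "atom occurs inside a transcendental/power kernel: %s", nm)))
        rest_pow[nm] <- t$pow[[nm]]
      }
    }
    if (!is.null(t$e) && any(sf_symbols(t$e) %in% anames))
      stop(pspm_condition("pspm_nonseparable_error",
                          "atom occurs inside an exponential"))
    if (length(mono) && sum(mono) > degree_cap)
      stop(pspm_condition("pspm_nonseparable_error", sprintf(
        "atom monomial %s exceeds degree cap %d", mono_format(mono), degree_cap)))
    xt <- sf_new(list(list(coef = t$coef, pow = rest_pow, e = t$e)))
    key <- mono_key(mono)
    if (is.null(comps[[key]])) comps[[key]] <- list(mono = mono, x = xt)
    else comps[[key]]$x <- sf_new(c(comps[[key]]$x$terms, xt$terms))
  }
  comps <- lapply(comps, function(cp) { cp$x <- sf_canonical(cp$x); cp })
  comps <- Filter(function(cp) length(cp$x$terms) > 0, comps)
  if (length(comps)) comps <- comps[order(names(comps))]
  sep_new(unname(comps), anames)
}

atom_names <- function(atoms) {
  if (is.character(atoms)) return(atoms)
  vapply(atoms, function(a) if (inherits(a, "env_atom")) a$name else as.character(a),
         character(1))
}

#' @export
print.sep_expr <- function(x, ...) {
  if (!length(x$components)) { cat("0\n"); return(invisible(x)) }
  parts <- vapply(x$components, function(cp) {
    m <- mono_format(cp$mono)
    xs <- sf_format(cp$x)
    if (m == "1") xs else paste0(m, " * (", xs, ")")
  }, character(1))
  cat(paste(parts, collapse = "  +  "), "\n")
  invisible(x)
}

# arithmetic on separated expressions ---------------------------------------

sep_zero <- function(atoms) sep_new(list(), atom_names(atoms))

sep_add <- function(a, b) {
  comps <- list()
  for (cp in c(a$components, b$components)) {
    key <- mono_key(cp$mono)
    if (is.null(comps[[key]])) comps[[key]] <- cp
    else comps[[key]]$x <- sf_add(comps[[key]]$x, cp$x)
  }
  comps <- Filter(function(cp) length(sf_canonical(cp$x)$terms) > 0, comps)
  comps <- lapply(comps, function(cp) { cp$x <- sf_canonical(cp$x); cp })
  if (length(comps)) comps <- comps[order(names(comps))]
  sep_new(unname(comps), union(a$atoms, b$atoms))
}

sep_scale <- function(a, c) {
  sep_new(lapply(a$components, function(cp) { cp$x <- sf_scale(cp$x, c); cp }), a$atoms)
}

sep_neg <- function(a) sep_scale(a, -1)
sep_sub <- function(a, b) sep_add(a, sep_neg(b))

# multiply by an atom-free symbolic factor
sep_mul_symf <- function(a, s) {
  comps <- lapply(a$components, function(cp) { cp$x <- sf_mul(cp$x, s); cp })
  comps <- Filter(function(cp) length(cp$x$terms) > 0, comps)
  sep_new(comps, a$atoms)
}

sep_mul <- function(a, b) {
  out <- sep_zero(union(a$atoms, b$atoms))
  for (ca in a$components) for (cb in b$components) {
    out <- sep_add(out, sep_new(list(list(
      mono = mono_mul(ca$mono, cb$mono), x = sf_mul(ca$x, cb$x))),
      out$atoms))
  }
  out
}

# reconstruct a single symf in which atoms are plain symbols
sep_to_symf <- function(a) {
  out <- sf_zero()
  for (cp in a$components) {
    m <- sf_const(1)
    for (nm in names(cp$mono)) m <- sf_mul(m, sf_pow_int(sf_sym(nm), cp$mono[[nm]]))
    out <- sf_add(out, sf_mul(m, cp$x))
  }
  out
}

# substitute numeric atom values -> plain symf in i-state variables
sep_at_valuation <- function(a, valuation) {
  out <- sf_zero()
  for (cp in a$components)
    out <- sf_add(out, sf_scale(cp$x, mono_eval(cp$mono, valuation)))
  sf_canonical(out)
}

sep_max_coef <- function(a) {
  if (!length(a$components)) return(0)
  max(vapply(a$components, function(cp) sf_max_coef(cp$x), numeric(1)))
}

sep_is_zero <- function(a, scale = 1, tol = 1e-9) {
  all(vapply(a$components, function(cp) sf_is_zero(cp$x, scale, tol), logical(1)))
}

sep_deriv <- function(a, var) {
  sep_new(Filter(function(cp) length(cp$x$terms) > 0,
                 lapply(a$components, function(cp) { cp$x <- sf_deriv(cp$x, var); cp })),
          a$atoms)
}

sep_format <- function(a) {
  if (!length(a$components)) return("0")
  paste(vapply(a$components, function(cp) {
    m <- mono_format(cp$mono)
    if (m == "1") sf_format(cp$x) else paste0(m, "*(", sf_format(cp$x), ")")
  }, character(1)), collapse = " + ")
}
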