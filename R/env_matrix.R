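# Matrices whose entries are polynomials in the environment atoms:
# K(E), H(E), M(E), Q(E).  Stored as a union list of atom monomials plus a
# numeric coefficient array (nrow x ncol x n_monomials).

em_new <- function(nrow, ncol, monos = list(), coefs = NULL) {
  if (is.null(coefs)) coefs <- array(0, dim = c(nrow, ncol, max(1L, length(monos))))
  if (!length(monos)) { monos <- list(integer(0)); coefs <- array(0, dim = c(nrow, ncol, 1)) }
  structure(list(monos = monos, coefs = coefs), class = "env_matrix")
}

em_dim <- function(em) dim(em$coefs)[1:2]

# build from a list of entries: list(i, j, mono, coef)
em_from_entries <- function(entries, nrow, ncol) {
  keys <- vapply(entries, function(e) mono_key(e$mono), character(1))
  uk <- unique(keys)
  monos <- lapply(uk, function(k) entries[[match(k, keys)]]$mono)
  coefs <- array(0, dim = c(nrow, ncol, length(uk)))
  for (idx in seq_along(entries)) {
    e <- entries[[idx]]; m <- match(keys[idx], uk)
    coefs[e$i, e$j, m] <- coefs[e$i, e$j, m] + e$coef
  }
  em_new(nrow, ncol, monos, coefs)
}

# entry (i,j) as a list of (mono, coef) with negligible coefs dropped
em_entry <- function(em, i, j, tol = 0) {
  out <- list()
  for (m in seq_along(em$monos)) {
    c <- em$coefs[i, j, m]
    if (abs(c) > tol) out[[length(out) + 1L]] <- list(mono = em$monos[[m]], coef = c)
  }
  out
}

em_entry_format <- function(em, i, j, tol = 1e-12) {
  parts <- vapply(em_entry(em, i, j, tol), function(t) {
    m <- mono_format(t$mono)
    if (m == "1") sprintf("%.6g", t$coef)
    else if (t$coef == 1) m
    else sprintf("%.6g*%s", t$coef, m)
  }, character(1))
  if (!length(parts)) "0" else paste(parts, collapse = " + ")
}

#' Evaluate an environment-dependent matrix at an atom valuation
#'
#' @param em an `env_matrix` (e.g. the `K` of a reduction result).
#' @param valuation named numeric atom values.
#' @return a numeric matrix.
#' @export
em_eval <- function(em, valuation) {
  d <- em_dim(em)
  out <- matrix(0, d[1], d[2])
  for (m in seq_along(em$monos))
    out <- out + em$coefs[, , m, drop = TRUE] * mono_eval(em$monos[[m]], valuation)
  out
}

em_add <- function(a, b, sb = 1) {
  d <- em_dim(a)
  entries <- list()
  grab <- function(em, s) {
    for (m in seq_along(em$monos)) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      c <- em$coefs[i, j, m]
      if (c != 0) entries[[length(entries) + 1L]] <<- list(i = i, j = j, mono = em$monos[[m]], coef = s * c)
    }
  }
  grab(a, 1); grab(b, sb)
  if (!length(entries)) return(em_new(d[1], d[2]))
  em_from_entries(entries, d[1], d[2])
}

em_sub <- function(a, b) em_add(a, b, sb = -1)

em_max_abs <- function(em) max(abs(em$coefs))

# entrywise comparison of the symbolic coefficients
em_equal <- function(a, b, tol = 1e-8) {
  d <- em_sub(a, b)
  em_max_abs(d) <= tol * max(em_max_abs(a), em_max_abs(b), 1)
}

# diagonal matrix from a single monomial times scalar (e.g. -mu0 I)
em_diag <- function(k, mono, coef) {
  entries <- lapply(seq_len(k), function(i) list(i = i, j = i, mono = mono, coef = coef))
  em_from_entries(entries, k, k)
}

# constant (atom-free) matrix
em_const <- function(M) {
  d <- dim(M)
  entries <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    if (M[i, j] != 0) entries[[length(entries) + 1L]] <- list(i = i, j = j, mono = integer(0), coef = M[i, j])
  if (!length(entries)) return(em_new(d[1], d[2]))
  em_from_entries(entries, d[1], d[2])
}

# multiply all entries by a single atom monomial
em_mono_scale <- function(em, mono, coef = 1) {
  monos <- lapply(em$monos, mono_mul, b = mono)
  em_new(em_dim(em)[1], em_dim(em)[2], monos, em$coefs * coef)
}

#' @export
print.env_matrix <- function(x, ...) {
  d <- em_dim(x)
  for (i in seq_len(d[1])) {
    cat("[", paste(vapply(seq_len(d[2]), function(j) em_entry_format(x, i, j), character(1)),
                   collapse = " | "), "]\n")
  }
  invisible(x)
}

# serialisable form: nested list of {monomial, coefficient} terms
em_to_list <- function(em, tol = 1e-12) {
  d <- em_dim(em)
  lapply(seq_len(d[1]), function(i) lapply(seq_len(d[2]), function(j) {
    lapply(em_entry(em, i, j, tol), function(t)
      list(monomial = mono_format(t$mono), coefficient = t$coef))
  }))
}

# (i,j) entry as a sep_expr with constant x-part (for residual algebra)
em_entry_sep <- function(em, i, j, atoms) {
  comps <- lapply(em_entry(em, i, j), function(t)
    list(mono = t$mono, x = sf_const(t$coef)))
  sep_new(comps, atoms)
}
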