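# The complete catalogue of one-dimensional reducible transport-degradation
# models: F1 (scalar survival-weight), F2 (physiological age with
# matrix-exponential weights), F3 (generalised von Bertalanffy with
# polynomial-in-zeta weights), plus the trigonometric special matrices and
# the age-structured linear chain trick.

# ---- environment linear/polynomial forms ----------------------------------
# small helper representation for parameters like v1(E): a list of
# (atom monomial, coefficient) pairs

ev_from <- function(x) {
  if (is.numeric(x)) {
    if (x == 0) return(list())
    return(list(list(mono = integer(0), coef = as.numeric(x))))
  }
  if (inherits(x, "env_atom")) x <- x$name
  if (is.character(x)) {
    m <- 1L; names(m) <- x
    return(list(list(mono = m, coef = 1)))
  }
  if (is.list(x)) return(x)   # already an ev form
  stop("cannot interpret environment parameter")
}

ev_scale <- function(ev, c) {
  if (c == 0) return(list())
  lapply(ev, function(t) { t$coef <- t$coef * c; t })
}

ev_add <- function(...) {
  out <- list()
  for (ev in list(...)) for (t in ev) {
    key <- mono_key(t$mono)
    if (is.null(out[[key]])) out[[key]] <- t
    else out[[key]]$coef <- out[[key]]$coef + t$coef
  }
  unname(Filter(function(t) abs(t$coef) > 1e-14, out))
}

ev_atoms <- function(ev) unique(unlist(lapply(ev, function(t) names(t$mono))))

ev_to_sep <- function(ev, x_part, atoms) {
  comps <- lapply(ev, function(t) list(mono = t$mono, x = sf_scale(x_part, t$coef)))
  sep_new(Filter(function(cp) length(cp$x$terms) > 0, comps), atoms)
}

ev_eval <- function(ev, valuation) {
  if (!length(ev)) return(0)
  sum(vapply(ev, function(t) t$coef * mono_eval(t$mono, valuation), numeric(1)))
}

ev_format <- function(ev) {
  if (!length(ev)) return("0")
  paste(vapply(ev, function(t) {
    m <- mono_format(t$mono)
    if (m == "1") sprintf("%g", t$coef)
    else if (t$coef == 1) m else sprintf("%g*%s", t$coef, m)
  }, character(1)), collapse = " + ")
}

# env matrix entries from ev forms: entries list(i,j,ev)
em_from_ev_entries <- function(entries, nrow, ncol) {
  flat <- list()
  for (e in entries) for (t in e$ev)
    flat[[length(flat) + 1L]] <- list(i = e$i, j = e$j, mono = t$mono, coef = t$coef)
  if (!length(flat)) return(em_new(nrow, ncol))
  em_from_entries(flat, nrow, ncol)
}

# ---- (H2)/(H3) -------------------------------------------------------------

#' Check the non-degeneracy conditions (H2) and (H3)
#'
#' (H2): every eigenvalue of `Lambda` has geometric multiplicity one.
#' (H3): when `w0` is expanded in a basis of (generalised) eigenvectors, the
#' coefficient on the highest-rank generalised eigenvector of every Jordan
#' chain is nonzero.  Together they certify that the components of
#' `exp(x Lambda) w0` are linearly independent scalar functions.
#'
#' @param Lambda real square matrix.
#' @param w0 real vector of matching length.
#' @param tol numeric tolerance for eigenvalue clustering and ranks.
#' @return list with `ok`, `h2`, `h3` and `details` naming any offending
#'   eigenvalue.
#' @export
check_h2_h3 <- function(Lambda, w0, tol = 1e-8) {
  k <- nrow(Lambda)
  stopifnot(ncol(Lambda) == k, length(w0) == k)
  ev <- eigen(Lambda, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  groups <- cluster_values(ev, tol * scale)
  h2 <- TRUE; h3 <- TRUE; details <- character(0)
  spaces <- list()
  for (gi in seq_along(groups)) {
    lam <- groups[[gi]]$value; m <- groups[[gi]]$mult
    N <- Lambda - diag(lam, k)
    geo <- k - mat_rank(N, tol)
    if (geo > 1) {
      h2 <- FALSE
      details <- c(details, sprintf("eigenvalue %s has geometric multiplicity %d",
                                    format(lam, digits = 6), geo))
    }
    spaces[[gi]] <- list(lam = lam, m = m, N = N)
  }
  if (h2) {
    for (gi in seq_along(spaces)) {
      s <- spaces[[gi]]
      B <- NULL
      if (s$m > 1) B <- null_basis(mat_pow(s$N, s$m - 1L), tol)
      for (gj in seq_along(spaces)) if (gj != gi) {
        o <- spaces[[gj]]
        B <- cbind(B, null_basis(mat_pow(o$N, o$m), tol))
      }
      if (is.null(B)) B <- matrix(0 + 0i, k, 0)
      aug <- cbind(B, as.complex(w0))
      if (mat_rank(aug, tol) == mat_rank(B, tol)) {
        h3 <- FALSE
        details <- c(details, sprintf(
          "w0 has zero coefficient on the highest-rank generalised eigenvector of eigenvalue %s",
          format(s$lam, digits = 6)))
      }
    }
  }
  list(ok = h2 && h3, h2 = h2, h3 = h3, details = details)
}

cluster_values <- function(vals, tol) {
  out <- list()
  used <- rep(FALSE, length(vals))
  for (i in seq_along(vals)) {
    if (used[i]) next
    grp <- abs(vals - vals[i]) <= tol & !used
    used[grp] <- TRUE
    out[[length(out) + 1L]] <- list(value = mean(vals[grp]), mult = sum(grp))
  }
  out
}

mat_rank <- function(M, tol = 1e-8) {
  if (!length(M) || min(dim(M)) == 0) return(0L)
  sv <- svd(M)$d
  sum(sv > tol * max(sv, 1))
}

mat_pow <- function(M, p) {
  out <- diag(nrow(M))
  for (i in seq_len(p)) out <- out %*% M
  out
}

null_basis <- function(M, tol = 1e-8) {
  s <- svd(M, nv = ncol(M))
  r <- sum(s$d > tol * max(s$d, 1))
  if (r == ncol(M)) return(NULL)
  s$v[, seq(r + 1, ncol(M)), drop = FALSE]
}

# ---- symbolic matrix exponential action (Putzer) ---------------------------

# components of exp(z Lambda) w0 as symf in the symbolic argument `zeta`
# (any symf); requires all eigenvalues real
matexp_action <- function(Lambda, w0, zeta, tol = 1e-9) {
  k <- nrow(Lambda)
  ev <- eigen(Lambda, only.values = TRUE)$values
  if (max(abs(Im(ev))) > tol * max(abs(ev), 1))
    stop(pspm_condition("pspm_complex_eigen_error", paste0(
      "matrix has complex eigenvalues; the trigonometric branch is exposed ",
      "through trig_matrix()/trig_solution(), not matrix-exponential weights")))
  lam <- sort(Re(ev), decreasing = TRUE)
  z <- "..z"
  zs <- sf_sym(z)
  # Putzer recursion for the scalar functions r_j(z)
  r <- vector("list", k)
  r[[1]] <- sf_exp(sf_scale(zs, lam[1]))
  if (k > 1) for (j in 2:k) {
    integrand <- sf_mul(sf_exp(sf_scale(zs, -lam[j])), r[[j - 1]])
    F <- sf_antideriv(integrand, z)
    if (is.null(F)) stop("Putzer integrand outside the symbolic class")
    F0 <- sf_subst(F, z, 0)
    r[[j]] <- sf_mul(sf_exp(sf_scale(zs, lam[j])),
                     sf_add(F, sf_const(-.sf_const_value(F0))))
  }
  P <- diag(k)
  vecs <- vector("list", k)
  for (j in seq_len(k)) {
    vecs[[j]] <- as.numeric(P %*% w0)
    P <- (Lambda - diag(lam[j], k)) %*% P
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    s <- sf_zero()
    for (j in seq_len(k)) if (abs(vecs[[j]][i]) > 1e-13)
      s <- sf_add(s, sf_scale(r[[j]], vecs[[j]][i]))
    out[[i]] <- sf_subst(s, z, zeta)
  }
  out
}

# ---- catalogue instances ---------------------------------------------------

catalogue_instance <- function(family, k, space, w, H, g, mu, params) {
  structure(list(family = family, k = k, space = space, w = w, H = H,
                 g = g, mu = mu, params = params),
            class = "catalogue_instance")
}

#' @export
print.catalogue_instance <- function(x, ...) {
  cat(sprintf("<catalogue %s> k = %d\n", x$family, x$k))
  cat("  g :", sep_format(x$g), "\n")
  cat("  mu:", sep_format(x$mu), "\n")
  for (i in seq_along(x$w)) cat(sprintf("  w_%d = %s\n", i, sf_format(x$w[[i]])))
  cat("H(E):\n"); print(x$H)
  invisible(x)
}

inst_atoms <- function(...) {
  unique(unlist(lapply(list(...), function(p) {
    if (is.null(p)) NULL
    else if (inherits(p, "env_atom")) p$name
    else if (is.character(p)) p
    else if (is.list(p)) ev_atoms(p)
    else NULL
  })))
}

#' Construct a scalar (k = 1) catalogue instance
#'
#' Family F1: arbitrary growth rate, death rate
#' `mu = gamma0(x) g(x,E) + mu0(E)`, single weight
#' `w(x) = exp(int_{x_b}^x gamma0)`, `H(E) = -mu0(E)`.
#'
#' @param gamma0 expression in the i-state variable (string or symf).
#' @param mu0 atom name (or numeric constant) for the x-independent death
#'   component.
#' @param g growth-rate expression (may use atoms).
#' @param space an [istate_space()] with `dim == 1`.
#' @param atoms extra atom names appearing in `g`.
#' @return a `catalogue_instance`.
#' @export
make_f1 <- function(gamma0, mu0, g, space, atoms = character(0)) {
  stopifnot(space$dim == 1)
  var <- space$vars[1]
  gamma0 <- as_symf(gamma0)
  mu0ev <- ev_from(mu0)
  anames <- unique(c(atoms, inst_atoms(mu0ev)))
  gsep <- normalize_separated(g, anames)
  w <- sf_exp(sf_integral_from(gamma0, var, space$x_b[1]))
  mu <- sep_add(sep_mul_symf(gsep, gamma0), ev_to_sep(mu0ev, sf_const(1), anames))
  H <- em_from_ev_entries(list(list(i = 1, j = 1, ev = ev_scale(mu0ev, -1))), 1, 1)
  catalogue_instance("F1", 1L, space, list(w), H, gsep, mu,
                     list(gamma0 = gamma0, mu0 = mu0ev))
}

#' Construct a physiological-age (F2) catalogue instance
#'
#' `g(x,E) = v0(x) v1(E)`, `mu = gamma0 g + mu0(E)`,
#' `w(x) = exp(int gamma0) exp(zeta(x) Lambda) w_xb` with
#' `zeta(x) = int_{x_b}^x dy/v0(y)`, and `H(E) = v1(E) Lambda - mu0(E) I`.
#' Requires (H2) and (H3) for `Lambda`, `w_xb`; eigenvalues must be real
#' (the complex/trigonometric branch lives in [trig_matrix()]).
#'
#' @param gamma0,v0 expressions in the i-state variable.
#' @param v1,mu0 atom names or numeric constants.
#' @param Lambda real k x k matrix; `w_xb` real k-vector.
#' @param space 1-D [istate_space()].
#' @return a `catalogue_instance`.
#' @export
make_f2 <- function(gamma0, mu0, v0, v1, Lambda, w_xb, space) {
  stopifnot(space$dim == 1)
  var <- space$vars[1]
  k <- nrow(Lambda)
  chk <- check_h2_h3(Lambda, w_xb)
  if (!chk$ok)
    stop(pspm_condition("pspm_h2h3_error",
                        paste(chk$details, collapse = "; ")))
  gamma0 <- as_symf(gamma0); v0 <- as_symf(v0)
  v1ev <- ev_from(v1); mu0ev <- ev_from(mu0)
  anames <- inst_atoms(v1ev, mu0ev)
  positivity_probe(v0, space, "v0")
  zeta <- sf_integral_from(sf_powbase(v0, -1), var, space$x_b[1])
  G <- sf_exp(sf_integral_from(gamma0, var, space$x_b[1]))
  wt <- matexp_action(Lambda, w_xb, zeta)
  w <- lapply(wt, function(f) sf_canonical(sf_mul(G, f)))
  gsep <- ev_to_sep(v1ev, v0, anames)
  mu <- sep_add(sep_mul_symf(gsep, gamma0), ev_to_sep(mu0ev, sf_const(1), anames))
  entries <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ev <- ev_scale(v1ev, Lambda[i, j])
    if (i == j) ev <- ev_add(ev, ev_scale(mu0ev, -1))
    if (length(ev)) entries[[length(entries) + 1L]] <- list(i = i, j = j, ev = ev)
  }
  H <- em_from_ev_entries(entries, k, k)
  catalogue_instance("F2", k, space, w, H, gsep, mu,
                     list(gamma0 = gamma0, v0 = v0, v1 = v1ev, mu0 = mu0ev,
                          Lambda = Lambda, w_xb = w_xb, zeta = zeta, G = G))
}

#' Construct a generalised von Bertalanffy (F3) catalogue instance
#'
#' `g(x,E) = v0(x)(v1(E) + v2(E) zeta + v3(E) zeta^2)`,
#' `mu = gamma0 g + mu0(E) + (k-1) v3(E) zeta`,
#' `w_j = exp(int gamma0) zeta^{j-1}`, and `H = H0 - mu0 I` with the banded
#' `H0` (subdiagonal `(i-1)v1`, diagonal `(i-1)v2`, superdiagonal
#' `-(k-i)v3`).
#'
#' @param gamma0,v0 expressions in the i-state variable.
#' @param mu0,v1,v2,v3 atom names or numeric constants (`v3 = 0` gives the
#'   Daphnia-style family; `k = 1` degenerates to F1).
#' @param k representation dimension.
#' @param space 1-D [istate_space()].
#' @param zeta optionally a precomputed symf for the transformed i-state
#'   (used by [mobius_reparam()]); default computed from `v0`.
#' @param G optional precomputed survival factor `exp(int gamma0)`.
#' @return a `catalogue_instance`.
#' @export
make_f3 <- function(gamma0, mu0, v0, v1, v2, v3 = 0, k, space,
                    zeta = NULL, G = NULL) {
  stopifnot(space$dim == 1)
  var <- space$vars[1]
  gamma0 <- as_symf(gamma0); v0 <- as_symf(v0)
  v1ev <- ev_from(v1); v2ev <- ev_from(v2); v3ev <- ev_from(v3)
  mu0ev <- ev_from(mu0)
  anames <- inst_atoms(v1ev, v2ev, v3ev, mu0ev)
  positivity_probe(v0, space, "v0")
  if (is.null(zeta)) zeta <- sf_integral_from(sf_powbase(v0, -1), var, space$x_b[1])
  if (is.null(G)) G <- sf_exp(sf_integral_from(gamma0, var, space$x_b[1]))
  w <- lapply(seq_len(k), function(j)
    sf_canonical(sf_mul(G, sf_pow_int(zeta, j - 1L))))
  zp <- list(sf_const(1), zeta, sf_mul(zeta, zeta))
  gsep <- sep_add(sep_add(
    ev_to_sep(v1ev, sf_mul(v0, zp[[1]]), anames),
    ev_to_sep(v2ev, sf_mul(v0, zp[[2]]), anames)),
    ev_to_sep(v3ev, sf_mul(v0, zp[[3]]), anames))
  mu <- sep_add(sep_add(
    sep_mul_symf(gsep, gamma0),
    ev_to_sep(mu0ev, sf_const(1), anames)),
    ev_to_sep(ev_scale(v3ev, k - 1), zeta, anames))
  entries <- list()
  for (i in seq_len(k)) {
    if (i >= 2) entries[[length(entries) + 1L]] <-
        list(i = i, j = i - 1L, ev = ev_scale(v1ev, i - 1))
    ev <- ev_add(ev_scale(v2ev, i - 1), ev_scale(mu0ev, -1))
    if (length(ev)) entries[[length(entries) + 1L]] <- list(i = i, j = i, ev = ev)
    if (i < k) entries[[length(entries) + 1L]] <-
        list(i = i, j = i + 1L, ev = ev_scale(v3ev, -(k - i)))
  }
  H <- em_from_ev_entries(entries, k, k)
  catalogue_instance("F3", as.integer(k), space, w, H, gsep, mu,
                     list(gamma0 = gamma0, v0 = v0, v1 = v1ev, v2 = v2ev,
                          v3 = v3ev, mu0 = mu0ev, zeta = zeta, G = G))
}

positivity_probe <- function(v0, space, what) {
  grid <- space_grid(space, 40L)
  vals <- tryCatch(do.call(sf_fun(v0, space$vars), grid), error = function(e) NA)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop(pspm_condition("pspm_positivity_error",
                        sprintf("%s is not positive on the i-state space", what)))
  invisible(TRUE)
}

#' Verify the defining identity of a catalogue instance
#'
#' Checks `g(x,E) w'(x) = (H(E) + mu(x,E) I) w(x)` componentwise: the
#' canonical-form residual must vanish; if the coefficient test is
#' inconclusive, a seeded numeric evaluation at 50 (x, valuation) pairs is
#' consulted.
#'
#' @param instance a `catalogue_instance`.
#' @param seed seed for the numeric fallback.
#' @return logical.
#' @export
verify_identity <- function(instance, seed = 1L) {
  sp <- instance$space
  var <- sp$vars[1]
  atoms <- instance$g$atoms
  k <- instance$k
  ok <- TRUE
  for (i in seq_len(k)) {
    lhs <- sep_mul_symf(instance$g, sf_deriv(instance$w[[i]], var))
    rhs <- sep_mul_symf(instance$mu, instance$w[[i]])
    for (j in seq_len(k)) {
      hij <- em_entry_sep(instance$H, i, j, atoms)
      rhs <- sep_add(rhs, sep_mul_symf(hij, instance$w[[j]]))
    }
    resid <- sep_sub(lhs, rhs)
    scale <- max(sep_max_coef(lhs), sep_max_coef(rhs), 1)
    if (!sep_is_zero(resid, scale = scale, tol = 1e-8)) {
      # numeric fallback at seeded (x, valuation) pairs
      pts <- space_sample(sp, 50L, seed)
      vals <- withr_seed(seed + 1L, stats::setNames(
        as.list(stats::runif(max(1, length(atoms)), 0.2, 2)),
        if (length(atoms)) atoms else "..dummy"))
      rs <- sep_at_valuation(resid, vals)
      rv <- tryCatch(rep_len(do.call(sf_fun(rs, sp$vars), pts), length(pts[[1]])),
                     error = function(e) Inf)
      if (max(abs(rv)) > 1e-8 * scale) ok <- FALSE
    }
  }
  ok
}

#' Mobius (linear fractional) reparametrisation of an F3 instance
#'
#' Transforms `zeta` to `eta = (a zeta + b)/(c zeta + d)` (with
#' `ad - bc != 0`), updating the parameters v1, v2, v3, gamma0 and mu0 by the
#' catalogue's covariance formulas.  The weight-function span is unchanged.
#'
#' @param instance an F3 `catalogue_instance`.
#' @param a,b,c,d transformation coefficients.
#' @return a new F3 `catalogue_instance`.
#' @export
mobius_reparam <- function(instance, a, b, c, d) {
  stopifnot(inherits(instance, "catalogue_instance"), instance$family == "F3")
  det <- a * d - b * c
  if (abs(det) < 1e-14)
    stop(pspm_condition("pspm_singular_transform_error", "ad - bc must be nonzero"))
  p <- instance$params
  k <- instance$k
  var <- instance$space$vars[1]
  v1 <- ev_scale(ev_add(ev_scale(p$v1, a^2), ev_scale(p$v2, -a * b), ev_scale(p$v3, b^2)), 1 / det)
  v2 <- ev_scale(ev_add(ev_scale(p$v1, -2 * a * c), ev_scale(p$v2, a * d + b * c),
                        ev_scale(p$v3, -2 * b * d)), 1 / det)
  v3 <- ev_scale(ev_add(ev_scale(p$v1, c^2), ev_scale(p$v2, -c * d), ev_scale(p$v3, d^2)), 1 / det)
  mu0 <- ev_add(p$mu0, ev_scale(ev_add(ev_scale(p$v1, a * c), ev_scale(p$v2, -b * c),
                                       ev_scale(p$v3, b * d)), -(k - 1) / det))
  zeta <- p$zeta
  denom <- sf_add(sf_scale(zeta, c), sf_const(d))
  eta <- sf_mul(sf_add(sf_scale(zeta, a), sf_const(b)), sf_powbase(denom, -1))
  gamma0 <- sf_add(p$gamma0,
                   sf_scale(sf_mul(sf_deriv(zeta, var), sf_powbase(denom, -1)), c * (k - 1)))
  G <- sf_canonical(sf_mul(p$G, sf_scale(sf_pow_int(denom, k - 1L), (1 / d)^(k - 1))))
  # eta' = det * zeta'/(c zeta + d)^2, so the state-dependent growth factor
  # becomes 1/eta' = v0 (c zeta + d)^2 / det
  v0new <- sf_canonical(sf_scale(sf_mul(p$v0, sf_pow_int(denom, 2L)), 1 / det))
  out <- make_f3(gamma0 = gamma0, mu0 = mu0, v0 = v0new, v1 = v1, v2 = v2, v3 = v3,
                 k = k, space = instance$space, zeta = eta, G = G)
  out$params$mobius <- c(a = a, b = b, c = c, d = d)
  out
}

#' Heuristic catalogue classification of (g, mu)
#'
#' Best-effort pattern matching of separated growth/death rates onto the F2
#' or F3 parameter forms with `v0 = 1` (after which `zeta = x - x_b`).  A
#' `"none"` verdict is advisory: [run_test()] remains the authoritative
#' check, since the catalogue's completeness holds only up to i-state
#' transformations that pattern matching cannot exhaust.
#'
#' @param g,mu expressions or separated expressions.
#' @param space 1-D [istate_space()].
#' @param atoms atom names.
#' @param k_hint dimension at which the F3 death compensation is probed.
#' @param seed seed for the atom valuations used in the gamma0 probe.
#' @return list with `family` ("F1"/"F2"/"F3"/"none"), extracted parameters,
#'   and on failure the `stage` that did not match.
#' @export
classify_ingredients <- function(g, mu, space, atoms, k_hint = 2L, seed = 1L) {
  stopifnot(space$dim == 1)
  anames <- atom_names(atoms)
  g <- normalize_separated(g, anames)
  mu <- normalize_separated(mu, anames)
  var <- space$vars[1]
  xb <- space$x_b[1]
  zeta <- sf_sub(sf_sym(var), sf_const(xb))
  # mu decomposition: gamma0 = (mu - mu0 - (k-1) v3 zeta)/g must be atom-free.
  # First try the simple route gamma0 = 0: mu = mu0(E) (+ compensation term).
  mu0 <- lapply(mu$components, function(cp) {
    const <- Filter(function(t) !length(t$pow) && is.null(t$e), cp$x$terms)
    if (!length(const)) return(NULL)
    list(mono = cp$mono, coef = sum(vapply(const, function(t) t$coef, numeric(1))))
  })
  mu0 <- Filter(Negate(is.null), mu0)
  # g route: every x_part polynomial of degree <= 2 in zeta (v0 = 1)
  v1 <- list(); v2 <- list(); v3 <- list()
  for (cp in g$components) {
    co <- poly_coeffs_in(cp$x, var, 2L)
    if (is.null(co))
      return(list(family = "none", stage = "g not polynomial of degree <= 2 in zeta (v0 = 1)"))
    # rebase from x-powers to zeta = x - xb powers
    c0 <- co[1] + co[2] * xb + co[3] * xb^2
    c1 <- co[2] + 2 * co[3] * xb
    c2 <- co[3]
    if (abs(c0) > 1e-13) v1 <- ev_add(v1, list(list(mono = cp$mono, coef = c0)))
    if (abs(c1) > 1e-13) v2 <- ev_add(v2, list(list(mono = cp$mono, coef = c1)))
    if (abs(c2) > 1e-13) v3 <- ev_add(v3, list(list(mono = cp$mono, coef = c2)))
  }
  # gamma0 probe: residual mu - mu0 - (k-1) v3 zeta, divided by g, must be the
  # same x-function at several atom valuations
  resid <- sep_sub(sep_sub(mu, ev_to_sep(mu0, sf_const(1), anames)),
                   ev_to_sep(ev_scale(v3, k_hint - 1), zeta, anames))
  gamma0 <- NULL
  if (!length(resid$components)) {
    gamma0 <- sf_zero()
  } else {
    vals_list <- withr_seed(seed, lapply(1:3, function(i)
      stats::setNames(as.list(stats::runif(length(anames), 0.3, 2.5)), anames)))
    pts <- space_sample(space, 16L, seed + 1L)
    ratio_vals <- NULL; consistent <- TRUE
    for (vv in vals_list) {
      rv <- rep_len(do.call(sf_fun(sep_at_valuation(resid, vv), space$vars), pts), 16L)
      gv <- rep_len(do.call(sf_fun(sep_at_valuation(g, vv), space$vars), pts), 16L)
      r <- rv / gv
      if (is.null(ratio_vals)) ratio_vals <- r
      else if (max(abs(r - ratio_vals)) > 1e-7 * max(abs(ratio_vals), 1)) consistent <- FALSE
    }
    if (!consistent)
      return(list(family = "none", stage = "mu - mu0 is not gamma0(x) * g(x,E)"))
    gamma0 <- NA  # atom-free but only known numerically
  }
  fam <- if (!length(v2) && !length(v3)) "F2" else "F3"
  list(family = fam, v0 = sf_const(1), v1 = v1, v2 = v2, v3 = v3,
       mu0 = mu0, gamma0 = gamma0, zeta = zeta, k_hint = k_hint)
}

# coefficients (c0, c1, c2) of a polynomial of degree <= 2, else NULL
poly_coeffs_in <- function(f, var, maxdeg = 2L) {
  co <- numeric(maxdeg + 1)
  for (t in f$terms) {
    if (!is.null(t$e)) return(NULL)
    if (!length(t$pow)) { co[1] <- co[1] + t$coef; next }
    if (length(t$pow) > 1) return(NULL)
    fct <- sf_factor(names(t$pow))
    if (fct$kind != "sym" || fct$name != var) return(NULL)
    p <- t$pow[[1]]
    if (p != round(p) || p < 1 || p > maxdeg) return(NULL)
    co[p + 1] <- co[p + 1] + t$coef
  }
  co
}

# ---- special matrices ------------------------------------------------------

#' Kac--Sylvester tridiagonal matrix
#'
#' Entries `l` at (l, l+1) and `k - j` at (j+1, j); its eigenvalues are the
#' integers `2j - k - 1`, `j = 1..k`.
#'
#' @param k dimension.
#' @return integer matrix.
#' @export
kac_sylvester <- function(k) {
  K <- matrix(0, k, k)
  for (l in seq_len(k - 1)) K[l, l + 1] <- l
  for (j in seq_len(k - 1)) K[j + 1, j] <- k - j
  K
}

#' Trigonometric companion matrix
#'
#' Entries `-(k - l)` at (l, l+1) and `j` at (j+1, j); similar to
#' `i * t(kac_sylvester(k))` via [similarity_S()], hence with purely
#' imaginary eigenvalues `(2j - k - 1) i`.
#'
#' @param k dimension.
#' @return numeric matrix.
#' @export
trig_matrix <- function(k) {
  M <- matrix(0, k, k)
  for (l in seq_len(k - 1)) M[l, l + 1] <- -(k - l)
  for (j in seq_len(k - 1)) M[j + 1, j] <- j
  M
}

#' Diagonal similarity between the trigonometric and Kac--Sylvester matrices
#'
#' `S M S^{-1} = i t(K)` with `S = diag(i^{j-1})`.
#'
#' @param k dimension.
#' @return complex diagonal matrix.
#' @export
similarity_S <- function(k) diag(1i^(seq_len(k) - 1), k)

#' Closed-form solution of the trigonometric ODE system
#'
#' `Phi_j(t) = sin^{j-1}(t) cos^{k-j}(t)` satisfies
#' `dPhi/dt = trig_matrix(k) Phi`.
#'
#' @param k dimension.
#' @param t numeric vector of times.
#' @return matrix with `length(t)` rows and `k` columns.
#' @export
trig_solution <- function(k, t) {
  vapply(seq_len(k), function(j) sin(t)^(j - 1) * cos(t)^(k - j),
         numeric(length(t)))
}

# symbolic weights for the trigonometric system (used by identity tests)
trig_weights <- function(k, var = "t") {
  tv <- sf_sym(var)
  lapply(seq_len(k), function(j)
    sf_mul(sf_pow_int(sf_sin(tv), j - 1L), sf_pow_int(sf_cos(tv), k - j)))
}

# ---- age-structured linear chain trick ------------------------------------

#' Reduce an age-structured model with matrix-exponential weights
#'
#' For age (`g = 1`, births at age 0), death rate
#' `mu = gamma0(x) + mu0(E)` and birth rate
#' `beta(x, E) = sum_j btilde_j(E) w_j(x)` with
#' `w(x) = exp(int_0^x gamma0) exp(x Lambda) w0`, the reduced system is
#' `dN/dt = (M(E) + Lambda - mu0(E) I) N` with `M_ij = w_i(0) btilde_j(E)`.
#'
#' @param beta_coeffs list (length k) of atom names / numerics for the
#'   btilde_j.
#' @param gamma0 expression in age.
#' @param mu0 atom name or numeric.
#' @param Lambda real k x k matrix satisfying (H2)/(H3) with `w0`.
#' @param w0 weight values at age 0.
#' @param x_max finite probe bound used when validating the model surface.
#' @return list with `K` (env_matrix), `w` (list of symf), `M`, `Lambda`,
#'   `model` (the equivalent [pspm_model()] for cross-checks) and a
#'   `recovery` context for [recover_age_density()].
#' @export
age_structured_reduce <- function(beta_coeffs, gamma0, mu0, Lambda, w0,
                                  x_max = Inf) {
  k <- nrow(Lambda)
  stopifnot(length(w0) == k, length(beta_coeffs) == k)
  chk <- check_h2_h3(Lambda, w0)
  if (!chk$ok) stop(pspm_condition("pspm_h2h3_error", paste(chk$details, collapse = "; ")))
  space <- istate_space(1, lower = 0, upper = x_max, x_b = 0)
  gamma0 <- as_symf(gamma0)
  mu0ev <- ev_from(mu0)
  bev <- lapply(beta_coeffs, ev_from)
  anames <- unique(c(inst_atoms(mu0ev), unlist(lapply(bev, ev_atoms))))
  G <- sf_exp(sf_integral_from(gamma0, "x", 0))
  wt <- matexp_action(Lambda, w0, sf_sym("x"))
  w <- lapply(wt, function(f) sf_canonical(sf_mul(G, f)))
  w_at_0 <- vapply(w, function(f) sf_eval(f, list(x = 0)), numeric(1))
  entries <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ev <- ev_scale(bev[[j]], w_at_0[i])
    if (length(ev)) entries[[length(entries) + 1L]] <- list(i = i, j = j, ev = ev)
  }
  M <- em_from_ev_entries(entries, k, k)
  entK <- entries
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ev <- ev_from(Lambda[i, j])
    if (i == j) ev <- ev_add(ev, ev_scale(mu0ev, -1))
    if (length(ev)) entK[[length(entK) + 1L]] <- list(i = i, j = j, ev = ev)
  }
  K <- em_from_ev_entries(entK, k, k)
  # equivalent structured model: birth Dirac at age 0, rate sum_j btilde_j w_j
  rate <- sep_zero(anames)
  for (j in seq_len(k)) rate <- sep_add(rate, ev_to_sep(bev[[j]], w[[j]], anames))
  mu_sep <- sep_add(normalize_separated(gamma0, anames),
                    ev_to_sep(mu0ev, sf_const(1), anames))
  model <- pspm_model(space, anames, g = "1", mu = mu_sep,
                      births = list(structure(list(rate_weight = rate, birth_state = 0),
                                              class = "birth_term")),
                      outputs = w, name = "age-structured")
  list(K = K, M = M, Lambda = Lambda, w = w, model = model,
       recovery = list(gamma0 = gamma0, mu0 = mu0ev, beta = bev, w = w, k = k))
}

#' Recover the age density from a reduced trajectory
#'
#' `n(t, x) = exp(-int_0^x gamma0) exp(-int_{t-x}^t mu0(E)) *
#'  sum_j btilde_j(E(t-x)) N_j(t-x)` for `x < t` (individuals born after the
#' start; earlier cohorts are not recoverable).
#'
#' @param N_history list with `times` and `values` (matrix, k columns) from
#'   [integrate_reduced()], or a function of t.
#' @param E_history function of t returning a named atom valuation (or a
#'   constant named list).
#' @param recovery the `recovery` context from [age_structured_reduce()].
#' @param t,x evaluation time and age(s), `x < t`.
#' @param dt fixed quadrature step for the mu0 survival integral.
#' @return numeric density value(s).
#' @export
recover_age_density <- function(N_history, E_history, recovery, t, x, dt = 1e-3) {
  if (any(x >= t))
    stop(pspm_condition("pspm_domain_error",
                        "density recoverable only for ages x < t"))
  Nfun <- as_history_fun(N_history)
  Efun <- as_env_fun(E_history)
  g0int <- sf_antideriv(recovery$gamma0, "x")
  if (is.null(g0int)) stop(pspm_condition("pspm_integration_error",
                                          "gamma0 not symbolically integrable"))
  g0f <- sf_fun(sf_sub(g0int, sf_const(sf_eval(g0int, list(x = 0)))), "x")
  # cumulative survival integral C(tau) = int_0^tau mu0(E) on a fixed grid
  nstep <- max(1L, ceiling(t / dt))
  h <- t / nstep
  mids <- (seq_len(nstep) - 0.5) * h
  muv <- vapply(mids, function(tm) ev_eval(recovery$mu0, Efun(tm)), numeric(1))
  knots <- seq(0, t, length.out = nstep + 1)
  C <- c(0, cumsum(muv) * h)
  Cfun <- function(tau) stats::approx(knots, C, xout = tau, rule = 2)$y
  vapply(x, function(xi) {
    tb <- t - xi
    muint <- C[nstep + 1] - Cfun(tb)
    Nb <- Nfun(tb)
    bsum <- sum(vapply(seq_len(recovery$k), function(j)
      ev_eval(recovery$beta[[j]], Efun(tb)) * Nb[j], numeric(1)))
    exp(-g0f(xi)) * exp(-muint) * bsum
  }, numeric(1))
}

as_history_fun <- function(h) {
  if (is.function(h)) return(h)
  times <- h$times; values <- as.matrix(h$values)
  function(t) vapply(seq_len(ncol(values)), function(j)
    stats::approx(times, values[, j], xout = t, rule = 2)$y, numeric(1))
}

as_env_fun <- function(e) {
  if (is.function(e)) return(e)
  force(e); function(t) e
}
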