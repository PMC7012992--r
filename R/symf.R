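# Symbolic engine: canonical multivariate expressions over plain symbols and
# kernel factors.  A `symf` is a finite sum of terms
#
#     coef * prod_f f^p_f * exp(e)
#
# where each factor f is a symbol ("x"), or a kernel: powbase(u)^r (a general
# power of a multi-term expression u), log(u), sin(u), cos(u), tan(u), with u
# itself a symf.  The exp slot `e` is a symf holding the (merged) argument of a
# single exponential factor.  This class of expressions is closed under
# addition, multiplication, integer powers, substitution and differentiation,
# which is exactly what iterated application of the backward operator needs.
# Equality holds iff canonical coefficients agree, so "simplifies to zero"
# is a coefficient-level test, not a sampling heuristic.

SF_DROP_TOL <- 1e-12   # relative coefficient cleanup within one expression

# ---- factor registry -------------------------------------------------------
# kernel factors are interned by canonical key so terms can carry bare keys
.sf_registry <- new.env(parent = emptyenv())

sf_register_factor <- function(key, obj) {
  if (!exists(key, envir = .sf_registry, inherits = FALSE))
    assign(key, obj, envir = .sf_registry)
  key
}

sf_factor <- function(key) {
  if (exists(key, envir = .sf_registry, inherits = FALSE))
    get(key, envir = .sf_registry)
  else
    list(kind = "sym", name = key)
}

# ---- construction ----------------------------------------------------------

sf_new <- function(terms) structure(list(terms = terms), class = "symf")

#' @keywords internal
sf_zero <- function() sf_new(list())

sf_const <- function(c) {
  if (c == 0) return(sf_zero())
  sf_new(list(list(coef = as.numeric(c), pow = numeric(0), e = NULL)))
}

sf_sym <- function(name) {
  p <- 1; names(p) <- name
  sf_new(list(list(coef = 1, pow = p, e = NULL)))
}

is_symf <- function(x) inherits(x, "symf")

as_symf <- function(x) {
  if (is_symf(x)) return(x)
  if (is.numeric(x) && length(x) == 1) return(sf_const(x))
  if (is.character(x) && length(x) == 1) return(sf_parse(x))
  if (is.language(x)) return(sf_parse(x))
  stop("cannot coerce to symf: ", paste(class(x), collapse = "/"))
}

# ---- canonical keys --------------------------------------------------------

.fmt_num <- function(x) {
  # stable textual form for canonical keys
  vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(round(v)))
    else sprintf("%.15g", v)
  }, character(1))
}

sf_term_key <- function(term) {
  k <- ""
  if (length(term$pow)) {
    o <- order(names(term$pow))
    k <- paste0(names(term$pow)[o], "^", .fmt_num(term$pow[o]), collapse = "*")
  }
  if (!is.null(term$e)) k <- paste0(k, "|exp{", sf_key(term$e), "}")
  k
}

sf_key <- function(x) {
  if (!length(x$terms)) return("0")
  keys <- vapply(x$terms, sf_term_key, character(1))
  o <- order(keys)
  paste0(.fmt_num(vapply(x$terms[o], function(t) t$coef, numeric(1))),
         "&", keys[o], collapse = "+")
}

# ---- canonicalisation ------------------------------------------------------

.sf_clean_term <- function(term) {
  # drop zero powers; fold exp-argument constant into coef; collapse exp(0)
  if (length(term$pow)) {
    term$pow <- term$pow[term$pow != 0]
    if (!length(term$pow)) term$pow <- numeric(0)
  }
  if (!is.null(term$e)) {
    e <- sf_canonical(term$e)
    if (!length(e$terms)) {
      term$e <- NULL
    } else {
      cidx <- which(vapply(e$terms, function(t)
        length(t$pow) == 0 && is.null(t$e), logical(1)))
      if (length(cidx)) {
        c0 <- sum(vapply(e$terms[cidx], function(t) t$coef, numeric(1)))
        term$coef <- term$coef * exp(c0)
        e$terms <- e$terms[-cidx]
        term$e <- if (length(e$terms)) e else NULL
      }
    }
  }
  term
}

sf_canonical <- function(x) {
  terms <- lapply(x$terms, .sf_clean_term)
  terms <- Filter(function(t) t$coef != 0 && is.finite(t$coef), terms)
  if (!length(terms)) return(sf_zero())
  keys <- paste0("k:", vapply(terms, sf_term_key, character(1)))
  merged <- list()
  for (i in seq_along(terms)) {
    k <- keys[[i]]
    if (is.null(merged[[k]])) merged[[k]] <- terms[[i]]
    else merged[[k]]$coef <- merged[[k]]$coef + terms[[i]]$coef
  }
  out <- unname(merged[order(names(merged))])
  mx <- max(abs(vapply(out, function(t) t$coef, numeric(1))))
  out <- Filter(function(t) abs(t$coef) > SF_DROP_TOL * mx, out)
  sf_new(out)
}

# ---- arithmetic ------------------------------------------------------------

sf_add <- function(a, b) sf_canonical(sf_new(c(a$terms, b$terms)))

sf_neg <- function(a) {
  sf_new(lapply(a$terms, function(t) { t$coef <- -t$coef; t }))
}

sf_sub <- function(a, b) sf_add(a, sf_neg(b))

sf_scale <- function(a, c) {
  if (c == 0) return(sf_zero())
  sf_new(lapply(a$terms, function(t) { t$coef <- t$coef * c; t }))
}

.sf_mul_terms <- function(t1, t2) {
  pow <- t1$pow
  for (nm in names(t2$pow)) pow[nm] <- (if (nm %in% names(pow)) pow[[nm]] else 0) + t2$pow[[nm]]
  e <- if (is.null(t1$e)) t2$e else if (is.null(t2$e)) t1$e else sf_add(t1$e, t2$e)
  list(coef = t1$coef * t2$coef, pow = pow, e = e)
}

sf_mul <- function(a, b) {
  if (!length(a$terms) || !length(b$terms)) return(sf_zero())
  out <- vector("list", length(a$terms) * length(b$terms))
  k <- 1L
  for (t1 in a$terms) for (t2 in b$terms) { out[[k]] <- .sf_mul_terms(t1, t2); k <- k + 1L }
  sf_canonical(sf_new(out))
}

sf_pow_int <- function(a, n) {
  n <- as.integer(n)
  if (n == 0) return(sf_const(1))
  if (n == 1) return(sf_canonical(a))
  if (length(a$terms) == 1) return(sf_powbase(a, n))
  if (n < 0) return(sf_powbase(a, n))
  r <- sf_const(1); base <- a; m <- n
  while (m > 0) {
    if (m %% 2L == 1L) r <- sf_mul(r, base)
    m <- m %/% 2L
    if (m > 0) base <- sf_mul(base, base)
  }
  r
}

# general real power: collapses single-term bases; otherwise interns a
# powbase kernel (normalised so the leading coefficient is +1 when positive)
sf_powbase <- function(u, r) {
  u <- sf_canonical(as_symf(u))
  if (!length(u$terms)) {
    if (r > 0) return(sf_zero())
    stop("sf_powbase: zero to a nonpositive power")
  }
  if (r == 0) return(sf_const(1))
  if (length(u$terms) == 1) {
    t <- u$terms[[1]]
    if (t$coef < 0 && r != round(r))
      stop("sf_powbase: negative base with fractional exponent")
    out <- list(coef = t$coef^r, pow = t$pow * r,
                e = if (is.null(t$e)) NULL else sf_scale(t$e, r))
    return(sf_canonical(sf_new(list(out))))
  }
  if (r == round(r) && r > 0) return(sf_pow_int(u, r))
  lead <- u$terms[[1]]$coef
  cf <- 1
  if (lead > 0 && lead != 1) { cf <- lead^r; u <- sf_scale(u, 1 / lead) }
  key <- sf_register_factor(paste0("pw{", sf_key(u), "}"),
                            list(kind = "powbase", arg = u))
  p <- r; names(p) <- key
  sf_canonical(sf_new(list(list(coef = cf, pow = p, e = NULL))))
}

# ---- kernel constructors ---------------------------------------------------

.sf_const_value <- function(u) {
  # numeric value if u is a constant, else NULL
  if (!length(u$terms)) return(0)
  if (length(u$terms) == 1 && !length(u$terms[[1]]$pow) && is.null(u$terms[[1]]$e))
    return(u$terms[[1]]$coef)
  NULL
}

.sf_kernel1 <- function(kind, u, fn) {
  u <- sf_canonical(as_symf(u))
  v <- .sf_const_value(u)
  if (!is.null(v)) return(sf_const(fn(v)))
  key <- sf_register_factor(paste0(kind, "{", sf_key(u), "}"),
                            list(kind = kind, arg = u))
  p <- 1; names(p) <- key
  sf_new(list(list(coef = 1, pow = p, e = NULL)))
}

sf_exp <- function(u) {
  u <- sf_canonical(as_symf(u))
  v <- .sf_const_value(u)
  if (!is.null(v)) return(sf_const(exp(v)))
  # pull out c*log(w) terms as powbase factors: exp(c log w + rest) = w^c exp(rest)
  extra <- sf_const(1); rest <- list()
  for (t in u$terms) {
    if (length(t$pow) == 1 && is.null(t$e) && t$pow[[1]] == 1 &&
        sf_factor(names(t$pow))$kind == "log") {
      extra <- sf_mul(extra, sf_powbase(sf_factor(names(t$pow))$arg, t$coef))
    } else rest[[length(rest) + 1L]] <- t
  }
  base <- list(coef = 1, pow = numeric(0),
               e = if (length(rest)) sf_canonical(sf_new(rest)) else NULL)
  sf_canonical(sf_mul(sf_new(list(base)), extra))
}

sf_log <- function(u) .sf_kernel1("log", u, log)
sf_sin <- function(u) .sf_kernel1("sin", u, sin)
sf_cos <- function(u) .sf_kernel1("cos", u, cos)
sf_tan <- function(u) .sf_kernel1("tan", u, tan)

sf_div <- function(a, b) sf_mul(as_symf(a), sf_powbase(as_symf(b), -1))

# ---- free symbols ----------------------------------------------------------

sf_symbols <- function(x) {
  syms <- character(0)
  for (t in x$terms) {
    for (nm in names(t$pow)) {
      f <- sf_factor(nm)
      syms <- c(syms, if (f$kind == "sym") f$name else sf_symbols(f$arg))
    }
    if (!is.null(t$e)) syms <- c(syms, sf_symbols(t$e))
  }
  unique(syms)
}

sf_depends_on <- function(x, var) var %in% sf_symbols(x)

# ---- differentiation -------------------------------------------------------

.sf_factor_deriv <- function(key, var) {
  # derivative of the factor function itself (a symf)
  f <- sf_factor(key)
  switch(f$kind,
    sym = if (f$name == var) sf_const(1) else sf_zero(),
    powbase = {
      du <- sf_deriv(f$arg, var)
      if (!length(du$terms)) sf_zero() else du   # chain handled by caller
    },
    log = sf_mul(sf_deriv(f$arg, var), sf_powbase(f$arg, -1)),
    sin = sf_mul(sf_deriv(f$arg, var), sf_cos(f$arg)),
    cos = sf_neg(sf_mul(sf_deriv(f$arg, var), sf_sin(f$arg))),
    tan = sf_mul(sf_deriv(f$arg, var),
                 sf_add(sf_const(1), sf_mul(sf_tan(f$arg), sf_tan(f$arg)))),
    stop("unknown factor kind: ", f$kind)
  )
}

sf_deriv <- function(x, var) {
  out <- sf_zero()
  for (t in x$terms) {
    base <- sf_new(list(t))
    for (nm in names(t$pow)) {
      f <- sf_factor(nm)
      fd <- .sf_factor_deriv(nm, var)
      if (!length(fd$terms)) next
      # d(f^p) = p f^(p-1) f' for powbase (fd = u'), and for f itself a
      # function: generic rule term * p * f'/f
      tt <- t; tt$pow[nm] <- tt$pow[nm] - 1
      contrib <- sf_mul(sf_canonical(sf_new(list(tt))), sf_scale(fd, t$pow[[nm]]))
      out <- sf_add(out, contrib)
    }
    if (!is.null(t$e)) {
      ed <- sf_deriv(t$e, var)
      if (length(ed$terms)) out <- sf_add(out, sf_mul(base, ed))
    }
  }
  sf_canonical(out)
}

# gradient over several variables
sf_grad <- function(x, vars) lapply(vars, function(v) sf_deriv(x, v))

# ---- substitution ----------------------------------------------------------

sf_subst <- function(x, var, val) {
  val <- if (is.numeric(val)) sf_const(val) else as_symf(val)
  out <- sf_zero()
  for (t in x$terms) {
    piece <- sf_const(t$coef)
    for (nm in names(t$pow)) {
      f <- sf_factor(nm); p <- t$pow[[nm]]
      fac <- switch(f$kind,
        sym = if (f$name == var) sf_powbase(val, p)
              else sf_powbase(sf_sym(f$name), p),
        powbase = sf_powbase(sf_subst(f$arg, var, val), p),
        log = sf_powbase(sf_log(sf_subst(f$arg, var, val)), p),
        sin = sf_powbase(sf_sin(sf_subst(f$arg, var, val)), p),
        cos = sf_powbase(sf_cos(sf_subst(f$arg, var, val)), p),
        tan = sf_powbase(sf_tan(sf_subst(f$arg, var, val)), p))
      piece <- sf_mul(piece, fac)
    }
    if (!is.null(t$e)) piece <- sf_mul(piece, sf_exp(sf_subst(t$e, var, val)))
    out <- sf_add(out, piece)
  }
  sf_canonical(out)
}

sf_subst_all <- function(x, vals) {
  for (nm in names(vals)) x <- sf_subst(x, nm, vals[[nm]])
  x
}

# ---- conversion to R language & evaluation ---------------------------------

sf_factor_lang <- function(key) {
  f <- sf_factor(key)
  switch(f$kind,
    sym = as.name(f$name),
    powbase = sf_lang(f$arg),
    log = call("log", sf_lang(f$arg)),
    sin = call("sin", sf_lang(f$arg)),
    cos = call("cos", sf_lang(f$arg)),
    tan = call("tan", sf_lang(f$arg)))
}

sf_lang <- function(x) {
  if (!length(x$terms)) return(0)
  pieces <- lapply(x$terms, function(t) {
    expr <- NULL
    for (nm in names(t$pow)) {
      fl <- sf_factor_lang(nm); p <- t$pow[[nm]]
      fac <- if (p == 1) fl else call("^", fl, p)
      expr <- if (is.null(expr)) fac else call("*", expr, fac)
    }
    if (!is.null(t$e)) {
      fac <- call("exp", sf_lang(t$e))
      expr <- if (is.null(expr)) fac else call("*", expr, fac)
    }
    if (is.null(expr)) t$coef
    else if (t$coef == 1) expr
    else if (t$coef == -1) call("-", expr)
    else call("*", t$coef, expr)
  })
  out <- pieces[[1]]
  for (p in pieces[-1]) out <- call("+", out, p)
  out
}

#' @keywords internal
sf_eval <- function(x, env) {
  # env: named list/vector of numeric values (vectors allowed -> vectorised)
  eval(sf_lang(x), envir = as.list(env), enclos = baseenv())
}

# compiled evaluator: function of a point environment, vectorised
sf_fun <- function(x, vars) {
  lang <- sf_lang(x)
  f <- function() NULL
  formals(f) <- structure(rep(list(quote(expr = )), length(vars)), names = vars)
  body(f) <- lang
  environment(f) <- baseenv()
  f
}

# ---- formatting ------------------------------------------------------------

sf_format <- function(x) {
  if (!length(x$terms)) return("0")
  paste(deparse(sf_lang(x), width.cutoff = 500L), collapse = "")
}

#' @export
print.symf <- function(x, ...) { cat(sf_format(x), "\n"); invisible(x) }

#' @export
format.symf <- function(x, ...) sf_format(x)

# ---- zero and equality tests -----------------------------------------------

sf_max_coef <- function(x) {
  if (!length(x$terms)) return(0)
  max(abs(vapply(x$terms, function(t) t$coef, numeric(1))))
}

# exact-in-canonical-form zero test: coefficients vanish relative to `scale`
sf_is_zero <- function(x, scale = 1, tol = 1e-9) {
  sf_max_coef(sf_canonical(x)) <= tol * max(scale, .Machine$double.xmin)
}

sf_equal <- function(a, b, scale = NULL) {
  d <- sf_sub(a, b)
  if (is.null(scale)) scale <- max(sf_max_coef(a), sf_max_coef(b), 1)
  sf_is_zero(d, scale = scale)
}

# ---- parsing ---------------------------------------------------------------

#' Parse an expression string into the symbolic engine
#'
#' Grammar: identifiers, numeric literals, `+ - * / ^`, parentheses and the
#' functions `exp`, `log`, `sin`, `cos`, `tan`, `sqrt`.  Exponents must be
#' numeric constants.
#'
#' @param x a character string or an R language object.
#' @return a `symf` object.
#' @keywords internal
sf_parse <- function(x) {
  lang <- if (is.character(x)) str2lang(x) else x
  rec <- function(e) {
    if (is.numeric(e)) return(sf_const(e))
    if (is.name(e)) return(sf_sym(as.character(e)))
    if (!is.call(e)) stop("unsupported expression element: ", deparse(e))
    op <- as.character(e[[1]])
    if (op == "(") return(rec(e[[2]]))
    if (op == "+" && length(e) == 2) return(rec(e[[2]]))
    if (op == "-" && length(e) == 2) return(sf_neg(rec(e[[2]])))
    if (op == "+") return(sf_add(rec(e[[2]]), rec(e[[3]])))
    if (op == "-") return(sf_sub(rec(e[[2]]), rec(e[[3]])))
    if (op == "*") return(sf_mul(rec(e[[2]]), rec(e[[3]])))
    if (op == "/") return(sf_div(rec(e[[2]]), rec(e[[3]])))
    if (op == "^") {
      ex <- rec(e[[3]]); v <- .sf_const_value(ex)
      if (is.null(v)) stop("exponent must be a numeric constant: ", deparse(e))
      return(sf_powbase(rec(e[[2]]), v))
    }
    if (op == "exp") return(sf_exp(rec(e[[2]])))
    if (op == "log") return(sf_log(rec(e[[2]])))
    if (op == "sin") return(sf_sin(rec(e[[2]])))
    if (op == "cos") return(sf_cos(rec(e[[2]])))
    if (op == "tan") return(sf_tan(rec(e[[2]])))
    if (op == "sqrt") return(sf_powbase(rec(e[[2]]), 0.5))
    stop("unsupported function in expression: ", op)
  }
  sf_canonical(rec(lang))
}

# ---- antidifferentiation ---------------------------------------------------

# Symbolic antiderivative with respect to `var`.  Supported term classes:
#   c * var^n                        (any real n; n = -1 gives log)
#   c * var^n * exp(a*var + ...)     (n a nonnegative integer, a != 0)
#   c * (a + b*var)^r                (r any real; r = -1 gives log)
# possibly multiplied by factors free of `var`.  Returns NULL when a term is
# outside this class.
sf_antideriv <- function(x, var) {
  x <- sf_canonical(x)
  out <- sf_zero()
  for (t in x$terms) {
    res <- .sf_antideriv_term(t, var)
    if (is.null(res)) return(NULL)
    out <- sf_add(out, res)
  }
  out
}

.sf_antideriv_term <- function(t, var) {
  free <- sf_const(t$coef)   # var-free multiplier
  n <- 0                     # power of var
  lin <- NULL                # linear powbase factor in var: list(u, r, b)
  for (nm in names(t$pow)) {
    f <- sf_factor(nm); p <- t$pow[[nm]]
    if (f$kind == "sym" && f$name == var) { n <- p; next }
    dep <- switch(f$kind, sym = FALSE, sf_depends_on(f$arg, var))
    if (!dep) {
      tt <- list(coef = 1, pow = structure(p, names = nm), e = NULL)
      free <- sf_mul(free, sf_new(list(tt)))
      next
    }
    if (f$kind == "powbase" && is.null(lin)) {
      u <- f$arg
      du <- sf_deriv(u, var)
      b <- .sf_const_value(du)
      if (!is.null(b) && b != 0) { lin <- list(u = u, r = p, b = b); next }
    }
    return(NULL)
  }
  alpha <- 0; erest <- NULL
  if (!is.null(t$e)) {
    de <- sf_deriv(t$e, var)
    a <- .sf_const_value(de)
    if (is.null(a)) return(NULL)          # exp argument not linear in var
    alpha <- a
    erest <- sf_subst(t$e, var, 0)        # var-free remainder of the argument
    if (sf_depends_on(erest, var)) return(NULL)
  }
  if (!is.null(lin)) {
    if (n != 0 || alpha != 0) return(NULL)
    F <- if (lin$r == -1) sf_scale(sf_log(lin$u), 1 / lin$b)
         else sf_scale(sf_powbase(lin$u, lin$r + 1), 1 / (lin$b * (lin$r + 1)))
    return(sf_mul(free, F))
  }
  if (alpha == 0) {
    F <- if (n == -1) sf_log(sf_sym(var))
         else sf_scale(sf_powbase(sf_sym(var), n + 1), 1 / (n + 1))
    return(sf_mul(free, F))
  }
  if (n < 0 || n != round(n)) return(NULL)
  # int var^n exp(alpha var) dx by parts, iterated
  xv <- sf_sym(var)
  expf <- sf_exp(if (is.null(erest)) sf_scale(xv, alpha)
                 else sf_add(sf_scale(xv, alpha), erest))
  acc <- sf_zero(); coef <- 1; m <- n
  repeat {
    acc <- sf_add(acc, sf_scale(sf_mul(sf_powbase(xv, m), expf), coef / alpha))
    if (m == 0) break
    coef <- -coef * m / alpha
    m <- m - 1
    if (m == 0) { acc <- sf_add(acc, sf_scale(expf, coef / alpha)); break }
  }
  sf_mul(free, acc)
}

# definite integral from numeric lo: F(x) - F(lo), still symbolic in x
sf_integral_from <- function(x, var, lo) {
  F <- sf_antideriv(x, var)
  if (is.null(F))
    stop(pspm_condition("pspm_integration_error",
         sprintf("no closed-form antiderivative in '%s' for: %s", var, sf_format(x))))
  Flo <- sf_subst(F, var, lo)
  v <- .sf_const_value(Flo)
  if (is.null(v)) stop(pspm_condition("pspm_integration_error",
       "antiderivative does not evaluate at the lower limit"))
  sf_add(F, sf_const(-v))
}

# ---- shared condition helper ----------------------------------------------

pspm_condition <- function(class, message) {
  structure(class = c(class, "pspm_error", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}
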