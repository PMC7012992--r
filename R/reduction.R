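# The TEST: iterated span closure of the output weight functions under the
# backward operator, and assembly of the reduced system
#   A(E) Psi = K(E) Psi,  A0(E) Psi = H(E) Psi,  K = H + M,  Gamma(E) = Q(E) Psi.

#' Numerically certified linear-independence check for weight functions
#'
#' Primary path: evaluate the functions at seeded interior sample points and
#' count singular values above `1e-8` times the largest.  Secondary path (for
#' one-dimensional analytic inputs): the symbolic Wronskian, whose identical
#' vanishing characterises dependence for analytic functions.  The two
#' verdicts must agree, otherwise an error asks for manual review.
#'
#' @param funcs list of symbolic x-expressions (strings or symf).
#' @param space an [istate_space()].
#' @param seed integer seed for the sample points.
#' @param wronskian logical; attempt the symbolic cross-check (1-D only).
#' @return list with `rank`, `dependent` (logical flags, TRUE for a function
#'   lying in the span of its predecessors) and a `certificate` recording the
#'   sample points and singular values.
#' @export
independence_check <- function(funcs, space, seed = 1L, wronskian = TRUE) {
  funcs <- lapply(funcs, as_symf)
  k <- length(funcs)
  stopifnot(k >= 1)
  m <- max(3L * k, 12L)
  pts <- space_sample(space, m, seed)
  A <- eval_matrix(funcs, pts, space)
  sv <- svd(A)$d
  rank <- sum(sv > 1e-8 * max(sv, .Machine$double.xmin))
  dep <- logical(k)
  r_prev <- 0L
  for (j in seq_len(k)) {
    svj <- svd(A[seq_len(j), , drop = FALSE])$d
    rj <- sum(svj > 1e-8 * max(svj, .Machine$double.xmin))
    dep[j] <- (rj == r_prev)
    r_prev <- rj
  }
  cert <- list(seed = seed, points = pts, singular_values = sv, wronskian = NA)
  if (wronskian && space$dim == 1 && k <= 6) {
    W <- tryCatch(wronskian_zero(funcs, space, pts), error = function(e) NULL)
    if (!is.null(W)) {
      cert$wronskian <- W$is_zero
      if (W$is_zero != (rank < k))
        stop(pspm_condition("pspm_disagreement_error", paste0(
          "numeric rank (", rank, "/", k, ") disagrees with the symbolic ",
          "Wronskian verdict; manual review needed")))
    }
  }
  list(rank = rank, dependent = dep, certificate = cert)
}

# evaluation matrix funcs x points; errors when a function is singular at all
# sampled points
eval_matrix <- function(funcs, pts, space) {
  k <- length(funcs); m <- length(pts[[1]])
  A <- matrix(NA_real_, k, m)
  for (i in seq_len(k)) {
    v <- tryCatch(do.call(sf_fun(funcs[[i]], space$vars), pts), error = function(e) NaN)
    v <- rep_len(v, m)
    if (all(!is.finite(v)))
      stop(pspm_condition("pspm_evaluation_error", sprintf(
        "function %d is singular at every sampled point", i)))
    v[!is.finite(v)] <- 0
    A[i, ] <- v
  }
  A
}

# symbolic Wronskian; zero-tested on canonical coefficients and on samples
wronskian_zero <- function(funcs, space, pts) {
  k <- length(funcs); var <- space$vars[1]
  rows <- list(funcs)
  for (d in seq_len(k - 1))
    rows[[d + 1]] <- lapply(rows[[d]], sf_deriv, var = var)
  W <- sym_det(rows, k)
  scale <- max(1, prod(vapply(funcs, sf_max_coef, numeric(1))))
  isz <- sf_is_zero(W, scale = scale)
  if (!isz) {
    # guard against near-cancellation: confirm on the sampled points
    v <- tryCatch(sf_eval(W, lapply(pts, function(p) p[seq_len(min(8, length(p)))])),
                  error = function(e) NA)
    if (all(is.finite(v)) && max(abs(v)) <= 1e-9 * scale) isz <- TRUE
  }
  list(is_zero = isz, wronskian = W)
}

# determinant of a k x k matrix of symfs by cofactor expansion (k small)
sym_det <- function(rows, k) {
  if (k == 1) return(rows[[1]][[1]])
  out <- sf_zero()
  for (j in seq_len(k)) {
    minor <- lapply(rows[-1], function(r) r[-j])
    sub <- sym_det(minor, k - 1)
    term <- sf_mul(rows[[1]][[j]], sub)
    out <- if (j %% 2 == 1) sf_add(out, term) else sf_sub(out, term)
  }
  out
}

# ---- span membership -------------------------------------------------------

# least squares of cand on basis at sample points, then coefficient-space
# confirmation in the canonical algebra
span_solve <- function(cand, basis, pts, space) {
  A <- eval_matrix(basis, pts, space)
  b <- eval_matrix(list(cand), pts, space)[1, ]
  # least squares via SVD pseudoinverse (robust to near-collinear bases)
  sv <- svd(t(A))
  dinv <- ifelse(sv$d > 1e-12 * max(sv$d), 1 / sv$d, 0)
  coef <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, b)))
  resid <- b - as.numeric(t(A) %*% coef)
  scale <- max(abs(b), 1e-12)
  resid_rel <- sqrt(mean(resid^2)) / scale
  ok_num <- resid_rel < 1e-8
  ok_sym <- FALSE
  if (ok_num) {
    resid <- cand
    for (j in seq_along(basis))
      if (coef[j] != 0) resid <- sf_sub(resid, sf_scale(basis[[j]], coef[j]))
    sscale <- max(sf_max_coef(cand), max(abs(coef)) *
                    max(vapply(basis, sf_max_coef, numeric(1))), 1e-12)
    ok_sym <- sf_is_zero(resid, scale = sscale, tol = 1e-8)
  }
  list(ok = ok_num && ok_sym, coef = coef, resid_rel = resid_rel)
}

# ---- the TEST --------------------------------------------------------------

#' Run the ODE-reducibility TEST
#'
#' Starts from the span of the output weight functions (together with every
#' birth rate weight, treated as an output on a par with the others), applies
#' the backward operator, and adds every environment-monomial component that
#' falls outside the current span, until the span closes or exceeds
#' `max_dim`.  On closure the matrices of the reduced system are assembled
#' and the defining identity is re-verified symbolically.
#'
#' @param model a [pspm_model()]; should pass [validate_model()].
#' @param max_dim span-size cap; exceeding it yields status
#'   `"not_reduced_within_cap"` (never a claim of irreducibility).
#' @param seed seed for sample points used in rank tests and coefficient
#'   solves.
#' @return a `reduction_result` with `status`, `basis` (list of symf, in
#'   provenance order), `provenance`, `K`, `H`, `M`, `Q` ([`env_matrix`][em_eval]
#'   objects), and the iteration `trace`.
#' @export
run_test <- function(model, max_dim = 12L, seed = 1L) {
  sp <- model$space
  pts <- space_sample(sp, max(3L * (max_dim + 2L), 24L), seed)
  seeds <- list()
  for (out in model$outputs) for (cp in out$components) seeds <- c(seeds, list(cp$x))
  for (b in model$births) for (cp in b$rate_weight$components) seeds <- c(seeds, list(cp$x))
  if (!length(seeds)) stop("model has no output weight functions")

  basis <- list(); prov <- list()
  add_if_new <- function(f, iteration, parent) {
    f <- sf_canonical(f)
    if (!length(f$terms)) return(FALSE)
    if (length(basis)) {
      s <- span_solve(f, basis, pts, sp)
      if (s$ok) return(FALSE)
      # eliminate the pivot terms of existing basis elements (an exact
      # row-reduction); the extension is unchanged but bases come out clean
      f <- reduce_pivots(f, basis)
      if (!length(f$terms)) return(FALSE)
    }
    f <- sf_scale(f, 1 / f$terms[[1]]$coef)
    basis[[length(basis) + 1L]] <<- f
    prov[[length(prov) + 1L]] <<- list(iteration = iteration, parent = parent)
    TRUE
  }
  for (f in seeds) add_if_new(f, 0L, NA_integer_)

  trace <- list()
  iteration <- 0L
  repeat {
    iteration <- iteration + 1L
    added <- 0L
    i <- 1L
    while (i <= length(basis)) {
      img <- tryCatch(apply_A(basis[[i]], model), error = function(e) e)
      if (inherits(img, "error")) {
        if (inherits(img, "pspm_nonseparable_error") || inherits(img, "pspm_domain_error"))
          stop(img)
        return(reduction_result("non_differentiable", basis, prov, model,
                                trace = trace, message = conditionMessage(img)))
      }
      for (cp in img$components) {
        if (length(basis) >= max_dim && added_outside(cp$x, basis, pts, sp)) {
          trace[[length(trace) + 1L]] <- list(iteration = iteration, added = NA)
          return(reduction_result("not_reduced_within_cap", basis, prov, model, trace = trace))
        }
        if (add_if_new(cp$x, iteration, i)) added <- added + 1L
      }
      i <- i + 1L
    }
    trace[[length(trace) + 1L]] <- list(iteration = iteration, added = added)
    if (added == 0L) break
    if (length(basis) > max_dim)
      return(reduction_result("not_reduced_within_cap", basis, prov, model, trace = trace))
  }

  assemble_reduction(model, basis, prov, pts, trace, seed)
}

# forward row-reduction: repeatedly subtract each basis element (leading
# coefficient 1) times the candidate's coefficient on its leading term key
reduce_pivots <- function(f, basis) {
  pivots <- vapply(basis, function(b) sf_term_key(b$terms[[1]]), character(1))
  for (pass in seq_len(length(basis) + 1L)) {
    changed <- FALSE
    for (j in seq_along(basis)) {
      keys <- vapply(f$terms, sf_term_key, character(1))
      hit <- match(pivots[j], keys)
      if (!is.na(hit)) {
        f <- sf_canonical(sf_sub(f, sf_scale(basis[[j]], f$terms[[hit]]$coef)))
        changed <- TRUE
        if (!length(f$terms)) return(f)
      }
    }
    if (!changed) break
  }
  f
}

added_outside <- function(f, basis, pts, sp) {
  if (!length(sf_canonical(f)$terms)) return(FALSE)
  !span_solve(f, basis, pts, sp)$ok
}

reduction_result <- function(status, basis, prov, model, K = NULL, H = NULL,
                             M = NULL, Q = NULL, trace = list(), message = NULL,
                             certificate = NULL) {
  structure(list(status = status, basis = basis, provenance = prov,
                 K = K, H = H, M = M, Q = Q, trace = trace,
                 atoms = model$atoms, space = model$space,
                 message = message, certificate = certificate),
            class = "reduction_result")
}

# express sep_expr img in the basis -> entries rows for row i of an env matrix
express_rows <- function(img, basis, pts, sp, i, what) {
  entries <- list()
  for (cp in img$components) {
    s <- span_solve(cp$x, basis, pts, sp)
    if (!s$ok)
      stop(pspm_condition("pspm_span_error", sprintf(
        "%s component %s falls outside the closed basis (relative residual %.2e)",
        what, mono_format(cp$mono), s$resid_rel)))
    for (j in seq_along(basis)) if (abs(s$coef[j]) > 1e-11)
      entries[[length(entries) + 1L]] <- list(i = i, j = j, mono = cp$mono, coef = s$coef[j])
  }
  entries
}

assemble_reduction <- function(model, basis, prov, pts, trace, seed) {
  sp <- model$space
  k <- length(basis)
  ic <- independence_check(basis, sp, seed = seed)
  if (ic$rank < k)
    stop(pspm_condition("pspm_disagreement_error",
                        "closed basis failed the final independence certification"))
  entK <- list(); entH <- list()
  for (i in seq_len(k)) {
    entK <- c(entK, express_rows(apply_A(basis[[i]], model), basis, pts, sp, i, "A(E)psi"))
    entH <- c(entH, express_rows(apply_A0(basis[[i]], model), basis, pts, sp, i, "A0(E)psi"))
  }
  K <- em_from_entries(entK, k, k)
  H <- em_from_entries(entH, k, k)
  M <- em_sub(K, H)
  r <- length(model$outputs)
  Q <- NULL
  if (r > 0) {
    entQ <- list()
    for (i in seq_len(r))
      entQ <- c(entQ, express_rows(model$outputs[[i]], basis, pts, sp, i, "output"))
    Q <- em_from_entries(entQ, r, k)
  }
  res <- reduction_result("reduced", basis, prov, model, K, H, M, Q,
                          trace = trace, certificate = ic$certificate)
  chk <- residual_zero(res, model)
  if (!chk$ok) {
    res$status <- "degraded"
    res$message <- chk$message
  }
  res
}

# symbolic residual A(E)Psi - K(E)Psi == 0, checked on canonical coefficients
residual_zero <- function(res, model) {
  k <- length(res$basis)
  for (i in seq_len(k)) {
    lhs <- apply_A(res$basis[[i]], model)
    for (j in seq_len(k)) {
      kij <- em_entry_sep(res$K, i, j, model$atoms)
      lhs <- sep_sub(lhs, sep_mul_symf(kij, res$basis[[j]]))
    }
    scale <- max(em_max_abs(res$K) * max(vapply(res$basis, sf_max_coef, numeric(1))), 1)
    if (!sep_is_zero(lhs, scale = scale, tol = 1e-8))
      return(list(ok = FALSE, message = sprintf(
        "residual of A(E)psi_%d - (K Psi)_%d does not vanish", i, i)))
  }
  list(ok = TRUE)
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction result> status: %s, basis dimension %d\n",
              x$status, length(x$basis)))
  for (i in seq_along(x$basis)) {
    p <- x$provenance[[i]]
    cat(sprintf("  psi_%d = %s   (iteration %d%s)\n", i, sf_format(x$basis[[i]]),
                p$iteration,
                if (is.na(p$parent)) "" else sprintf(", from psi_%d", p$parent)))
  }
  if (!is.null(x$K)) { cat("K(E):\n"); print(x$K) }
  invisible(x)
}

#' Assemble the birth-coupling matrix M(E) from a closed basis
#'
#' M satisfies `B(E) Psi = M(E) Psi`: entry (i,j) collects, over all birth
#' terms, the weight value at the birth state times the coefficient of
#' `psi_j` in the birth rate weight.  Cross-checks `K - H` from [run_test()].
#'
#' @param basis list of weight functions (symf) or a `reduction_result`.
#' @param model the [pspm_model()].
#' @param seed seed for the coefficient-solve sample points.
#' @return an `env_matrix`.
#' @export
assemble_M <- function(basis, model, seed = 1L) {
  if (inherits(basis, "reduction_result")) basis <- basis$basis
  basis <- lapply(basis, as_symf)
  k <- length(basis)
  sp <- model$space
  pts <- space_sample(sp, max(3L * (k + 2L), 24L), seed)
  entries <- list()
  for (b in model$births) {
    vals <- stats::setNames(as.list(b$birth_state), sp$vars)
    wvals <- vapply(basis, function(f) sf_eval(f, vals), numeric(1))
    for (cp in b$rate_weight$components) {
      s <- span_solve(cp$x, basis, pts, sp)
      if (!s$ok)
        stop(pspm_condition("pspm_span_error",
          "a birth rate weight lies outside the span of the basis"))
      for (i in seq_len(k)) for (j in seq_len(k))
        if (abs(wvals[i] * s$coef[j]) > 1e-13)
          entries[[length(entries) + 1L]] <- list(i = i, j = j, mono = cp$mono,
                                                  coef = wvals[i] * s$coef[j])
    }
  }
  if (!length(entries)) return(em_new(k, k))
  em_from_entries(entries, k, k)
}

#' Verify a reduction numerically and under similarity rebasing
#'
#' Draws random atom valuations and i-state points, checks the pointwise
#' residual of `A(E) psi_i - (K(E) Psi)_i`, and confirms that rebasing the
#' weight functions by a random invertible L conjugates K accordingly.
#'
#' @param result a `reduction_result` with status `"reduced"`.
#' @param model the model it was computed from.
#' @param n_valuations number of random atom valuations.
#' @param seed RNG seed.
#' @return list with `pass`, `max_residual`, `similarity_pass` and, on
#'   failure, the located entry.
#' @export
verify_reduction <- function(result, model, n_valuations = 5L, seed = 1L) {
  stopifnot(inherits(result, "reduction_result"))
  k <- length(result$basis)
  sp <- model$space
  worst <- 0; located <- NULL
  vals_list <- withr_seed(seed, lapply(seq_len(n_valuations), function(i)
    stats::setNames(as.list(stats::runif(length(model$atoms), 0.2, 2)), model$atoms)))
  pts <- space_sample(sp, 20L, seed + 1L)
  wf <- lapply(result$basis, sf_fun, vars = sp$vars)
  for (valuation in vals_list) {
    Kv <- em_eval(result$K, valuation)
    Psi <- t(eval_matrix(result$basis, pts, sp))          # m x k
    Aps <- vapply(seq_len(k), function(i) {
      img <- sep_at_valuation(apply_A(result$basis[[i]], model), valuation)
      rep_len(do.call(sf_fun(img, sp$vars), pts), length(pts[[1]]))
    }, numeric(length(pts[[1]])))                          # m x k
    R <- Aps - Psi %*% t(Kv)
    scale <- max(abs(Aps), 1)
    rel <- max(abs(R)) / scale
    if (rel > worst) {
      worst <- rel
      ij <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1, ]
      located <- c(entry = unname(ij[2]))
    }
  }
  pass <- worst < 1e-8
  # similarity covariance: K~ = L K L^{-1} for rebased weights
  L <- withr_seed(seed + 2L, matrix(stats::runif(k * k, -1, 1), k, k) + diag(k))
  sim_ok <- TRUE
  for (valuation in vals_list[seq_len(min(2, length(vals_list)))]) {
    Kv <- em_eval(result$K, valuation)
    Kt <- L %*% Kv %*% solve(L)
    # rebased weights Lw must satisfy A(E)(Lw) = Kt (Lw); verify numerically
    Psi <- t(eval_matrix(result$basis, pts, sp)) %*% t(L)
    Aps <- vapply(seq_len(k), function(i) {
      img <- sep_zero(model$atoms)
      for (j in seq_len(k)) if (L[i, j] != 0)
        img <- sep_add(img, sep_scale(apply_A(result$basis[[j]], model), L[i, j]))
      rep_len(do.call(sf_fun(sep_at_valuation(img, valuation), sp$vars), pts),
              length(pts[[1]]))
    }, numeric(length(pts[[1]])))
    if (max(abs(Aps - Psi %*% t(Kt))) > 1e-7 * max(abs(Aps), 1)) sim_ok <- FALSE
  }
  list(pass = pass && sim_ok, max_residual = worst,
       similarity_pass = sim_ok, located = located)
}

#' Reorder a reduction's basis (and conjugate its matrices)
#'
#' Useful for presenting K in a canonical basis ordering, e.g. by total
#' degree, so the matrix layout is stable across runs.
#'
#' @param result a `reduction_result`.
#' @param perm integer permutation: new position `i` takes old element
#'   `perm[i]`.
#' @return the permuted `reduction_result`.
#' @export
reorder_reduction <- function(result, perm) {
  k <- length(result$basis)
  stopifnot(length(perm) == k, sort(perm) == seq_len(k))
  P <- matrix(0, k, k)
  for (i in seq_len(k)) P[i, perm[i]] <- 1
  permute_em <- function(em, rows = TRUE, cols = TRUE) {
    if (is.null(em)) return(NULL)
    coefs <- em$coefs
    for (m in seq_len(dim(coefs)[3])) {
      Mm <- coefs[, , m, drop = TRUE]
      if (!is.matrix(Mm)) Mm <- matrix(Mm, em_dim(em)[1], em_dim(em)[2])
      if (rows) Mm <- P %*% Mm
      if (cols) Mm <- Mm %*% t(P)
      coefs[, , m] <- Mm
    }
    em_new(dim(coefs)[1], dim(coefs)[2], em$monos, coefs)
  }
  result$basis <- result$basis[perm]
  result$provenance <- result$provenance[perm]
  result$K <- permute_em(result$K)
  result$H <- permute_em(result$H)
  result$M <- permute_em(result$M)
  if (!is.null(result$Q)) result$Q <- permute_em(result$Q, rows = FALSE, cols = TRUE)
  result
}
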