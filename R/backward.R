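# The backward (Kolmogorov) operator acting on weight functions psi:
#   (A0 psi)(x) = grad(psi) . g(x,E) - mu(x,E) psi(x)     (transport + death)
#   (B  psi)(x) = sum_i psi(b_i) * beta_i(x,E)            (Dirac-mixture birth)
# Weight functions are E-free; the result is a separated expression whose
# environment monomials carry the E-dependence.

#' Apply the transport--death part of the backward operator
#'
#' @param psi weight function (string/language/symf); a function of the
#'   i-state only.
#' @param model a validated [pspm_model()].
#' @return a separated expression for `grad(psi) . g - mu * psi`.
#' @export
apply_A0 <- function(psi, model) {
  psi <- as_symf(psi)
  if (any(sf_symbols(psi) %in% model$atoms))
    stop("weight functions must not depend on environment atoms")
  out <- sep_zero(model$atoms)
  for (i in seq_along(model$space$vars)) {
    dpsi <- sf_deriv(psi, model$space$vars[i])
    if (length(dpsi$terms))
      out <- sep_add(out, sep_mul_symf(model$g[[i]], dpsi))
  }
  sep_sub(out, sep_mul_symf(model$mu, psi))
}

#' Apply the birth part of the backward operator
#'
#' Each Dirac birth term contributes `psi(b_i) * rate_weight_i(x, E)`, the
#' value at the birth state folded into the coefficients.
#'
#' @inheritParams apply_A0
#' @return a separated expression.
#' @export
apply_B <- function(psi, model) {
  psi <- as_symf(psi)
  out <- sep_zero(model$atoms)
  for (b in model$births) {
    vals <- stats::setNames(as.list(b$birth_state), model$space$vars)
    v <- sf_eval(psi, vals)
    if (!is.finite(v))
      stop(pspm_condition("pspm_domain_error", sprintf(
        "weight function is not finite at birth state (%s)",
        paste(signif(b$birth_state, 6), collapse = ","))))
    if (v != 0) out <- sep_add(out, sep_scale(b$rate_weight, v))
  }
  out
}

#' Apply the full backward operator A(E) = A0(E) + B(E)
#'
#' @inheritParams apply_A0
#' @return a separated expression.
#' @export
apply_A <- function(psi, model) {
  psi <- as_symf(psi)
  sep_add(apply_A0(psi, model), apply_B(psi, model))
}
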