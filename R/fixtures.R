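# Registry of worked-example models, each with its expected reduction
# metadata (dimension and weight basis) used by the acceptance suite.

#' Registry of built-in example models
#'
#' Each entry carries `model`, `expected_k`, and where the basis is printed
#' in closed form, `expected_basis` (strings in the model's i-state
#' variables).
#'
#' Entries:
#' \describe{
#'   \item{daphnia}{size-structured Daphnia model: `g = delta f(E) - eps x`,
#'     constant death rate, birth rate `alpha f(E) x^2` into a Dirac at
#'     `x_b`; outputs biomass `x^3` and surface area `x^2`; reduces to the
#'     four moments 1, x, x^2, x^3.}
#'   \item{biomass_scalar}{a scalar reduction: `g = a(E) x`, death `mu0(E)`,
#'     births `b(E) x` at `x_b`; total biomass `x` closes on its own.}
#'   \item{physiological_age}{pure maturation `g = v(E)` with death
#'     `mu0(E)`; outputs 1 and x.}
#'   \item{erlang_k3}{age-structured linear chain with Erlang stage weights
#'     (alpha = 2, k = 3).}
#'   \item{size_age}{2-D i-state (size, physiological age):
#'     `g = (a + b x1, c)`, death `mu0(E)`, birth rate
#'     `f(E)(1 - e^{-x2}) x1^2` into a Dirac at (0.5, 0); closes at 6.}
#'   \item{quadratic_cross}{2-D with quadratic cross-feeding growth
#'     `g = (a + b x1, c x1^2)`; output `x2`; closes at 4.}
#'   \item{exp_interaction}{3-D with exponential growth interactions; output
#'     `x3`; closes at 4.}
#' }
#'
#' @return named list of fixture entries.
#' @export
fixtures <- function() {
  fx <- list()

  p <- daphnia_params()
  fx$daphnia <- list(
    model = daphnia_model(p), params = p, expected_k = 4L,
    expected_basis = c("x^3", "x^2", "x", "1"),
    reference_valuation = c(f = 2))

  sp <- istate_space(1, lower = 0.5, upper = 3)
  fx$biomass_scalar <- list(
    model = pspm_model(sp, lapply(c("a", "b", "mu0"), env_atom),
                       g = "a*x", mu = "mu0",
                       births = list(birth_term("b*x", 0.5, atoms = "b")),
                       outputs = list("x"), name = "biomass_scalar"),
    expected_k = 1L, expected_basis = "x",
    reference_valuation = c(a = 1, b = 1, mu0 = 1))

  spa <- istate_space(1, lower = 0, upper = 5)
  fx$physiological_age <- list(
    model = pspm_model(spa, lapply(c("v", "mu0"), env_atom),
                       g = "v", mu = "mu0", births = list(),
                       outputs = list("1", "x"), name = "physiological_age"),
    expected_k = 2L, expected_basis = c("1", "x"),
    reference_valuation = c(v = 1, mu0 = 1))

  er <- erlang_chain(alpha = 2, k = 3L)
  fx$erlang_k3 <- list(
    model = er$reduction$model, expected_k = 3L,
    expected_basis = vapply(er$reduction$w, sf_format, character(1)),
    reduction = er$reduction, alpha = er$alpha,
    reference_valuation = c(b1 = 1, b2 = 1, b3 = 1, mu0 = 1))

  sp2 <- istate_space(2, lower = c(0, 0), upper = c(2, 3), x_b = c(0.5, 0))
  fx$size_age <- list(
    model = pspm_model(sp2, lapply(c("a", "b", "c", "f", "mu0"), env_atom),
                       g = list("a + b*x1", "c"), mu = "mu0",
                       births = list(birth_term("f*(1 - exp(-x2))*x1^2", c(0.5, 0),
                                                atoms = "f")),
                       outputs = list("f*(1 - exp(-x2))*x1^2"),
                       name = "size_age"),
    expected_k = 6L,
    expected_basis = c("1", "x1", "x1^2", "exp(-x2)", "x1*exp(-x2)", "x1^2*exp(-x2)"),
    reference_valuation = c(a = 1, b = 1, c = 1, f = 1, mu0 = 1))

  sp3 <- istate_space(2, lower = c(0, 0), upper = c(2, 3), x_b = c(0.1, 0))
  fx$quadratic_cross <- list(
    model = pspm_model(sp3, lapply(c("a", "b", "c", "mu0"), env_atom),
                       g = list("a + b*x1", "c*x1^2"), mu = "mu0",
                       births = list(), outputs = list("x2"),
                       name = "quadratic_cross"),
    expected_k = 4L, expected_basis = c("x2", "x1^2", "x1", "1"),
    reference_valuation = c(a = 1, b = 1, c = 1, mu0 = 1))

  sp4 <- istate_space(3, lower = c(0, 0, 0), upper = c(2, 2, 3), x_b = c(0, 0, 0))
  fx$exp_interaction <- list(
    model = pspm_model(sp4, lapply(c("a1", "a2", "c1", "c2", "c3", "mu0"), env_atom),
                       g = list("a1", "a2",
                                "c1*exp(x1) + c2*exp(0.5*x2) + c3*exp(x1 + 0.5*x2)"),
                       mu = "mu0", births = list(), outputs = list("x3"),
                       name = "exp_interaction"),
    expected_k = 4L,
    expected_basis = c("x3", "exp(x1)", "exp(0.5*x2)", "exp(x1 + 0.5*x2)"),
    reference_valuation = c(a1 = 1, a2 = 1, c1 = 1, c2 = 1, c3 = 1, mu0 = 1))

  fx
}

#' Default Daphnia fixture parameters
#'
#' Length-structured: growth `delta f(E) - eps x`, birth rate
#' `alpha f(E) x^2`, constant death rate.  At the operating point f = 1 the
#' growth asymptote delta f/eps = 2 lies inside the i-state interval.
#'
#' @return named list of parameters.
#' @export
daphnia_params <- function() {
  list(delta = 1, eps = 0.5, alpha = 0.75, mu = 0.1, x_b = 0.5, x_max = 2.5)
}

#' The classical Erlang linear chain (age-structured)
#'
#' `Lambda` with diagonal `-alpha` and subdiagonal `alpha`,
#' `w0 = (alpha, 0, ..., 0)`, giving Erlang stage weights
#' `w_j(x) = alpha^j x^{j-1} e^{-alpha x}/(j-1)!`.
#'
#' @param alpha stage rate.
#' @param k number of stages.
#' @return list with `alpha`, `k`, `Lambda`, `w0` and the
#'   [age_structured_reduce()] output under atoms `b1..bk`, `mu0`.
#' @export
erlang_chain <- function(alpha = 2, k = 3L) {
  L <- diag(-alpha, k)
  for (i in seq(2, k)) L[i, i - 1] <- alpha
  w0 <- c(alpha, rep(0, k - 1))
  red <- age_structured_reduce(as.list(paste0("b", seq_len(k))), "0", "mu0",
                               L, w0, x_max = Inf)
  list(alpha = alpha, k = k, Lambda = L, w0 = w0, reduction = red)
}
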