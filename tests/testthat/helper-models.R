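# Shared fixtures: built in code, numeric parameters from daphnia_params().

daphnia_fixture <- function() {
  p <- daphnia_params()
  list(p = p, model = daphnia_model(p))
}

# the coefficient matrix of the explicit Daphnia moment system in basis
# (1, x, x^2, x^3), at functional-response value f
daphnia_K_explicit <- function(p, f) {
  rbind(
    c(-p$mu, 0, p$alpha * f, 0),
    c(p$delta * f, -(p$mu + p$eps), p$x_b * p$alpha * f, 0),
    c(0, 2 * p$delta * f, p$x_b^2 * p$alpha * f - (p$mu + 2 * p$eps), 0),
    c(0, 0, p$x_b^3 * p$alpha * f + 3 * p$delta * f, -(p$mu + 3 * p$eps)))
}

# permutation ordering a reduction's basis by total degree (monomials first)
degree_order <- function(basis) {
  deg <- vapply(basis, function(b) {
    if (!length(b$terms)) return(0)
    max(vapply(b$terms, function(t) sum(t$pow), numeric(1)))
  }, numeric(1))
  order(deg)
}

# random polynomial-exponential symf in one variable, for property tests
random_symf <- function(var = "x", n_terms = 3) {
  terms <- lapply(seq_len(n_terms), function(i) {
    deg <- sample(0:3, 1)
    co <- round(runif(1, -2, 2), 3)
    t <- sf_scale(sf_pow_int(sf_sym(var), deg), co)
    if (runif(1) < 0.4)
      t <- sf_mul(t, sf_exp(sf_scale(sf_sym(var), round(runif(1, -1.5, 0.5), 3))))
    t
  })
  Reduce(sf_add, terms)
}

erlang_fixture <- function(alpha = 2, k = 3L) erlang_chain(alpha, k)
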