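# Catalogue families, their defining identity, special matrices, and the
# age-structured linear chain trick.

test_that("F1 instances: trivial, constant, and reciprocal survival weights", {
  sp <- istate_space(1, lower = 0.5, upper = 3)
  # gamma0 = 0: w = 1, H = -mu0
  f0 <- make_f1("0", "mu0", g = "f - 0.2*x", sp, atoms = "f")
  expect_true(sf_equal(f0$w[[1]], sf_const(1)))
  expect_equal(em_eval(f0$H, list(mu0 = 0.4, f = 1)), matrix(-0.4))
  expect_true(verify_identity(f0))
  # constant gamma0: w = e^{c(x - x_b)}
  fc <- make_f1("0.8", "mu0", g = "f", sp, atoms = "f")
  expect_true(sf_equal(fc$w[[1]], sf_parse(sprintf("exp(-%.17g)*exp(0.8*x)", 0.8 * 0.5))))
  expect_true(verify_identity(fc))
  # gamma0 = 1/x: biomass-style weight proportional to x
  fb <- make_f1("1/x", "mu0", g = "f*x", sp, atoms = "f")
  expect_true(sf_equal(fb$w[[1]], sf_parse("2*x")))
  expect_true(verify_identity(fb))
  # cross-check with the backward operator: A0 w = -mu0 w for the fb model
  m <- pspm_model(sp, lapply(c("f", "mu0"), env_atom), g = "f*x",
                  mu = sep_add(pspmreduce:::sep_mul_symf(fb$g, sf_parse("1/x")),
                               normalize_separated("mu0", c("f", "mu0"))),
                  births = list(), outputs = list(fb$w[[1]]))
  img <- apply_A0(fb$w[[1]], m)
  expect_true(sep_is_zero(sep_sub(img,
    pspmreduce:::sep_mul_symf(normalize_separated("-mu0", c("f", "mu0")), fb$w[[1]])),
    scale = 1))
})

test_that("(H2)/(H3) classify eigenstructures as in the catalogue conditions", {
  # repeated eigenvalue with full eigenspace: H2 fails
  r1 <- check_h2_h3(diag(c(1, 1)), c(1, 1))
  expect_false(r1$h2)
  # Jordan block with w0 on the chain generator: passes
  J <- rbind(c(2, 0), c(1, 2))
  expect_true(check_h2_h3(J, c(1, 0))$ok)
  # w0 equal to the eigenvector: H3 fails
  r3 <- check_h2_h3(J, c(0, 1))
  expect_true(r3$h2)
  expect_false(r3$h3)
  # rank certified by the resulting exponential components
  w <- pspmreduce:::matexp_action(J, c(1, 0), sf_sym("x"))
  sp <- istate_space(1, lower = 0, upper = 2)
  expect_identical(independence_check(w, sp, seed = 3)$rank, 2L)
  w2 <- pspmreduce:::matexp_action(J, c(0, 1), sf_sym("x"))
  expect_identical(independence_check(w2, sp, seed = 3)$rank, 1L)
})

test_that("F2 with the Erlang chain produces the Erlang stage weights", {
  al <- 2; k <- 3
  sp <- istate_space(1, lower = 0, upper = Inf, x_b = 0)
  L <- diag(-al, k); for (i in 2:k) L[i, i - 1] <- al
  inst <- make_f2("0", "mu0", "1", 1, L, c(al, rep(0, k - 1)), sp)
  for (j in 1:k) {
    expected <- sf_parse(sprintf("%.17g * x^%d * exp(-%g*x)",
                                 al^j / factorial(j - 1), j - 1, al))
    expect_true(sf_equal(inst$w[[j]], expected))
  }
  expect_true(verify_identity(inst))
  # Erlang normalisation: each w_j integrates to one over [0, inf)
  for (j in 1:k) {
    q <- stats::integrate(sf_fun(inst$w[[j]], "x"), 0, Inf)$value
    expect_equal(q, 1, tolerance = 1e-8)
  }
})

test_that("F3 reproduces the Daphnia transport matrix up to similarity; k = 1 degenerates to F1", {
  fx <- daphnia_fixture(); p <- fx$p
  sp <- fx$model$space
  inst <- make_f3(gamma0 = "0", mu0 = p$mu, v0 = "1",
                  v1 = list(list(mono = c(f = 1L), coef = p$delta),
                            list(mono = integer(0), coef = -p$eps * p$x_b)),
                  v2 = -p$eps, v3 = 0, k = 4, space = sp)
  expect_true(verify_identity(inst))
  res <- run_test(fx$model, seed = 3)
  for (f in c(0.9, 1.4)) {
    val <- list(f = f)
    eH1 <- sort(Re(eigen(em_eval(inst$H, val), only.values = TRUE)$values))
    eH2 <- sort(Re(eigen(em_eval(res$H, val), only.values = TRUE)$values))
    expect_equal(eH1, eH2, tolerance = 1e-8)
  }
  # k = 1: single weight, H collapses to -mu0
  i1 <- make_f3("0", "mu0", "1", "v1", "v2", 0, k = 1, space = sp)
  expect_length(i1$w, 1)
  expect_equal(em_eval(i1$H, list(mu0 = 0.7, v1 = 1, v2 = 1)), matrix(-0.7))
  expect_true(verify_identity(i1))
})

test_that("randomized F1/F2/F3 instances satisfy the identity with full rank", {
  set.seed(31)
  sp <- istate_space(1, lower = 0.2, upper = 3)
  for (rep in 1:6) {
    k <- sample(2:4, 1)
    fam <- sample(c("F2", "F3"), 1)
    g0 <- sprintf("%.3f", runif(1, 0, 0.5))
    if (fam == "F2") {
      L <- diag(sort(runif(k, -2, -0.2), decreasing = TRUE))
      if (k > 1) for (i in 2:k) L[i, i - 1] <- runif(1, 0.3, 1)
      inst <- make_f2(g0, "mu0", "1", "v1", L, runif(k, 0.5, 1.5), sp)
    } else {
      inst <- make_f3(g0, "mu0", sprintf("%.3f", runif(1, 0.5, 2)), "v1", "v2",
                      round(runif(1, 0, 0.4), 3), k = k, space = sp)
    }
    expect_true(verify_identity(inst))
    expect_identical(independence_check(inst$w, sp, seed = rep)$rank, as.integer(k))
  }
})

test_that("a perturbed H breaks the identity", {
  sp <- istate_space(1, lower = 0.2, upper = 3)
  inst <- make_f3("0", "mu0", "1", "v1", "v2", 0, k = 3, space = sp)
  inst$H$coefs[2, 2, 1] <- inst$H$coefs[2, 2, 1] + 1e-3
  expect_false(verify_identity(inst))
})

test_that("Mobius reparametrisation preserves the identity and the weight span", {
  sp <- istate_space(1, lower = 0.5, upper = 1.8)
  inst <- make_f3("0.3", "mu0", "1", "v1", "v2", "v3", k = 3, space = sp)
  # identity transformation changes nothing
  id <- mobius_reparam(inst, 1, 0, 0, 1)
  expect_true(verify_identity(id))
  expect_equal(ev_fmt <- pspmreduce:::ev_format(id$params$v1), "v1")
  # the printed coefficient formula at (a,b,c,d) = (1,1,0,1): v1 - v2 + v3
  sh <- mobius_reparam(inst, 1, 1, 0, 1)
  expect_identical(pspmreduce:::ev_format(sh$params$v1), "v1 + -1*v2 + v3")
  # a generic transform: identity holds, g and mu are unchanged as functions,
  # and the weight spans coincide
  tr <- mobius_reparam(inst, 1.2, 0.4, 0.3, 1.1)
  expect_true(verify_identity(tr))
  val <- list(v1 = 1.1, v2 = 0.4, v3 = 0.2, mu0 = 0.3)
  pts <- space_sample(sp, 12, 2)
  for (fld in c("g", "mu")) {
    a <- do.call(sf_fun(sep_at_valuation(inst[[fld]], val), "x"), pts)
    b <- do.call(sf_fun(sep_at_valuation(tr[[fld]], val), "x"), pts)
    expect_equal(a, b, tolerance = 1e-10)
  }
  A <- eval_matrix(c(inst$w, tr$w), space_sample(sp, 24, 5), sp)
  expect_identical(sum(svd(A)$d > 1e-8 * max(svd(A)$d)), 3L)
  expect_error(mobius_reparam(inst, 1, 2, 0.5, 1),
               class = "pspm_singular_transform_error")
})

test_that("Kac-Sylvester and trigonometric matrix spectra and similarity", {
  expect_equal(kac_sylvester(1), matrix(0))
  expect_equal(sort(Re(eigen(kac_sylvester(3))$values)), c(-2, 0, 2),
               tolerance = 1e-9)
  for (k in 2:10) {
    expect_equal(sort(Re(eigen(kac_sylvester(k), only.values = TRUE)$values)),
                 2 * seq_len(k) - k - 1, tolerance = 1e-9)
    ei <- eigen(trig_matrix(k), only.values = TRUE)$values
    expect_equal(sort(Im(ei)), 2 * seq_len(k) - k - 1, tolerance = 1e-9)
    expect_lt(max(abs(Re(ei))), 1e-9)
  }
  for (k in 2:8) {
    S <- similarity_S(k)
    D <- S %*% trig_matrix(k) %*% solve(S) - 1i * t(kac_sylvester(k))
    expect_lt(max(Mod(D)), 1e-12)
  }
})

test_that("sin/cos powers solve the trigonometric ODE system exactly", {
  for (k in 2:6) {
    tw <- pspmreduce:::trig_weights(k)
    M <- trig_matrix(k)
    for (l in seq_len(k)) {
      rhs <- sf_zero()
      for (j in seq_len(k)) if (M[l, j] != 0) rhs <- sf_add(rhs, sf_scale(tw[[j]], M[l, j]))
      expect_true(sf_is_zero(sf_sub(sf_deriv(tw[[l]], "t"), rhs), scale = k))
    }
    # numeric values agree with trig_solution
    ts <- seq(0.1, 1.4, length.out = 7)
    V <- trig_solution(k, ts)
    for (j in seq_len(k))
      expect_equal(V[, j], sf_eval(tw[[j]], list(t = ts)), tolerance = 1e-12)
  }
})

test_that("the Erlang linear chain reduces to the classical stage system", {
  er <- erlang_fixture(alpha = 2, k = 3L)
  al <- er$alpha; k <- er$k
  # symbolic match of the right-hand side: row 1 couples alpha*btilde_j to
  # every stage and loses (alpha + mu0); rows i >= 2 gain alpha N_{i-1}
  entries <- list()
  for (j in 1:k) entries[[length(entries) + 1L]] <-
      list(i = 1L, j = j, mono = stats::setNames(1L, paste0("b", j)), coef = al)
  for (i in 1:k) {
    entries[[length(entries) + 1L]] <- list(i = i, j = i, mono = integer(0), coef = -al)
    entries[[length(entries) + 1L]] <- list(i = i, j = i, mono = c(mu0 = 1L), coef = -1)
    if (i >= 2) entries[[length(entries) + 1L]] <-
        list(i = i, j = i - 1L, mono = integer(0), coef = al)
  }
  Kexp <- pspmreduce:::em_from_entries(entries, k, k)
  expect_true(em_equal(er$reduction$K, Kexp, tol = 1e-12))
  # no births: K collapses to Lambda - mu0 I
  red0 <- age_structured_reduce(as.list(rep(0, k)), "0", "mu0", er$Lambda, er$w0)
  expect_equal(em_eval(red0$K, list(mu0 = 0.5)), er$Lambda - 0.5 * diag(k),
               tolerance = 1e-12)
  # the TEST on the equivalent structured model yields a similar K
  res <- run_test(er$reduction$model, seed = 4)
  expect_identical(res$status, "reduced")
  expect_length(res$basis, k)
  set.seed(19)
  for (rep in 1:5) {
    val <- as.list(runif(k + 1, 0.2, 2))
    names(val) <- c(paste0("b", 1:k), "mu0")
    e1 <- eigen(em_eval(er$reduction$K, val), only.values = TRUE)$values
    e2 <- eigen(em_eval(res$K, val), only.values = TRUE)$values
    expect_equal(sort(Re(e1)), sort(Re(e2)), tolerance = 1e-7)
    expect_equal(sort(Im(e1)), sort(Im(e2)), tolerance = 1e-7)
  }
})

test_that("for age structure, F3 members coincide with F2 members (linear chain lemma)", {
  # v1 = 1, v2 = 1, v3 = 0.1 with g = 1: zeta solves the Riccati equation;
  # the F2 member with Lambda = H0 must span the same weight space
  v1 <- 1; v2 <- 1; v3 <- 0.1; k <- 3
  rts <- sort(Re(polyroot(c(v1, v2, v3))))
  z1 <- rts[2]; z2 <- rts[1]
  u0 <- z1 / z2; a <- v3 * (z1 - z2)
  x <- sf_sym("x")
  u <- sf_scale(sf_exp(sf_scale(x, a)), u0)
  zeta <- sf_mul(sf_sub(sf_const(z1), sf_scale(u, z2)),
                 sf_powbase(sf_sub(sf_const(1), u), -1))
  # zeta solves zeta' = v1 + v2 zeta + v3 zeta^2 (symbolic residual zero)
  resid <- sf_sub(sf_deriv(zeta, "x"),
                  sf_add(sf_const(v1),
                         sf_add(sf_scale(zeta, v2), sf_scale(sf_mul(zeta, zeta), v3))))
  pts <- list(x = seq(0.1, 2, length.out = 9))
  expect_lt(max(abs(sf_eval(resid, pts))), 1e-10)
  # F3-age member: gamma0_tilde = gamma0 - (k-1) v3 zeta with gamma0 = 0.1
  gamma0 <- 0.1
  # zeta escapes to infinity at x = log(1/u0)/a ~ 2.66; stay below it
  sp <- istate_space(1, lower = 0, upper = 2, x_b = 0)
  g0t <- sf_sub(sf_const(gamma0), sf_scale(zeta, (k - 1) * v3))
  v0 <- sf_powbase(sf_add(sf_const(v1),
                          sf_add(sf_scale(zeta, v2), sf_scale(sf_mul(zeta, zeta), v3))), -1)
  # int_0^x zeta = z1 x - ((z1 - z2)/a)(log(1 - u) - log(1 - u0)), so the
  # survival factor exp(int gamma0_tilde) is available in closed form
  intzeta <- sf_add(sf_scale(x, z1),
                    sf_scale(sf_sub(sf_log(sf_sub(sf_const(1), u)),
                                    sf_const(log(1 - u0))), -(z1 - z2) / a))
  G <- sf_exp(sf_sub(sf_scale(x, gamma0), sf_scale(intzeta, (k - 1) * v3)))
  f3 <- make_f3(g0t, "mu0", v0, v1, v2, v3, k = k, space = sp, zeta = zeta, G = G)
  expect_true(verify_identity(f3))
  # g is identically 1
  gv <- do.call(sf_fun(sep_at_valuation(f3$g, list(mu0 = 1)), "x"), pts)
  expect_equal(gv, rep(1, 9), tolerance = 1e-10)
  # F2-age member with Lambda = H0 and the plain gamma0
  H0 <- matrix(0, k, k)
  for (i in 1:k) {
    if (i >= 2) H0[i, i - 1] <- (i - 1) * v1
    H0[i, i] <- (i - 1) * v2
    if (i < k) H0[i, i + 1] <- -(k - i) * v3
  }
  f2 <- make_f2(sprintf("%.17g", gamma0), "mu0", "1", 1, H0, c(1, 0, 0), sp)
  expect_true(verify_identity(f2))
  A <- eval_matrix(c(f3$w, f2$w), space_sample(sp, 24, 7), sp)
  expect_identical(sum(svd(A)$d > 1e-8 * max(svd(A)$d)), as.integer(k))
})

test_that("classification recovers catalogue families from raw ingredients", {
  spd <- istate_space(1, lower = 0.5, upper = 2.5)
  cls <- classify_ingredients("1*f - 0.5*x", "0.1", spd, atoms = "f")
  expect_identical(cls$family, "F3")
  expect_identical(pspmreduce:::ev_format(cls$v2), "-0.5")
  expect_equal(pspmreduce:::ev_eval(cls$v1, list(f = 1)), 1 - 0.5 * 0.5,
               tolerance = 1e-12)  # delta f - eps x_b at f = 1
  expect_equal(pspmreduce:::ev_eval(cls$mu0, list()), 0.1, tolerance = 1e-12)

  sp <- istate_space(1, lower = 0, upper = 5)
  cls2 <- classify_ingredients("v", "mu0", sp, atoms = c("v", "mu0"))
  expect_identical(cls2$family, "F2")

  cls3 <- classify_ingredients("f*exp(x) + h*x", "0", spd, atoms = c("f", "h"))
  expect_identical(cls3$family, "none")
})

test_that("age density recovery matches the closed survival form and is monotone in mu0", {
  er <- erlang_fixture(alpha = 2, k = 3L)
  k <- 3
  env <- env_input(b1 = 0.8, b2 = 1.2, b3 = 1.5, mu0 = 0.3)
  N0 <- c(1, 0.5, 0.25)
  tr <- integrate_reduced(er$reduction$K, env, N0, seq(0, 6, by = 1e-3))
  # constant E, gamma0 = 0: n(t,x) = e^{-mu0 x} sum_j btilde_j N_j(t - x)
  tq <- 5; xq <- c(0.5, 1.5, 3)
  n <- recover_age_density(tr, env, er$reduction$recovery, t = tq, x = xq)
  Nf <- pspmreduce:::as_history_fun(tr)
  for (i in seq_along(xq)) {
    Nb <- Nf(tq - xq[i])
    expected <- exp(-0.3 * xq[i]) * sum(c(0.8, 1.2, 1.5) * Nb)
    expect_equal(n[i], expected, tolerance = 1e-6)
  }
  # x >= t is not recoverable
  expect_error(recover_age_density(tr, env, er$reduction$recovery, t = 1, x = 2),
               class = "pspm_domain_error")
  # larger mu0 gives pointwise smaller density
  envh <- env_input(b1 = 0.8, b2 = 1.2, b3 = 1.5, mu0 = 1.2)
  nh <- recover_age_density(tr, envh, er$reduction$recovery, t = tq, x = xq)
  expect_true(all(nh < n))
})
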