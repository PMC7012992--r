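# Linear independence certification and the span-closure TEST.

test_that("independence_check ranks monomials and scalar multiples correctly", {
  sp <- istate_space(1, lower = 0.1, upper = 2)
  r1 <- independence_check(list("1", "x", "x^2", "x^3"), sp, seed = 5)
  expect_identical(r1$rank, 4L)
  expect_false(any(r1$dependent))

  r2 <- independence_check(list("x", "2*x"), sp, seed = 5)
  expect_identical(r2$rank, 1L)
  expect_identical(r2$dependent, c(FALSE, TRUE))
  expect_length(r2$certificate$singular_values, 2)
})

test_that("matrix-exponential components of a full Jordan block are independent", {
  # single 3x3 Jordan block (lambda = -1), w0 = (0,0,1): components span
  # {e^-x, x e^-x, x^2 e^-x}; oracle = the symbolic Wronskian path inside
  # independence_check must agree with the numeric rank
  L <- rbind(c(-1, 1, 0), c(0, -1, 1), c(0, 0, -1))
  w <- pspmreduce:::matexp_action(L, c(0, 0, 1), sf_sym("x"))
  sp <- istate_space(1, lower = 0, upper = 4)
  r <- independence_check(w, sp, seed = 9)
  expect_identical(r$rank, 3L)
  expect_false(isTRUE(r$certificate$wronskian))
  # explicit span check against the closed-form building blocks
  blocks <- list(sf_parse("exp(-x)"), sf_parse("x*exp(-x)"), sf_parse("x^2*exp(-x)"))
  A <- eval_matrix(c(w, blocks), space_sample(sp, 18, 2), sp)
  expect_identical(sum(svd(A)$d > 1e-8 * max(svd(A)$d)), 3L)
  # an eigenvector start collapses the span to rank 1
  w1 <- pspmreduce:::matexp_action(L, c(1, 0, 0), sf_sym("x"))
  expect_identical(independence_check(w1, sp, seed = 9)$rank, 1L)
})

test_that("Daphnia TEST closes at dimension 4 with K equal to the moment system", {
  fx <- daphnia_fixture()
  res <- run_test(fx$model, seed = 3)
  expect_identical(res$status, "reduced")
  expect_length(res$basis, 4)
  expect_identical(vapply(res$basis, sf_format, character(1)),
                   c("x^3", "x^2", "x", "1"))
  r2 <- reorder_reduction(res, degree_order(res$basis))
  for (f in c(0.7, 1, 1.6)) {
    expect_equal(em_eval(r2$K, list(f = f)), daphnia_K_explicit(fx$p, f),
                 tolerance = 1e-10)
  }
  # K = H + M entrywise
  expect_true(em_equal(pspmreduce:::em_add(res$H, res$M), res$K))
  # outputs are recovered: Gamma = Q Psi with Q picking x^3 and x^2
  expect_equal(em_eval(res$Q, list(f = 1)), rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
               tolerance = 1e-10)
})

test_that("pure transport with a single output reduces to one dimension", {
  sp <- istate_space(1, lower = 0, upper = 5)
  m <- pspm_model(sp, lapply(c("v", "mu0"), env_atom), g = "v", mu = "mu0",
                  births = list(), outputs = list("1"))
  res <- run_test(m, seed = 2)
  expect_identical(res$status, "reduced")
  expect_length(res$basis, 1)
  expect_equal(em_eval(res$K, list(v = 1.3, mu0 = 0.4)), matrix(-0.4),
               tolerance = 1e-12)
})

test_that("the TEST is idempotent and the span grows monotonically", {
  fx <- daphnia_fixture()
  res <- run_test(fx$model, seed = 3)
  m2 <- pspm_model(fx$model$space, list(env_atom("f")),
                   g = sprintf("%.17g*f - %.17g*x", fx$p$delta, fx$p$eps),
                   mu = sprintf("%.17g", fx$p$mu),
                   births = fx$model$births, outputs = res$basis)
  res2 <- run_test(m2, seed = 8)
  expect_length(res2$basis, 4)
  # monotonicity: every seed function lies in the span of the closed basis
  pts <- space_sample(fx$model$space, 30, 4)
  for (o in fx$model$outputs) for (cp in o$components) {
    s <- pspmreduce:::span_solve(cp$x, res$basis, pts, fx$model$space)
    expect_true(s$ok)
  }
  # trace records non-negative additions ending in closure
  expect_identical(res$trace[[length(res$trace)]]$added, 0L)
})

test_that("a growth law outside the catalogue classes exceeds the cap", {
  # probing with a weight the growth law actually moves: each image of x
  # brings in e^x, then x e^x, e^{2x}, ... without closing
  sp <- istate_space(1, lower = 0.3, upper = 2)
  m <- pspm_model(sp, lapply(c("f", "h"), env_atom),
                  g = "f*exp(x) + h*x", mu = "0", births = list(),
                  outputs = list("x"))
  res <- run_test(m, max_dim = 12, seed = 2)
  expect_identical(res$status, "not_reduced_within_cap")
})

test_that("assemble_M reproduces K - H and the Dirac birth column structure", {
  fx <- daphnia_fixture(); p <- fx$p
  res <- run_test(fx$model, seed = 3)
  M <- assemble_M(res, fx$model)
  expect_true(em_equal(M, res$M))
  # single nonzero column at the x^2 slot, entries x_b^i alpha f
  Mv <- em_eval(M, list(f = 1))
  j2 <- match("x^2", vapply(res$basis, sf_format, character(1)))
  expect_equal(Mv[, -j2], matrix(0, 4, 3), tolerance = 1e-12)
  pw <- vapply(res$basis, function(b) sf_eval(b, list(x = p$x_b)), numeric(1))
  expect_equal(Mv[, j2], pw * p$alpha, tolerance = 1e-10)
  # no births -> zero matrix
  m0 <- pspm_model(fx$model$space, list(env_atom("f")), g = "f - 0.5*x",
                   mu = "0.1", births = list(), outputs = list("x"))
  r0 <- run_test(m0, seed = 2)
  expect_equal(em_max_abs(assemble_M(r0, m0)), 0)
})

test_that("verify_reduction passes exact results, fails a perturbed K, passes rebased", {
  fx <- daphnia_fixture()
  res <- run_test(fx$model, seed = 3)
  v <- verify_reduction(res, fx$model, n_valuations = 5, seed = 7)
  expect_true(v$pass)
  expect_lt(v$max_residual, 1e-10)
  bad <- res
  bad$K$coefs[2, 3, 1] <- bad$K$coefs[2, 3, 1] + 1e-3
  vb <- verify_reduction(bad, fx$model, n_valuations = 5, seed = 7)
  expect_false(vb$pass)
  expect_true(!is.null(vb$located))
})

test_that("the TEST recovers catalogue F2 reductions (oracle equivalence)", {
  # an F2 instance with distinct real eigenvalues; outputs = catalogue w
  sp <- istate_space(1, lower = 0, upper = 4)
  L <- rbind(c(-0.5, 0, 0), c(1, -1.2, 0), c(0, 0.7, -2))
  inst <- make_f2(gamma0 = "0", mu0 = "mu0", v0 = "1", v1 = "v1",
                  Lambda = L, w_xb = c(1, 0.5, 0.25), space = sp)
  m <- pspm_model(sp, lapply(c("v1", "mu0"), env_atom),
                  g = inst$g, mu = inst$mu, births = list(),
                  outputs = inst$w)
  res <- run_test(m, seed = 6)
  expect_identical(res$status, "reduced")
  expect_length(res$basis, 3)
  for (v1v in c(0.8, 1.7)) {
    val <- list(v1 = v1v, mu0 = 0.3)
    e1 <- sort(eigen(em_eval(res$K, val), only.values = TRUE)$values)
    e2 <- sort(eigen(v1v * L - 0.3 * diag(3), only.values = TRUE)$values)
    expect_equal(Re(e1), Re(e2), tolerance = 1e-8)
  }
})
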