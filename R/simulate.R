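# Numerical cross-validation: integrate the reduced ODE, simulate the
# structured model by cohorts along characteristics, and compare outputs.
# The reduction is exact; the cohort discretisation is the approximate side,
# so agreement improving under dt-halving is the operational check.

#' Build an environment input (atom valuations as functions of time)
#'
#' @param ... named atom values: constants, functions of `t`, or
#'   piecewise-constant specifications `list(breaks = , values = )` where
#'   `values` has one more element than `breaks`.
#' @return a function of `t` returning a named list of atom values.
#' @export
env_input <- function(...) {
  spec <- list(...)
  if (length(spec) == 1 && is.null(names(spec)) && is.function(spec[[1]]))
    return(spec[[1]])
  fns <- lapply(spec, function(s) {
    if (is.function(s)) return(s)
    if (is.list(s) && !is.null(s$breaks)) {
      force(s)
      return(function(t) s$values[[findInterval(t, s$breaks) + 1L]])
    }
    force(s); function(t) s
  })
  nm <- names(spec)
  function(t) stats::setNames(lapply(fns, function(f) f(t)), nm)
}

#' Integrate the reduced system dN/dt = K(E(t)) N
#'
#' @param K an `env_matrix` (from [run_test()] or a catalogue constructor), or
#'   a plain numeric matrix (constant environment).
#' @param env an [env_input()] (ignored for a plain matrix).
#' @param N0 initial state.
#' @param t_grid output times (also the fixed RK4 steps for
#'   `method = "rk4"`).
#' @param method `"rk4"` (fixed step) or `"lsoda"` (adaptive via deSolve,
#'   rtol 1e-8).
#' @return list with `times` and `values` (matrix, one row per time).
#' @export
integrate_reduced <- function(K, env = NULL, N0, t_grid, method = c("rk4", "lsoda")) {
  method <- match.arg(method)
  Kfun <- if (inherits(K, "env_matrix")) {
    if (is.null(env)) stop("env input required for an environment-dependent K")
    function(t) em_eval(K, env(t))
  } else {
    Kc <- as.matrix(K); function(t) Kc
  }
  if (method == "lsoda") {
    rhs <- function(t, y, parms) list(as.numeric(Kfun(t) %*% y))
    out <- deSolve::ode(y = N0, times = t_grid, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    return(list(times = out[, 1], values = unname(out[, -1, drop = FALSE])))
  }
  n <- length(t_grid)
  values <- matrix(NA_real_, n, length(N0))
  values[1, ] <- N0
  y <- N0
  for (i in seq_len(n - 1)) {
    t0 <- t_grid[i]; h <- t_grid[i + 1] - t0
    k1 <- Kfun(t0) %*% y
    k2 <- Kfun(t0 + h / 2) %*% (y + h / 2 * k1)
    k3 <- Kfun(t0 + h / 2) %*% (y + h / 2 * k2)
    k4 <- Kfun(t0 + h) %*% (y + h * k3)
    y <- y + h / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4)
    values[i + 1, ] <- y
  }
  list(times = t_grid, values = values)
}

#' Create a cohort population
#'
#' A finite list of point masses approximating the population measure.
#'
#' @param positions matrix (n x dim) or vector of i-state positions.
#' @param masses nonnegative masses.
#' @return a `cohort_population`.
#' @export
cohort_population <- function(positions, masses) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(masses), all(masses >= 0))
  structure(list(positions = positions, masses = as.numeric(masses)),
            class = "cohort_population")
}

#' Simulate the structured model by cohorts along characteristics
#'
#' Cohort positions follow `dx/dt = g(x, E(t))` (RK4); masses decay by the
#' exact exponential of the midpoint death rate; each birth term spawns one
#' pooled cohort per step at its birth state with mass
#' `sum_c m_c beta_i(x_c, E) dt` (midpoint rule).  Outputs are
#' `sum_c m_c psi(x_c)` for the requested weight functions.
#'
#' @param model a [pspm_model()].
#' @param env an [env_input()].
#' @param init a [cohort_population()].
#' @param dt time step.
#' @param t_end end time.
#' @param weights list of weight functions (symf/strings) to report; default
#'   the model outputs' x-parts at atom values 1.
#' @param prune relative mass threshold below which cohorts are merged into
#'   their nearest neighbour (mass conserving).
#' @return list with `times`, `outputs` (matrix), `cohorts` (final
#'   [cohort_population()]), `cohort_count` per step.
#' @export
simulate_cohorts <- function(model, env, init, dt, t_end, weights = NULL,
                             prune = 1e-14) {
  sp <- model$space
  vars <- sp$vars
  if (is.null(weights))
    weights <- lapply(model$outputs, function(o)
      sep_at_valuation(o, stats::setNames(as.list(rep(1, length(model$atoms))), model$atoms)))
  weights <- lapply(weights, as_symf)
  wfuns <- lapply(weights, sf_fun, vars = vars)
  gfun <- model_rate_fun(model$g, model$atoms, vars)        # list over dims
  mufun <- model_rate_fun(list(model$mu), model$atoms, vars)[[1]]
  bfuns <- lapply(model$births, function(b)
    model_rate_fun(list(b$rate_weight), model$atoms, vars)[[1]])
  nsteps <- as.integer(round(t_end / dt))
  times <- seq(0, by = dt, length.out = nsteps + 1)
  P <- init$positions; m <- init$masses
  outputs <- matrix(NA_real_, nsteps + 1, length(weights))
  counts <- integer(nsteps + 1)
  eval_outputs <- function(P, m) vapply(wfuns, function(f)
    sum(m * do.call(f, pos_args(P, vars))), numeric(1))
  outputs[1, ] <- eval_outputs(P, m)
  counts[1] <- nrow(P)
  for (s in seq_len(nsteps)) {
    t0 <- times[s]
    E0 <- env(t0); Eh <- env(t0 + dt / 2); E1 <- env(t0 + dt)
    # RK4 on positions
    g1 <- g_eval(gfun, P, E0, vars)
    g2 <- g_eval(gfun, P + dt / 2 * g1, Eh, vars)
    g3 <- g_eval(gfun, P + dt / 2 * g2, Eh, vars)
    g4 <- g_eval(gfun, P + dt * g3, E1, vars)
    Pmid <- P + dt / 2 * g1
    Pnew <- P + dt / 6 * (g1 + 2 * g2 + 2 * g3 + g4)
    # clip minor overshoot of the i-state space
    for (d in seq_len(sp$dim)) {
      over <- pmax(Pnew[, d] - sp$upper[d], sp$lower[d] - Pnew[, d])
      if (any(over > 1e-9))
        stop(pspm_condition("pspm_blowup_error",
                            "cohort left the i-state space; growth law inconsistent with bounds"))
      Pnew[, d] <- pmin(pmax(Pnew[, d], sp$lower[d]), sp$upper[d])
    }
    # exact exponential of midpoint death rate
    mu_mid <- rate_eval(mufun, Pmid, Eh, vars)
    mnew <- m * exp(-mu_mid * dt)
    # births: one pooled cohort per birth term (midpoint rule).  The midpoint
    # flux must include reproduction by individuals born earlier in the same
    # step (mass ~ rate * dt/2 sitting at the birth states), otherwise the
    # flux carries an O(dt) bias; the small linear solve below restores the
    # second-order balance.  Newborn cohorts are then advanced by their
    # expected half step of growth and survival.
    nb <- length(model$births)
    if (nb > 0) {
      base <- vapply(seq_len(nb), function(bi)
        sum(m * exp(-mu_mid * dt / 2) * rate_eval(bfuns[[bi]], Pmid, Eh, vars)),
        numeric(1))
      bstates <- do.call(rbind, lapply(model$births, function(b) b$birth_state))
      B <- matrix(0, nb, nb)
      for (bi in seq_len(nb))
        B[bi, ] <- rate_eval(bfuns[[bi]], bstates, Eh, vars)
      rate <- solve(diag(nb) - (dt / 2) * B, base)
      for (bi in seq_len(nb)) {
        bm <- rate[bi] * dt
        if (bm > 0) {
          bs <- bstates[bi, , drop = FALSE]
          gb <- g_eval(gfun, bs, Eh, vars)
          mub <- rate_eval(mufun, bs, Eh, vars)
          bpos <- pmin(pmax(bs[1, ] + dt / 2 * gb[1, ], sp$lower), sp$upper)
          Pnew <- rbind(Pnew, bpos)
          mnew <- c(mnew, bm * exp(-mub * dt / 2))
        }
      }
    }
    # prune: merge negligible cohorts into nearest neighbour
    tot <- sum(mnew)
    tiny <- which(mnew < prune * tot)
    if (length(tiny) && length(mnew) > length(tiny)) {
      keep <- setdiff(seq_along(mnew), tiny)
      for (i in tiny) {
        dists <- rowSums((Pnew[keep, , drop = FALSE] -
                            matrix(Pnew[i, ], length(keep), sp$dim, byrow = TRUE))^2)
        j <- keep[which.min(dists)]
        mnew[j] <- mnew[j] + mnew[i]
      }
      Pnew <- Pnew[keep, , drop = FALSE]; mnew <- mnew[keep]
    }
    P <- Pnew; m <- mnew
    outputs[s + 1, ] <- eval_outputs(P, m)
    counts[s + 1] <- nrow(P)
  }
  list(times = times, outputs = outputs,
       cohorts = cohort_population(P, m), cohort_count = counts)
}

pos_args <- function(P, vars) stats::setNames(lapply(seq_along(vars), function(d) P[, d]), vars)

# compile separated rates into functions of (i-state vectors, atom values)
model_rate_fun <- function(seps, atoms, vars) {
  lapply(seps, function(se) {
    comps <- lapply(se$components, function(cp)
      list(mono = cp$mono, f = sf_fun(cp$x, vars)))
    function(P, E) {
      out <- 0
      args <- pos_args(P, vars)
      for (cp in comps) out <- out + mono_eval(cp$mono, E) * do.call(cp$f, args)
      out + numeric(nrow(P))
    }
  })
}

g_eval <- function(gfun, P, E, vars) {
  matrix(vapply(gfun, function(f) f(P, E), numeric(nrow(P))),
         nrow(P), length(gfun))
}

rate_eval <- function(f, P, E, vars) f(P, E)

#' Simulate the closed-loop Daphnia--resource community
#'
#' Integrates both representations of the community with resource feedback
#' `dE/dt = h(E) - f(E) N2`: the 5-dimensional reduced system
#' (N0..N3 and E) by RK4, and the structured counterpart (cohorts plus the
#' resource ODE fed back each step with frozen-coefficient RK4 stages).
#'
#' @param params list with `delta`, `eps`, `alpha`, `mu`, `x_b`, `x_max`, and
#'   functions `f_E(E)` (functional response) and `h_E(E)` (resource supply).
#' @param init list with `cohorts` (a [cohort_population()]) and `E0`.
#' @param dt step size; `t_end` end time.
#' @return list with `reduced` (times, values N0..N3 and E) and `structured`
#'   (times, outputs N0..N3, E trace, final cohorts).
#' @export
run_daphnia_community <- function(params, init, dt, t_end) {
  p <- params
  model <- daphnia_model(p)
  fe <- p$f_E; he <- p$h_E
  # reduced closed loop: y = (N0..N3, E)
  Krow <- function(E) {
    f <- fe(E)
    rbind(c(-p$mu, 0, p$alpha * f, 0),
          c(p$delta * f, -(p$mu + p$eps), p$x_b * p$alpha * f, 0),
          c(0, 2 * p$delta * f, p$x_b^2 * p$alpha * f - (p$mu + 2 * p$eps), 0),
          c(0, 0, p$x_b^3 * p$alpha * f + 3 * p$delta * f, -(p$mu + 3 * p$eps)))
  }
  rhs <- function(y) {
    N <- y[1:4]; E <- y[5]
    c(as.numeric(Krow(E) %*% N), he(E) - fe(E) * N[3])
  }
  nsteps <- as.integer(round(t_end / dt))
  times <- seq(0, by = dt, length.out = nsteps + 1)
  w <- lapply(0:3, function(i) sf_pow_int(sf_sym("x"), i))
  wfuns <- lapply(w, sf_fun, vars = "x")
  N0v <- vapply(wfuns, function(f) sum(init$cohorts$masses * f(init$cohorts$positions[, 1])),
                numeric(1))
  yr <- c(N0v, init$E0)
  red <- matrix(NA_real_, nsteps + 1, 5); red[1, ] <- yr
  for (s in seq_len(nsteps)) {
    k1 <- rhs(yr); k2 <- rhs(yr + dt / 2 * k1)
    k3 <- rhs(yr + dt / 2 * k2); k4 <- rhs(yr + dt * k3)
    yr <- yr + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    red[s + 1, ] <- yr
  }
  # structured closed loop
  P <- init$cohorts$positions; m <- init$cohorts$masses; E <- init$E0
  strN <- matrix(NA_real_, nsteps + 1, 4)
  strE <- numeric(nsteps + 1)
  outs <- function(P, m) vapply(wfuns, function(f) sum(m * f(P[, 1])), numeric(1))
  strN[1, ] <- outs(P, m); strE[1] <- E
  for (s in seq_len(nsteps)) {
    N2 <- sum(m * P[, 1]^2)
    # resource advanced by RK4 with N2 frozen over the step
    re <- function(E) he(E) - fe(E) * N2
    e1 <- re(E); e2 <- re(E + dt / 2 * e1); e3 <- re(E + dt / 2 * e2); e4 <- re(E + dt * e3)
    Emid <- E + dt / 2 * e1
    Enew <- E + dt / 6 * (e1 + 2 * e2 + 2 * e3 + e4)
    g <- function(x, E) p$delta * fe(E) - p$eps * x
    x1 <- g(P[, 1], E); x2 <- g(P[, 1] + dt / 2 * x1, Emid)
    x3 <- g(P[, 1] + dt / 2 * x2, Emid); x4 <- g(P[, 1] + dt * x3, Enew)
    Pmid <- P[, 1] + dt / 2 * x1
    Pnew <- P[, 1] + dt / 6 * (x1 + 2 * x2 + 2 * x3 + x4)
    mnew <- m * exp(-p$mu * dt)
    base <- sum(m * exp(-p$mu * dt / 2) * p$alpha * fe(Emid) * Pmid^2)
    birth <- dt * base / (1 - dt / 2 * p$alpha * fe(Emid) * p$x_b^2)
    bpos <- p$x_b + dt / 2 * g(p$x_b, Emid)
    P <- cbind(c(Pnew, bpos)); m <- c(mnew, birth * exp(-p$mu * dt / 2))
    E <- Enew
    strN[s + 1, ] <- outs(P, m); strE[s + 1] <- E
  }
  list(reduced = list(times = times, values = red),
       structured = list(times = times, outputs = strN, E = strE,
                         cohorts = cohort_population(P, m)))
}

# the standard Daphnia fixture model from a parameter list
daphnia_model <- function(p) {
  sp <- istate_space(1, lower = p$x_b, upper = p$x_max)
  pspm_model(sp, list(env_atom("f", "functional response")),
             g = sprintf("%.17g*f - %.17g*x", p$delta, p$eps),
             mu = sprintf("%.17g", p$mu),
             births = list(birth_term(sprintf("%.17g*f*x^2", p$alpha), p$x_b, atoms = "f")),
             outputs = list("x^3", "x^2"),
             name = "daphnia")
}

#' Compare two trajectories
#'
#' @param a,b lists with `times` and a values matrix (`values` or `outputs`);
#'   `b` is linearly interpolated onto `a`'s grid when the grids differ.
#' @param columns optional column indices to compare.
#' @return list with per-column `sup_rel` and `l2_rel` errors and `max_gap`
#'   (the largest interpolation gap, 0 for identical grids).
#' @export
compare_trajectories <- function(a, b, columns = NULL) {
  va <- traj_values(a); vb <- traj_values(b)
  ta <- a$times; tb <- b$times
  if (is.null(columns)) columns <- seq_len(min(ncol(va), ncol(vb)))
  max_gap <- 0
  if (length(ta) != length(tb) || max(abs(ta - tb)) > 1e-12) {
    vb <- vapply(seq_len(ncol(vb)), function(j)
      stats::approx(tb, vb[, j], xout = ta, rule = 2)$y, numeric(length(ta)))
    max_gap <- max(diff(sort(tb)))
  }
  sup_rel <- numeric(length(columns)); l2_rel <- numeric(length(columns))
  for (ii in seq_along(columns)) {
    j <- columns[ii]
    scale <- max(abs(va[, j]), 1e-12)
    d <- va[, j] - vb[, j]
    sup_rel[ii] <- max(abs(d)) / scale
    l2_rel[ii] <- sqrt(mean(d^2)) / sqrt(mean(va[, j]^2) + 1e-24)
  }
  list(sup_rel = sup_rel, l2_rel = l2_rel, max_gap = max_gap)
}

traj_values <- function(x) {
  v <- if (!is.null(x$values)) x$values else x$outputs
  as.matrix(v)
}

#' Empirical convergence order from a dt-halving ladder
#'
#' @param errors sup-norm errors at successively halved steps (>= 3 rungs).
#' @return the least-squares slope of log2(error) against rung index
#'   (positive = order of convergence).
#' @export
convergence_order <- function(errors) {
  stopifnot(length(errors) >= 3)
  l <- log2(errors)
  x <- seq_along(l)
  -unname(stats::coef(stats::lm(l ~ x))[2])
}
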