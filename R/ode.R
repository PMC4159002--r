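#' Mass-action model of units of replication with helpers (and parasites)
#'
#' Reaction scheme: units of replication X form complexes with other units,
#' with helpers H, and with parasites P; helpers and parasites can also pair.
#' A complex containing a catalyst (X or H) and a replicable template (X or
#' P) fires at rate `kappa * theta(N)`, releasing its members plus a copy of
#' the template. Copies of X are faithful with probability `1 - mu`;
#' mutants become helpers, parasites or junk with fractions `lambda_H`,
#' `lambda_P`, `lambda_J = 1 - lambda_H - lambda_P`. Parasite copies do not
#' mutate (strong parasites). Every species and complex decays at rate `d`.
#' `theta(N) = max(0, 1 - N / Theta)` is a phenomenological competition
#' term (N is the total concentration of species and complexes), which
#' bounds the dynamics and makes extinction an equilibrium.
#'
#' Two closure details are derived from the lattice model's orientation
#' rule. An X-H pair binds in either orientation but only the one with the
#' helper presenting its 5' end replicates (a helper cannot be replicated),
#' so only a fraction `productive_xh` (default 1/2) of X-H complex firings
#' are productive. A parasite has no 5' end, so X-P and H-P complexes always
#' replicate the parasite. The dissociation rates are free closure
#' parameters: replicating unit/helper complexes default to `1 - a`
#' (mirroring the lattice rule `k2 = 1 - k1`); parasite-containing
#' complexes default to dissociating at rate 1, without which the
#' parasite's per-capita replication exactly matches the unit's while
#' escaping the mutation load and no coexistence equilibrium exists at any
#' mutation rate under this resource closure.
#'
#' @param a_xx,a_xh,a_xp,a_hp Complex-formation rates.
#' @param b_xx,b_xh,b_xp,b_hp Dissociation rates (defaults above).
#' @param kappa Replication rate.
#' @param Theta Resource scale.
#' @param d Decay rate.
#' @param mu Mutation probability per replication.
#' @param lambda_H,lambda_P Mutant fractions (must satisfy
#'   `lambda_H + lambda_P <= 1`).
#' @param productive_xh Productive fraction of X-H complex firings.
#' @param parasites Include the parasite equations? With `FALSE` the
#'   parasite branch of the mutation flux is lost and P stays at zero.
#' @return An object of class `ode_params` (scheme `"helpers"`).
#' @export
ode_params_helpers <- function(a_xx = 0.7, a_xh = 0.7, a_xp = 0.7,
                               a_hp = 0.7, b_xx = 1 - a_xx, b_xh = 1 - a_xh,
                               b_xp = 1, b_hp = 1, kappa = 1,
                               Theta = 1, d = 0.03, mu = 0.1,
                               lambda_H = 0.5, lambda_P = 0.03,
                               productive_xh = 0.5,
                               parasites = TRUE) {
  if (lambda_H + lambda_P > 1 + 1e-12)
    stop("lambda_H + lambda_P must be <= 1")
  rates <- c(a_xx, a_xh, a_xp, a_hp, b_xx, b_xh, b_xp, b_hp, kappa, Theta, d)
  if (any(rates < 0)) stop("rates must be nonnegative")
  structure(list(scheme = "helpers", a_xx = a_xx, a_xh = a_xh, a_xp = a_xp,
                 a_hp = a_hp, b_xx = b_xx, b_xh = b_xh, b_xp = b_xp,
                 b_hp = b_hp, kappa = kappa, Theta = Theta, d = d, mu = mu,
                 lambda_H = lambda_H, lambda_P = lambda_P,
                 lambda_J = 1 - lambda_H - lambda_P,
                 productive_xh = productive_xh,
                 parasites = isTRUE(parasites)),
            class = "ode_params")
}

#' Mass-action model of units of replication with stallers
#'
#' Reaction scheme: units of replication X replicate in pairs (complex Cxx)
#' and replicate parasites P (complex Cpx); mutant copies of X become
#' stallers S, parasites or junk J with fractions `lambda_S`, `lambda_P`,
#' `lambda_J`; mutant copies of P become stallers or junk with fractions
#' `lambda_pS`, `lambda_pJ`. Stallers bind both X and P into dead-end
#' complexes (Cxs, Cps) in which no replication happens. Every species and
#' complex decays at rate `d`; replication is throttled by
#' `theta(N) = max(0, 1 - N / Theta)`.
#'
#' @param a_xx,a_px,a_xs,a_ps Complex-formation rates.
#' @param b_xx,b_px,b_xs,b_ps Dissociation rates (default `1 - a`).
#' @param kappa,Theta,d,mu As in [ode_params_helpers()].
#' @param lambda_S,lambda_P Mutant fractions of X copies
#'   (`lambda_J = 1 - lambda_S - lambda_P`).
#' @param lambda_pS Staller fraction of parasite mutants; defaults to the
#'   unit-of-replication fractions renormalized over stallers and junk.
#' @return An object of class `ode_params` (scheme `"stallers"`).
#' @export
ode_params_stallers <- function(a_xx = 0.9, a_px = 0.8, a_xs = 0.75,
                                a_ps = 0.75, b_xx = 1 - a_xx,
                                b_px = 1 - a_px, b_xs = 1 - a_xs,
                                b_ps = 1 - a_ps, kappa = 1, Theta = 1,
                                d = 0.03, mu = 0.4, lambda_S = 0.3,
                                lambda_P = 0, lambda_pS = NULL) {
  if (lambda_S + lambda_P > 1 + 1e-12)
    stop("lambda_S + lambda_P must be <= 1")
  lambda_J <- 1 - lambda_S - lambda_P
  if (is.null(lambda_pS)) {
    lambda_pS <- if (lambda_S + lambda_J > 0)
      lambda_S / (lambda_S + lambda_J) else 0
  }
  structure(list(scheme = "stallers", a_xx = a_xx, a_px = a_px,
                 a_xs = a_xs, a_ps = a_ps, b_xx = b_xx, b_px = b_px,
                 b_xs = b_xs, b_ps = b_ps, kappa = kappa, Theta = Theta,
                 d = d, mu = mu, lambda_S = lambda_S, lambda_P = lambda_P,
                 lambda_J = lambda_J, lambda_pS = lambda_pS,
                 lambda_pJ = 1 - lambda_pS),
            class = "ode_params")
}

rhs_helpers <- function(y, p) {
  X <- y[1]; H <- y[2]; P <- y[3]; J <- y[4]
  Cxx <- y[5]; Cxh <- y[6]; Cxp <- y[7]; Chp <- y[8]
  para <- if (p$parasites) 1 else 0
  th <- max(0, 1 - sum(y) / p$Theta)
  f <- p$kappa * th
  vxx <- p$a_xx * X * X;      wxx <- p$b_xx * Cxx;  rxx <- f * Cxx
  # only the helper-presents-5' orientation of an X-H complex replicates
  vxh <- p$a_xh * X * H;      wxh <- p$b_xh * Cxh
  rxh <- p$productive_xh * f * Cxh
  vxp <- para * p$a_xp * X * P; wxp <- p$b_xp * Cxp; rxp <- f * Cxp
  vhp <- para * p$a_hp * H * P; whp <- p$b_hp * Chp; rhp <- f * Chp
  mut <- p$mu * (rxx + rxh)
  c(X = -2 * vxx + 2 * wxx - vxh + wxh - vxp + wxp +
        rxx * (2 + 1 - p$mu) + rxh * (1 + 1 - p$mu) + rxp - p$d * X,
    H = -vxh + wxh - vhp + whp + rxh + rhp + mut * p$lambda_H - p$d * H,
    P = para * (-vxp + wxp - vhp + whp + 2 * rxp + 2 * rhp +
                mut * p$lambda_P - p$d * P),
    J = mut * p$lambda_J - p$d * J,
    Cxx = vxx - wxx - rxx - p$d * Cxx,
    Cxh = vxh - wxh - rxh - p$d * Cxh,
    Cxp = vxp - wxp - rxp - p$d * Cxp,
    Chp = vhp - whp - rhp - p$d * Chp)
}

rhs_stallers <- function(y, p) {
  X <- y[1]; S <- y[2]; P <- y[3]; J <- y[4]
  Cxx <- y[5]; Cpx <- y[6]; Cxs <- y[7]; Cps <- y[8]
  th <- max(0, 1 - sum(y) / p$Theta)
  f <- p$kappa * th
  vxx <- p$a_xx * X * X; wxx <- p$b_xx * Cxx; rxx <- f * Cxx
  vpx <- p$a_px * P * X; wpx <- p$b_px * Cpx; rpx <- f * Cpx
  vxs <- p$a_xs * X * S; wxs <- p$b_xs * Cxs
  vps <- p$a_ps * P * S; wps <- p$b_ps * Cps
  c(X = -2 * vxx + 2 * wxx - vpx + wpx - vxs + wxs +
        rxx * (2 + 1 - p$mu) + rpx - p$d * X,
    S = -vxs + wxs - vps + wps + p$mu * (rxx * p$lambda_S +
        rpx * p$lambda_pS) - p$d * S,
    P = -vpx + wpx - vps + wps + rpx * (1 + 1 - p$mu) +
        p$mu * rxx * p$lambda_P - p$d * P,
    J = p$mu * (rxx * p$lambda_J + rpx * p$lambda_pJ) - p$d * J,
    Cxx = vxx - wxx - rxx - p$d * Cxx,
    Cpx = vpx - wpx - rpx - p$d * Cpx,
    Cxs = vxs - wxs - p$d * Cxs,
    Cps = vps - wps - p$d * Cps)
}

#' Build an ODE model from a parameter set
#'
#' @param params An [ode_params_helpers()] or [ode_params_stallers()]
#'   object.
#' @return An object of class `ode_model` with fields `params`, `state`
#'   (state-variable names) and `rhs(t, y, ...)` (in the form `deSolve`
#'   expects; it rejects negative states).
#' @export
ode_model <- function(params) {
  stopifnot(inherits(params, "ode_params"))
  state <- if (params$scheme == "helpers")
    c("X", "H", "P", "J", "Cxx", "Cxh", "Cxp", "Chp")
  else
    c("X", "S", "P", "J", "Cxx", "Cpx", "Cxs", "Cps")
  core <- if (params$scheme == "helpers") rhs_helpers else rhs_stallers
  rhs <- function(t, y, parms = NULL, ...) {
    if (any(y < -1e-6)) stop("state must be nonnegative")
    y <- pmax(y, 0)
    list(unname(core(y, params)))
  }
  structure(list(params = params, state = state, rhs = rhs,
                 core = core), class = "ode_model")
}

#' Evaluate the right-hand side of a model
#'
#' @param model An [ode_model()].
#' @param y Nonnegative state vector (length 8).
#' @return Named derivative vector.
#' @export
ode_rhs <- function(model, y) {
  if (any(y < 0)) stop("state must be nonnegative")
  setNames(as.numeric(model$core(unname(y), model$params)), model$state)
}

#' Integrate an ODE model
#'
#' Stiff-capable integration (`deSolve::ode`, lsoda) that respects the
#' nonnegative orthant (small negative excursions are clamped).
#'
#' @param model An [ode_model()].
#' @param y0 Nonnegative initial state (named or in `model$state` order).
#' @param times Output times.
#' @param atol,rtol Integration tolerances.
#' @return A data frame: `time` plus one column per state variable.
#' @export
integrate_model <- function(model, y0, times = seq(0, 1000, by = 1),
                            atol = 1e-10, rtol = 1e-8) {
  if (any(y0 < 0)) stop("initial state must be nonnegative")
  y0 <- setNames(rep_len(unname(y0), length(model$state)), model$state)
  out <- deSolve::ode(y = y0, times = times, func = model$rhs, parms = NULL,
                      atol = atol, rtol = rtol)
  df <- as.data.frame(out)
  df[, -1] <- pmax(as.matrix(df[, -1]), 0)
  names(df)[1] <- "time"
  df
}

jacobian_fd <- function(f, y, eps = 1e-7) {
  n <- length(y)
  f0 <- f(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- max(0, ym[j] - h)
    J[, j] <- (f(yp) - f(ym)) / (yp[j] - ym[j])
  }
  J
}

#' Find an equilibrium by Newton iteration
#'
#' @param model An [ode_model()].
#' @param guess Starting state (e.g. the endpoint of a long integration).
#' @param tol Convergence tolerance on the residual.
#' @param max_iter Newton iteration cap.
#' @return A list: `y` (equilibrium), `eigenvalues` (of the
#'   finite-difference Jacobian), `stable`, `converged`, `residual`.
#' @export
find_equilibrium <- function(model, guess, tol = 1e-10, max_iter = 50) {
  f <- function(y) as.numeric(model$core(pmax(y, 0), model$params))
  y <- pmax(unname(guess), 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- f(y)
    if (max(abs(r)) < tol) { converged <- TRUE; break }
    J <- jacobian_fd(f, y)
    dy <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dy)) break
    step <- 1
    repeat {
      y2 <- y + step * dy
      if (max(abs(f(pmax(y2, 0)))) < max(abs(r)) || step < 1e-4) break
      step <- step / 2
    }
    y <- y2
  }
  ev <- eigen(jacobian_fd(f, pmax(y, 0)), only.values = TRUE)$values
  list(y = setNames(pmax(y, 0), model$state), eigenvalues = ev,
       stable = all(Re(ev) < 1e-8), converged = converged,
       residual = max(abs(f(pmax(y, 0)))))
}

set_param <- function(params, name, value) {
  params[[name]] <- value
  # keep derived simplex fractions consistent
  if (params$scheme == "helpers" && name %in% c("lambda_H", "lambda_P"))
    params$lambda_J <- 1 - params$lambda_H - params$lambda_P
  if (params$scheme == "stallers" && name %in% c("lambda_S", "lambda_P")) {
    params$lambda_J <- 1 - params$lambda_S - params$lambda_P
    params$lambda_pS <- if (params$lambda_S + params$lambda_J > 0)
      params$lambda_S / (params$lambda_S + params$lambda_J) else 0
    params$lambda_pJ <- 1 - params$lambda_pS
  }
  params
}

#' Continue an equilibrium branch in one parameter
#'
#' Pseudo-arclength continuation of Newton equilibria: a secant predictor
#' along the branch and a Newton corrector on the system augmented with the
#' arclength constraint. The branch follows folds (turning points). At each
#' accepted point the Jacobian eigenvalues and the stability flag are
#' recorded.
#'
#' @param params An `ode_params` object (the starting parameter set; its
#'   `free_param` entry is overridden along the branch).
#' @param free_param Name of the continued parameter (e.g. `"mu"`,
#'   `"lambda_S"`).
#' @param range Length-2 numeric: parameter interval to cover.
#' @param step Initial arclength step (in the parameter's scale).
#' @param y0 Starting state; by default a long integration from a seeded
#'   state at `range[1]` is used.
#' @param max_points Branch length cap.
#' @return An object of class `equilibrium_branch`: a data frame with the
#'   parameter, the state, the leading eigenvalue (`lead_re`, `lead_im`),
#'   `stable`, and the parameter component of the branch tangent
#'   (`tangent_p`). Attribute `diagnostic` reports early termination.
#' @export
continue_equilibria <- function(params, free_param, range, step = 0.01,
                                y0 = NULL, max_points = 1500) {
  p0 <- range[1]
  params <- set_param(params, free_param, p0)
  model <- ode_model(params)
  if (is.null(y0)) {
    # probe several seeded states and keep the first that relaxes onto an
    # equilibrium (a nontrivial one is tried before extinction)
    seeds <- list(rep(0.05, 8), c(0.3, 0.01, 0, 0.01, rep(0, 4)),
                  c(0.2, rep(0, 7)), rep(0, 8))
    eq <- NULL
    for (seed in seeds) {
      tr <- integrate_model(model, seed, times = c(0, 500, 2000, 8000))
      cand <- find_equilibrium(model, as.numeric(tr[nrow(tr), -1]))
      if (cand$converged) { eq <- cand; break }
    }
  } else {
    eq <- find_equilibrium(model, y0)
  }
  if (is.null(eq) || !eq$converged)
    stop("no starting equilibrium found at range[1]")
  fy <- function(y, p) {
    m <- ode_model(set_param(params, free_param, p))
    as.numeric(m$core(pmax(y, 0), m$params))
  }
  n <- length(eq$y)
  rows <- list()
  diagnostic <- "completed"
  push <- function(y, p, tp) {
    m <- ode_model(set_param(params, free_param, p))
    f <- function(z) as.numeric(m$core(pmax(z, 0), m$params))
    ev <- eigen(jacobian_fd(f, pmax(y, 0)), only.values = TRUE)$values
    lead <- ev[which.max(Re(ev))]
    rows[[length(rows) + 1L]] <<- c(p, pmax(y, 0), Re(lead), Im(lead),
                                    as.numeric(all(Re(ev) < 1e-8)), tp)
  }
  u <- c(eq$y, p0)
  push(u[1:n], u[n + 1], NA)
  # first predictor: natural continuation
  dir <- sign(range[2] - range[1])
  u_prev <- u
  p1 <- p0 + dir * step
  eq1 <- find_equilibrium(ode_model(set_param(params, free_param, p1)),
                          u[1:n])
  if (!eq1$converged) stop("continuation failed on the first step")
  u <- c(eq1$y, p1)
  push(u[1:n], u[n + 1], u[n + 1] - u_prev[n + 1])
  h <- step
  hmin <- step / 256
  lo <- min(range) - 1e-12; hi <- max(range) + 1e-12
  while (length(rows) < max_points) {
    tvec <- u - u_prev
    nrm <- sqrt(sum(tvec^2))
    if (nrm < 1e-14) { diagnostic <- "stalled"; break }
    tvec <- tvec / nrm
    ok <- FALSE
    while (h >= hmin) {
      pred <- u + h * tvec
      z <- pred
      good <- FALSE
      for (it in 1:30) {
        r <- c(fy(z[1:n], z[n + 1]), sum(tvec * (z - pred)))
        if (max(abs(r)) < 1e-10) { good <- TRUE; break }
        Jy <- jacobian_fd(function(y) fy(y, z[n + 1]), z[1:n])
        hp <- 1e-7 * max(1, abs(z[n + 1]))
        Jp <- (fy(z[1:n], z[n + 1] + hp) - fy(z[1:n], z[n + 1] - hp)) / (2 * hp)
        Jaug <- rbind(cbind(Jy, Jp), tvec)
        dz <- tryCatch(solve(Jaug, -r), error = function(e) NULL)
        if (is.null(dz)) break
        z <- z + dz
      }
      if (good) { ok <- TRUE; break }
      h <- h / 2
    }
    if (!ok) { diagnostic <- "Newton corrector diverged; branch truncated"; break }
    u_prev <- u
    u <- z
    push(u[1:n], u[n + 1], u[n + 1] - u_prev[n + 1])
    if (u[n + 1] < lo || u[n + 1] > hi) break
    if (any(u[1:n] < -0.05)) { diagnostic <- "branch left the nonnegative orthant"; break }
    h <- min(h * 1.4, step)
  }
  mat <- do.call(rbind, rows)
  df <- as.data.frame(mat)
  names(df) <- c("param", model$state, "lead_re", "lead_im", "stable",
                 "tangent_p")
  df$stable <- df$stable > 0.5
  attr(df, "free_param") <- free_param
  attr(df, "params") <- params
  attr(df, "diagnostic") <- diagnostic
  class(df) <- c("equilibrium_branch", "data.frame")
  df
}

#' Detect bifurcations along an equilibrium branch
#'
#' Scans consecutive branch points for: folds (the parameter component of
#' the branch tangent changes sign at a turning point), Hopf points (the
#' real part of a complex leading eigenvalue pair crosses zero), and
#' transcritical points (the branch meets the extinction state). Homoclinic
#' bifurcations are not equilibrium phenomena and can only be flagged by
#' limit-cycle period blow-up; see [estimate_homoclinic()].
#'
#' @param branch An [continue_equilibria()] result.
#' @param imag_tol Minimum `|Im|` for a crossing to count as Hopf.
#' @param ext_tol State norm below which a point counts as extinct.
#' @return A data frame with columns `type`, `param`, `X`.
#' @export
detect_bifurcations <- function(branch, imag_tol = 1e-6, ext_tol = 1e-4) {
  out <- list()
  tp <- branch$tangent_p
  re <- branch$lead_re
  im <- branch$lead_im
  p <- branch$param
  X <- branch$X
  n <- nrow(branch)
  add <- function(type, i) {
    out[[length(out) + 1L]] <<- data.frame(type = type,
                                           param = mean(p[c(i, i + 1)]),
                                           X = mean(X[c(i, i + 1)]))
  }
  for (i in seq_len(n - 1)) {
    if (i > 1 && !is.na(tp[i]) && !is.na(tp[i + 1]) &&
        sign(tp[i]) != 0 && sign(tp[i + 1]) != 0 &&
        sign(tp[i]) != sign(tp[i + 1]))
      add("fold", i)
    if (re[i] * re[i + 1] < 0) {
      if (abs(im[i]) > imag_tol && abs(im[i + 1]) > imag_tol)
        add("hopf", i)
    }
  }
  # transcritical: the branch meets the extinction state
  norms <- rowSums(abs(as.matrix(branch[, 2:9])))
  for (i in seq_len(n - 1)) {
    if ((norms[i] <= ext_tol) != (norms[i + 1] <= ext_tol))
      add("transcritical", i)
  }
  if (!length(out))
    return(data.frame(type = character(0), param = numeric(0),
                      X = numeric(0)))
  do.call(rbind, out)
}

#' Estimate a homoclinic bifurcation by period blow-up
#'
#' Beyond a Hopf point the limit cycle's period grows without bound as a
#' homoclinic connection is approached. This helper integrates the model
#' over a grid of parameter values, measures the oscillation period of X
#' (peak to peak), and reports the first parameter value at which the period
#' exceeds `period_cap` (or the cycle collapses), flagged as an estimate.
#'
#' @param params An `ode_params` object.
#' @param free_param Parameter name.
#' @param values Grid of parameter values to probe (ordered away from the
#'   Hopf point).
#' @param y0 Initial state.
#' @param t_max Integration horizon.
#' @param period_cap Period threshold for the blow-up call.
#' @return A list: `estimate` (parameter value or NA), `periods` (data
#'   frame of measured periods).
#' @export
estimate_homoclinic <- function(params, free_param, values, y0 = rep(0.05, 8),
                                t_max = 3000, period_cap = 500) {
  periods <- data.frame(param = numeric(0), period = numeric(0),
                        extinct = logical(0))
  est <- NA_real_
  for (v in values) {
    model <- ode_model(set_param(params, free_param, v))
    tr <- integrate_model(model, y0, times = seq(0, t_max, by = 0.5))
    x <- tr$X
    tail_x <- x[tr$time > t_max / 2]
    tail_t <- tr$time[tr$time > t_max / 2]
    pk <- which(diff(sign(diff(tail_x))) == -2) + 1
    extinct <- max(tail_x) < 1e-6
    per <- if (length(pk) >= 2) mean(diff(tail_t[pk])) else Inf
    periods <- rbind(periods, data.frame(param = v, period = per,
                                         extinct = extinct))
    if ((is.infinite(per) || per > period_cap) && is.na(est)) est <- v
  }
  list(estimate = est, periods = periods)
}

#' Classify the long-run attractor of a model
#'
#' Integrates from a seeded state and inspects the tail of the trajectory:
#' `"extinct"` if X stays below `x_min`, `"steady"` if X has converged to a
#' fixed value, `"oscillating"` otherwise.
#'
#' @param params An `ode_params` object.
#' @param y0 Initial state; the default seeds X at 0.2 with a trace
#'   parasite inoculum (`1e-4`).
#' @param t_max Integration horizon.
#' @param x_min X level below which the system counts as extinct.
#' @param flat_tol Peak-to-peak X variation below which the tail counts as
#'   steady.
#' @return One of `"extinct"`, `"steady"`, `"oscillating"`.
#' @export
ode_attractor <- function(params, y0 = c(0.2, 0, 1e-4, 0, 0, 0, 0, 0),
                          t_max = 20000, x_min = 1e-4, flat_tol = 1e-5) {
  model <- ode_model(params)
  tr <- integrate_model(model, y0, times = seq(0, t_max, by = 10))
  tail_x <- tr$X[tr$time > t_max * 0.85]
  if (max(tail_x) < x_min) return("extinct")
  if (max(tail_x) - min(tail_x) < flat_tol) return("steady")
  "oscillating"
}

#' Destabilization and extinction mutation-rate thresholds
#'
#' Scans a grid of mutation rates and classifies the attractor at each with
#' [ode_attractor()]. The destabilization threshold is the largest `mu`
#' whose attractor is a steady viable equilibrium; the extinction threshold
#' is the largest `mu` at which the system is viable at all (steady or
#' oscillating). Used to compare how helper or staller production shifts
#' the persistence boundary.
#'
#' @param params An `ode_params` object.
#' @param mu_values Increasing grid of mutation rates.
#' @param ... Passed to [ode_attractor()].
#' @return Named numeric: `destabilization`, `extinction` (`-Inf` when no
#'   grid point qualifies).
#' @export
ode_viability_threshold <- function(params, mu_values, ...) {
  destab <- -Inf
  ext <- -Inf
  for (mu in mu_values) {
    s <- ode_attractor(set_param(params, "mu", mu), ...)
    if (s == "steady" && mu > destab) destab <- mu
    if (s != "extinct" && mu > ext) ext <- mu
  }
  c(destabilization = destab, extinction = ext)
}
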