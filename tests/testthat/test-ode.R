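test_that("parameter constructors enforce simplex and rate constraints", {
  expect_error(ode_params_helpers(lambda_H = 0.8, lambda_P = 0.3), "<= 1")
  expect_error(ode_params_helpers(d = -1), "nonnegative")
  expect_error(ode_params_stallers(lambda_S = 0.9, lambda_P = 0.2), "<= 1")
  p <- ode_params_stallers(lambda_S = 0.3, lambda_P = 0.1)
  expect_equal(p$lambda_J, 0.6)
  # parasite mutant fractions renormalize over stallers and junk
  expect_equal(p$lambda_pS, 0.3 / 0.9)
  expect_equal(p$lambda_pS + p$lambda_pJ, 1)
})

test_that("extinction is an equilibrium and it is stable at the published parameter sets", {
  for (params in list(ode_params_helpers(mu = 0.1, lambda_H = 0.5),
                      ode_params_helpers(mu = 0.1, lambda_H = 0.5,
                                         parasites = FALSE),
                      ode_params_stallers(mu = 0.4, lambda_S = 0.3),
                      ode_params_stallers(mu = 0.52, lambda_S = 0.7))) {
    model <- ode_model(params)
    expect_equal(unname(ode_rhs(model, rep(0, 8))), rep(0, 8))
    eq <- find_equilibrium(model, rep(0, 8))
    expect_true(eq$stable)
  }
})

test_that("with mu = 0 the mutant branches carry no flux", {
  model <- ode_model(ode_params_helpers(mu = 0, lambda_H = 0.9))
  tr <- integrate_model(model, c(0.3, 0, 0, 0, 0, 0, 0, 0),
                        times = seq(0, 400, by = 2))
  expect_true(all(tr$H == 0))
  expect_true(all(tr$J == 0))
  expect_gt(tr$X[nrow(tr)], 0)
  # mutant classes with no inflow decay from any start
  m2 <- ode_model(ode_params_stallers(mu = 0))
  tr2 <- integrate_model(m2, c(0.3, 0.2, 0, 0.2, 0, 0, 0, 0),
                         times = seq(0, 800, by = 2))
  expect_lt(tr2$J[nrow(tr2)], 1e-4)
  expect_lt(tr2$S[nrow(tr2)], 1e-3)
})

test_that("integration respects trivial closed forms and the nonnegative orthant", {
  # all-zero start stays identically zero
  model <- ode_model(ode_params_helpers())
  tr0 <- integrate_model(model, rep(0, 8), times = seq(0, 100, by = 1))
  expect_true(all(as.matrix(tr0[, -1]) == 0))
  # no complex formation: X decays exponentially at rate d
  m <- ode_model(ode_params_helpers(a_xx = 0, a_xh = 0, a_xp = 0, a_hp = 0,
                                    d = 0.03))
  tr <- integrate_model(m, c(1, 0, 0, 0, 0, 0, 0, 0),
                        times = seq(0, 100, by = 1))
  expect_equal(tr$X, exp(-0.03 * tr$time), tolerance = 1e-6)
  expect_true(all(as.matrix(tr[, -1]) >= 0))
  expect_error(integrate_model(m, c(-1, rep(0, 7))), "nonnegative")
})

test_that("the right-hand side never drags a zero coordinate negative", {
  set.seed(701)
  for (params in list(ode_params_helpers(mu = 0.2, lambda_H = 0.3),
                      ode_params_stallers(mu = 0.4, lambda_S = 0.3,
                                          lambda_P = 0.05))) {
    model <- ode_model(params)
    for (rep in 1:40) {
      y <- runif(8, 0, 0.4)
      zero <- sample.int(8, sample(1:4, 1))
      y[zero] <- 0
      dy <- ode_rhs(model, y)
      expect_true(all(dy[zero] >= -1e-12))
    }
  }
})

test_that("long integration endpoints agree with Newton equilibria", {
  params <- ode_params_stallers(mu = 0.4, lambda_S = 0.3)
  model <- ode_model(params)
  tr <- integrate_model(model, c(0.2, 0, 1e-4, 0, 0, 0, 0, 0),
                        times = seq(0, 15000, by = 25))
  yend <- as.numeric(tr[nrow(tr), -1])
  eq <- find_equilibrium(model, yend)
  expect_true(eq$converged)
  expect_true(eq$stable)
  expect_equal(unname(eq$y), yend, tolerance = 1e-3)
  expect_lt(eq$residual, 1e-9)
})

test_that("the extinction branch continues across the parameter range, always stable", {
  br <- continue_equilibria(ode_params_helpers(lambda_H = 0.5),
                            "mu", c(0.05, 0.3), step = 0.05,
                            y0 = rep(0, 8))
  expect_gte(nrow(br), 5)
  expect_true(all(br$stable))
  expect_true(all(abs(as.matrix(br[, 2:9])) < 1e-8))
  expect_equal(nrow(detect_bifurcations(br)), 0)
})

test_that("branch eigenvalues match an independent finite-difference Jacobian", {
  params <- ode_params_stallers(mu = 0.4, lambda_S = 0.3)
  br <- continue_equilibria(params, "lambda_S", c(0.3, 0.4), step = 0.05)
  i <- nrow(br)
  y <- as.numeric(br[i, 2:9])
  model <- ode_model(quasirep:::set_param(params, "lambda_S", br$param[i]))
  f <- function(z) unname(ode_rhs(model, pmax(z, 0)))
  # coarser, independently coded central differences
  J <- matrix(0, 8, 8)
  for (j in 1:8) {
    h <- 1e-5
    yp <- y; yp[j] <- yp[j] + h
    ym <- pmax(y, 0); ym[j] <- max(0, ym[j] - h)
    J[, j] <- (f(yp) - f(ym)) / (yp[j] - ym[j])
  }
  ev <- eigen(J, only.values = TRUE)$values
  lead <- ev[which.max(Re(ev))]
  expect_equal(Re(lead), br$lead_re[i], tolerance = 1e-3)
  expect_equal(abs(Im(lead)), abs(br$lead_im[i]), tolerance = 1e-3)
})

test_that("helper production shifts the viability boundary in opposite directions with and without parasites", {
  # with parasites: more helper production destabilizes at lower mu
  mus_p <- seq(0.23, 0.33, by = 0.02)
  destab_with <- vapply(c(0, 0.5, 0.95), function(lh) {
    ode_viability_threshold(ode_params_helpers(lambda_H = lh),
                            mus_p)[["destabilization"]]
  }, numeric(1))
  expect_true(all(diff(destab_with) <= 0))
  expect_lt(destab_with[3], destab_with[1])
  # without parasites: more helper production extends viability
  mus_np <- seq(0.50, 0.75, by = 0.05)
  destab_without <- vapply(c(0, 0.5, 0.95), function(lh) {
    ode_viability_threshold(ode_params_helpers(lambda_H = lh,
                                               parasites = FALSE),
                            mus_np,
                            y0 = c(0.2, rep(0, 7)))[["destabilization"]]
  }, numeric(1))
  expect_true(all(diff(destab_without) >= 0))
  expect_gt(destab_without[3], destab_without[1])
})

test_that("staller production separates parasite invasion, coexistence and overload regimes", {
  # low lambda_S: an inoculated parasite drives the system extinct
  expect_equal(ode_attractor(ode_params_stallers(mu = 0.4, lambda_S = 0.05)),
               "extinct")
  # intermediate lambda_S: viable despite the parasite inoculum
  expect_true(ode_attractor(ode_params_stallers(mu = 0.4, lambda_S = 0.3)) !=
                "extinct")
  # high lambda_S: parasites cannot invade (P dies out)
  model_hi <- ode_model(ode_params_stallers(mu = 0.4, lambda_S = 0.8))
  tr <- integrate_model(model_hi, c(0.2, 0, 1e-4, 0, 0, 0, 0, 0),
                        times = seq(0, 15000, by = 25))
  expect_lt(tr$P[nrow(tr)], 1e-6)
  expect_gt(tr$X[nrow(tr)], 0.1)
  # at high mutation rate, heavy staller production kills the system
  expect_true(ode_attractor(ode_params_stallers(mu = 0.52, lambda_S = 0.3),
                            y0 = c(0.2, rep(0, 7))) != "extinct")
  expect_equal(ode_attractor(ode_params_stallers(mu = 0.52, lambda_S = 0.8),
                             y0 = c(0.2, rep(0, 7))),
               "extinct")
})

test_that("a monotone stable branch yields no bifurcations and folds are flagged at turning points", {
  params <- ode_params_stallers(mu = 0.4, lambda_S = 0.6)
  start <- integrate_model(ode_model(params), c(0.2, rep(0, 7)),
                           times = c(0, 2000, 8000))
  br <- continue_equilibria(params, "lambda_S", c(0.6, 0.75), step = 0.05,
                            y0 = as.numeric(start[nrow(start), -1]))
  expect_true(all(br$stable))
  expect_equal(nrow(detect_bifurcations(br)), 0)
  # fabricate a fold signature and confirm detection logic
  fake <- br
  n <- nrow(fake)
  fake$tangent_p <- c(NA, rep(0.05, max(0, n - 3)), -0.05, -0.05)
  bif <- detect_bifurcations(fake)
  expect_true("fold" %in% bif$type)
})
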