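test_that("logistic equilibrium and closed-form growth limits hold", {
  # X(0) = X_max with no death is a fixed point
  p <- physio_params(mu_max = 0.04, X_max = 10, k_d = 0)
  sim <- simulate_culture(p, t_end = 50, dt = 0.1,
                          init = tibble::tibble(time = 0, Xv = 10, Xd = 0,
                                                GLC = 5, GLN = 5, LAC = 0, GLU = 0))
  expect_equal(max(abs(sim$X - 10)), 0)

  # all q = 0: concentrations constant, X tracks the analytic logistic with
  # first-order (Euler) error that shrinks with dt
  p2 <- physio_params(mu_max = 0.05, X_max = 12, k_d = 0)
  init <- culture_init(Xv0 = 0.5, Xd0 = 0)
  analytic <- function(t, X0, mu, Xm) Xm * X0 * exp(mu * t) / (Xm - X0 + X0 * exp(mu * t))
  errs <- vapply(c(0.1, 0.001), function(dt) {
    s <- simulate_culture(p2, t_end = 100, dt = dt, init = init)
    max(abs(s$X - analytic(s$time, 0.5, 0.05, 12)))
  }, numeric(1))
  expect_lt(errs[1], 0.05)           # coarse grid already close
  expect_lt(errs[2], errs[1] / 50)   # first-order convergence
  s <- simulate_culture(p2, t_end = 100, dt = 0.1, init = culture_init())
  expect_equal(s$GLC, rep(28, nrow(s)))
  expect_equal(s$GLN, rep(8, nrow(s)))
})

test_that("X = Xv + Xd at machine precision and the batch profile is sane", {
  sim <- simulate_culture(truth_physio(), t_end = 144, dt = 0.1)
  expect_lt(max(abs(sim$X - sim$Xv - sim$Xd)), 1e-12)
  expect_true(all(as.matrix(sim[, c("GLC", "GLN", "LAC", "GLU")]) >= 0))
  # lactate overflow then reconsumption; glucose monotone decreasing
  expect_true(all(diff(sim$GLC) <= 1e-12))
  i_peak <- which.max(sim$LAC)
  expect_gt(i_peak, 1L)
  expect_lt(i_peak, nrow(sim))
  expect_lt(sim$LAC[nrow(sim)], max(sim$LAC) * 0.9)
})

test_that("halving dt perturbs the trajectory at first order only", {
  p <- truth_physio()
  a <- simulate_culture(p, t_end = 96, dt = 0.2)
  b <- simulate_culture(p, t_end = 96, dt = 0.1)
  common <- intersect(a$time, b$time)
  dX <- max(abs(a$X[match(common, a$time)] - b$X[match(common, b$time)]))
  expect_lt(dX, 0.5 * 0.2) # |dX| <= C dt with modest C
})

test_that("instantaneous profiles report rates, yields, and rate maxima", {
  p0 <- physio_params(mu_max = 0.04, X_max = 10)
  prof0 <- instantaneous_profiles(p0, t_end = 48)
  mets <- dplyr::filter(prof0, variable != "Xv")
  expect_equal(max(abs(mets$rate)), 0)

  prof <- instantaneous_profiles(truth_physio(), t_end = 144)
  am <- attr(prof, "argmax")
  t_lac <- am$t_max_rate[am$variable == "LAC"]
  t_glc <- am$t_max_rate[am$variable == "GLC"]
  expect_lt(t_lac, t_glc) # overflow peaks before peak glucose consumption

  # algebraic check on the two-phase mixture: with saturated uptake confined
  # to the exponential fraction and no death, dM and dX are both
  # proportional to X * Psi_e, so the apparent yield is the constant q_e/mu
  pc <- physio_params(mu_max = 0.04, X_max = 10, k_d = 0,
                      q_g_e = -0.2, q_g_s = 0, K_g = 1e-9)
  profc <- instantaneous_profiles(pc, t_end = 48,
                                  init = culture_init(Xv0 = 0.25, Xd0 = 0))
  yc <- dplyr::filter(profc, variable == "GLC")$yield
  # constant up to the first-order Euler offset between the update stencils
  expect_lt(diff(range(yc)) / abs(mean(yc)), 0.05)
  expect_equal(mean(yc), -0.2 / 0.04, tolerance = 0.01)
})

test_that("error metrics implement the printed identities", {
  # identity case
  m0 <- error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0$sse, 0); expect_equal(m0$pe, 0)
  expect_equal(m0$mape, 0); expect_equal(m0$mppe, 0); expect_equal(m0$mppe_alt, 0)

  # small-denominator pathology of MAPE
  m1 <- error_metrics(0.1, 0.2)
  expect_equal(m1$mape, 100)

  # hand arithmetic
  m2 <- error_metrics(c(3, 4), c(0, 0))
  expect_equal(m2$sse, 25)
  expect_equal(m2$pe, sqrt(12.5))
  expect_equal(m2$mppe, 100 * sqrt(25 / (25 * 2)))
  expect_equal(m2$mppe_alt, 100 * sqrt(25 / 25))

  # zero observations are excluded from MAPE and counted
  m3 <- error_metrics(c(0, 1), c(0.5, 1))
  expect_equal(m3$mape_excluded, 1L)
  expect_equal(m3$mape, 0)

  # unit invariance: MAPE/MPPE unchanged, SSE scales by c^2, PE by c
  e <- c(1.2, 3.4, 0.7); m <- c(1.0, 3.9, 0.5)
  a <- error_metrics(e, m); b <- error_metrics(10 * e, 10 * m)
  expect_equal(b$mape, a$mape); expect_equal(b$mppe, a$mppe)
  expect_equal(b$sse, 100 * a$sse); expect_equal(b$pe, 10 * a$pe)

  expect_error(error_metrics(numeric(0), numeric(0)), "no data")
  expect_error(error_metrics(c(1, NA), c(1, 1)), "non-finite")
})

test_that("fit recovers parameters from its own noiseless output", {
  p <- truth_physio()
  obs <- synth_culture(p, sigma = 0)
  fit <- suppressWarnings(fit_physio(obs, offset_guess(p)))
  est <- tidy(fit)
  truth <- unlist(p[est$term])
  expect_lt(max(abs(est$estimate - truth) / abs(truth)), 0.01)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("constant-biomass data with k_d = 0 truth fits k_d to zero", {
  p <- physio_params(mu_max = 0.03, X_max = 15, k_d = 0,
                     q_g_e = -0.3, q_l_e = 0.4, K_g = 1)
  obs <- synth_culture(p, sigma = 0, init = culture_init(Xv0 = 0.25, Xd0 = 0.001))
  # dead biomass stays at its initial value
  fit <- suppressWarnings(fit_physio(obs, offset_guess(p)))
  expect_lt(fit$params$k_d, 1e-4)
})

test_that("fit input contracts are enforced", {
  p <- truth_physio()
  obs <- synth_culture(p, sigma = 0)
  expect_error(fit_physio(obs[1:3, ], p), "at least 4")
  obs$GLC[2] <- NA
  expect_error(fit_physio(obs, p), "non-finite")
})
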