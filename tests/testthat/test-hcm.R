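test_that("mode kinetics saturate as Michaelis-Menten", {
  expect_equal(em_rate(0, k = 2, K = 1), 0)
  expect_equal(em_rate(1e9, k = 2, K = 1, e = 1, v = 1), 2, tolerance = 1e-8)
  expect_equal(em_rate(1, k = 2, K = 1, e = 1, v = 1), 1) # half saturation
  expect_equal(em_rate(1, k = 2, K = 1, e = 0.5, v = 0.5), 0.25)
})

test_that("carbon returns weight uptake by carbon content", {
  fams <- diauxic_families()
  cp <- truth_cybernetic()
  carbon <- c(GLCx = 6, LACx = 3, Xx = 0)
  # single consumed substrate: R = 6 * r * |Z_glc|
  R <- carbon_returns(fams[1], list(GLCx = 28, LACx = 0), cp, e = 1, carbon)
  kern <- em_rate(28, cp$k[1], cp$K[1])
  expect_equal(R, 6 * kern * 1)

  # same kinetics, 5-C vs 6-C substrate: ordering follows carbon count
  net <- diauxic_net()
  cp_same <- cybernetic_params(k = c(0.3, 0.3), K = c(1, 1))
  R2 <- carbon_returns(fams, list(GLCx = 10, LACx = 10), cp_same,
                       e = c(1, 1), carbon)
  expect_gt(R2[1], R2[2])

  # exhaustion: all returns zero, matching law falls back to uniform u
  R0 <- carbon_returns(fams, list(GLCx = 0, LACx = 0), cp, e = c(1, 1), carbon)
  expect_equal(R0, c(0, 0))
  cv <- cybernetic_variables(R0)
  expect_equal(cv$u, c(0.5, 0.5))
  expect_equal(cv$v, c(1, 1))

  expect_error(
    carbon_returns(fams, list(GLCx = 1, LACx = 1), cp, e = c(1, 1),
                   carbon = c(GLCx = 6)),
    "missing carbon counts.*LACx"
  )
})

test_that("matching laws compute u and v as printed", {
  cv <- cybernetic_variables(c(1, 1))
  expect_equal(cv$u, c(0.5, 0.5)); expect_equal(cv$v, c(1, 1))
  cv2 <- cybernetic_variables(c(3, 1))
  expect_equal(cv2$u, c(0.75, 0.25)); expect_equal(cv2$v, c(1, 1 / 3))
  cv3 <- cybernetic_variables(5)
  expect_equal(cv3$u, 1); expect_equal(cv3$v, 1)
  expect_error(cybernetic_variables(c(-1, 2)), "nonnegative")
})

test_that("cybernetic invariants hold along every trajectory", {
  net <- diauxic_net()
  fams <- diauxic_families(net)
  traj <- simulate_hcm(fams, truth_cybernetic(), hcm_init(), net,
                       t_end = 144, dt = 0.1)
  expect_lt(max(abs(traj$u_glc + traj$u_lac - 1)), 1e-12)
  expect_true(all(traj$v_glc >= 0 & traj$v_glc <= 1))
  expect_true(all(traj$v_lac >= 0 & traj$v_lac <= 1))
  expect_true(all(traj$e_glc >= 0 & traj$e_glc <= 1))
  expect_true(all(as.matrix(traj[, c("X", "GLCx", "LACx")]) >= 0))
  # when any return is positive the most attractive mode runs at full tilt
  expect_true(all(abs(pmax(traj$v_glc, traj$v_lac) - 1) < 1e-12 |
                    (traj$GLCx + traj$LACx) == 0))
})

test_that("the diauxic switch emerges without a hard-coded phase change", {
  net <- diauxic_net()
  traj <- simulate_hcm(diauxic_families(net), truth_cybernetic(), hcm_init(),
                       net, t_end = 144, dt = 0.1)
  i_peak <- which.max(traj$LACx)
  expect_gt(traj$LACx[i_peak], 1) # overflow accumulates
  expect_gt(i_peak, 10L)
  expect_lt(i_peak, nrow(traj)) # and is later consumed
  expect_lt(traj$LACx[nrow(traj)], 0.2 * traj$LACx[i_peak])
  # lactate family takes over enzyme allocation while LAC is being consumed
  # (after exhaustion of both substrates u falls back to uniform)
  consuming <- which(seq_len(nrow(traj)) > i_peak & traj$LACx > 0.5 * traj$LACx[i_peak])
  expect_gt(max(traj$u_lac[consuming]), 0.9)
})

test_that("two identical families split regulation symmetrically", {
  net <- diauxic_net()
  f <- diauxic_families(net)[[1]]
  f2 <- f; f2$label <- "glc2"
  cp <- cybernetic_params(k = c(0.3, 0.3), K = c(0.8, 0.8), e0 = c(0.5, 0.5))
  traj <- simulate_hcm(list(f, f2), cp, hcm_init(), net, t_end = 48, dt = 0.1)
  expect_lt(max(abs(traj$u_glc - 0.5)), 1e-12)
  expect_equal(traj$e_glc, traj$e_glc2, tolerance = 1e-12)
  expect_equal(traj$r_glc, traj$r_glc2, tolerance = 1e-12)
})

test_that("relative enzyme converges to its saturated fixed point", {
  net <- diauxic_net()
  f <- diauxic_families(net)[[1]]
  # negligible uptake keeps mu ~ 0 and the substrate saturating: with u = 1
  # the relative-enzyme balance has fixed point e = 1
  cp <- cybernetic_params(k = 1e-9, K = 1, alpha = 0.02, beta = 0.1, e0 = 0.1)
  traj <- simulate_hcm(list(f), cp, c(X = 0.1, GLCx = 1e6, LACx = 0), net,
                       t_end = 400, dt = 0.1)
  expect_equal(traj$e_glc[nrow(traj)], 1, tolerance = 1e-4)
})

test_that("refining dt changes final concentrations by less than 1 percent", {
  net <- diauxic_net()
  fams <- diauxic_families(net)
  a <- simulate_hcm(fams, truth_cybernetic(), hcm_init(), net, t_end = 96, dt = 0.1)
  b <- simulate_hcm(fams, truth_cybernetic(), hcm_init(), net, t_end = 96, dt = 0.01)
  for (v in c("X", "GLCx", "LACx")) {
    fa <- a[[v]][nrow(a)]; fb <- b[[v]][nrow(b)]
    expect_lt(abs(fa - fb) / max(fb, 1e-6), 0.01)
  }
})

test_that("flux snapshots are regulated mode combinations at steady state", {
  net <- diauxic_net()
  fams <- diauxic_families(net)
  traj <- simulate_hcm(fams, truth_cybernetic(), hcm_init(), net,
                       t_end = 96, dt = 0.1)
  snaps <- flux_snapshots(traj, c(0, 44, 72), fams)
  expect_equal(snaps$reaction, net$reactions$id)
  S <- stoichiometric_matrix(net)
  for (cn in c("t0", "t44", "t72")) {
    expect_lt(max(abs(S %*% snaps[[cn]])), 1e-9)
  }
  # single family: snapshot proportional to its flux vector
  traj1 <- simulate_hcm(fams[1], cybernetic_params(k = 0.3, K = 0.8, e0 = 0.9),
                        hcm_init(), net, t_end = 24, dt = 0.1)
  s1 <- flux_snapshots(traj1, 12, fams[1])
  ratio <- s1$t12 / fams[[1]]$flux
  ratio <- ratio[is.finite(ratio) & abs(fams[[1]]$flux) > 0]
  expect_lt(diff(range(ratio)), 1e-12)

  expect_error(flux_snapshots(traj, 1e4, fams), "outside")
})

test_that("the genetic algorithm is seed-deterministic with monotone best SSE", {
  net <- diauxic_net()
  fams <- diauxic_families(net)
  cp <- truth_cybernetic()
  traj <- simulate_hcm(fams, cp, hcm_init(), net, t_end = 96, dt = 0.2)
  data <- polarflux:::series_at(traj[, c("time", "X", "GLCx", "LACx")],
                                seq(0, 96, by = 12))
  f1 <- fit_hcm_ga(fams, data, seed = 7, params0 = cp, init = hcm_init(),
                   net = net, t_end = 96, dt = 0.2)
  f2 <- fit_hcm_ga(fams, data, seed = 7, params0 = cp, init = hcm_init(),
                   net = net, t_end = 96, dt = 0.2)
  expect_identical(f1$params$k, f2$params$k)
  expect_identical(f1$params$K, f2$params$K)
  expect_identical(f1$history, f2$history)
  expect_true(glance(f1)$monotone)
  # recovery of the generating kinetics
  expect_lt(max(abs(f1$params$k - cp$k) / cp$k), 0.05)

  expect_error(
    fit_hcm_ga(fams, dplyr::mutate(data, X = 1, GLCx = 1, LACx = 1),
               seed = 1, params0 = cp, init = hcm_init(), net = net),
    "degenerate"
  )
})
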