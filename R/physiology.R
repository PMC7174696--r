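# Segregated two-population batch-culture physiology.
#
# Total biomass X follows logistic growth toward X_max; dead biomass X_d grows
# first-order at k_d from its own level (as printed in the source model, which
# is known to overestimate late-phase death); viable biomass is the
# difference. Viable cells split into an exponential fraction
# Psi_e = 1 - X/X_max and a stationary fraction Psi_s = X/X_max, each with its
# own maximum specific rate per metabolite, saturated Michaelis-Menten style
# by a key driver metabolite:
#   GLC <- GLC,  GLN <- GLN,  LAC <- GLC (exponential) / LAC (stationary),
#   GLU <- GLN (both phases).
# All specific rates are signed: negative = consumption. Integration is
# explicit Euler at dt = 0.1 h to match the model's printed update equations.

PHYSIO_PAR_NAMES <- c("mu_max", "X_max", "k_d",
                      "q_g_e", "q_g_s", "q_n_e", "q_n_s",
                      "q_l_e", "q_l_s", "q_u_e", "q_u_s",
                      "K_g", "K_n", "K_l")

#' Physiological model parameters
#'
#' @param mu_max Maximum specific growth rate (1/h), > 0.
#' @param X_max Maximum total biomass (mM), > 0.
#' @param k_d First-order death rate (1/h), >= 0.
#' @param q_g_e,q_g_s,q_n_e,q_n_s,q_l_e,q_l_s,q_u_e,q_u_s Maximum specific
#'   rates (mM per mM biomass per h) for GLC, GLN, LAC, GLU in the
#'   exponential (`_e`) and stationary (`_s`) phase; signed, negative =
#'   consumption.
#' @param K_g,K_n,K_l Saturation constants (mM), > 0, for the GLC-, GLN- and
#'   LAC-driven terms.
#' @param biomass_conversion mM biomass per (cells/mL); no default is shipped
#'   because the conversion is a dataset-level calibration — supply it when
#'   converting counts.
#' @return A named list of class `physio_params`.
#' @export
physio_params <- function(mu_max, X_max, k_d = 0,
                          q_g_e = 0, q_g_s = 0, q_n_e = 0, q_n_s = 0,
                          q_l_e = 0, q_l_s = 0, q_u_e = 0, q_u_s = 0,
                          K_g = 1, K_n = 1, K_l = 1,
                          biomass_conversion = NULL) {
  if (mu_max <= 0) abort("mu_max must be > 0")
  if (X_max <= 0) abort("X_max must be > 0")
  if (k_d < 0) abort("k_d must be >= 0")
  if (any(c(K_g, K_n, K_l) <= 0)) abort("saturation constants must be > 0")
  structure(
    list(mu_max = mu_max, X_max = X_max, k_d = k_d,
         q_g_e = q_g_e, q_g_s = q_g_s, q_n_e = q_n_e, q_n_s = q_n_s,
         q_l_e = q_l_e, q_l_s = q_l_s, q_u_e = q_u_e, q_u_s = q_u_s,
         K_g = K_g, K_n = K_n, K_l = K_l,
         biomass_conversion = biomass_conversion),
    class = "physio_params"
  )
}

as_physio_params <- function(x) {
  if (inherits(x, "physio_params")) return(x)
  do.call(physio_params, as.list(x)[intersect(names(x), c(PHYSIO_PAR_NAMES, "biomass_conversion"))])
}

#' Default initial condition of the emulated batch design
#'
#' 28 mM GLC, 8 mM GLN, no LAC/GLU, and an inoculum expressed directly in mM
#' biomass.
#'
#' @param Xv0 Initial viable biomass (mM).
#' @param Xd0 Initial dead biomass (mM).
#' @return A one-row tibble in canonical culture-series form.
#' @export
culture_init <- function(Xv0 = 0.25, Xd0 = 0.005) {
  tibble::tibble(time = 0, Xv = Xv0, Xd = Xd0,
                 GLC = 28, GLN = 8, LAC = 0, GLU = 0)
}

#' Simulate a batch culture with the segregated physiology model
#'
#' Explicit forward Euler: biomass first (logistic total + first-order
#' death), then each metabolite using the updated viable biomass, the phase
#' fractions from the updated total biomass, and the previous step's
#' concentrations in the saturation terms. Concentrations are floored at 0,
#' which also switches off the self-driven consumption terms at exhaustion.
#'
#' @param params A `physio_params`.
#' @param t_end Horizon (h).
#' @param dt Step (h), > 0; default 0.1.
#' @param init One-row data frame with `time`, `Xv`, `Xd`, `GLC`, `GLN`,
#'   `LAC`, `GLU` (see [culture_init()]).
#' @return A `culture_series` tibble with columns `time`, `X`, `Xv`, `Xd`,
#'   `GLC`, `GLN`, `LAC`, `GLU`.
#' @export
simulate_culture <- function(params, t_end = 144, dt = 0.1,
                             init = culture_init()) {
  p <- as_physio_params(params)
  if (dt <= 0) abort("dt must be > 0")
  init <- tibble::as_tibble(init)
  conc0 <- unlist(init[1, c("GLC", "GLN", "LAC", "GLU")])
  if (any(conc0 < 0) || init$Xv[1] < 0 || init$Xd[1] < 0) {
    abort("initial concentrations must be >= 0")
  }
  n <- floor(t_end / dt) + 1L
  out <- matrix(NA_real_, n, 8,
                dimnames = list(NULL, c("time", "X", "Xv", "Xd",
                                        "GLC", "GLN", "LAC", "GLU")))
  X <- init$Xv[1] + init$Xd[1]; Xd <- init$Xd[1]
  GLC <- init$GLC[1]; GLN <- init$GLN[1]; LAC <- init$LAC[1]; GLU <- init$GLU[1]
  out[1, ] <- c(init$time[1], X, X - Xd, Xd, GLC, GLN, LAC, GLU)
  for (i in seq_len(n - 1L)) {
    X_new <- X + p$mu_max * X * (1 - X / p$X_max) * dt
    Xd_new <- Xd + p$k_d * Xd * dt
    Xv_new <- X_new - Xd_new
    psi_e <- 1 - X_new / p$X_max
    psi_s <- X_new / p$X_max
    sat_g <- GLC / (p$K_g + GLC)
    sat_n <- GLN / (p$K_n + GLN)
    sat_l <- LAC / (p$K_l + LAC)
    GLC <- max(0, GLC + (p$q_g_e * sat_g * psi_e + p$q_g_s * sat_g * psi_s) * Xv_new * dt)
    GLN <- max(0, GLN + (p$q_n_e * sat_n * psi_e + p$q_n_s * sat_n * psi_s) * Xv_new * dt)
    LAC <- max(0, LAC + (p$q_l_e * sat_g * psi_e + p$q_l_s * sat_l * psi_s) * Xv_new * dt)
    GLU <- max(0, GLU + (p$q_u_e * sat_n * psi_e + p$q_u_s * sat_n * psi_s) * Xv_new * dt)
    X <- X_new; Xd <- Xd_new
    out[i + 1L, ] <- c(out[1, 1] + i * dt, X, Xv_new, Xd, GLC, GLN, LAC, GLU)
  }
  res <- tibble::as_tibble(as.data.frame(out))
  class(res) <- c("culture_series", class(res))
  res
}

#' Instantaneous rates, specific rates, and apparent yields along a simulation
#'
#' Numeric first differences of a simulated trajectory: rate = dM/dt,
#' specific rate = rate / Xv, apparent yield = dM/dX against the total
#' biomass model. The `argmax` attribute records the time of each variable's
#' maximum absolute rate.
#'
#' @param params A `physio_params`.
#' @param t_end,dt,init Passed to [simulate_culture()].
#' @return A tibble `time`, `variable`, `rate`, `specific_rate`, `yield`,
#'   with an `argmax` attribute (tibble `variable`, `t_max_rate`).
#' @export
instantaneous_profiles <- function(params, t_end = 144, dt = 0.1,
                                   init = culture_init()) {
  sim <- simulate_culture(params, t_end = t_end, dt = dt, init = init)
  vars <- c("Xv", "GLC", "GLN", "LAC", "GLU")
  dX <- diff(sim$X)
  mids <- sim$time[-1]
  long <- purrr::map_dfr(vars, function(v) {
    dM <- diff(sim[[v]])
    tibble::tibble(
      time = mids, variable = v,
      rate = dM / dt,
      specific_rate = dM / dt / sim$Xv[-1],
      yield = ifelse(abs(dX) > 0, dM / dX, NA_real_)
    )
  })
  argmax <- long |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(t_max_rate = .data$time[which.max(abs(.data$rate))],
                     .groups = "drop")
  attr(long, "argmax") <- argmax
  long
}

# ---- error metrics --------------------------------------------------------

#' Model accuracy metrics (SSE, PE, MAPE, MPPE)
#'
#' `SSE = sum((e - m)^2)`, `PE = sqrt(SSE/n)`,
#' `MAPE = (100/n) * sum(|e - m| / |e|)` with zero-valued observations
#' excluded and counted (`mape_excluded`) — the familiar small-denominator
#' pathology of MAPE. The printed MPPE form is
#' `100 * sqrt(SSE / (sum(e^2) * n))`; because its typesetting is ambiguous
#' about where `n` sits, the normalized-RMSE reading
#' `100 * sqrt(SSE / sum(e^2))` is always reported too as `mppe_alt`.
#'
#' @param e Observed values.
#' @param m Modeled values (same length).
#' @return A one-row tibble: `n`, `sse`, `pe`, `mape`, `mape_excluded`,
#'   `mppe`, `mppe_alt`.
#' @export
error_metrics <- function(e, m) {
  if (length(e) != length(m)) abort("e and m must have equal length")
  n <- length(e)
  if (n == 0L) abort("no data points")
  if (any(!is.finite(e)) || any(!is.finite(m))) abort("non-finite data")
  sse <- sum((e - m)^2)
  nz <- e != 0
  mape <- if (any(nz)) 100 / sum(nz) * sum(abs((e[nz] - m[nz]) / e[nz])) else NA_real_
  se2 <- sum(e^2)
  tibble::tibble(
    n = n,
    sse = sse,
    pe = sqrt(sse / n),
    mape = mape,
    mape_excluded = sum(!nz),
    mppe = if (se2 > 0) 100 * sqrt(sse / (se2 * n)) else ifelse(sse == 0, 0, NA_real_),
    mppe_alt = if (se2 > 0) 100 * sqrt(sse / se2) else ifelse(sse == 0, 0, NA_real_)
  )
}

fit_report <- function(data, model, vars) {
  purrr::map_dfr(vars, function(v) {
    dplyr::bind_cols(tibble::tibble(variable = v),
                     error_metrics(data[[v]], model[[v]]))
  })
}

# interpolate a simulated series onto observation times
series_at <- function(sim, times) {
  out <- purrr::map(setdiff(names(sim), "time"), function(v) {
    stats::approx(sim$time, sim[[v]], xout = times, rule = 2)$y
  })
  names(out) <- setdiff(names(sim), "time")
  dplyr::bind_cols(tibble::tibble(time = times), tibble::as_tibble(out))
}

# ---- fitting --------------------------------------------------------------

# one-metabolite simulators on a precomputed biomass trajectory; keeping the
# state feedback out of the full model makes the stage-2 fits cheap
sim_self <- function(M0, q_e, q_s, K, Xv, psi_e, psi_s, dt) {
  n <- length(Xv); M <- numeric(n); M[1] <- M0
  for (i in seq_len(n - 1L)) {
    sat <- M[i] / (K + M[i])
    M[i + 1L] <- max(0, M[i] + (q_e * sat * psi_e[i + 1L] +
                                  q_s * sat * psi_s[i + 1L]) * Xv[i + 1L] * dt)
  }
  M
}

#' Fit the physiological model to culture data
#'
#' Two-stage bounded least squares: the biomass parameters (`mu_max`,
#' `X_max`, `k_d`) are fitted first against the viable/dead biomass columns;
#' with biomass fixed, each metabolite's rate parameters (and shared
#' saturation constants) are then fitted in the driver order GLC, GLN, LAC
#' (driven by the fitted GLC trajectory in the exponential phase), GLU
#' (driven by GLN). SSE is evaluated at the observation times.
#'
#' @param data A culture series tibble (`time`, `Xv`, `Xd`, `GLC`, `GLN`,
#'   `LAC`, `GLU`), >= 4 time points.
#' @param init_guess A `physio_params` used as the optimizer start.
#' @param dt Integration step for the model during fitting.
#' @return An object of class `physio_fit` with elements `params`
#'   (`physio_params`), `report` (per-variable metric tibble), `model`
#'   (fitted trajectory at `dt`), `data`, and `convergence` codes.
#'   [tidy()] and [glance()] methods are provided.
#' @export
fit_physio <- function(data, init_guess, dt = 0.1) {
  data <- tibble::as_tibble(data)
  if (nrow(data) < 4L) abort("need at least 4 time points per fitted variable")
  num_cols <- intersect(c("time", "Xv", "Xd", "GLC", "GLN", "LAC", "GLU"), names(data))
  if (any(!is.finite(as.matrix(data[num_cols])))) abort("non-finite data")
  g <- as_physio_params(init_guess)
  t_end <- max(data$time)
  times <- data$time
  conv <- integer(0)
  n_grid <- floor(t_end / dt) + 1L
  grid <- seq(0, t_end, by = dt)[seq_len(n_grid)]
  idx <- vapply(times, function(tt) which.min(abs(grid - tt)), integer(1))
  ctl <- function(k) list(maxit = 1000, factr = 1e1, ndeps = rep(1e-7, k))

  # stage 1a: total biomass is autonomous (discrete logistic) — fit mu_max,
  # X_max against Xv + Xd; stage 1b: dead biomass is autonomous geometric
  # growth — fit k_d against Xd alone, keeping the tiny dead-cell signal from
  # being swamped by the viable-cell SSE
  Xtot <- data$Xv + data$Xd
  X0 <- Xtot[1]
  sim_X <- function(mu, Xmax) {
    X <- numeric(n_grid); X[1] <- X0
    for (i in seq_len(n_grid - 1L)) X[i + 1L] <- X[i] + mu * X[i] * (1 - X[i] / Xmax) * dt
    X
  }
  o1 <- optim(c(g$mu_max, g$X_max),
              function(th) sum((Xtot - sim_X(th[1], th[2])[idx])^2),
              method = "L-BFGS-B",
              lower = c(1e-5, max(Xtot) * 0.8), upper = c(2, max(Xtot) * 50),
              control = ctl(2))
  conv["biomass"] <- o1$convergence
  o_kd <- optim(max(g$k_d, 1e-4),
                function(kd) sum((data$Xd - data$Xd[1] * (1 + kd * dt)^(seq_len(n_grid) - 1L)[idx])^2),
                method = "Brent", lower = 0, upper = 1)
  p <- g
  p$mu_max <- o1$par[1]; p$X_max <- o1$par[2]; p$k_d <- o_kd$par

  # fixed biomass trajectory on the dt grid
  X <- sim_X(p$mu_max, p$X_max)
  Xd_traj <- data$Xd[1] * (1 + p$k_d * dt)^(seq_len(n_grid) - 1L)
  Xv <- X - Xd_traj
  psi_e <- 1 - X / p$X_max
  psi_s <- X / p$X_max

  qmax <- 5
  fit_self <- function(obs, start) {
    f <- function(theta) {
      M <- sim_self(obs[1], theta[1], theta[2], theta[3], Xv, psi_e, psi_s, dt)
      sum((obs - M[idx])^2)
    }
    optim(start, f, method = "L-BFGS-B",
          lower = c(-qmax, -qmax, 0.01), upper = c(qmax, qmax, 50),
          control = ctl(3))
  }

  # GLC and GLN: saturation on the state itself in both phases
  o_g <- fit_self(data$GLC, c(g$q_g_e, g$q_g_s, g$K_g))
  conv["GLC"] <- o_g$convergence
  p$q_g_e <- o_g$par[1]; p$q_g_s <- o_g$par[2]; p$K_g <- o_g$par[3]
  glc_traj <- sim_self(data$GLC[1], p$q_g_e, p$q_g_s, p$K_g, Xv, psi_e, psi_s, dt)

  o_n <- fit_self(data$GLN, c(g$q_n_e, g$q_n_s, g$K_n))
  conv["GLN"] <- o_n$convergence
  p$q_n_e <- o_n$par[1]; p$q_n_s <- o_n$par[2]; p$K_n <- o_n$par[3]
  gln_traj <- sim_self(data$GLN[1], p$q_n_e, p$q_n_s, p$K_n, Xv, psi_e, psi_s, dt)

  # LAC: exponential driven by fitted GLC (K_g fixed), stationary self-driven (K_l)
  lac_sse <- function(theta) {
    M <- sim_lac(data$LAC[1], glc_traj, theta[1], theta[2], p$K_g, theta[3],
                 Xv, psi_e, psi_s, dt)
    sum((data$LAC - M[idx])^2)
  }
  o_l <- optim(c(g$q_l_e, g$q_l_s, g$K_l), lac_sse, method = "L-BFGS-B",
               lower = c(-qmax, -qmax, 0.01), upper = c(qmax, qmax, 50),
               control = ctl(3))
  conv["LAC"] <- o_l$convergence
  p$q_l_e <- o_l$par[1]; p$q_l_s <- o_l$par[2]; p$K_l <- o_l$par[3]

  # GLU: driven by fitted GLN in both phases (K_n fixed)
  glu_sse <- function(theta) {
    M <- sim_driver_only(data$GLU[1], gln_traj, theta[1], theta[2], p$K_n,
                         Xv, psi_e, psi_s, dt)
    sum((data$GLU - M[idx])^2)
  }
  o_u <- optim(c(g$q_u_e, g$q_u_s), glu_sse, method = "L-BFGS-B",
               lower = c(-qmax, -qmax), upper = c(qmax, qmax),
               control = ctl(2))
  conv["GLU"] <- o_u$convergence
  p$q_u_e <- o_u$par[1]; p$q_u_s <- o_u$par[2]

  model <- simulate_culture(p, t_end, dt, init = data[1, ])
  mod_at <- series_at(model, times)
  report <- fit_report(data, mod_at, c("Xv", "Xd", "GLC", "GLN", "LAC", "GLU"))
  if (any(conv != 0)) {
    warn(paste0("optimizer did not fully converge for: ",
                paste(names(conv)[conv != 0], collapse = ", "),
                "; best-so-far parameters returned"))
  }
  structure(list(params = p, report = report, model = model, data = data,
                 convergence = conv),
            class = "physio_fit")
}

# self-driven metabolite (GLC, GLN): both phases saturate on the state itself
# LAC: exponential phase saturates on the supplied GLC trajectory, stationary
# on LAC itself. GLU: both phases on the supplied GLN trajectory.
sim_lac <- function(M0, glc, q_e, q_s, K_g, K_l, Xv, psi_e, psi_s, dt) {
  n <- length(Xv); M <- numeric(n); M[1] <- M0
  for (i in seq_len(n - 1L)) {
    M[i + 1L] <- max(0, M[i] + (q_e * glc[i] / (K_g + glc[i]) * psi_e[i + 1L] +
                                  q_s * M[i] / (K_l + M[i]) * psi_s[i + 1L]) *
                       Xv[i + 1L] * dt)
  }
  M
}

sim_driver_only <- function(M0, drv, q_e, q_s, K, Xv, psi_e, psi_s, dt) {
  n <- length(Xv); M <- numeric(n); M[1] <- M0
  for (i in seq_len(n - 1L)) {
    sat <- drv[i] / (K + drv[i])
    M[i + 1L] <- max(0, M[i] + (q_e * sat * psi_e[i + 1L] +
                                  q_s * sat * psi_s[i + 1L]) * Xv[i + 1L] * dt)
  }
  M
}

#' @export
print.physio_fit <- function(x, ...) {
  cat("<physio_fit> segregated two-population culture model\n")
  print(tidy(x), n = 14)
  invisible(x)
}

#' Tidy fitted physiology parameters
#' @param x A `physio_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @export
tidy.physio_fit <- function(x, ...) {
  tibble::tibble(term = PHYSIO_PAR_NAMES,
                 estimate = unlist(x$params[PHYSIO_PAR_NAMES]))
}

#' One-row fit summary (total SSE and mean MPPE across variables)
#' @param x A `physio_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.physio_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$data),
    total_sse = sum(x$report$sse),
    mean_mppe = mean(x$report$mppe, na.rm = TRUE),
    converged = all(x$convergence == 0)
  )
}
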