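# Hybrid cybernetic model (HCM): each selected elementary mode behaves like a
# pathway catalyzed by a key enzyme whose synthesis and activity are
# allocated by matching-law cybernetic variables computed from per-mode
# "returns" (carbon consumption by default):
#   u_i = R_i / sum(R),   v_i = R_i / max(R).
# The mode kinetic kernel is Michaelis-Menten in the family's preferential
# metabolite, r_i = k_i * M/(K_i + M) * e_i, with e_i the relative enzyme
# level integrated in e/e_max form:
#   de_i/dt = beta_i * sat_i * u_i - (beta_i + mu) * e_i
# (negative growth dilution by default; the printed positive sign is exposed
# via `dilution = "positive"`). With u = 1, saturating substrate and mu = 0
# the fixed point is e = 1, the saturated maximum.

#' An EM family for cybernetic modeling
#'
#' The mode's flux vector is rescaled so the uptake of the preferential
#' metabolite is 1, making the kinetic kernel directly the preferential
#' uptake rate.
#'
#' @param em Named signed flux vector (single or lumped mode).
#' @param net The network.
#' @param preferential External metabolite id this family preferentially
#'   consumes (GLC for a growth family, LAC for a lactate-reconsumption
#'   family).
#' @param label Family label.
#' @return A list of class `hcm_family` with the scaled flux vector, its
#'   external exchange `Z` (per unit preferential uptake), and biomass index
#'   `Z_X`.
#' @export
hcm_family <- function(em, net, preferential, label = preferential) {
  Z <- external_exchange(net, em)
  if (!preferential %in% names(Z)) {
    abort(paste0("preferential metabolite ", preferential,
                 " is not an external metabolite"))
  }
  up <- Z[[preferential]]
  if (up >= -FLUX_TOL) {
    abort(paste0("family mode does not consume ", preferential))
  }
  scale <- abs(up)
  structure(list(flux = em / scale, Z = Z / scale,
                 Z_X = em[[net$biomass]] / scale,
                 preferential = preferential, label = label),
            class = "hcm_family")
}

#' Cybernetic rate parameters
#'
#' @param k Maximum uptake rates, one per family (mM per mM biomass per h).
#'   The fitting default start is 1.
#' @param K Saturation constants, one per family (mM); fitting start 10.
#' @param alpha,beta Enzyme synthesis and decay constants (1/h). No values
#'   are printed for CHO; the shipped defaults (0.01, 0.05) are conventions
#'   on the scale used for microbial cybernetic models and should be
#'   overridden when calibrating.
#' @param e0 Initial relative enzyme levels in `[0, 1]`; default 0.9 for the
#'   first family and 0.1 for the others.
#' @return A list of class `cybernetic_params`.
#' @export
cybernetic_params <- function(k, K, alpha = 0.01, beta = 0.05, e0 = NULL) {
  n <- length(k)
  if (length(K) != n) abort("k and K must have one entry per family")
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  if (any(c(k, K, alpha, beta) <= 0)) abort("k, K, alpha, beta must be > 0")
  e0 <- e0 %||% c(0.9, rep(0.1, n - 1L))[seq_len(n)]
  if (any(e0 < 0 | e0 > 1)) abort("initial relative enzymes must be in [0, 1]")
  structure(list(k = k, K = K, alpha = alpha, beta = beta, e0 = e0),
            class = "cybernetic_params")
}

#' Regulated uptake rate of one mode
#'
#' Computes `k * M/(K + M) * e * v`: the Michaelis-Menten kernel in the
#' preferential metabolite, scaled by the relative enzyme level and the
#' activity variable.
#'
#' @param M Preferential metabolite concentration (mM, >= 0).
#' @param k,K Kernel parameters.
#' @param e Relative enzyme level in `[0, 1]`.
#' @param v Cybernetic activity variable in `[0, 1]`.
#' @return Rate (mM per mM biomass per h).
#' @export
em_rate <- function(M, k, K, e = 1, v = 1) {
  M <- pmax(M, 0)
  k * M / (K + M) * e * v
}

#' Carbon-consumption returns of each family
#'
#' `R_i = kernel_i * e_i * sum over consumed externals |Z| * carbon`, the
#' unregulated rate weighted by the carbon each mode draws in — the metabolic
#' objective driving the matching laws.
#'
#' @param families List of `hcm_family`.
#' @param conc Named concentrations of external metabolites (mM).
#' @param params `cybernetic_params`.
#' @param e Relative enzyme levels.
#' @param carbon Named carbon counts per external metabolite id.
#' @return Nonnegative numeric vector, one return per family.
#' @export
carbon_returns <- function(families, conc, params, e, carbon) {
  vapply(seq_along(families), function(i) {
    f <- families[[i]]
    consumed <- names(f$Z)[f$Z < -FLUX_TOL]
    missing_c <- consumed[!consumed %in% names(carbon)]
    if (length(missing_c) > 0L) {
      abort(paste0("missing carbon counts for: ", paste(missing_c, collapse = ", ")))
    }
    kern <- em_rate(conc[[f$preferential]], params$k[i], params$K[i], e = e[i], v = 1)
    kern * sum(abs(f$Z[consumed]) * carbon[consumed])
  }, numeric(1))
}

#' Matching-law cybernetic variables
#'
#' `u_i = R_i / sum(R)` (enzyme synthesis allocation, sums to 1) and
#' `v_i = R_i / max(R)` (activity, max is 1). When every return is zero —
#' substrates exhausted — `u` falls back to uniform and `v` to 1 for all, so
#' the ODE system stays defined.
#'
#' @param R Nonnegative returns vector.
#' @return List with `u` and `v`.
#' @export
cybernetic_variables <- function(R) {
  if (any(R < 0)) abort("returns must be nonnegative")
  s <- sum(R)
  if (s == 0) {
    n <- length(R)
    return(list(u = rep(1 / n, n), v = rep(1, n)))
  }
  list(u = R / s, v = R / max(R))
}

#' Simulate a hybrid cybernetic model
#'
#' Explicit Euler integration of external metabolites
#' (`dM/dt = sum_i r_i v_i Z_{i,M} X`), biomass (`dX/dt = sum_i r_i v_i
#' Z_{i,X} X`), and relative enzymes (synthesis allocated by `u`, first-order
#' decay, growth dilution lagged one step). States are floored at zero;
#' `sum(u) = 1` holds at every step.
#'
#' @param families List of `hcm_family` (same network).
#' @param params `cybernetic_params` with one entry per family.
#' @param init Named initial concentrations: biomass `X` plus one entry per
#'   tracked external metabolite (mM).
#' @param net The network (for carbon counts).
#' @param t_end Horizon (h).
#' @param dt Step (h), default 0.1.
#' @param dilution `"negative"` (standard, default) or `"positive"` (the
#'   printed sign).
#' @return A tibble of class `hcm_trajectory`: `time`, `X`, one column per
#'   external metabolite, and `e_<label>`, `u_<label>`, `v_<label>`,
#'   `r_<label>` per family.
#' @export
simulate_hcm <- function(families, params, init, net, t_end = 144, dt = 0.1,
                         dilution = c("negative", "positive")) {
  dilution <- match.arg(dilution)
  dil_sign <- if (dilution == "negative") 1 else -1
  nf <- length(families)
  stopifnot(nf >= 1L, length(params$k) == nf)
  carbon <- setNames(net$metabolites$carbon, net$metabolites$id)
  ext <- unique(unlist(purrr::map(families, ~ names(.x$Z))))
  tracked <- intersect(names(init), ext)
  conc <- unlist(init[tracked])
  X <- init[["X"]]
  if (is.null(X) || X <= 0) abort("init must include positive biomass X")
  if (any(conc < 0)) abort("initial concentrations must be >= 0")
  e <- params$e0
  labels <- purrr::map_chr(families, "label")
  n <- floor(t_end / dt) + 1L
  nm <- c("time", "X", tracked,
          paste0("e_", labels), paste0("u_", labels),
          paste0("v_", labels), paste0("r_", labels))
  out <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))

  # per-family constants: exchange matrix over tracked metabolites, biomass
  # indices, preferential-metabolite index, and the (fixed) carbon weight
  # sum(|Z_consumed| * carbon) so returns reduce to kernel * e * weight
  Zmat <- do.call(rbind, purrr::map(families, function(f) {
    z <- f$Z[tracked]; z[is.na(z)] <- 0; z
  }))
  Z_X <- purrr::map_dbl(families, "Z_X")
  pref <- purrr::map_chr(families, "preferential")
  pref_idx <- match(pref, tracked)
  if (any(is.na(pref_idx))) {
    abort(paste0("init must include the preferential metabolite(s): ",
                 paste(pref[is.na(pref_idx)], collapse = ", ")))
  }
  cw <- vapply(families, function(f) {
    consumed <- names(f$Z)[f$Z < -FLUX_TOL]
    missing_c <- consumed[!consumed %in% names(carbon)]
    if (length(missing_c) > 0L) {
      abort(paste0("missing carbon counts for: ", paste(missing_c, collapse = ", ")))
    }
    sum(abs(f$Z[consumed]) * carbon[consumed])
  }, numeric(1))
  out[] <- .hcm_core(params$k, params$K, params$beta, e, cw, Zmat, Z_X,
                     as.integer(pref_idx), unname(conc), X, n, dt, dil_sign)
  if (any(!is.finite(out))) {
    bad <- which(rowSums(!is.finite(out)) > 0)[1]
    warn(paste0("non-finite state at t = ", out[max(1, bad - 1L), 1],
                " h; trajectory truncated"))
    out <- out[seq_len(max(1L, bad - 1L)), , drop = FALSE]
  }
  res <- tibble::as_tibble(as.data.frame(out))
  attr(res, "labels") <- labels
  class(res) <- c("hcm_trajectory", class(res))
  res
}

#' Biomass-normalized reaction-flux snapshots of an HCM trajectory
#'
#' At each requested time the whole-network flux is the regulated,
#' mode-weighted combination `sum_i r_i v_i flux_i` (per unit biomass, since
#' the rates are specific rates). By linearity every snapshot satisfies the
#' internal steady-state balance.
#'
#' @param traj An `hcm_trajectory`.
#' @param times Times (h) within the trajectory span.
#' @param families The families used in the simulation.
#' @return A tibble `reaction` x one column per time (`t<h>`).
#' @export
flux_snapshots <- function(traj, times, families) {
  labels <- attr(traj, "labels")
  if (any(times < min(traj$time) | times > max(traj$time))) {
    abort("snapshot times outside trajectory span")
  }
  rx <- names(families[[1]]$flux)
  cols <- purrr::map(times, function(tt) {
    i <- which.min(abs(traj$time - tt))
    flux <- setNames(numeric(length(rx)), rx)
    for (j in seq_along(families)) {
      rv <- traj[[paste0("r_", labels[j])]][i] * traj[[paste0("v_", labels[j])]][i]
      flux <- flux + rv * families[[j]]$flux
    }
    flux
  })
  out <- tibble::tibble(reaction = rx)
  for (k in seq_along(times)) out[[paste0("t", times[k])]] <- cols[[k]]
  out
}

# ---- genetic-algorithm fitting -------------------------------------------

# build a fast SSE objective over log(k), log(K): family constants and the
# observation index map are computed once, each evaluation is one compiled
# trajectory plus a vectorized residual
make_hcm_objective <- function(families, params0, init, net, data, t_end, dt) {
  nf <- length(families)
  carbon <- setNames(net$metabolites$carbon, net$metabolites$id)
  ext <- unique(unlist(purrr::map(families, ~ names(.x$Z))))
  tracked <- intersect(names(init), ext)
  conc0 <- unname(unlist(init[tracked]))
  X0 <- init[["X"]]
  Zmat <- do.call(rbind, purrr::map(families, function(f) {
    z <- f$Z[tracked]; z[is.na(z)] <- 0; unname(z)
  }))
  Z_X <- purrr::map_dbl(families, "Z_X")
  pref_idx <- match(purrr::map_chr(families, "preferential"), tracked)
  cw <- vapply(families, function(f) {
    consumed <- names(f$Z)[f$Z < -FLUX_TOL]
    sum(abs(f$Z[consumed]) * carbon[consumed])
  }, numeric(1))
  n <- floor(t_end / dt) + 1L
  grid <- (seq_len(n) - 1L) * dt
  idx <- vapply(data$time, function(tt) which.min(abs(grid - tt)), integer(1))
  vars <- intersect(names(data), c("X", tracked))
  col_of <- c(X = 2L, setNames(2L + seq_along(tracked), tracked))
  obs <- as.matrix(data[, vars, drop = FALSE])
  cols <- col_of[vars]
  function(theta) {
    k <- exp(theta[seq_len(nf)])
    K <- exp(theta[nf + seq_len(nf)])
    out <- .hcm_core(k, K, params0$beta, params0$e0, cw, Zmat, Z_X,
                     as.integer(pref_idx), conc0, X0, n, dt, 1)
    sum((obs - out[idx, cols, drop = FALSE])^2)
  }
}

#' Fit HCM kinetic parameters with the printed genetic algorithm
#'
#' Initializes every `k = 1` and `K = 10`; each generation perturbs one
#' parameter per candidate by a random factor, runs a 200-step SSE-driven
#' local minimization (Nelder-Mead in log space) per candidate, then crosses
#' the best set with the second best by acquiring the second-best's perturbed
#' parameter. Stops on a constant SSE or after more than `max_stall`
#' generations without improvement, followed by a final local polish.
#' Deterministic for a fixed seed; best SSE is non-increasing across
#' generations.
#'
#' @param families,init,net As in [simulate_hcm()].
#' @param data Observed culture series (`time`, `X` and/or external
#'   metabolite columns).
#' @param seed Integer seed (required; every stochastic step draws from it).
#' @param params0 `cybernetic_params` supplying `alpha`, `beta`, `e0` (the
#'   GA only fits `k` and `K`).
#' @param t_end,dt Simulation grid for SSE evaluation.
#' @param local_steps Iterations of each local minimization (printed: 200).
#' @param max_stall Generations without improvement before stopping
#'   (printed: 10).
#' @return An object of class `hcm_fit`: `params` (fitted
#'   `cybernetic_params`), `sse`, `history` (best SSE per generation),
#'   `families`. With [tidy()]/[glance()] methods.
#' @export
fit_hcm_ga <- function(families, data, seed, params0, init, net,
                       t_end = max(data$time), dt = 0.1,
                       local_steps = 200, max_stall = 10) {
  if (sd(unlist(data[setdiff(names(data), "time")])) == 0) {
    abort("degenerate data: zero variance")
  }
  set.seed(seed)
  np <- length(families)
  obj <- make_hcm_objective(families, params0, init, net, data, t_end, dt)
  # the printed procedure asks for an SSE-driven numeric minimization of a
  # fixed step budget; an exploratory simplex pass followed by a bounded
  # quasi-Newton refine is robust against the k/K ridge degeneracy
  polish <- function(theta, steps) {
    o1 <- optim(theta, obj, method = "Nelder-Mead",
                control = list(maxit = steps))
    o2 <- optim(o1$par, obj, method = "L-BFGS-B",
                lower = log(1e-4), upper = log(1e4),
                control = list(maxit = steps, factr = 1e1,
                               ndeps = rep(1e-6, length(theta))))
    if (o2$value <= o1$value) o2 else o1
  }
  theta <- log(c(rep(1, np), rep(10, np)))
  cur <- polish(theta, local_steps)
  best <- cur$par; best_sse <- cur$value
  history <- best_sse
  stall <- 0L
  repeat {
    # one candidate per parameter, each perturbing that parameter only
    cand <- purrr::map(seq_along(best), function(j) {
      th <- best
      th[j] <- th[j] + log(stats::runif(1, 0.25, 4))
      o <- polish(th, local_steps)
      list(par = o$par, value = o$value, perturbed = j)
    })
    vals <- purrr::map_dbl(cand, "value")
    ord <- order(vals)
    b1 <- cand[[ord[1]]]; b2 <- cand[[ord[2]]]
    child <- b1$par
    child[b2$perturbed] <- b2$par[b2$perturbed]
    oc <- polish(child, local_steps)
    gen_best <- min(b1$value, oc$value)
    gen_par <- if (oc$value <= b1$value) oc$par else b1$par
    if (gen_best < best_sse - 1e-12) {
      improved <- best_sse - gen_best
      best_sse <- gen_best; best <- gen_par; stall <- 0L
      constant <- improved < 1e-10 * max(1, best_sse)
    } else {
      stall <- stall + 1L
      constant <- FALSE
    }
    history <- c(history, best_sse)
    if (constant || stall > max_stall) break
    if (length(history) > 60L) break # hard cap, defends the budget
  }
  final <- polish(best, max(local_steps, 400))
  if (final$value < best_sse) { best <- final$par; best_sse <- final$value }
  history <- c(history, best_sse)
  params <- params0
  params$k <- exp(best[seq_len(np)])
  params$K <- exp(best[np + seq_len(np)])
  structure(list(params = params, sse = best_sse, history = history,
                 families = families, seed = seed),
            class = "hcm_fit")
}

#' @export
print.hcm_fit <- function(x, ...) {
  cat("<hcm_fit> ", length(x$families), " families, SSE = ",
      format(x$sse), "\n", sep = "")
  invisible(x)
}

#' Tidy fitted cybernetic parameters
#' @param x An `hcm_fit`.
#' @param ... Unused.
#' @return Tibble `family`, `k`, `K`.
#' @export
tidy.hcm_fit <- function(x, ...) {
  tibble::tibble(family = purrr::map_chr(x$families, "label"),
                 k = x$params$k, K = x$params$K)
}

#' One-row GA fit summary
#' @param x An `hcm_fit`.
#' @param ... Unused.
#' @return One-row tibble with final SSE and generation count.
#' @export
glance.hcm_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, generations = length(x$history) - 2L,
                 monotone = !is.unsorted(rev(x$history)))
}
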