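# Exponential-phase dynamic metabolite profiles from a single (or lumped)
# elementary mode driven by the physiological biomass model: at every Euler
# step dM_i = (Z_i / Z_X) dX, where Z_i is the mode's signed net exchange of
# external metabolite i (negative = consumption) and Z_X its biomass flux.

# signed external exchange rates of a flux vector: rows of the external
# stoichiometric block times the flux
external_exchange <- function(net, v) {
  S_ext <- stoichiometric_matrix(net, rows = "external")
  if (!is.null(names(v))) v <- v[colnames(S_ext)]
  as.numeric(S_ext %*% v) |> setNames(rownames(S_ext))
}

#' Render dynamic metabolite profiles from one elementary mode
#'
#' @param em Named signed flux vector (a row of an `em_set`, or a
#'   `lumped_em`).
#' @param net The `rxn_network` the fluxes belong to.
#' @param params A `physio_params` driving the biomass trajectory.
#' @param init One-row data frame with `Xv`, `Xd` and an initial
#'   concentration column per external metabolite to track (missing ones
#'   start at 0).
#' @param horizon Horizon in h (default 48, the first exponential-phase
#'   section).
#' @param dt Euler step (h).
#' @return A `culture_series`-style tibble: `time`, `X`, `Xv`, `Xd`, one
#'   column per external metabolite.
#' @export
render_profiles <- function(em, net, params, init, horizon = 48, dt = 0.1) {
  p <- as_physio_params(params)
  if (dt <= 0) abort("dt must be > 0")
  Z <- external_exchange(net, em)
  if (is.null(net$biomass)) abort("network has no biomass reaction")
  Z_X <- em[[net$biomass]]
  if (abs(Z_X) <= FLUX_TOL) abort("mode has zero biomass flux; not renderable")
  ext <- names(Z)
  n <- floor(horizon / dt) + 1L
  X <- init$Xv[1] + (init$Xd[1] %||% 0); Xd <- init$Xd[1] %||% 0
  conc <- setNames(numeric(length(ext)), ext)
  for (m in ext) if (!is.null(init[[m]])) conc[m] <- init[[m]][1]
  out <- matrix(NA_real_, n, 4 + length(ext),
                dimnames = list(NULL, c("time", "X", "Xv", "Xd", ext)))
  out[1, ] <- c(0, X, X - Xd, Xd, conc)
  for (i in seq_len(n - 1L)) {
    X_new <- X + p$mu_max * X * (1 - X / p$X_max) * dt
    Xd_new <- Xd + p$k_d * Xd * dt
    dX <- X_new - X
    conc <- pmax(conc + (Z / Z_X) * dX, 0) # named arg first: pmax keeps its names
    X <- X_new; Xd <- Xd_new
    out[i + 1L, ] <- c(i * dt, X, X - Xd, Xd, conc)
  }
  res <- tibble::as_tibble(as.data.frame(out))
  class(res) <- c("culture_series", class(res))
  res
}

#' Compare EM selectors by dynamic-profile accuracy
#'
#' Renders the exponential-phase profile of each supplied selection and
#' scores it against observed data with the full metric set (SSE, PE, MAPE,
#' MPPE). CPU time per selection is measured and reported as informational
#' only.
#'
#' @param selections Named list of signed flux vectors (one per selector,
#'   e.g. the PSYA lump, a CMOA pick).
#' @param net,params,init,dt As in [render_profiles()].
#' @param data Observed culture series with a `time` column and one column
#'   per compared external metabolite.
#' @param variables Which data columns to score (default: every external
#'   metabolite present in the data).
#' @param horizon Comparison horizon (h); data beyond it are ignored.
#' @return A tibble: `selector`, `variable`, metric columns, `cpu_s`.
#' @export
compare_selectors <- function(selections, net, params, init, data,
                              variables = NULL, horizon = 48, dt = 0.1) {
  ext <- net$metabolites$id[net$metabolites$role == "external"]
  variables <- variables %||% intersect(names(data), ext)
  data <- data[data$time <= horizon + 1e-9, , drop = FALSE]
  purrr::imap_dfr(selections, function(v, nm) {
    t0 <- proc.time()[["elapsed"]]
    prof <- render_profiles(v, net, params, init, horizon = horizon, dt = dt)
    cpu <- proc.time()[["elapsed"]] - t0
    mod <- series_at(prof, data$time)
    purrr::map_dfr(variables, function(var) {
      dplyr::bind_cols(tibble::tibble(selector = nm, variable = var),
                       error_metrics(data[[var]], mod[[var]]))
    }) |> dplyr::mutate(cpu_s = cpu)
  })
}
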