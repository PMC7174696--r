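# Polar Space Yield Analysis (PSYA).
#
# A nonnegative yield vector Y = (Y_1, ..., Y_n) is re-described as a module
# lambda = ||Y|| and a hyperspherical angle sequence theta_1..theta_{n-1}
# with cos(theta_j) = ||Y[1..j]|| / ||Y[1..j+1]||, so theta_j in [0, 90]
# degrees for nonnegative yields: theta_1 = 0 means pure first-coordinate
# (GLC) consumption, theta_1 = 90 pure second-coordinate (GLN). Degenerate
# all-zero prefixes take theta = 90 by convention, which keeps the inverse
# map exact. Angles are degrees externally, radians internally.

#' Polar (module/angle) coordinates of a yield vector
#'
#' @param y Nonnegative numeric yield vector (length >= 2), not all zero.
#' @return A list of class `polar_point`: `lam` (Euclidean module), `theta`
#'   (degrees, length `length(y) - 1`), and the `ordering` (names of `y`,
#'   if any).
#' @export
to_polar <- function(y) {
  y <- unlist(y)
  if (any(y < 0)) abort("yields must be nonnegative")
  if (all(y == 0)) abort("all-zero yield vector has no polar direction")
  if (length(y) < 2L) abort("need at least two yield coordinates")
  pref <- sqrt(cumsum(y^2))
  n <- length(y)
  theta <- numeric(n - 1L)
  for (j in seq_len(n - 1L)) {
    if (pref[j + 1L] == 0) {
      theta[j] <- 90 # all-zero prefix convention
    } else {
      theta[j] <- rad2deg(acos(pmin(1, pref[j] / pref[j + 1L])))
    }
  }
  structure(list(lam = unname(pref[n]), theta = theta, ordering = names(y)),
            class = "polar_point")
}

#' Invert the polar transform
#'
#' @param p A `polar_point` (or a list with `lam` and `theta` in degrees).
#' @return The nonnegative yield vector; `to_polar(from_polar(p))` round-trips
#'   within 1e-9 relative.
#' @export
from_polar <- function(p) {
  lam <- p$lam
  theta <- deg2rad(p$theta)
  n <- length(theta) + 1L
  pref <- numeric(n)
  pref[n] <- lam
  for (j in seq(n - 1L, 1L)) pref[j] <- pref[j + 1L] * cos(theta[j])
  y <- numeric(n)
  y[1] <- pref[1]
  if (n > 1L) y[2:n] <- sqrt(pmax(0, pref[2:n]^2 - pref[1:(n - 1L)]^2))
  if (!is.null(p$ordering)) names(y) <- p$ordering
  y
}

#' Polar coordinates for every mode in yield space
#'
#' @param ems An `em_set`.
#' @param ordering Ordered reaction ids defining the yield coordinates
#'   (substrates before products, higher participation first).
#' @param normalizer Yield normalizer reaction (default biomass).
#' @return A tibble of class `em_polar`: `mode`, `lam`, `theta1..thetaK`
#'   (degrees), plus the yield columns; modes outside the yield space are
#'   dropped (recorded in the `dropped` attribute).
#' @export
polar_coords <- function(ems, ordering, normalizer = NULL) {
  yl <- efm_yields(ems, ordering, normalizer)
  dropped <- yl$mode[!yl$in_yield_space]
  yl <- yl[yl$in_yield_space, , drop = FALSE]
  Y <- as.matrix(yl[, ordering, drop = FALSE])
  pol <- purrr::map(seq_len(nrow(Y)), function(i) to_polar(Y[i, ]))
  th <- do.call(rbind, purrr::map(pol, "theta"))
  colnames(th) <- paste0("theta", seq_len(ncol(th)))
  out <- dplyr::bind_cols(
    tibble::tibble(mode = yl$mode, lam = purrr::map_dbl(pol, "lam")),
    tibble::as_tibble(as.data.frame(th)),
    yl[, ordering, drop = FALSE]
  )
  attr(out, "ordering") <- ordering
  attr(out, "dropped") <- dropped
  class(out) <- c("em_polar", class(out))
  out
}

#' Experimental yield point in polar form
#'
#' @param yields Named nonnegative vector of measured yields, in the same
#'   ordering used for the EM polar description.
#' @param source Free-text provenance note.
#' @return A list of class `experimental_point` with `gamma` (module),
#'   `phi` (angles, degrees), `yields`, `ordering`, `source`.
#' @export
experimental_point <- function(yields, source = "measured") {
  p <- to_polar(yields)
  structure(list(gamma = p$lam, phi = p$theta, yields = unlist(yields),
                 ordering = names(yields), source = source),
            class = "experimental_point")
}

#' Polar mismatch score between a mode and the experimental point
#'
#' `Upsilon = ((lam - Gamma)/Gamma)^2 + sum_j ((theta_j - Phi_j)/Phi_j)^2`;
#' components with `Phi_j = 0` use the absolute squared difference scaled by
#' 90 degrees instead of the undefined relative form. Zero iff the polar
#' points coincide. Scale-invariant in the underlying EM flux.
#'
#' @param em_polar A `polar_point` (or list with `lam`, `theta` in degrees).
#' @param exp An `experimental_point`.
#' @return Nonnegative scalar.
#' @export
score_em <- function(em_polar, exp) {
  if (exp$gamma == 0) abort("experimental module Gamma is zero")
  if (length(em_polar$theta) != length(exp$phi)) {
    abort("angle orderings of mode and experimental point do not match")
  }
  u_lam <- ((em_polar$lam - exp$gamma) / exp$gamma)^2
  phi <- exp$phi
  rel <- ifelse(phi > 0, (em_polar$theta - phi) / phi, (em_polar$theta - phi) / 90)
  u_lam + sum(rel^2)
}

upsilon_scores <- function(polar_tbl, exp) {
  ths <- grep("^theta", names(polar_tbl), value = TRUE)
  vapply(seq_len(nrow(polar_tbl)), function(i) {
    score_em(list(lam = polar_tbl$lam[i],
                  theta = as.numeric(polar_tbl[i, ths])), exp)
  }, numeric(1))
}

# distance in normalized polar coordinates (lam/Gamma, theta/90)
polar_dist <- function(a, b, gamma) {
  sqrt(((a$lam - b$lam) / gamma)^2 + sum(((a$theta - b$theta) / 90)^2))
}

# ---- active set selection -------------------------------------------------

new_active_set <- function(members, weights, contains_point, scores, residual,
                           certificate = NULL, method = "psya") {
  structure(list(members = members, weights = weights,
                 contains_point = contains_point, scores = scores,
                 residual = residual, certificate = certificate,
                 method = method),
            class = "active_set")
}

#' @export
print.active_set <- function(x, ...) {
  cat("<active_set> (", x$method, ") modes ", paste(x$members, collapse = ", "),
      if (x$contains_point) " [contains experimental point]" else
        " [point outside hull]",
      "\n", sep = "")
  invisible(x)
}

#' Tidy an active set
#' @param x An `active_set`.
#' @param ... Unused.
#' @return Tibble `mode`, `weight`, `upsilon`.
#' @export
tidy.active_set <- function(x, ...) {
  tibble::tibble(mode = x$members, weight = x$weights, upsilon = x$scores)
}

# containment of the experimental yields in the convex hull of member yields
containment_test <- function(Y_members, y_exp, tol = 1e-6) {
  sol <- convex_lsq(Y_members, y_exp, sum_to_one = TRUE)
  contained <- sol$residual <= tol
  certificate <- NULL
  if (!contained) {
    # separating direction from the least-distance point on the hull:
    # r . y_exp > max_i r . Y_i certifies non-containment
    r <- y_exp - sol$fitted
    certificate <- list(direction = r,
                        margin = sum(r * y_exp) - max(Y_members %*% r))
  }
  list(w = sol$w, residual = sol$residual, contained = contained,
       certificate = certificate)
}

#' PSYA: select a minimal active set of modes around the experimental point
#'
#' The first member minimizes the polar mismatch `Upsilon` (ties broken by
#' smallest mode index). Subsequent members are chosen greedily by
#' `dist(candidate, experimental point) - dist(candidate, centroid of the
#' already-selected members)` in normalized polar coordinates — drawn toward
#' the data while pushed away from the current set — until the experimental
#' point lies in the members' convex hull (nonnegative least-squares residual
#' at most `tol` on measured yields) or the member count reaches
#' `length(measured yields) + 1`. Fully deterministic.
#'
#' @param ems An `em_set`.
#' @param exp An `experimental_point`.
#' @param ordering Reaction ids of the measured yields, in the experimental
#'   ordering; defaults to the experimental point's own ordering.
#' @param normalizer Yield normalizer (default biomass).
#' @param tol Containment residual tolerance.
#' @return An `active_set`; when the point is outside the hull of all modes,
#'   `contains_point` is `FALSE`, a warning is emitted, the nearest-`Upsilon`
#'   set is returned and `certificate` holds a separating direction.
#' @export
select_active_set <- function(ems, exp, ordering = exp$ordering,
                              normalizer = NULL, tol = 1e-6) {
  pol <- polar_coords(ems, ordering, normalizer)
  if (nrow(pol) == 0L) abort("no mode has nonzero normalizer flux")
  ths <- grep("^theta", names(pol), value = TRUE)
  ups <- upsilon_scores(pol, exp)
  Y <- as.matrix(pol[, ordering, drop = FALSE])
  y_exp <- exp$yields
  max_size <- min(length(ordering) + 1L, nrow(pol))

  sel <- which.min(ups) # ties: which.min takes the first (smallest index)
  ct <- containment_test(Y[sel, , drop = FALSE], y_exp, tol)
  while (!ct$contained && length(sel) < max_size) {
    cand <- setdiff(seq_len(nrow(pol)), sel)
    centroid <- list(lam = mean(pol$lam[sel]),
                     theta = colMeans(pol[sel, ths, drop = FALSE]))
    exp_pt <- list(lam = exp$gamma, theta = exp$phi)
    score <- vapply(cand, function(i) {
      ci <- list(lam = pol$lam[i], theta = as.numeric(pol[i, ths]))
      polar_dist(ci, exp_pt, exp$gamma) - polar_dist(ci, centroid, exp$gamma)
    }, numeric(1))
    sel <- c(sel, cand[which.min(score)])
    ct <- containment_test(Y[sel, , drop = FALSE], y_exp, tol)
  }
  if (!ct$contained) {
    warn("experimental point is outside the convex hull of the candidate modes; returning nearest-Upsilon set")
  }
  new_active_set(members = pol$mode[sel], weights = ct$w,
                 contains_point = ct$contained, scores = ups[sel],
                 residual = ct$residual, certificate = ct$certificate,
                 method = "psya")
}

#' Lump an active set into one virtual mode (LPSYA / LYSA)
#'
#' Members are rescaled to unit biomass (normalizer) flux and combined with
#' the active set's convex weights; by linearity the lump satisfies the
#' steady-state balance, but it is a "virtual" mode — support-minimality is
#' not preserved.
#'
#' @param aset An `active_set`.
#' @param ems The `em_set` it indexes into.
#' @param normalizer Normalizer reaction id (default biomass).
#' @return Named signed flux vector of class `lumped_em` with a `weights`
#'   attribute; `virtual` attribute flags a best-approximation lump when the
#'   point was not contained.
#' @export
lump_modes <- function(aset, ems, normalizer = NULL) {
  normalizer <- normalizer %||% ems$network$biomass
  M <- ems$modes[aset$members, , drop = FALSE]
  M <- M / abs(M[, normalizer])
  v <- as.numeric(t(M) %*% aset$weights)
  names(v) <- colnames(ems$modes)
  structure(v, class = "lumped_em", weights = aset$weights,
            members = aset$members, virtual = TRUE,
            approximate = !aset$contains_point)
}

# ---- CMOA baseline --------------------------------------------------------

CMOA_OBJECTIVES <- c("max_biomass_per_glc", "max_biomass_per_gln",
                     "max_atp_per_glc", "max_atp_per_gln",
                     "max_atp_per_flux", "max_biomass_per_flux",
                     "max_glc_per_biomass", "max_gln_per_biomass",
                     "max_atp_per_step", "min_steps", "min_flux")

#' Common Metabolic Objective Analysis: pick one mode by an FBA-style objective
#'
#' Flux magnitudes are used throughout; "flux units" is the sum of absolute
#' fluxes of the mode normalized to unit biomass flux (so it is
#' scale-independent), and "reaction steps" is the support size. Modes with a
#' zero denominator are excluded; ties break to the lowest mode index.
#'
#' @param ems An `em_set`.
#' @param objective One of `"max_biomass_per_glc"`, `"max_biomass_per_gln"`,
#'   `"max_atp_per_glc"`, `"max_atp_per_gln"`, `"max_atp_per_flux"`,
#'   `"max_biomass_per_flux"`, `"max_glc_per_biomass"`,
#'   `"max_gln_per_biomass"`, `"max_atp_per_step"`, `"min_steps"`,
#'   `"min_flux"`.
#' @param roles Named list mapping the roles `biomass`, `glc`, `gln`, `atp`
#'   to reaction ids; defaults to the network's `roles` attribute when the
#'   network was built by [toy_network()].
#' @return A list: `mode` (index), `value` (objective value), `flux` (the
#'   mode's named flux vector).
#' @export
cmoa_select <- function(ems, objective, roles = attr(ems$network, "roles")) {
  objective <- match.arg(objective, CMOA_OBJECTIVES)
  M <- abs(ems$modes)
  if (nrow(M) == 0L) abort("empty EM set")
  get_role <- function(r) {
    id <- roles[[r]] %||% if (r == "biomass") ems$network$biomass else NULL
    if (is.null(id)) abort(paste0("objective needs a '", r, "' role reaction"))
    M[, id]
  }
  steps <- rowSums(M > FLUX_TOL)
  val <- switch(objective,
    max_biomass_per_glc = get_role("biomass") / get_role("glc"),
    max_biomass_per_gln = get_role("biomass") / get_role("gln"),
    max_atp_per_glc = get_role("atp") / get_role("glc"),
    max_atp_per_gln = get_role("atp") / get_role("gln"),
    max_atp_per_flux = get_role("atp") / rowSums(M),
    max_biomass_per_flux = get_role("biomass") / rowSums(M),
    max_glc_per_biomass = get_role("glc") / get_role("biomass"),
    max_gln_per_biomass = get_role("gln") / get_role("biomass"),
    max_atp_per_step = get_role("atp") / steps,
    min_steps = steps,
    min_flux = rowSums(M / ifelse(get_role("biomass") > FLUX_TOL,
                                  get_role("biomass"), NA_real_))
  )
  minimize <- objective %in% c("min_steps", "min_flux")
  val[!is.finite(val)] <- NA_real_
  if (all(is.na(val))) abort("objective undefined on every mode (zero denominators)")
  idx <- if (minimize) which.min(val) else which.max(val)
  list(mode = idx, value = val[idx],
       flux = setNames(ems$modes[idx, ], colnames(ems$modes)),
       objective = objective)
}

# ---- simplified YSA baseline ---------------------------------------------

# volume of the simplex spanned by the rows of P (k points in d dims)
simplex_volume <- function(P) {
  k <- nrow(P)
  if (k < 2L) return(0)
  E <- sweep(P[-1, , drop = FALSE], 2L, P[1, ])
  G <- E %*% t(E)
  d <- det(G)
  if (d <= 0) return(0)
  sqrt(d) / factorial(k - 1L)
}

#' Simplified Yield Space Analysis selector (YSA/LYSA baseline)
#'
#' A documented simplification of the Song–Ramkrishna yield-space method:
#' the first member is the mode nearest the experimental point in Cartesian
#' measured-yield space; further members are chosen greedily to maximize the
#' enclosing simplex volume among candidates that strictly reduce the
#' convex-combination residual, until the point is contained or the
#' `length(measured) + 1` cap is reached. Lumping the result with
#' [lump_modes()] gives the LYSA combination.
#'
#' @inheritParams select_active_set
#' @return An `active_set` with `method = "ysa"`.
#' @export
ysa_select <- function(ems, exp, ordering = exp$ordering, normalizer = NULL,
                       tol = 1e-6) {
  yl <- efm_yields(ems, ordering, normalizer)
  yl <- yl[yl$in_yield_space, , drop = FALSE]
  if (nrow(yl) == 0L) abort("no mode has nonzero normalizer flux")
  Y <- as.matrix(yl[, ordering, drop = FALSE])
  y_exp <- exp$yields
  max_size <- min(length(ordering) + 1L, nrow(Y))
  d2 <- rowSums(sweep(Y, 2L, y_exp)^2)
  sel <- which.min(d2)
  ct <- containment_test(Y[sel, , drop = FALSE], y_exp, tol)
  while (!ct$contained && length(sel) < max_size) {
    cand <- setdiff(seq_len(nrow(Y)), sel)
    gain <- vapply(cand, function(i) {
      cti <- containment_test(Y[c(sel, i), , drop = FALSE], y_exp, tol)
      if (cti$residual < ct$residual - 1e-12) {
        simplex_volume(Y[c(sel, i), , drop = FALSE])
      } else {
        -Inf
      }
    }, numeric(1))
    if (all(!is.finite(gain))) break
    sel <- c(sel, cand[which.max(gain)])
    ct <- containment_test(Y[sel, , drop = FALSE], y_exp, tol)
  }
  if (!ct$contained) {
    warn("experimental point not contained; returning best-residual YSA set")
  }
  pol <- polar_coords(ems, ordering, normalizer)
  ups <- setNames(upsilon_scores(pol, exp), pol$mode)
  new_active_set(members = yl$mode[sel], weights = ct$w,
                 contains_point = ct$contained,
                 scores = unname(ups[as.character(yl$mode[sel])]),
                 residual = ct$residual, certificate = ct$certificate,
                 method = "ysa")
}
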