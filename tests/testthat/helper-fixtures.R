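# Shared fixtures: all built in code, nothing on disk.

# canonical row-sorted form for comparing EM sets (scale to max-abs 1, round,
# sort rows) — independent of either enumerator's internal conventions
canon_modes <- function(M) {
  if (nrow(M) == 0L) return(unname(M))
  M <- t(apply(M, 1L, function(v) { m <- max(abs(v)); if (m > 0) v / m else v }))
  M <- round(M, 6)
  unname(M[order(apply(M, 1L, paste, collapse = ",")), , drop = FALSE])
}

expect_same_modes <- function(a, b) {
  expect_equal(canon_modes(a$modes), canon_modes(b$modes), tolerance = 1e-6)
}

# the package's stated synthetic batch world: plausible CHO-scale kinetics
# for a 144 h culture started at 28 mM GLC / 8 mM GLN
truth_physio <- function() {
  physio_params(mu_max = 0.035, X_max = 18, k_d = 0.004,
                q_g_e = -0.35, q_g_s = -0.05,
                q_n_e = -0.12, q_n_s = -0.02,
                q_l_e = 0.5, q_l_s = -0.08,
                q_u_e = 0.06, q_u_s = 0.01,
                K_g = 1.0, K_n = 0.5, K_l = 2.0)
}

# optimizer start: truth uniformly off by +30%
offset_guess <- function(p, factor = 1.3) {
  for (nm in setdiff(names(p), "biomass_conversion")) p[[nm]] <- p[[nm]] * factor
  p
}

tiny_met <- function(id, role, carbon = 0) {
  tibble::tibble(id = id, name = id, role = role, compartment = "c",
                 carbon = carbon)
}

tiny_rxn <- function(id, eq) {
  p <- polarflux:::parse_equation(eq, id)
  tibble::tibble(id = id, reversible = p$reversible, stoich = list(p$stoich))
}

# two-family diauxic network: growth on glucose with lactate overflow,
# then growth on the accumulated lactate
diauxic_net <- function() {
  rxn_network(
    dplyr::bind_rows(
      tiny_met("GLCx", "external", 6), tiny_met("LACx", "external", 3),
      tiny_met("Xx", "external", 0),
      tiny_met("GLC", "internal", 6), tiny_met("PYR", "internal", 3),
      tiny_met("LAC", "internal", 3), tiny_met("X", "internal", 0)
    ),
    dplyr::bind_rows(
      tiny_rxn("r1", "GLCx -> GLC"), tiny_rxn("r2", "GLC -> 2 PYR"),
      tiny_rxn("r3", "PYR -> LAC"), tiny_rxn("r4", "LAC -> LACx"),
      tiny_rxn("r5", "PYR -> X"), tiny_rxn("r6", "X -> Xx"),
      tiny_rxn("r7", "LACx -> LAC"), tiny_rxn("r8", "LAC -> PYR")
    ),
    biomass = "r6"
  )
}

diauxic_families <- function(net = diauxic_net()) {
  v1 <- setNames(c(1, 1, 1, 1, 1, 1, 0, 0), net$reactions$id)
  v2 <- setNames(c(0, 0, 0, 0, 2, 2, 2, 2), net$reactions$id)
  list(glc = hcm_family(v1, net, "GLCx", "glc"),
       lac = hcm_family(v2, net, "LACx", "lac"))
}

truth_cybernetic <- function() {
  cybernetic_params(k = c(0.3, 0.15), K = c(0.8, 1.5),
                    alpha = 0.01, beta = 0.05)
}

hcm_init <- function() c(X = 0.25, GLCx = 28, LACx = 0)

# fan fixture: no internal metabolites, so any flux vector is steady-state;
# modes sit at evenly spaced polar angles in the (other, targ) yield plane
fan_fixture <- function(angles = seq(5, 85, by = 10)) {
  net <- rxn_network(
    dplyr::bind_rows(tiny_met("A", "external"), tiny_met("B", "external"),
                     tiny_met("C", "external"), tiny_met("Xx", "external")),
    dplyr::bind_rows(tiny_rxn("other", "A -> B"), tiny_rxn("targ", "A -> C"),
                     tiny_rxn("vb", "A -> Xx")),
    biomass = "vb"
  )
  M <- cbind(other = cos(angles * pi / 180),
             targ = sin(angles * pi / 180), vb = 1)
  list(net = net, ems = as_em_set(M, net), angles = angles)
}

# hand-built yield triangle whose members are affinely independent, plus the
# experimental point at known convex weights 0.5/0.3/0.2
triangle_fixture <- function() {
  net <- rxn_network(
    dplyr::bind_rows(tiny_met("S", "external"), tiny_met("P", "external"),
                     tiny_met("Q", "external"), tiny_met("Xx", "external")),
    dplyr::bind_rows(tiny_rxn("up", "S -> P"), tiny_rxn("sec", "S -> Q"),
                     tiny_rxn("vb", "S -> Xx")),
    biomass = "vb"
  )
  M <- rbind(c(up = 1.0, sec = 0.2, vb = 1),
             c(up = 0.2, sec = 1.5, vb = 1),
             c(up = 2.0, sec = 1.0, vb = 1))
  w <- c(0.5, 0.3, 0.2)
  yexp <- setNames(as.numeric(w %*% M[, c("up", "sec")]), c("up", "sec"))
  list(net = net, ems = as_em_set(M, net), weights = w,
       exp = experimental_point(yexp))
}
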