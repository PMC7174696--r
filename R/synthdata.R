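# Synthetic fixtures: toy networks with exactly known EM sets, an
# independent brute-force EM oracle (deliberately naive, no code shared with
# the enumeration engine), and noisy culture time series sampled the way the
# emulated batch design does (every 24 h to 144 h, 28 mM GLC / 8 mM GLN).

#' Construct a toy metabolic network
#'
#' Kinds: `"linear_chain"` (n irreversible reactions, exactly 1 EM),
#' `"diamond"` (two routes, exactly 2 EM), `"glycolysis_mini"` (6-carbon
#' substrate, ATP, overflow product, biomass; exercises the CMOA
#' objectives), `"two_substrate_mini"` (6-C and 5-C substrates, overflow and
#' secondary products, biomass; includes zero-biomass modes, so the
#' not-in-yield-space path is exercised), `"random"` (seeded sparse network
#' for oracle-equivalence testing; at most 14 reactions after splitting).
#'
#' @param kind Network kind.
#' @param n Chain length for `"linear_chain"`; reaction count for
#'   `"random"`.
#' @param seed Seed for `"random"`.
#' @return A validated `rxn_network` with a `roles` attribute naming
#'   `biomass`, `glc`, `gln`, `atp` reactions where present.
#' @export
toy_network <- function(kind = c("linear_chain", "diamond", "glycolysis_mini",
                                 "two_substrate_mini", "random"),
                        n = 3L, seed = 1L) {
  kind <- match.arg(kind)
  met <- function(id, role, carbon = 0, compartment = "cytosol") {
    tibble::tibble(id = id, name = id, role = role,
                   compartment = compartment, carbon = carbon)
  }
  rxn <- function(id, eq) {
    p <- parse_equation(eq, id)
    tibble::tibble(id = id, reversible = p$reversible, stoich = list(p$stoich))
  }
  if (kind == "linear_chain") {
    stopifnot(n >= 2L)
    ids <- paste0("M", seq_len(n - 1L))
    mets <- dplyr::bind_rows(met("Ain", "external"), met("Aout", "external"),
                             met(ids, "internal"))
    eqs <- c(paste("Ain ->", ids[1]),
             if (n > 2L) paste(ids[-(n - 1L)], "->", ids[-1]),
             paste(ids[n - 1L], "-> Aout"))
    rxns <- dplyr::bind_rows(purrr::map2(paste0("v", seq_len(n)), eqs, rxn))
    return(rxn_network(mets, rxns))
  }
  if (kind == "diamond") {
    mets <- dplyr::bind_rows(met(c("Ax", "Dx"), "external"),
                             met(c("A", "B", "C", "D"), "internal"))
    rxns <- dplyr::bind_rows(
      rxn("vin", "Ax -> A"), rxn("v1", "A -> B"), rxn("v2", "A -> C"),
      rxn("v3", "B -> D"), rxn("v4", "C -> D"), rxn("vout", "D -> Dx")
    )
    return(rxn_network(mets, rxns))
  }
  if (kind == "glycolysis_mini") {
    mets <- dplyr::bind_rows(
      met("GLCx", "external", 6), met("LACx", "external", 3),
      met("Xx", "external", 0),
      met("GLC", "internal", 6), met("PYR", "internal", 3),
      met("ATP", "internal", 0)
    )
    rxns <- dplyr::bind_rows(
      rxn("g1", "GLCx -> GLC"),
      rxn("g2", "GLC -> 2 PYR + 2 ATP"),
      rxn("g3", "PYR -> LACx"),
      rxn("g4", "PYR + ATP -> Xx"),
      rxn("g5", "ATP -> ") # maintenance sink
    )
    net <- rxn_network(mets, rxns, biomass = "g4")
    attr(net, "roles") <- list(biomass = "g4", glc = "g1", atp = "g5")
    return(net)
  }
  if (kind == "two_substrate_mini") {
    mets <- dplyr::bind_rows(
      met("GLCx", "external", 6), met("GLNx", "external", 5),
      met("LACx", "external", 3), met("GLUx", "external", 5),
      met("CO2x", "external", 1), met("Xx", "external", 0),
      met("GLC", "internal", 6), met("GLN", "internal", 5),
      met("PYR", "internal", 3), met("LAC", "internal", 3),
      met("GLU", "internal", 5), met("X", "internal", 0)
    )
    rxns <- dplyr::bind_rows(
      rxn("v1", "GLCx -> GLC"),
      rxn("v2", "GLNx -> GLN"),
      rxn("v3", "GLC -> 2 PYR"),
      rxn("v4", "PYR -> LAC"),
      rxn("v5", "LAC -> LACx"),
      rxn("v6", "GLN -> GLU"),
      rxn("v7", "GLU -> GLUx"),
      rxn("v8", "PYR + GLN -> X"),   # growth on GLC + GLN
      rxn("v9", "2 GLN -> PYR + GLU + 2 CO2x"), # glutaminolysis-like
      rxn("v10", "2 PYR + GLU -> X"),
      rxn("v11", "X -> Xx")          # biomass export, the yield normalizer
    )
    net <- rxn_network(mets, rxns, biomass = "v11")
    attr(net, "roles") <- list(biomass = "v11", glc = "v1", gln = "v2")
    return(net)
  }
  # random: seeded sparse network, guaranteed <= 14 columns after splitting
  stopifnot(n >= 3L)
  withr_seed <- function(code) { # local seed without touching global RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  withr_seed(function() {
    n_int <- sample(2:4, 1)
    ints <- paste0("I", seq_len(n_int))
    exts <- c("SRCx", "SNKx")
    mets <- dplyr::bind_rows(met(exts, "external"), met(ints, "internal"))
    n_rev_budget <- max(0L, 14L - n)
    rxns <- purrr::map_dfr(seq_len(n), function(j) {
      kind_j <- sample(c("exchange_in", "exchange_out", "convert"), 1,
                       prob = c(0.2, 0.2, 0.6))
      if (kind_j == "exchange_in") {
        st <- setNames(c(-1, 1), c("SRCx", sample(ints, 1)))
      } else if (kind_j == "exchange_out") {
        st <- setNames(c(-1, 1), c(sample(ints, 1), "SNKx"))
      } else {
        k_in <- sample(ints, sample(1:2, 1))
        k_out <- sample(setdiff(ints, k_in), min(sample(1:2, 1), n_int - length(k_in)))
        if (length(k_out) == 0L) k_out <- "SNKx"
        st <- c(setNames(rep(-sample(1:2, 1), length(k_in)), k_in),
                setNames(rep(sample(1:2, 1), length(k_out)), k_out))
      }
      tibble::tibble(id = paste0("v", j), reversible = stats::runif(1) < 0.25,
                     stoich = list(st))
    })
    # respect the split-size cap
    n_rev <- sum(rxns$reversible)
    if (n + n_rev > 14L) {
      drop <- which(rxns$reversible)[seq_len(n + n_rev - 14L)]
      rxns$reversible[drop] <- FALSE
    }
    rxn_network(mets, rxns)
  })
}

#' Brute-force elementary mode oracle
#'
#' Exhaustively enumerates every support subset of the (original, signed)
#' reaction set, keeps supports whose restricted stoichiometric matrix has a
#' one-dimensional nullspace with a sign-feasible flux (irreversible
#' reactions all nonnegative, after an optional global sign flip), and
#' discards strict supersets of feasible supports. Provably complete by
#' exhaustion; shares no code with [enumerate_efms()].
#'
#' @param net A `rxn_network` with at most `max_reactions` reactions after
#'   splitting.
#' @param max_reactions Size cap (default 14).
#' @return An `em_set` (canonicalized like the engine's, so sets compare
#'   directly).
#' @export
brute_force_efms <- function(net, max_reactions = 14L) {
  n_split <- nrow(net$reactions) + sum(net$reactions$reversible)
  if (n_split > max_reactions) {
    abort(paste0("split network has ", n_split, " reactions; oracle cap is ",
                 max_reactions))
  }
  S <- stoichiometric_matrix(net, rows = "internal")
  q <- ncol(S)
  rev_flags <- net$reactions$reversible
  accepted_supports <- list()
  modes <- list()
  for (size in seq_len(q)) {
    combs <- utils::combn(q, size, simplify = FALSE)
    for (supp in combs) {
      if (any(vapply(accepted_supports, function(a) all(a %in% supp), logical(1)))) next
      N <- nullspace(S[, supp, drop = FALSE])
      if (ncol(N) != 1L) next
      v <- as.numeric(N)
      v <- v / max(abs(v))
      if (any(abs(v) <= 1e-9)) next # support not fully used -> smaller support exists
      irr <- !rev_flags[supp]
      feasible <- all(v[irr] > 0) || all(v[irr] < 0)
      if (!feasible) next
      if (any(irr) && all(v[irr] < 0)) v <- -v
      full <- numeric(q)
      full[supp] <- v
      accepted_supports[[length(accepted_supports) + 1L]] <- supp
      modes[[length(modes) + 1L]] <- full
    }
  }
  M <- do.call(rbind, modes)
  if (is.null(M)) M <- matrix(numeric(0), 0, q)
  if (nrow(M) > 0L) M <- t(apply(M, 1L, canonical_mode, reversible = rev_flags))
  colnames(M) <- net$reactions$id
  new_em_set(dedup_modes(M), net, provenance = list("brute_force"))
}

#' Generate a noisy synthetic batch-culture series
#'
#' Simulates the physiological model at `dt = 0.1` h, subsamples to the
#' sampling grid (default every 24 h to 144 h, the emulated experimental
#' design), and applies seeded multiplicative Gaussian noise
#' (`value * (1 + sigma * z)`, floored at 0; additive optional). The truth
#' parameters are attached as the `truth` attribute for recovery tests.
#'
#' @param params Truth `physio_params`.
#' @param grid Sampling times (h).
#' @param sigma Noise level as a fraction (>= 0).
#' @param seed Integer seed; same seed, same series.
#' @param init Initial condition (default [culture_init()]).
#' @param noise `"multiplicative"` (analyzer-like, default) or `"additive"`.
#' @param dt Simulation step.
#' @return A `culture_series` tibble at the grid times.
#' @export
synth_culture <- function(params, grid = seq(0, 144, by = 24), sigma = 0.05,
                          seed = 1L, init = culture_init(),
                          noise = c("multiplicative", "additive"), dt = 0.1) {
  noise <- match.arg(noise)
  if (sigma < 0) abort("sigma must be >= 0")
  sim <- simulate_culture(params, t_end = max(grid), dt = dt, init = init)
  obs <- series_at(sim, grid)
  vars <- c("Xv", "Xd", "GLC", "GLN", "LAC", "GLU")
  if (sigma > 0) {
    set.seed(seed)
    for (v in vars) {
      z <- stats::rnorm(nrow(obs))
      obs[[v]] <- if (noise == "multiplicative") {
        pmax(0, obs[[v]] * (1 + sigma * z))
      } else {
        pmax(0, obs[[v]] + sigma * z)
      }
    }
  }
  obs$X <- obs$Xv + obs$Xd
  attr(obs, "truth") <- params
  class(obs) <- c("culture_series", class(obs))
  obs
}
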