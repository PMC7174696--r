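# Random truth sets for the parameter-recovery harness. Sampled kinetics are
# screened so that every fitted parameter actually acts on the sampled
# trajectory (GLN persisting into the stationary phase, GLC exhausted, a
# visible LAC decline): a parameter with zero trajectory sensitivity cannot
# be recovered by any estimator.
random_truth_physio <- function() {
  repeat {
    p <- physio_params(
      mu_max = runif(1, 0.025, 0.05), X_max = runif(1, 12, 25),
      k_d = runif(1, 0.002, 0.008),
      q_g_e = runif(1, -0.5, -0.2), q_g_s = runif(1, -0.1, -0.02),
      q_n_e = runif(1, -0.2, -0.06), q_n_s = runif(1, -0.04, -0.01),
      q_l_e = runif(1, 0.3, 0.6), q_l_s = runif(1, -0.12, -0.04),
      q_u_e = runif(1, 0.03, 0.09), q_u_s = runif(1, 0.005, 0.02),
      K_g = runif(1, 0.5, 2), K_n = runif(1, 0.3, 1), K_l = runif(1, 1, 3)
    )
    sim <- simulate_culture(p)
    gln96 <- sim$GLN[sim$time == 96]
    lac_drop <- (max(sim$LAC) - sim$LAC[nrow(sim)]) / max(sim$LAC)
    if (gln96 > 0.3 && lac_drop > 0.15 && sim$GLC[sim$time == 96] < 1) return(p)
  }
}
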