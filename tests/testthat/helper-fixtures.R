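# Small designs and parameter sets reused across tests.

tiny_design <- function(traits = c("y", "PY"), lines = 6, reps = 3,
                        treatments = default_treatments(2),
                        varieties = "V1", generations = c("M2", "M3")) {
  trial_design(varieties = varieties, treatments = treatments,
               seeds_per_treatment = 300, replications = reps,
               lines_per_treatment = lines, generations = generations,
               traits = traits)
}

tiny_params <- function(sigma_g = c(y = 8, PY = 25),
                        sigma_e = c(y = 2, PY = 25),
                        path = c(y = 0.6), shifts = NULL) {
  sim_params(means = c(y = 50, PY = 100), shifts = shifts,
             sigma_g = sigma_g, sigma_e = sigma_e,
             path_coefficients = path)
}

# hand-built trait table: 3 lines x 2 reps, MSG = 32, MSE = 2
hand_anova_table <- function() {
  tibble::tibble(
    variety = "V", generation = "M2", treatment = "C",
    line = rep(c("A", "B", "C"), each = 2), replicate = rep(1:2, 3),
    trait = "y", value = c(10, 12, 14, 16, 18, 20)
  )
}
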