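# Small models shared across tests; everything is built in code.

# One unregulated gene: m(t) = pro (1 - e^-t), P_ss = rbs * pro / deg.
single_gene_model <- function(pro = 2, rbs = 3, deg = 0.5) {
  spec <- network_spec(list(gene_spec("g1")), list(), "mrna_protein")
  model_instance(spec, c(g1_pro = pro, g1_rbs = rbs,
                         p_degradation_rate = deg))
}

# g1 (unregulated) represses g2; activation variant selectable.
two_gene_model <- function(sign = "repression", Kd = 1, h = 2) {
  spec <- network_spec(
    list(gene_spec("g1"), gene_spec("g2")),
    list(regulation_spec("r1", "g1", "g2", sign)),
    "mrna_protein"
  )
  model_instance(spec, c(
    g1_pro = 2, g2_pro = 3, g1_rbs = 1, g2_rbs = 1.5,
    r1_Kd = Kd, r1_h = h, p_degradation_rate = 0.5
  ))
}

# Three-gene cascade used for parameter-recovery tests:
# g1 (unregulated) -| g2 -> g3.
cascade_spec <- function() {
  network_spec(
    list(gene_spec("g1"), gene_spec("g2"), gene_spec("g3")),
    list(regulation_spec("r1", "g1", "g2", "repression"),
         regulation_spec("r2", "g2", "g3", "activation")),
    "mrna_protein"
  )
}

cascade_truth <- function() {
  c(g1_pro = 1.5, g2_pro = 2.5, g3_pro = 2.0,
    g1_rbs = 1.2, g2_rbs = 0.8, g3_rbs = 1.5,
    r1_Kd = 1.0, r1_h = 2, r2_Kd = 0.8, r2_h = 2,
    p_degradation_rate = 0.5)
}

# Protein-only repressilator; sustained oscillations from asymmetric ICs.
repressilator_model <- function() {
  spec <- network_spec(
    list(gene_spec("g1"), gene_spec("g2"), gene_spec("g3")),
    list(regulation_spec("r1", "g1", "g2", "repression"),
         regulation_spec("r2", "g2", "g3", "repression"),
         regulation_spec("r3", "g3", "g1", "repression")),
    "protein_only"
  )
  model_instance(
    spec,
    c(r1_syn = 10, r2_syn = 10, r3_syn = 10,
      r1_Kd = 1, r2_Kd = 1, r3_Kd = 1,
      r1_h = 4, r2_h = 4, r3_h = 4,
      g1_deg = 1, g2_deg = 1, g3_deg = 1),
    initial_conditions = c(p_g1 = 2, p_g2 = 0.1, p_g3 = 0.5)
  )
}

# Dense two-protein fluorescence-style dataset from a model, optionally
# noise-free (for oracle-style fitting tests).
make_dataset <- function(model, species, step = 1, t_end = 20,
                         perturbations = list(), seed = NULL,
                         noise = TRUE) {
  pert <- Reduce(apply_perturbation, perturbations, model)
  grid <- time_grid(0, t_end, step)
  traj <- simulate_model(pert, grid)
  clean <- traj$values[, species, drop = FALSE]
  values <- if (noise) add_noise(clean, seed = seed) else clean
  structure(
    list(values = values, grid = grid, times = grid$times,
         species = species, perturbations = perturbations,
         technology = "fluorescence", resolution = "high",
         cost = 0, seed = seed),
    class = "grn_dataset"
  )
}
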