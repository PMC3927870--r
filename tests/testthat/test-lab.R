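test_that("noise arithmetic follows v + sb*g1 + ss*g2*v with clipping", {
  nm <- noise_model()
  v <- c(0, 1, 10)
  # explicit draws: identity when g1 = g2 = 0
  expect_equal(add_noise(v, nm, g1 = rep(0, 3), g2 = rep(0, 3)), v)
  # v=1, g1=1, g2=0 -> 1.1
  expect_equal(add_noise(1, nm, g1 = 1, g2 = 0), 1.1)
  # clipping at zero
  expect_equal(add_noise(0.05, nm, g1 = -10, g2 = 0), 0)
  nm_noclip <- noise_model(clip_at_zero = FALSE)
  expect_equal(add_noise(0.05, nm_noclip, g1 = -10, g2 = 0), 0.05 - 1)
  # reproducible given seed; consumes the stream otherwise
  expect_identical(add_noise(v, nm, seed = 9), add_noise(v, nm, seed = 9))
})

test_that("noise moments: ~20% relative SD at large signal, >= 0 at zero", {
  nm <- noise_model()
  draws <- add_noise(rep(1000, 1e5), nm, seed = 101)
  expect_gt(sd(draws) / 1000, 0.19)
  expect_lt(sd(draws) / 1000, 0.21)
  zeros <- add_noise(rep(0, 1e4), nm, seed = 102)
  expect_true(all(zeros >= 0))
  # at small v the SD approaches the baseline 0.1
  small <- add_noise(rep(0.001, 1e5), noise_model(clip_at_zero = FALSE),
                     seed = 103)
  expect_equal(sd(small), 0.1, tolerance = 0.02)
})

test_that("ledger conserves credits and rejects overdrafts untouched", {
  led <- credit_ledger(5000)
  led <- debit(led, "fluorescence [wildtype]", 400)
  led <- debit(led, "gelshift [r1]", 1600)
  expect_equal(led$balance, 3000)
  expect_equal(led$budget - sum(led$transactions$cost), led$balance)
  before <- led
  expect_error(debit(led, "too expensive", 4000), "insufficient credits",
               class = "grnlab_budget_error")
  expect_identical(before, led)
  expect_error(credit_ledger(0))
})

test_that("perturbations act on the right constants and are pure", {
  m <- two_gene_model()
  kd <- apply_perturbation(m, perturbation("sirna_knockdown", "g1"))
  expect_equal(unname(kd$mrna_deg_factor["g1"]), 10)
  expect_equal(unname(m$mrna_deg_factor["g1"]), 1) # original untouched

  rb <- apply_perturbation(m, perturbation("rbs_decrease", "g2"))
  expect_equal(unname(rb$params["g2_rbs"]), unname(m$params["g2_rbs"]) / 10)

  ps <- apply_perturbation(m, perturbation("parameter_scale", "g1_rbs",
                                           factor = 2))
  ps <- apply_perturbation(ps, perturbation("parameter_scale", "g1_rbs",
                                            factor = 0.5))
  expect_equal(ps$params, m$params) # inverse round trip

  expect_error(apply_perturbation(m, perturbation("deletion", "gX")),
               "unknown gene")
  expect_error(
    apply_perturbation(m, perturbation("parameter_scale", "nope", factor = 2)),
    "unknown parameter")
})

test_that("knockdown shifts the steady state by the closed form", {
  # unregulated gene: m_ss = pro / delta_m, so a 10x knockdown gives m_ss/10
  m <- single_gene_model(pro = 2)
  kd <- apply_perturbation(m, perturbation("sirna_knockdown", "g1"))
  ss <- steady_state(kd)
  expect_equal(unname(ss$state["m_g1"]), 2 / 10, tolerance = 1e-7)
})

test_that("deletion silences mRNA and protein over any horizon", {
  m <- two_gene_model()
  del <- apply_perturbation(m, perturbation("deletion", "g1"))
  traj <- simulate_model(del, time_grid(0, 30, 1))
  expect_true(all(traj$values[, c("m_g1", "p_g1")] == 0))
  # with its repressor gone, g2 runs at full promoter strength
  expect_equal(traj$values[nrow(traj$values), "m_g2"][[1]],
               unname(m$params["g2_pro"]), tolerance = 1e-6)
})

test_that("protein_only perturbation semantics target protein kinetics", {
  rep3 <- repressilator_model()
  kd <- apply_perturbation(rep3, perturbation("sirna_knockdown", "g2"))
  expect_equal(unname(kd$params["g2_deg"]), 10)
  rb <- apply_perturbation(rep3, perturbation("rbs_decrease", "g1"))
  # incoming synthesis (r3: g3 -> g1) divided by 10
  expect_equal(unname(rb$params["r3_syn"]), 1)
  expect_equal(unname(rb$params["r1_syn"]), 10)
})

test_that("experiments simulate, add noise, and debit the right price", {
  model <- model_instance(cascade_spec(), cascade_truth())
  led <- credit_ledger(5000)
  res <- run_experiment(
    model, list(),
    measurement_request("fluorescence", targets = c("p_g2", "p_g3")),
    led, seed = 7
  )
  expect_equal(res$ledger$balance, 4600)
  ds <- res$dataset
  expect_identical(ds$species, c("p_g2", "p_g3"))
  expect_equal(ds$times, 0:20) # fluorescence samples every time unit
  expect_true(all(ds$values >= 0))

  # deletion + high-res microarray: 800 + 1000
  res2 <- run_experiment(
    model, list(perturbation("deletion", "g1")),
    measurement_request("microarray", resolution = "high"),
    res$ledger, seed = 8
  )
  expect_equal(res2$ledger$balance, 4600 - 1800)
  expect_equal(res2$dataset$times, seq(0, 20, 2))
  # the deleted gene's truth is identically zero; its measured values are
  # pure baseline noise, clipped at zero
  expect_lt(max(res2$dataset$values[, "m_g1"]), 0.5)
  expect_true(any(res2$dataset$values[, "m_g1"] == 0))

  # over-budget request errors and leaves the ledger unchanged
  poor <- credit_ledger(100)
  expect_error(
    run_experiment(model, list(),
                   measurement_request("fluorescence",
                                       targets = c("p_g1", "p_g2")),
                   poor, seed = 1),
    class = "grnlab_budget_error"
  )
  expect_equal(poor$balance, 100)

  # technology/model-class pairing is enforced
  expect_error(
    run_experiment(model, list(),
                   measurement_request("massspec"), led, seed = 1),
    "protein_only"
  )
  expect_error(
    run_experiment(repressilator_model(), list(),
                   measurement_request("microarray"), led, seed = 1),
    "mrna_protein"
  )
})

test_that("dataset provenance regenerates the dataset exactly", {
  model <- model_instance(cascade_spec(), cascade_truth())
  req <- measurement_request("fluorescence", targets = c("p_g1", "p_g3"))
  pert <- list(perturbation("sirna_knockdown", "g2"))
  d1 <- run_experiment(model, pert, req, credit_ledger(1000), seed = 33)
  d2 <- run_experiment(model, pert, req, credit_ledger(1000), seed = 33)
  expect_identical(d1$dataset$values, d2$dataset$values)
})

test_that("gel shift returns the exact constants for 1600 credits", {
  model <- model_instance(cascade_spec(), cascade_truth())
  led <- credit_ledger(4000)
  gs <- gelshift(model, "r1", led)
  expect_identical(gs$Kd, unname(cascade_truth()["r1_Kd"]))
  expect_identical(gs$h, unname(cascade_truth()["r1_h"]))
  expect_equal(gs$ledger$balance, 2400)
  gs2 <- gelshift(model, "r2", gs$ledger)
  expect_equal(gs2$ledger$balance, 800) # two gel shifts debit 3200
  expect_error(gelshift(model, "r9", led), "unknown regulation")
  expect_error(gelshift(model, "r1", credit_ledger(1000)),
               class = "grnlab_budget_error")
})

test_that("the starting dataset is a free low-resolution microarray", {
  model <- model_instance(cascade_spec(), cascade_truth())
  ds <- initial_dataset(model, seed = 5)
  expect_equal(ds$cost, 0)
  expect_equal(ds$times, seq(0, 20, 4))
  expect_true(all(startsWith(ds$species, "m_")))
  expect_identical(ds$values, initial_dataset(model, seed = 5)$values)
  expect_error(initial_dataset(repressilator_model()))
})
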