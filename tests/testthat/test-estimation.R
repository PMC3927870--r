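test_that("chi-square is zero at the truth and counts sigmas", {
  m <- single_gene_model()
  spec <- m$spec
  truth <- m$params
  ds <- make_dataset(m, c("m_g1", "p_g1"), step = 2, t_end = 10,
                     noise = FALSE)
  expect_equal(chi2(spec, truth, ds), 0, tolerance = 1e-10)

  # one observation displaced by exactly one SD adds exactly 1
  nm <- noise_model()
  x <- ds$values[3, "m_g1"]
  ds1 <- ds
  ds1$values[3, "m_g1"] <- x + sqrt(noise_variance(x, nm))
  expect_equal(chi2(spec, truth, ds1, nm), 1, tolerance = 1e-8)

  # additive over independent datasets, invariant to point permutation
  ds2 <- make_dataset(m, c("p_g1", "m_g1"), step = 2, t_end = 10,
                      noise = FALSE) # same points, different column order
  ds2$values <- ds2$values + 0.05
  ds1b <- ds1; ds1b$values <- ds1$values + 0.02
  expect_equal(chi2(spec, truth, list(ds1b, ds2), nm),
               chi2(spec, truth, ds1b, nm) + chi2(spec, truth, ds2, nm))

  # -2 log-likelihood identity up to the Gaussian normalizing constant
  dsn <- make_dataset(m, c("m_g1", "p_g1"), step = 2, t_end = 10, seed = 3)
  cc <- chi2(spec, truth, dsn, nm)
  traj <- simulate_model(m, dsn$grid)
  xs <- traj$values[, dsn$species]
  ll <- sum(dnorm(dsn$values, xs, sqrt(noise_variance(xs, nm)), log = TRUE))
  expect_equal(cc, -2 * ll - sum(log(2 * pi * noise_variance(xs, nm))),
               tolerance = 1e-8)
})

test_that("steady-state relations recover rbs, promoter and degradation", {
  spec <- cascade_spec()
  truth <- cascade_truth()
  model <- model_instance(spec, truth)
  species <- species_names(spec)
  ds <- make_dataset(model, species, step = 1, t_end = 60, noise = FALSE)
  init <- steady_state_init(ds, spec)
  p <- init$params
  expect_equal(p[["p_degradation_rate"]],
               truth[["p_degradation_rate"]], tolerance = 0.01)
  for (g in c("g1", "g2", "g3")) {
    expect_equal(p[[paste0(g, "_rbs")]], truth[[paste0(g, "_rbs")]],
                 tolerance = 0.01)
  }
  # promoter read-off is exact only where no regulation acts
  expect_equal(p[["g1_pro"]], truth[["g1_pro"]], tolerance = 0.01)
  expect_match(paste(init$warnings, collapse = " "), "unit regulation")

  # degenerate inputs: all-zero data yield warnings, not estimates
  ds0 <- ds
  ds0$values[] <- 0
  init0 <- steady_state_init(ds0, spec)
  expect_false("p_degradation_rate" %in% names(init0$params))
  expect_true(length(init0$warnings) > 0)
  # no wildtype data at all
  dsp <- ds
  dsp$perturbations <- list(perturbation("deletion", "g1"))
  expect_match(steady_state_init(dsp, spec)$warnings, "no wildtype")
})

test_that("Hill inversion from 3 steady points is exact and flags poor
           bracketing", {
  Kd <- 2; h <- 3
  P <- c(0.8, 2, 4.5)
  term <- regulation_term(P, Kd, h, "repression")
  sol <- solve_regulation(P, term, "repression")
  expect_equal(sol$Kd, Kd, tolerance = 1e-9)
  expect_equal(sol$h, h, tolerance = 1e-9)
  expect_false(sol$poorly_determined)
  # activation branch
  term_a <- regulation_term(P, Kd, h, "activation")
  sol_a <- solve_regulation(P, term_a, "activation")
  expect_equal(sol_a$Kd, Kd, tolerance = 1e-9)
  expect_equal(sol_a$h, h, tolerance = 1e-9)
  # order invariance
  sol_r <- solve_regulation(rev(P), rev(term), "repression")
  expect_equal(sol_r$Kd, sol$Kd)
  # concentrations far above Kd: solvable but flagged
  P_hi <- c(50, 80, 120)
  sol_hi <- solve_regulation(P_hi, regulation_term(P_hi, Kd, h, "repression"),
                             "repression")
  expect_true(sol_hi$poorly_determined)
  expect_error(solve_regulation(P[1:2], term[1:2]), "3 steady-state")
  expect_error(solve_regulation(P, c(0.5, 1, 0.2)), "inside")
})

test_that("multistart fitting descends and stratifies its starts", {
  m <- single_gene_model()
  spec <- m$spec
  truth <- m$params
  ds <- make_dataset(m, c("m_g1", "p_g1"), step = 1, t_end = 15, seed = 5)
  # a single start from the truth can only improve on it
  start_truth <- matrix(log10(truth), 1,
                        dimnames = list(NULL, names(truth)))
  fit <- fit_multistart(spec, ds, n_starts = 1, starts = start_truth,
                        seed = 1)
  # same integration tolerances as the fitting objective
  expect_lte(fit$value, chi2(spec, truth, ds, rtol = 1e-5, atol = 1e-7))
  expect_s3_class(fit, "grn_fit")
  expect_equal(fit$value, min(fit$starts$value))

  # Latin-hypercube starts occupy distinct equal-probability strata
  fit2 <- fit_multistart(spec, ds, n_starts = 8, seed = 11,
                         control = list(iter.max = 1, eval.max = 2))
  for (j in seq_len(ncol(fit2$start_points))) {
    u <- (fit2$start_points[, j] - fit2$lower[j]) /
      (fit2$upper[j] - fit2$lower[j])
    expect_setequal(floor(u * 8), 0:7)
  }
})

test_that("noise-free fits recover a small model tightly", {
  m <- single_gene_model()
  ds <- make_dataset(m, c("m_g1", "p_g1"), step = 1, t_end = 20,
                     noise = FALSE)
  fit <- fit_multistart(m$spec, ds, n_starts = 12, bounds = c(-2, 1.5),
                        seed = 3)
  expect_equal(unname(fit$par / m$params[names(fit$par)]), rep(1, 3),
               tolerance = 0.02)
})

test_that("steady-state initialization speeds up convergence", {
  spec <- cascade_spec()
  truth <- cascade_truth()
  model <- model_instance(spec, truth)
  species <- species_names(spec)
  steady <- make_dataset(model, species, step = 1, t_end = 60,
                         noise = FALSE)
  fitting <- list(make_dataset(model, species, step = 1, seed = 9))
  init <- steady_state_init(steady, spec)$params
  guess <- random_parameters(spec, seed = 2)
  guess[names(init)] <- init
  warm <- fit_multistart(spec, fitting, n_starts = 1,
                         starts = matrix(log10(guess), 1,
                                         dimnames = list(NULL, names(guess))))
  cold_starts <- log10(vapply(1:3, function(s)
    random_parameters(spec, seed = 100 + s), numeric(length(guess))))
  cold <- fit_multistart(spec, fitting, n_starts = 3,
                         starts = t(cold_starts))
  expect_lte(warm$starts$iterations[1], median(cold$starts$iterations))
})

test_that("profiles flag structural non-identifiability and cover truth", {
  # observing only the protein leaves promoter and RBS strength coupled
  # through their product: the promoter profile must stay flat
  m <- single_gene_model()
  spec <- m$spec
  ds <- make_dataset(m, "p_g1", step = 1, t_end = 15, noise = FALSE)
  start <- matrix(log10(m$params), 1,
                  dimnames = list(NULL, names(m$params)))
  fit <- fit_multistart(spec, ds, n_starts = 1, starts = start,
                        bounds = c(-2, 2))
  prof <- profile_likelihood(fit, "g1_pro", ds, n_points = 9, span = 1.5)
  expect_false(prof$identifiable)
  expect_true(all(prof$profile$chi2 >= fit$value - 1e-6)) # never below min
  # flat wherever the compensating rbs strength is inside its bounds:
  # a decade either side of the fitted value
  inner <- prof$profile$value >= fit$par[["g1_pro"]] / 10 &
    prof$profile$value <= fit$par[["g1_pro"]] * 10
  expect_true(sum(inner) >= 5)
  expect_lt(diff(range(prof$profile$chi2[inner])), prof$threshold)

  # with both species observed the degradation rate is identifiable and
  # its 95% profile interval covers the truth in most replicates
  hits <- vapply(1:15, function(rep) {
    dsn <- make_dataset(m, c("m_g1", "p_g1"), step = 1, t_end = 15,
                        seed = 500 + rep)
    f <- fit_multistart(spec, dsn, n_starts = 1, starts = start,
                        bounds = c(-2, 2))
    pr <- profile_likelihood(f, "p_degradation_rate", dsn,
                             n_points = 9, span = 1)
    isTRUE(pr$identifiable) &&
      pr$ci[["lower"]] <= 0.5 && pr$ci[["upper"]] >= 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("experiment ranking rewards spread per credit", {
  m <- single_gene_model()
  spec <- m$spec
  # ensemble disagreeing only in protein kinetics: mRNA is identical
  ens <- rbind(m$params, m$params, m$params)
  ens[2, "g1_rbs"] <- 6; ens[3, "p_degradation_rate"] <- 0.1
  cand <- list(
    list(perturbations = list(),
         request = measurement_request("fluorescence",
                                       targets = c("p_g1", "p_g1"))),
    list(perturbations = list(),
         request = measurement_request("microarray", resolution = "low"))
  )
  ranked <- rank_experiments(spec, ens, cand)
  expect_equal(ranked$candidate[1], 1) # protein read-out discriminates
  expect_lt(ranked$spread[ranked$candidate == 2], 1e-4) # zero up to solver tol
  # a single candidate trivially ranks first
  expect_equal(nrow(rank_experiments(spec, ens, cand[1])), 1L)
  expect_error(rank_experiments(spec, ens, list()), "empty")
})
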