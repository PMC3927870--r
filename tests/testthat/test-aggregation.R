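test_that("arithmetic-mean aggregation averages per cell", {
  m1 <- matrix(1, 4, 2); m2 <- matrix(3, 4, 2)
  pool <- submission_pool(c("a", "b"), predictions = list(m1, m2))
  expect_equal(aggregate_predictions(pool, 1), m1) # k = 1 is the identity
  expect_equal(aggregate_predictions(pool, 2), matrix(2, 4, 2))
  # symmetric in the first k teams
  pool_swapped <- submission_pool(c("b", "a"), predictions = list(m2, m1))
  expect_equal(aggregate_predictions(pool_swapped, 2),
               aggregate_predictions(pool, 2))
})

test_that("geometric-mean aggregation has the expected algebra", {
  pool <- submission_pool(c("a", "b"),
                          parameters = list(c(x = 0.1, y = 2),
                                            c(x = 10, y = 2)))
  agg <- aggregate_parameters(pool, 2)
  expect_equal(agg[["x"]], 1) # geometric symmetry of 0.1 and 10
  expect_equal(agg[["y"]], 2) # identical values pass through
  # equals exp(mean(log v)) computed independently
  withr::with_seed(5, {
    vals <- lapply(1:4, function(i) setNames(10^runif(6, -2, 2),
                                             letters[1:6]))
  })
  pool2 <- submission_pool(paste0("t", 1:4), parameters = vals)
  agg2 <- aggregate_parameters(pool2, 4)
  oracle <- exp(Reduce(`+`, lapply(vals, log)) / 4)
  expect_equal(agg2, oracle[names(agg2)])
  # commutes with parameter-wise rescaling
  scaled <- lapply(vals, function(v) v * 3)
  pool3 <- submission_pool(paste0("t", 1:4), parameters = scaled)
  expect_equal(aggregate_parameters(pool3, 4), agg2 * 3)
  # n copies of one submission return it exactly
  pool4 <- submission_pool(c("a", "b", "c"),
                           parameters = rep(list(vals[[1]]), 3))
  expect_equal(aggregate_parameters(pool4, 3), vals[[1]])
  expect_error(aggregate_parameters(
    submission_pool("a", parameters = list(c(x = -1))), 1), "positive")
})

test_that("consensus links follow the vote tally with lexicographic ties", {
  l <- function(s, sg, d) link_prediction(s, sg, d)
  pool <- submission_pool(
    paste0("t", 1:4),
    links = list(
      list(l("g1", "+", "g2"), l("g2", "-", "g3"), l("g3", "+", "g1")),
      list(l("g1", "+", "g2"), l("g2", "-", "g3"), l("g4", "+", "g1")),
      list(l("g1", "+", "g2"), l("g2", "-", "g3"), l("g3", "+", "g1")),
      list(l("g1", "+", "g2"), l("g5", "-", "g3"), l("g4", "+", "g1"))
    )
  )
  cons <- consensus_links(pool)
  votes <- attr(cons, "votes")
  # oracle: brute-force multiset tally of the canonical keys
  keys <- vapply(unlist(pool$links, recursive = FALSE),
                 function(x) paste(x$source, x$sign,
                                   paste(x$destinations, collapse = ","),
                                   sep = "|"),
                 character(1))
  expect_equal(as.vector(votes[names(table(keys))]),
               as.vector(table(keys)))
  # top three: g1+g2 (4), g2-g3 (3), then the 2-2 tie between g3+g1 and
  # g4+g1 resolves lexicographically to g3|+|g1
  expect_equal(vapply(cons, `[[`, character(1), "source"),
               c("g1", "g2", "g3"))
  expect_false(attr(cons, "incomplete"))
  # identical 3-link submissions are returned unchanged
  pool_same <- submission_pool(c("a", "b"),
                               links = rep(list(pool$links[[1]]), 2))
  expect_equal(consensus_links(pool_same)[1:3],
               pool$links[[1]][order(vapply(pool$links[[1]], grnlab:::link_key,
                                            character(1)))])
})

test_that("aggregation curves start at the leading team and flatten for
           identical submissions", {
  grid_gold <- matrix(rep(seq(1, 3, length.out = 41), 2), ncol = 2)
  preds <- list(grid_gold * 1.05, grid_gold * 0.8, grid_gold * 1.5)
  params <- list(c(a = 1.1, b = 0.6), c(a = 0.7, b = 0.4), c(a = 3, b = 1.5))
  gold_params <- c(a = 1, b = 0.5)
  pool <- submission_pool(paste0("t", 1:3), parameters = params,
                          predictions = preds)
  cur <- aggregation_curves(pool, gold_params, grid_gold)
  fwd <- cur[cur$order == "forward", ]
  expect_equal(fwd$D_param[1], parameter_distance(params[[1]], gold_params))
  expect_equal(fwd$D_prot[1], protein_distance(preds[[1]], grid_gold))
  rev1 <- cur[cur$order == "reverse", ]
  expect_equal(rev1$D_param[1], parameter_distance(params[[3]], gold_params))
  # both orders converge to the same all-team aggregate
  expect_equal(fwd$D_param[3], rev1$D_param[3])
  # identical submissions give flat curves
  pool_same <- submission_pool(paste0("t", 1:3),
                               parameters = rep(params[1], 3),
                               predictions = rep(preds[1], 3))
  cur_same <- aggregation_curves(pool_same, gold_params, grid_gold)
  expect_equal(var(cur_same$D_param), 0)
  expect_equal(var(cur_same$D_prot), 0)
})

test_that("aggregate parameter distance improves with k on noisy pools", {
  # pools built as gold * exp(eps): forward aggregation should reduce
  # D_param on average as teams are added
  withr::with_seed(21, {
    gold <- setNames(10^runif(20, -1, 1), paste0("v", 1:20))
    gains <- replicate(20, {
      subs <- lapply(1:8, function(i) gold * exp(rnorm(20, 0, 0.6)))
      pool <- submission_pool(paste0("t", 1:8), parameters = subs)
      d1 <- parameter_distance(subs[[1]], gold)
      dall <- parameter_distance(aggregate_parameters(pool, 8), gold)
      dall < d1
    })
    expect_gt(mean(gains), 0.85)
  })
})

test_that("per-parameter sensitivity R2 matches the closed form", {
  grid_gold <- matrix(rep(seq(0.5, 2, length.out = 41), 2), ncol = 2)
  gold_params <- c(a = 1, b = 2, c = 3)
  withr::with_seed(8, {
    preds <- lapply(1:6, function(i) grid_gold * runif(1, 0.7, 1.4))
    D_prot <- vapply(preds, function(p) protein_distance(p, grid_gold),
                     numeric(1))
    params <- lapply(seq_along(preds), function(i) {
      c(a = 0.5 + 2 * D_prot[i],     # exactly linear in D_prot
        b = 2,                       # constant -> undefined R2
        c = 10^runif(1, -0.5, 0.5))  # noise
    })
  })
  pool <- submission_pool(paste0("t", 1:6), parameters = params,
                          predictions = preds)
  sens <- parameter_sensitivity(pool, gold_params, grid_gold)
  expect_equal(sens$per_parameter[["a"]], 1, tolerance = 1e-9)
  expect_true(is.na(sens$per_parameter[["b"]]))
  # independent closed form: R2 = 1 - SSres/SStot
  v <- vapply(params, `[[`, numeric(1), "c")
  fit <- lm(sens$D_prot ~ v)
  r2_oracle <- 1 - sum(residuals(fit)^2) /
    sum((sens$D_prot - mean(sens$D_prot))^2)
  expect_equal(sens$per_parameter[["c"]], r2_oracle)
  expect_true(is.na(parameter_sensitivity(
    submission_pool(paste0("t", 1:6),
                    parameters = rep(list(gold_params), 6),
                    predictions = rep(list(grid_gold), 6)),
    gold_params, grid_gold)$overall_r2))
})
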