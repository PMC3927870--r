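#' Measurement noise model
#'
#' Purchased data report `v_noisy = v + sigma_b * g1 + sigma_s * g2 * v`
#' with `g1`, `g2` independent standard normal draws per value: a baseline
#' (signal-independent) component of SD `sigma_b` and a signal-proportional
#' component of SD `sigma_s * v`, so large signals are measured with a
#' relative error close to `sigma_s` (~20% at the defaults). Negative noisy
#' values are clipped at 0.
#'
#' @param sigma_b Baseline noise SD (default 0.1).
#' @param sigma_s Signal-proportional noise SD (default 0.2).
#' @param clip_at_zero Clip negative noisy values to 0 (default TRUE).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_b = 0.1, sigma_s = 0.2, clip_at_zero = TRUE) {
  stopifnot(sigma_b >= 0, sigma_s >= 0)
  structure(list(sigma_b = sigma_b, sigma_s = sigma_s,
                 clip_at_zero = clip_at_zero), class = "noise_model")
}

#' Noise variance at a signal level
#'
#' `sigma_b^2 + sigma_s^2 * v^2`, the variance used both to generate noisy
#' data and to weight scoring/likelihood residuals.
#'
#' @param v Noise-free signal value(s).
#' @param nm A [noise_model()].
#' @return Variance(s).
#' @export
noise_variance <- function(v, nm) nm$sigma_b^2 + nm$sigma_s^2 * v^2

#' Add measurement noise to simulated values
#'
#' @param values Numeric vector/matrix of noise-free values (`>= 0`).
#' @param nm A [noise_model()].
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param g1,g2 Optional explicit standard-normal draws (same shape as
#'   `values`), mainly for testing the arithmetic.
#' @return Noisy values, clipped at 0 when the noise model says so.
#' @export
add_noise <- function(values, nm = noise_model(), seed = NULL,
                      g1 = NULL, g2 = NULL) {
  stopifnot(all(values >= 0))
  n <- length(values)
  draws <- with_seed(seed, {
    list(g1 = if (is.null(g1)) rnorm(n) else g1,
         g2 = if (is.null(g2)) rnorm(n) else g2)
  })
  noisy <- values + nm$sigma_b * draws$g1 + nm$sigma_s * draws$g2 * values
  if (nm$clip_at_zero) noisy[noisy < 0] <- 0
  attributes(noisy) <- attributes(values)
  noisy
}

#' Experiment price table
#'
#' Credit costs: gene deletion 800, siRNA knockdown 350, RBS-activity
#' decrease 450, two-protein fluorescence time course 400, microarray
#' (all mRNAs) 500 low / 1000 high resolution, mass spectrometry (all
#' proteins) 500 low / 1000 high, gel-shift (exact Kd and h of one
#' regulation) 1600.
#'
#' @param ... Named overrides of individual prices.
#' @return Named list of positive integer costs.
#' @export
price_table <- function(...) {
  prices <- list(
    deletion = 800L, sirna_knockdown = 350L, rbs_decrease = 450L,
    fluorescence = 400L, microarray_low = 500L, microarray_high = 1000L,
    massspec_low = 500L, massspec_high = 1000L, gelshift = 1600L
  )
  prices <- modifyList(prices, list(...))
  stopifnot(all(unlist(prices) > 0))
  prices
}

#' Credit ledger
#'
#' Tracks a virtual experimental budget. The starting budget is a required
#' argument: the credit amount is a property of the study design, not of the
#' package. Ledgers are immutable values; [debit()] returns a new ledger and
#' a failed purchase leaves the original untouched.
#'
#' @param budget Initial credits (positive).
#' @return An object of class `credit_ledger` with fields `budget`,
#'   `balance` and a `transactions` data frame.
#' @export
credit_ledger <- function(budget) {
  stopifnot(is.numeric(budget), length(budget) == 1L, budget > 0)
  structure(
    list(budget = budget, balance = budget,
         transactions = data.frame(description = character(0),
                                   cost = numeric(0),
                                   balance_after = numeric(0))),
    class = "credit_ledger"
  )
}

#' Debit a ledger
#' @param ledger A [credit_ledger()].
#' @param description What was bought.
#' @param cost Credits to debit.
#' @return The updated ledger; errors (class `grnlab_budget_error`) when the
#'   balance is insufficient.
#' @export
debit <- function(ledger, description, cost) {
  stopifnot(inherits(ledger, "credit_ledger"), cost >= 0)
  if (ledger$balance < cost) {
    stop(structure(
      class = c("grnlab_budget_error", "error", "condition"),
      list(message = sprintf(
        "insufficient credits: need %s, balance %s", cost, ledger$balance),
        call = sys.call(-1))
    ))
  }
  ledger$balance <- ledger$balance - cost
  ledger$transactions <- rbind(
    ledger$transactions,
    data.frame(description = description, cost = cost,
               balance_after = ledger$balance)
  )
  ledger
}

#' Perturbation of a model
#'
#' Kinds: `deletion` (eliminates both mRNA and protein of a gene),
#' `sirna_knockdown` (mRNA degradation rate x10), `rbs_decrease`
#' (translation rate /10), `parameter_scale` (named parameter x `factor`,
#' free of charge -- used for the scored prediction condition).
#'
#' @param kind One of `deletion`, `sirna_knockdown`, `rbs_decrease`,
#'   `parameter_scale`.
#' @param target Gene id (first three kinds) or parameter name.
#' @param factor Fold change for `parameter_scale` (`> 0`).
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(kind = c("deletion", "sirna_knockdown",
                                  "rbs_decrease", "parameter_scale"),
                         target, factor = NULL) {
  kind <- match.arg(kind)
  if (kind == "parameter_scale") {
    stopifnot(is.numeric(factor), factor > 0)
  } else if (!is.null(factor)) {
    stop("factor is only meaningful for parameter_scale")
  }
  structure(list(kind = kind, target = target, factor = factor),
            class = "perturbation")
}

#' Apply a perturbation to a model
#'
#' Pure: returns a new [model_instance()]; the input is not modified.
#' On `protein_only` models the mRNA-level perturbations act on their
#' protein-level counterparts: knockdown multiplies the gene's protein
#' degradation rate by 10 and an RBS decrease divides all incoming synthesis
#' rates by 10.
#'
#' @param model A [model_instance()].
#' @param p A [perturbation()].
#' @return The perturbed model.
#' @export
apply_perturbation <- function(model, p) {
  stopifnot(inherits(model, "model_instance"), inherits(p, "perturbation"))
  spec <- model$spec
  m1 <- spec$model_class == "mrna_protein"
  if (p$kind != "parameter_scale" && !p$target %in% gene_ids(spec)) {
    stop("unknown gene id: ", p$target)
  }
  switch(p$kind,
    deletion = {
      model$deleted <- union(model$deleted, p$target)
      if (m1) model$initial_conditions[paste0("m_", p$target)] <- 0
      model$initial_conditions[paste0("p_", p$target)] <- 0
    },
    sirna_knockdown = {
      if (m1) {
        model$mrna_deg_factor[p$target] <- model$mrna_deg_factor[p$target] * 10
      } else {
        nm <- paste0(p$target, "_deg")
        model$params[nm] <- model$params[nm] * 10
      }
    },
    rbs_decrease = {
      if (m1) {
        nm <- paste0(p$target, "_rbs")
        model$params[nm] <- model$params[nm] / 10
      } else {
        regs <- regs_targeting(spec, p$target)
        if (length(regs) == 0L) {
          nm <- paste0(p$target, "_basal")
          model$params[nm] <- model$params[nm] / 10
        } else {
          for (r in regs) {
            nm <- paste0(r$id, "_syn")
            model$params[nm] <- model$params[nm] / 10
          }
        }
      }
    },
    parameter_scale = {
      if (!p$target %in% names(model$params)) {
        stop("unknown parameter: ", p$target)
      }
      model$params[p$target] <- model$params[p$target] * p$factor
    }
  )
  model
}

#' Measurement request
#'
#' Technologies: `fluorescence` (exactly 2 proteins, every time unit),
#' `microarray` (all mRNAs, `mrna_protein` models only), `massspec` (all
#' proteins, `protein_only` models only); the array/mass-spec technologies
#' come at `low` (every 4 time units) or `high` (every 2) resolution.
#' `gelshift` requests are handled by [gelshift()] directly.
#'
#' @param technology One of `fluorescence`, `microarray`, `massspec`.
#' @param targets For fluorescence, exactly 2 protein species names (e.g.
#'   `c("p_g3", "p_g5")`); ignored otherwise.
#' @param resolution `"low"` or `"high"` (microarray/massspec).
#' @return An object of class `measurement_request`.
#' @export
measurement_request <- function(technology = c("fluorescence", "microarray",
                                               "massspec"),
                                targets = NULL,
                                resolution = c("low", "high")) {
  technology <- match.arg(technology)
  resolution <- match.arg(resolution)
  if (technology == "fluorescence") {
    if (is.null(targets) || length(targets) != 2L) {
      stop("fluorescence measures exactly 2 proteins")
    }
  }
  structure(list(technology = technology, targets = targets,
                 resolution = resolution), class = "measurement_request")
}

measurement_grid <- function(request, t_end = 20) {
  step <- switch(request$technology,
    fluorescence = 1,
    if (request$resolution == "low") 4 else 2
  )
  time_grid(0, t_end, step)
}

measurement_cost <- function(request, prices) {
  switch(request$technology,
    fluorescence = prices$fluorescence,
    microarray = if (request$resolution == "low") prices$microarray_low
                 else prices$microarray_high,
    massspec = if (request$resolution == "low") prices$massspec_low
               else prices$massspec_high
  )
}

perturbation_cost <- function(p, prices) {
  switch(p$kind,
    deletion = prices$deletion,
    sirna_knockdown = prices$sirna_knockdown,
    rbs_decrease = prices$rbs_decrease,
    parameter_scale = 0L
  )
}

#' Run a priced in-silico experiment
#'
#' Applies the perturbations, simulates the perturbed model on the
#' technology's grid, restricts to the requested species, adds measurement
#' noise and debits the ledger. A request the budget cannot cover errors out
#' before anything is simulated, leaving the ledger unchanged.
#'
#' @param model A [model_instance()] (the hidden truth).
#' @param perturbations List of [perturbation()]s (may be empty = wildtype).
#' @param request A [measurement_request()].
#' @param ledger A [credit_ledger()].
#' @param seed Optional integer seed for the noise draws.
#' @param prices A [price_table()].
#' @param t_end Measurement horizon.
#' @return List with `dataset` (class `grn_dataset`: noisy time-by-species
#'   `values`, `grid`, provenance) and the updated `ledger`.
#' @export
run_experiment <- function(model, perturbations = list(), request, ledger,
                           seed = NULL, prices = price_table(), t_end = 20) {
  stopifnot(inherits(request, "measurement_request"))
  m1 <- model$spec$model_class == "mrna_protein"
  if (request$technology == "microarray" && !m1) {
    stop("microarray is only available for mrna_protein models")
  }
  if (request$technology == "massspec" && m1) {
    stop("mass spectrometry is only available for protein_only models")
  }
  if (inherits(perturbations, "perturbation")) {
    perturbations <- list(perturbations)
  }
  cost <- measurement_cost(request, prices) +
    sum(vapply(perturbations, perturbation_cost, numeric(1), prices = prices))
  desc <- paste0(
    request$technology,
    if (request$technology != "fluorescence") paste0("_", request$resolution),
    if (length(perturbations)) {
      paste0(" [", paste(vapply(perturbations, function(p)
        paste0(p$kind, ":", p$target), character(1)), collapse = ", "), "]")
    } else " [wildtype]"
  )
  ledger <- debit(ledger, desc, cost) # errors before simulating
  pert_model <- Reduce(apply_perturbation, perturbations, model)
  grid <- measurement_grid(request, t_end)
  traj <- simulate_model(pert_model, grid)
  keep <- switch(request$technology,
    fluorescence = request$targets,
    microarray = grep("^m_", colnames(traj$values), value = TRUE),
    massspec = grep("^p_", colnames(traj$values), value = TRUE)
  )
  if (!all(keep %in% colnames(traj$values))) stop("unknown species requested")
  clean <- traj$values[, keep, drop = FALSE]
  noisy <- add_noise(clean, seed = seed)
  ds <- structure(
    list(values = noisy, grid = grid, times = grid$times,
         species = keep,
         perturbations = perturbations, technology = request$technology,
         resolution = request$resolution, cost = cost, seed = seed),
    class = "grn_dataset"
  )
  list(dataset = ds, ledger = ledger)
}

#' Buy the true (Kd, h) of one regulation (gel shift)
#'
#' Returns the stored dissociation constant and Hill coefficient exactly
#' (no noise) for 1600 credits.
#'
#' @param model A [model_instance()] holding the truth.
#' @param regulation Regulation id.
#' @param ledger A [credit_ledger()].
#' @param prices A [price_table()].
#' @return List with `Kd`, `h` and the updated `ledger`.
#' @export
gelshift <- function(model, regulation, ledger, prices = price_table()) {
  if (!regulation %in% regulation_ids(model$spec)) {
    stop("unknown regulation id: ", regulation)
  }
  ledger <- debit(ledger, paste0("gelshift [", regulation, "]"),
                  prices$gelshift)
  list(Kd = unname(model$params[paste0(regulation, "_Kd")]),
       h = unname(model$params[paste0(regulation, "_h")]),
       ledger = ledger)
}

#' Free starting dataset
#'
#' The zero-cost low-resolution wildtype microarray handed out at the start
#' of a parameter-estimation session (`mrna_protein` models only).
#'
#' @param model A [model_instance()].
#' @param seed Optional integer noise seed.
#' @param t_end Measurement horizon.
#' @return A `grn_dataset` with `cost = 0`.
#' @export
initial_dataset <- function(model, seed = NULL, t_end = 20) {
  stopifnot(model$spec$model_class == "mrna_protein")
  grid <- time_grid(0, t_end, 4)
  traj <- simulate_model(model, grid)
  keep <- grep("^m_", colnames(traj$values), value = TRUE)
  clean <- traj$values[, keep, drop = FALSE]
  structure(
    list(values = add_noise(clean, seed = seed), grid = grid,
         times = grid$times, species = keep,
         perturbations = list(), technology = "microarray",
         resolution = "low", cost = 0, seed = seed),
    class = "grn_dataset"
  )
}
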