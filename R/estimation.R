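#' Goodness-of-fit chi-square of a parameter vector
#'
#' `chi2 = sum_i (y_i - x_i)^2 / sigma_i^2` over every data point of every
#' dataset, where `x` is the model prediction under the dataset's
#' perturbations on its measurement grid, and the variance follows the
#' challenge noise model evaluated at the model prediction,
#' `sigma^2 = sigma_b^2 + sigma_s^2 x^2` (the variance the generating
#' process actually used). Up to an additive constant this is -2 times the
#' Gaussian log-likelihood, so likelihood-ratio tests reduce to chi-square
#' differences.
#'
#' @param spec A [network_spec()].
#' @param params Named positive parameter vector.
#' @param datasets A `grn_dataset` or list of them.
#' @param nm A [noise_model()].
#' @param initial_conditions Optional named IC vector (initial conditions
#'   are treated as known, as in the challenge).
#' @param rtol,atol Integrator tolerances used during fitting.
#' @param maxsteps Solver step cap per output interval (see
#'   [simulate_model()]).
#' @return Non-negative scalar; integration failures propagate with the
#'   dataset index in the message.
#' @export
chi2 <- function(spec, params, datasets, nm = noise_model(),
                 initial_conditions = NULL, rtol = 1e-8, atol = 1e-10,
                 maxsteps = 5000) {
  if (inherits(datasets, "grn_dataset")) datasets <- list(datasets)
  model <- model_instance(spec, params, initial_conditions)
  total <- 0
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    pert_model <- Reduce(apply_perturbation, ds$perturbations, model)
    traj <- tryCatch(
      simulate_model(pert_model, ds$grid, rtol = rtol, atol = atol,
                     maxsteps = maxsteps),
      error = function(e) {
        stop("integration error in dataset ", i, ": ",
             conditionMessage(e))
      })
    x <- traj$values[, ds$species, drop = FALSE]
    total <- total + sum((ds$values - x)^2 / noise_variance(x, nm))
  }
  total
}

#' Steady-state initial parameter guesses
#'
#' Reads off what the steady-state relations determine from wildtype
#' (unperturbed) `mrna_protein` data: at steady state
#' `mRNA_degradation * mRNA = promoter * regulation_terms` and
#' `protein_degradation * protein = rbs * mRNA`. The protein degradation
#' rate is estimated from the relaxation time course of an unregulated
#' protein (closed-form single-gene solution, 1-d least squares); RBS
#' strengths follow as `deg * P_ss / m_ss`; promoter strengths are set to
#' the steady mRNA level (mRNA degradation rate 1, regulation terms assumed
#' unity where unknown -- exact for unregulated genes, a starting guess
#' otherwise).
#'
#' @param datasets A `grn_dataset` or list of them; wildtype datasets whose
#'   late time points are near steady state are used.
#' @param spec A [network_spec()] of class `mrna_protein`.
#' @return List with `params` (partial named guess vector) and `warnings`
#'   (character vector of quantities that could not be determined).
#' @export
steady_state_init <- function(datasets, spec) {
  stopifnot(spec$model_class == "mrna_protein")
  if (inherits(datasets, "grn_dataset")) datasets <- list(datasets)
  wt <- Filter(function(d) length(d$perturbations) == 0L, datasets)
  warnings <- character(0)
  if (!length(wt)) {
    return(list(params = numeric(0),
                warnings = "no wildtype dataset supplied"))
  }
  # steady level per species: mean of the last quarter of each time course
  ss <- list()
  for (d in wt) {
    tailidx <- which(d$times >= max(d$times) * 0.75)
    for (s in d$species) {
      ss[[s]] <- c(ss[[s]], mean(d$values[tailidx, s]))
    }
  }
  ss <- vapply(ss, mean, numeric(1))
  g <- gene_ids(spec)
  unreg <- unregulated_genes(spec)
  params <- numeric(0)

  # protein degradation from an unregulated gene's protein relaxation
  deg <- NA_real_
  for (gid in unreg) {
    pspecies <- paste0("p_", gid)
    mss <- ss[paste0("m_", gid)]
    pss <- ss[pspecies]
    if (is.na(mss) || is.na(pss) || mss <= 0 || pss <= 0) next
    d <- Filter(function(x) pspecies %in% x$species, wt)
    if (!length(d)) next
    d <- d[[1]]
    pobs <- d$values[, pspecies]
    tt <- d$times
    # single unregulated gene from zero ICs: m(t) = m_ss (1 - e^-t),
    # p(t; deg) = deg * P_ss * [(1-e^{-deg t})/deg - (e^{-t}-e^{-deg t})/(deg-1)]
    pred <- function(delta) {
      mix <- if (abs(delta - 1) < 1e-8) {
        tt * exp(-tt)
      } else {
        (exp(-tt) - exp(-delta * tt)) / (delta - 1)
      }
      delta * pss * ((1 - exp(-delta * tt)) / delta - mix)
    }
    obj <- function(delta) sum((pobs - pred(delta))^2)
    opt <- optimize(obj, c(1e-3, 20), tol = 1e-10)
    deg <- opt$minimum
    break
  }
  if (is.na(deg)) {
    warnings <- c(warnings,
                  "protein degradation rate undetermined (no usable unregulated protein time course)")
  } else {
    params["p_degradation_rate"] <- deg
  }

  for (gid in g) {
    mss <- ss[paste0("m_", gid)]
    pss <- ss[paste0("p_", gid)]
    if (!is.na(mss) && mss > 0) {
      params[paste0(gid, "_pro")] <- unname(mss) # delta_m = 1, unit regulation
      if (!gid %in% unreg) {
        warnings <- c(warnings, paste0(
          gid, "_pro assumes unit regulation terms (gene is regulated)"))
      }
    }
    if (!is.na(deg) && !is.na(mss) && !is.na(pss) && mss > 0) {
      params[paste0(gid, "_rbs")] <- unname(deg * pss / mss)
    }
  }
  if (!length(params)) {
    warnings <- c(warnings, "no steady levels could be estimated")
  }
  if (any(params <= 0, na.rm = TRUE)) {
    params <- params[params > 0]
    warnings <- c(warnings, "non-positive estimates dropped")
  }
  list(params = params, warnings = warnings)
}

#' Solve a Hill regulation from steady-state points
#'
#' Given at least 3 pairs of regulator concentration and regulatory-term
#' value (each strictly inside (0, 1)), recovers `(Kd, h)` by linear least
#' squares on the logit-log linearization of the Hill relation:
#' repression `log(1/term - 1) = h (log P - log Kd)`, activation
#' `log(term/(1-term)) = h (log P - log Kd)`. Exact on exact points. The
#' solution is flagged poorly determined when the observed concentrations
#' do not bracket the fitted `Kd` (terms all on one side of 1/2).
#'
#' @param P Regulator concentrations (distinct, `> 0`).
#' @param term Regulatory-term values in (0, 1).
#' @param sign `"activation"` or `"repression"` (or `"+"`/`"-"`).
#' @return List with `Kd`, `h`, `poorly_determined`.
#' @export
solve_regulation <- function(P, term, sign = "repression") {
  if (length(P) < 3L) stop("at least 3 steady-state points required")
  stopifnot(length(P) == length(term), all(P > 0))
  if (any(term <= 0) || any(term >= 1)) {
    stop("regulatory terms must lie strictly inside (0, 1)")
  }
  if (anyDuplicated(P)) stop("regulator concentrations must be distinct")
  sign <- switch(sign, "+" = "activation", "-" = "repression",
                 activation = "activation", repression = "repression")
  y <- if (sign == "repression") log(1 / term - 1) else log(term / (1 - term))
  fit <- lm(y ~ log(P))
  h <- unname(coef(fit)[2])
  Kd <- exp(-unname(coef(fit)[1]) / h)
  poorly <- !(min(term) < 0.5 && max(term) > 0.5)
  list(Kd = Kd, h = h, poorly_determined = poorly)
}

# Central-difference gradient in log10-parameter space.
fd_gradient <- function(fn, x, step = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + step
    xm[j] <- xm[j] - step
    (fn(xp) - fn(xm)) / (2 * step)
  }, numeric(1))
}

# Objective factory: chi2 as a function of log10 free parameters, with
# fixed parameters spliced back in; integration failures cost a large
# finite penalty so the optimizer can back away.
make_objective <- function(spec, datasets, nm, fixed = NULL,
                           initial_conditions = NULL,
                           rtol = 1e-5, atol = 1e-7, maxsteps = 1000) {
  free <- setdiff(parameter_names(spec), names(fixed))
  function(logx) {
    params <- c(setNames(10^logx, free), fixed)
    val <- tryCatch(
      chi2(spec, params, datasets, nm, initial_conditions,
           rtol = rtol, atol = atol, maxsteps = maxsteps),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
}

#' Latin-hypercube multistart maximum-likelihood fit
#'
#' Minimizes the chi-square objective in log10-parameter space from
#' `n_starts` Latin-hypercube start points spread over the box `bounds`
#' (each parameter's starts occupy distinct equal-probability strata), using
#' a bounded quasi-Newton local optimizer (`nlminb`) with central
#' finite-difference gradients (step 1e-6 in log10 space). Fully seeded.
#'
#' Optimization runs in two stages: every start is first screened with a
#' short iteration budget (`screen`), then the `refine_top` most promising
#' screened solutions are polished under the full `control` budget. Basin
#' selection happens in the first optimizer iterations, so screening
#' preserves the multistart coverage while avoiding full polish of starts
#' that descend into poor basins. Set `screen = NULL` to polish every
#' start.
#'
#' @param spec A [network_spec()].
#' @param datasets A `grn_dataset` or list of them.
#' @param nm A [noise_model()].
#' @param n_starts Number of Latin-hypercube starts (>= 1).
#' @param bounds Log10 lower/upper bounds: either a length-2 vector applied
#'   to every parameter (default `c(-3, 3)`, i.e. parameters in 1e-3..1e3)
#'   or a 2-row matrix (lower/upper) with one column per free parameter.
#' @param seed Optional integer seed for the start design.
#' @param fixed Optional named vector of parameters held fixed.
#' @param initial_conditions Optional known IC vector.
#' @param starts Optional explicit start matrix (rows = starts, columns =
#'   free parameters, log10 scale); overrides the LHS design.
#' @param control Passed to [stats::nlminb()] for the polish stage.
#' @param screen [stats::nlminb()] control list for the screening stage, or
#'   `NULL` to fully optimize every start.
#' @param refine_top Number of screened starts carried into the polish
#'   stage.
#' @return An object of class `grn_fit`: `par` (best parameters, natural
#'   scale, including fixed), `value` (best chi-square), `free` (names),
#'   `starts` (per-start data frame: value, convergence, iterations),
#'   `bounds`.
#' @export
fit_multistart <- function(spec, datasets, nm = noise_model(),
                           n_starts = 20, bounds = c(-3, 3), seed = NULL,
                           fixed = NULL, initial_conditions = NULL,
                           starts = NULL,
                           control = list(iter.max = 150, eval.max = 300,
                                          rel.tol = 1e-6),
                           screen = list(iter.max = 25, eval.max = 60,
                                         rel.tol = 1e-4),
                           refine_top = 5) {
  stopifnot(n_starts >= 1)
  free <- setdiff(parameter_names(spec), names(fixed))
  d <- length(free)
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == 2)
    bounds <- bounds[, free, drop = FALSE]
    lower <- bounds[1, ]; upper <- bounds[2, ]
  } else {
    stopifnot(length(bounds) == 2, bounds[2] > bounds[1])
    lower <- rep(bounds[1], d); upper <- rep(bounds[2], d)
  }
  stopifnot(all(upper > lower))
  obj <- make_objective(spec, datasets, nm, fixed, initial_conditions)
  if (is.null(starts)) {
    u <- with_seed(seed, lhs::randomLHS(n_starts, d))
    starts <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
    colnames(starts) <- free
  } else {
    starts <- as.matrix(starts)
    if (!is.null(colnames(starts))) starts <- starts[, free, drop = FALSE]
    n_starts <- nrow(starts)
  }
  one_run <- function(x0, ctrl) {
    x0 <- pmin(pmax(x0, lower), upper)
    res <- tryCatch(
      nlminb(x0, obj, gradient = function(x) fd_gradient(obj, x),
             lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) {
      list(par = x0, objective = Inf, convergence = 1L,
           iterations = NA_integer_, message = "optimizer error")
    } else res
  }
  two_stage <- !is.null(screen) && n_starts > refine_top
  runs <- lapply(seq_len(n_starts), function(i) {
    one_run(starts[i, ], if (two_stage) screen else control)
  })
  if (two_stage) {
    vals <- vapply(runs, `[[`, numeric(1), "objective")
    for (i in utils::head(order(vals), refine_top)) {
      polished <- one_run(runs[[i]]$par, control)
      if (is.finite(polished$objective) &&
          polished$objective <= runs[[i]]$objective) {
        polished$iterations <- polished$iterations + runs[[i]]$iterations
        runs[[i]] <- polished
      }
    }
  }
  values <- vapply(runs, `[[`, numeric(1), "objective")
  if (all(!is.finite(values))) {
    stop("fit error: all starts failed; per-start diagnostics: ",
         paste(vapply(runs, function(r) r$message %||% "?", character(1)),
               collapse = "; "))
  }
  best <- which.min(values)
  par <- c(setNames(10^runs[[best]]$par, free), fixed)
  structure(
    list(par = par[parameter_names(spec)], value = values[best],
         free = free, lower = setNames(lower, free),
         upper = setNames(upper, free),
         best_logpar = setNames(runs[[best]]$par, free),
         start_points = starts,
         starts = data.frame(
           start = seq_len(n_starts), value = values,
           convergence = vapply(runs, `[[`, integer(1), "convergence"),
           iterations = vapply(runs, function(r)
             as.integer(r$iterations %||% NA_integer_), integer(1))),
         spec = spec, fixed = fixed,
         initial_conditions = initial_conditions),
    class = "grn_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Profile likelihood of one parameter
#'
#' Fixes the parameter on a log10 grid around its fitted value (default 21
#' points spanning two decades each way, extended adaptively until the
#' chi-square threshold is crossed or a bound is hit) and re-optimizes all
#' other free parameters at every grid point, warm-starting from the
#' neighbouring solution. The 95% confidence interval collects fixed values
#' with `chi2 - chi2_min <= qchisq(0.95, 1) = 3.84`; a parameter whose
#' profile stays below the threshold all the way to a bound is flagged
#' non-identifiable on that side.
#'
#' @param fit A `grn_fit` from [fit_multistart()].
#' @param param Name of the profiled parameter.
#' @param datasets,nm The data and noise model used in the fit.
#' @param n_points Grid points per side before adaptive extension.
#' @param span Half-width of the initial grid in log10 units.
#' @param threshold Chi-square increase defining the CI.
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `grn_profile`: data frame `profile`
#'   (`value`, `chi2`, and the re-optimized parameters), `ci` (lower/upper,
#'   `NA` = open), `identifiable`, `ensemble` (matrix of full parameter
#'   vectors within the threshold, for experiment ranking).
#' @export
profile_likelihood <- function(fit, param, datasets, nm = noise_model(),
                               n_points = 21, span = 2,
                               threshold = qchisq(0.95, 1),
                               control = list(iter.max = 100,
                                              eval.max = 200,
                                              rel.tol = 1e-6)) {
  stopifnot(inherits(fit, "grn_fit"), param %in% fit$free)
  spec <- fit$spec
  others <- setdiff(fit$free, param)
  lo <- fit$lower[[param]]; hi <- fit$upper[[param]]
  lo_o <- fit$lower[others]; hi_o <- fit$upper[others]
  center <- fit$best_logpar[[param]]

  prof_at <- function(fixed_log, start_others) {
    fixed <- c(setNames(10^fixed_log, param), fit$fixed)
    obj <- make_objective(spec, datasets, nm, fixed,
                          fit$initial_conditions)
    if (!length(others)) {
      return(list(value = obj(numeric(0)), par = numeric(0)))
    }
    res <- tryCatch(
      nlminb(start_others, obj,
             gradient = function(x) fd_gradient(obj, x),
             lower = lo_o, upper = hi_o, control = control),
      error = function(e) NULL)
    if (is.null(res)) list(value = NA_real_, par = start_others)
    else list(value = res$objective, par = res$par)
  }

  walk <- function(direction) {
    step <- span / ((n_points - 1) / 2)
    vals <- list()
    start <- fit$best_logpar[others]
    x <- center
    max_steps <- ceiling((if (direction > 0) hi - center else center - lo) /
                           step)
    for (k in seq_len(max_steps)) {
      x <- x + direction * step
      if (x > hi + 1e-9 || x < lo - 1e-9) break
      r <- prof_at(x, start)
      vals[[length(vals) + 1L]] <-
        c(value = x, chi2 = r$value, setNames(r$par, others))
      if (!is.na(r$value)) start <- r$par
      past_initial <- k >= (n_points - 1) / 2
      if (past_initial && !is.na(r$value) &&
          r$value - fit$value > threshold) break
    }
    vals
  }

  up <- walk(+1)
  down <- rev(walk(-1))
  mid <- c(value = center, chi2 = fit$value,
           fit$best_logpar[others])
  prof <- as.data.frame(do.call(rbind, c(down, list(mid), up)))
  prof$value <- 10^prof$value

  dchi <- prof$chi2 - min(prof$chi2, na.rm = TRUE)
  inside <- which(dchi <= threshold)
  ci <- c(lower = NA_real_, upper = NA_real_)
  ident <- c(lower = FALSE, upper = FALSE)
  if (length(inside)) {
    lo_i <- min(inside); hi_i <- max(inside)
    # lower side: crossing found iff a grid point above threshold precedes
    if (lo_i > 1) {
      ci["lower"] <- exp(approx(dchi[c(lo_i - 1, lo_i)],
                                log(prof$value[c(lo_i - 1, lo_i)]),
                                xout = threshold)$y)
      ident["lower"] <- TRUE
    }
    if (hi_i < nrow(prof)) {
      ci["upper"] <- exp(approx(dchi[c(hi_i, hi_i + 1)],
                                log(prof$value[c(hi_i, hi_i + 1)]),
                                xout = threshold)$y)
      ident["upper"] <- TRUE
    }
  }
  ensemble <- NULL
  if (length(inside)) {
    rows <- lapply(inside, function(i) {
      full <- c(setNames(prof$value[i], param),
                if (length(others)) setNames(10^unlist(prof[i, others]),
                                             others),
                fit$fixed)
      full[parameter_names(spec)]
    })
    ensemble <- do.call(rbind, rows)
  }
  structure(
    list(param = param, profile = prof, ci = ci,
         identifiable = all(ident), side_identifiable = ident,
         threshold = threshold, chi2_min = fit$value,
         ensemble = ensemble),
    class = "grn_profile"
  )
}

#' Rank candidate experiments by prediction spread per credit
#'
#' Simulates every candidate experiment for every parameter vector in an
#' ensemble (e.g. the profile-likelihood ensemble of parameter vectors
#' consistent with the current data) and ranks candidates by decreasing
#' prediction spread -- the maximum over measured species and time points of
#' the ensemble standard deviation -- per credit spent. Conditions whose
#' predictions all ensemble members agree on cannot reduce uncertainty and
#' rank last.
#'
#' @param spec A [network_spec()].
#' @param ensemble Matrix of parameter vectors (rows), columns named as
#'   [parameter_names()].
#' @param candidates List of candidates, each a list with `perturbations`
#'   (list of [perturbation()]s) and `request` (a [measurement_request()]).
#' @param prices A [price_table()].
#' @param initial_conditions Optional known IC vector.
#' @param t_end Measurement horizon.
#' @return Data frame (one row per candidate, ranked): `candidate`,
#'   `spread`, `cost`, `spread_per_credit`.
#' @export
rank_experiments <- function(spec, ensemble, candidates,
                             prices = price_table(),
                             initial_conditions = NULL, t_end = 20) {
  if (!length(candidates)) stop("empty candidate list")
  ensemble <- as.matrix(ensemble)
  stopifnot(nrow(ensemble) >= 1)
  rows <- lapply(seq_along(candidates), function(ci) {
    cand <- candidates[[ci]]
    grid <- measurement_grid(cand$request, t_end)
    sims <- lapply(seq_len(nrow(ensemble)), function(i) {
      model <- model_instance(spec, ensemble[i, ], initial_conditions)
      model <- Reduce(apply_perturbation, cand$perturbations %||% list(),
                      model)
      traj <- simulate_model(model, grid, rtol = 1e-6, atol = 1e-8)
      keep <- switch(cand$request$technology,
        fluorescence = cand$request$targets,
        microarray = grep("^m_", colnames(traj$values), value = TRUE),
        massspec = grep("^p_", colnames(traj$values), value = TRUE))
      traj$values[, keep, drop = FALSE]
    })
    arr <- simplify2array(sims) # time x species x ensemble
    spread <- if (nrow(ensemble) == 1L) 0 else {
      max(apply(arr, c(1, 2), sd))
    }
    cost <- measurement_cost(cand$request, prices) +
      sum(vapply(cand$perturbations %||% list(), perturbation_cost,
                 numeric(1), prices = prices))
    data.frame(candidate = ci, spread = spread, cost = cost,
               spread_per_credit = spread / cost)
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread_per_credit), ]
}
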