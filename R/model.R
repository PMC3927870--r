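#' Uniform sampling grid
#'
#' Time is non-dimensional (measured in units of the mRNA half-life).
#'
#' @param t0 Start time (default 0).
#' @param t_end End time (default 20, the prediction horizon).
#' @param step Sampling interval.
#' @return An object of class `time_grid` with a `times` vector of
#'   `N = (t_end - t0)/step + 1` points.
#' @export
time_grid <- function(t0 = 0, t_end = 20, step = 0.5) {
  stopifnot(t_end > t0, step > 0)
  times <- seq(t0, t_end, by = step)
  structure(list(t0 = t0, t_end = t_end, step = step, times = times),
            class = "time_grid")
}

#' Model instance
#'
#' Binds a topology to kinetic constants and initial conditions. Default
#' initial conditions are zero for every species (induction from scratch);
#' they can be overridden per species.
#'
#' @param spec A [network_spec()].
#' @param params Named numeric parameter vector (see [parameter_names()]).
#' @param initial_conditions Optional named numeric vector over (a subset
#'   of) [species_names()]; unnamed species start at 0.
#' @return An object of class `model_instance`.
#' @export
model_instance <- function(spec, params, initial_conditions = NULL) {
  params <- validate_parameters(spec, params)
  sp <- species_names(spec)
  ic <- setNames(numeric(length(sp)), sp)
  if (!is.null(initial_conditions)) {
    unknown <- setdiff(names(initial_conditions), sp)
    if (length(unknown)) stop("unknown species in initial conditions: ",
                              paste(unknown, collapse = ", "))
    if (any(initial_conditions < 0)) stop("initial conditions must be >= 0")
    ic[names(initial_conditions)] <- initial_conditions
  }
  structure(
    list(
      spec = spec, params = params, initial_conditions = ic,
      # perturbation state (virtual lab); all neutral for a fresh model
      deleted = character(0),
      mrna_deg_factor = setNames(rep(1, length(spec$genes)), gene_ids(spec))
    ),
    class = "model_instance"
  )
}

#' Hill regulation term
#'
#' Fractional promoter activity contributed by one regulator at
#' concentration `P`: repression `1 / (1 + (P/Kd)^h)`, activation
#' `(P/Kd)^h / (1 + (P/Kd)^h)`. Both equal 1/2 at `P = Kd` for any Hill
#' coefficient; repression decreases and activation increases in `P`.
#'
#' @param P Regulator concentration(s), `>= 0`.
#' @param Kd Dissociation constant, `> 0`.
#' @param h Hill coefficient, `> 0`.
#' @param sign `"activation"` or `"repression"` (or `"+"`/`"-"`).
#' @return Value(s) in `[0, 1]`.
#' @export
regulation_term <- function(P, Kd, h, sign) {
  if (!is.finite(Kd) || Kd <= 0) stop("invalid parameter: Kd must be > 0")
  if (!is.finite(h) || h <= 0) stop("invalid parameter: h must be > 0")
  if (any(P < 0)) stop("regulator concentration must be >= 0")
  sign <- switch(sign,
    "+" = "activation", "-" = "repression",
    activation = "activation", repression = "repression",
    stop("unknown sign: ", sign)
  )
  x <- (P / Kd)^h
  out <- if (sign == "repression") 1 / (1 + x) else x / (1 + x)
  # overflowing (P/Kd)^h means full saturation
  out[!is.finite(x)] <- if (sign == "repression") 0 else 1
  out
}

# Regulations whose target set includes `gene`.
regs_targeting <- function(spec, gene) {
  Filter(function(r) gene %in% r$targets, spec$regulations)
}

#' Production rate of a gene at a given state
#'
#' `mrna_protein` models: mRNA production is the promoter strength times the
#' product of all regulation terms acting on the gene (the promoter strength
#' itself, i.e. an empty product, for unregulated genes); protein production
#' is RBS strength times the mRNA level. `protein_only` models: protein
#' production is the basal rate (unregulated genes) plus the sum over
#' incoming regulations of synthesis rate times regulation term.
#'
#' @param gene Gene id.
#' @param state Named numeric vector of species concentrations.
#' @param model A [model_instance()].
#' @param what For `mrna_protein` models, `"mrna"` or `"protein"`.
#' @return Production rate (scalar).
#' @export
production_rate <- function(gene, state, model, what = c("mrna", "protein")) {
  spec <- model$spec
  if (!gene %in% gene_ids(spec)) stop("unknown gene id: ", gene)
  if (gene %in% model$deleted) return(0)
  p <- model$params
  regs <- regs_targeting(spec, gene)
  terms <- vapply(regs, function(r) {
    regulation_term(state[[paste0("p_", r$source)]],
                    p[[paste0(r$id, "_Kd")]], p[[paste0(r$id, "_h")]],
                    r$sign)
  }, numeric(1))
  if (spec$model_class == "mrna_protein") {
    what <- match.arg(what)
    if (what == "mrna") {
      p[[paste0(gene, "_pro")]] * prod(terms)
    } else {
      p[[paste0(gene, "_rbs")]] * state[[paste0("m_", gene)]]
    }
  } else {
    basal <- if (length(regs) == 0L) p[[paste0(gene, "_basal")]] else 0
    syn <- vapply(regs, function(r) p[[paste0(r$id, "_syn")]], numeric(1))
    basal + sum(syn * terms)
  }
}

# Reference R-level right-hand side; the compiled C version in src/ is the
# production path, this one backs it up in tests and odd debugging sessions.
grn_rhs_r <- function(t, y, model) {
  spec <- model$spec
  g <- gene_ids(spec)
  p <- model$params
  dy <- setNames(numeric(length(y)), names(y))
  for (gid in g) {
    if (gid %in% model$deleted) next
    if (spec$model_class == "mrna_protein") {
      m <- y[[paste0("m_", gid)]]
      dy[paste0("m_", gid)] <-
        production_rate(gid, y, model, "mrna") -
        model$mrna_deg_factor[[gid]] * m
      dy[paste0("p_", gid)] <-
        p[[paste0(gid, "_rbs")]] * m -
        p[["p_degradation_rate"]] * y[[paste0("p_", gid)]]
    } else {
      dy[paste0("p_", gid)] <-
        production_rate(gid, y, model) -
        p[[paste0(gid, "_deg")]] * y[[paste0("p_", gid)]]
    }
  }
  list(dy)
}

# Flatten a model instance into the numeric layout the C right-hand side
# reads: header [class, G, R, shared_pdeg], per-gene blocks of 4, then
# per-regulation blocks of 8 (source, n_targets, t1, t2, sign, Kd, h, syn).
pack_model <- function(model) {
  spec <- model$spec
  g <- gene_ids(spec)
  G <- length(g)
  R <- length(spec$regulations)
  p <- model$params
  cls <- if (spec$model_class == "mrna_protein") 1 else 2
  head <- c(cls, G, R,
            if (cls == 1) p[["p_degradation_rate"]] else 0)
  gene_block <- unlist(lapply(g, function(gid) {
    del <- as.numeric(gid %in% model$deleted)
    if (cls == 1) {
      c(p[[paste0(gid, "_pro")]], p[[paste0(gid, "_rbs")]],
        model$mrna_deg_factor[[gid]], del)
    } else {
      basal <- if (gid %in% unregulated_genes(spec)) {
        p[[paste0(gid, "_basal")]]
      } else 0
      c(p[[paste0(gid, "_deg")]], basal, 0, del)
    }
  }))
  reg_block <- unlist(lapply(spec$regulations, function(r) {
    tg <- match(r$targets, g)
    c(match(r$source, g), length(tg), tg[1], if (length(tg) == 2) tg[2] else 0,
      if (r$sign == "activation") 1 else -1,
      p[[paste0(r$id, "_Kd")]], p[[paste0(r$id, "_h")]],
      if (cls == 2) p[[paste0(r$id, "_syn")]] else 0)
  }))
  as.double(c(head, gene_block, reg_block))
}

#' Simulate a model on a time grid
#'
#' Deterministic integration of the network ODEs with a stiff-capable solver
#' (`deSolve::lsoda`, compiled right-hand side), relative tolerance `1e-8`
#' and absolute tolerance `1e-10` by default.
#'
#' Dynamics: `mrna_protein` models solve
#' `d mRNA_i/dt = production_i - mRNA_i` (mRNA degradation rate fixed at 1)
#' and `d P_i/dt = rbs_i * mRNA_i - delta_p * P_i`; `protein_only` models
#' solve `d P_i/dt = production_i - delta_i * P_i`.
#'
#' @param model A [model_instance()].
#' @param grid A [time_grid()].
#' @param rtol,atol Integrator tolerances.
#' @param maxsteps Maximum internal solver steps per output interval;
#'   exceeded = integration error (keeps pathological parameter corners
#'   from stalling fitting loops).
#' @return An object of class `trajectory`: list with `grid`, `times` and a
#'   time-by-species `values` matrix of noise-free concentrations.
#' @export
simulate_model <- function(model, grid = time_grid(), rtol = 1e-8,
                           atol = 1e-10, maxsteps = 5000) {
  stopifnot(inherits(model, "model_instance"), inherits(grid, "time_grid"))
  sp <- species_names(model$spec)
  y0 <- model$initial_conditions[sp]
  if (length(model$deleted)) {
    del_sp <- intersect(c(paste0("m_", model$deleted),
                          paste0("p_", model$deleted)), sp)
    y0[del_sp] <- 0
  }
  .Call(C_grn_set_model, pack_model(model))
  out <- try(deSolve::ode(
    y = unname(y0), times = grid$times, func = "grn_derivs",
    dllname = "grnlab", initfunc = NULL, parms = NULL,
    rtol = rtol, atol = atol, method = "lsoda", maxsteps = maxsteps
  ), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(grid$times)) {
    stop("integration error: solver failed (",
         if (inherits(out, "try-error")) attr(out, "condition")$message
         else paste0("stopped at t=", max(out[, 1])),
         "); consider loosening tolerances or checking parameters")
  }
  values <- out[, -1, drop = FALSE]
  colnames(values) <- sp
  # integration round-off can leave tiny negative excursions near zero
  values[values < 0 & values > -1e-9] <- 0
  structure(list(grid = grid, times = grid$times, values = values),
            class = "trajectory")
}

#' Steady state of a model
#'
#' Integrates to a long horizon and accepts the end state when every
#' component satisfies `|dx/dt| < tol * (1 + |x|)`; the state is then
#' polished by damped Newton iteration on the right-hand side. Models that
#' fail the derivative test (e.g. sustained oscillators) are flagged as
#' non-converged.
#'
#' @param model A [model_instance()].
#' @param t_max Integration horizon used for convergence detection.
#' @param tol Relative derivative tolerance.
#' @return List with `converged` (logical), `state` (named vector, `NA` when
#'   not converged) and `residual` (max scaled derivative at the end state).
#' @export
steady_state <- function(model, t_max = 500, tol = 1e-8) {
  grid <- time_grid(0, t_max, step = t_max / 100)
  traj <- simulate_model(model, grid)
  y <- traj$values[nrow(traj$values), ]
  dy <- grn_rhs_r(t_max, y, model)[[1]]
  resid <- max(abs(dy) / (1 + abs(y)))
  if (resid >= tol) {
    return(list(converged = FALSE, state = setNames(rep(NA_real_, length(y)),
                                                    names(y)),
                residual = resid))
  }
  # damped Newton polish with a finite-difference Jacobian
  f <- function(x) grn_rhs_r(t_max, setNames(x, names(y)), model)[[1]]
  x <- unname(y)
  for (it in 1:20) {
    fx <- f(x)
    if (max(abs(fx)) < 1e-13) break
    J <- matrix(0, length(x), length(x))
    hstep <- pmax(1e-7 * abs(x), 1e-9)
    for (j in seq_along(x)) {
      xp <- x; xp[j] <- xp[j] + hstep[j]
      J[, j] <- (f(xp) - fx) / hstep[j]
    }
    dx <- try(solve(J, -fx), silent = TRUE)
    if (inherits(dx, "try-error")) break
    xn <- pmax(x + dx, 0)
    if (max(abs(f(xn))) < max(abs(fx))) x <- xn else break
  }
  state <- setNames(x, names(y))
  dy <- grn_rhs_r(t_max, state, model)[[1]]
  list(converged = TRUE, state = state,
       residual = max(abs(dy) / (1 + abs(state))))
}
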