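#' Prediction submission
#'
#' Predicted time courses for the scored proteins on the challenge grid
#' (t = 0..20, step 0.5, N = 41 points).
#'
#' @param values Numeric time-by-protein matrix (41 rows), column names the
#'   protein species.
#' @param grid A [time_grid()] (default the challenge grid).
#' @return An object of class `prediction_submission`.
#' @export
prediction_submission <- function(values, grid = time_grid(0, 20, 0.5)) {
  values <- as.matrix(values)
  if (nrow(values) != length(grid$times)) {
    stop("prediction must have one row per grid point (",
         length(grid$times), ")")
  }
  if (any(values < 0)) stop("predicted concentrations must be >= 0")
  structure(list(values = values, grid = grid, times = grid$times),
            class = "prediction_submission")
}

# Scored window: literal indexing of the challenge formula. With 1-based
# grid indices (t_1 = 0), the sum runs from the 11th point (t = 5.0) to
# N = 41, i.e. 31 points per protein, while the normalizer is 3 * (N - 11).
scored_indices <- function(N) 11:N

#' Protein prediction distance
#'
#' Variance-weighted mean squared distance between the predicted and
#' noise-free simulated protein time courses, evaluated from the 11th time
#' point onwards:
#' `D_prot = 1/(K(N-11)) * sum_k sum_{i=11}^{N}
#'   (pred_k(t_i) - sim_k(t_i))^2 / (sigma_b^2 + sigma_s^2 sim_k(t_i)^2)`
#' with K the number of scored proteins (3 in the challenge).
#'
#' @param pred A [prediction_submission()] (or bare matrix on the same grid).
#' @param gold Noise-free gold time-by-protein matrix on the same grid, with
#'   the same columns.
#' @param nm A [noise_model()] supplying the variance weights.
#' @return Non-negative scalar distance.
#' @export
protein_distance <- function(pred, gold, nm = noise_model()) {
  pv <- if (inherits(pred, "prediction_submission")) pred$values else pred
  gv <- if (inherits(gold, "trajectory")) gold$values else gold
  if (!all(dim(pv) == dim(gv))) stop("grid mismatch between pred and gold")
  N <- nrow(pv)
  idx <- scored_indices(N)
  num <- (pv[idx, , drop = FALSE] - gv[idx, , drop = FALSE])^2
  den <- noise_variance(gv[idx, , drop = FALSE], nm)
  sum(num / den) / (ncol(pv) * (N - 11))
}

#' Parameter prediction distance
#'
#' Mean squared log10 ratio between predicted and true parameter values:
#' `D_param = 1/Np * sum_i (log10(v_i^pred / v_i^real))^2`. A mismatch by a
#' factor of x costs the same whatever the parameter's nominal value, and
#' the distance is symmetric in pred/real.
#'
#' @param pred,gold Named positive numeric vectors over the same parameters.
#' @return Non-negative scalar distance.
#' @export
parameter_distance <- function(pred, gold) {
  if (is.null(names(pred)) || is.null(names(gold))) {
    stopifnot(length(pred) == length(gold))
  } else {
    missing <- setdiff(names(gold), names(pred))
    if (length(missing)) {
      stop("missing parameters: ", paste(missing, collapse = ", "))
    }
    pred <- pred[names(gold)]
  }
  if (any(pred <= 0) || any(gold <= 0)) {
    stop("parameter values must be strictly positive")
  }
  mean(log10(pred / gold)^2)
}

#' Resampling null p-value for protein predictions
#'
#' Builds composite predictions by drawing, independently for every scored
#' protein and time point, the value submitted by a uniformly random team,
#' and compares the team's distance against the distribution of composite
#' distances (the "relative" null: a submission is only credited for being
#' better than recombinations of the whole field).
#'
#' With `method = "sample"`, `B` composites are drawn and
#' `p = (1 + #\{D_null <= D_team\}) / (B + 1)` (add-one smoothing keeps
#' p > 0). With `method = "exhaustive"` (feasible only for toy pools) all
#' `n_teams^(cells)` composites are enumerated and the exact tail
#' proportion is returned.
#'
#' @param submissions List of [prediction_submission()]s (>= 2).
#' @param team Index of the scored team in `submissions`.
#' @param gold Gold time-by-protein matrix on the shared grid.
#' @param nm A [noise_model()].
#' @param B Number of resamples.
#' @param seed Optional integer seed.
#' @param method `"sample"` or `"exhaustive"`.
#' @return List with `p`, the team's distance `D`, and `null` (class
#'   `null_distribution`: sampled statistic values, `B`, `seed`).
#' @export
null_pvalue_protein <- function(submissions, team, gold, nm = noise_model(),
                                B = 1e5, seed = NULL,
                                method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(length(submissions) >= 2L, B >= 1)
  gv <- if (inherits(gold, "trajectory")) gold$values else gold
  vals <- lapply(submissions, function(s) {
    v <- if (inherits(s, "prediction_submission")) s$values else s
    if (!all(dim(v) == dim(gv))) stop("grid mismatch in submission")
    v
  })
  D_team <- protein_distance(vals[[team]], gv, nm)
  N <- nrow(gv); K <- ncol(gv)
  idx <- scored_indices(N)
  # per-cell scored contributions for each team: (len(idx) * K) x n_teams
  den <- noise_variance(gv[idx, , drop = FALSE], nm)
  contrib <- vapply(vals, function(v) {
    as.vector((v[idx, , drop = FALSE] - gv[idx, , drop = FALSE])^2 / den)
  }, numeric(length(idx) * K))
  norm <- K * (N - 11)
  if (method == "exhaustive") {
    n_comp <- length(vals)^nrow(contrib)
    if (n_comp > 2e5) stop("composite space too large to enumerate")
    choices <- expand.grid(rep(list(seq_along(vals)), nrow(contrib)))
    D_null <- apply(choices, 1L, function(ch) {
      sum(contrib[cbind(seq_len(nrow(contrib)), ch)]) / norm
    })
    p <- mean(D_null <= D_team + 1e-12)
  } else {
    D_null <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        ch <- sample.int(length(vals), nrow(contrib), replace = TRUE)
        sum(contrib[cbind(seq_len(nrow(contrib)), ch)]) / norm
      }, numeric(1))
    })
    p <- (1 + sum(D_null <= D_team + 1e-12)) / (B + 1)
  }
  list(p = p, D = D_team,
       null = structure(list(values = D_null, B = length(D_null),
                             seed = seed), class = "null_distribution"))
}

#' Resampling null p-value for parameter predictions
#'
#' As [null_pvalue_protein()], but the composite draws one team's value
#' independently for each parameter.
#'
#' @param submissions List of named positive parameter vectors (>= 2).
#' @param team Index of the scored team.
#' @param gold Named positive vector of true parameter values.
#' @param B Number of resamples.
#' @param seed Optional integer seed.
#' @param method `"sample"` or `"exhaustive"`.
#' @return List with `p`, `D` and `null` as in [null_pvalue_protein()].
#' @export
null_pvalue_parameter <- function(submissions, team, gold, B = 1e5,
                                  seed = NULL,
                                  method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(length(submissions) >= 2L, B >= 1)
  contrib <- vapply(submissions, function(s) {
    s <- if (!is.null(names(s))) s[names(gold)] else s
    log10(s / gold)^2
  }, numeric(length(gold)))
  D_team <- mean(contrib[, team])
  Np <- length(gold)
  if (method == "exhaustive") {
    n_comp <- length(submissions)^Np
    if (n_comp > 2e5) stop("composite space too large to enumerate")
    choices <- expand.grid(rep(list(seq_along(submissions)), Np))
    D_null <- apply(choices, 1L, function(ch) {
      mean(contrib[cbind(seq_len(Np), ch)])
    })
    p <- mean(D_null <= D_team + 1e-12)
  } else {
    D_null <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        ch <- sample.int(length(submissions), Np, replace = TRUE)
        mean(contrib[cbind(seq_len(Np), ch)])
      }, numeric(1))
    })
    p <- (1 + sum(D_null <= D_team + 1e-12)) / (B + 1)
  }
  list(p = p, D = D_team,
       null = structure(list(values = D_null, B = length(D_null),
                             seed = seed), class = "null_distribution"))
}

#' Combined parameter-estimation score
#'
#' `Score1 = -log10(p_prot * p_param)`.
#'
#' @param p_prot,p_param P-values in (0, 1].
#' @return Non-negative score.
#' @examples
#' score1(1.21e-25, 3.25e-3) # ~27.4
#' @export
score1 <- function(p_prot, p_param) {
  stopifnot(p_prot > 0, p_prot <= 1, p_param > 0, p_param <= 1)
  -log10(p_prot * p_param)
}

#' Combined topology-inference score
#'
#' `Score2 = -log10(p_netw)`.
#'
#' @param p_netw P-value in (0, 1].
#' @return Non-negative score.
#' @examples
#' score2(1.49e-2) # ~1.83
#' @export
score2 <- function(p_netw) {
  stopifnot(p_netw > 0, p_netw <= 1)
  -log10(p_netw)
}
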