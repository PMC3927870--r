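#' Submission pool
#'
#' Ordered collection of team submissions. The order is meaningful: the
#' aggregation functions operate on the first `k` entries, so a pool sorted
#' best-to-worst yields forward rank-order aggregation.
#'
#' @param teams Character vector of team ids.
#' @param parameters Optional list of named parameter vectors (one per team).
#' @param predictions Optional list of [prediction_submission()]s or
#'   matrices on a shared grid.
#' @param links Optional list of per-team lists of [link_prediction()]s.
#' @return An object of class `submission_pool`.
#' @export
submission_pool <- function(teams, parameters = NULL, predictions = NULL,
                            links = NULL) {
  n <- length(teams)
  for (x in list(parameters, predictions, links)) {
    if (!is.null(x) && length(x) != n) {
      stop("every supplied component must have one entry per team")
    }
  }
  if (!is.null(parameters)) {
    nms <- lapply(parameters, function(p) sort(names(p)))
    if (!all(vapply(nms, identical, logical(1), nms[[1]]))) {
      stop("all parameter submissions must cover the same parameters")
    }
  }
  structure(list(teams = teams, parameters = parameters,
                 predictions = predictions, links = links),
            class = "submission_pool")
}

pred_values <- function(x) {
  if (inherits(x, "prediction_submission")) x$values else as.matrix(x)
}

#' Aggregate predictions by arithmetic mean
#'
#' Per-protein, per-time-point arithmetic mean over the first `k` teams of
#' the pool.
#'
#' @param pool A [submission_pool()] with predictions.
#' @param k Number of leading teams to aggregate.
#' @return Time-by-protein matrix of aggregated predictions.
#' @export
aggregate_predictions <- function(pool, k = length(pool$teams)) {
  stopifnot(!is.null(pool$predictions), k >= 1, k <= length(pool$teams))
  vals <- lapply(pool$predictions[seq_len(k)], pred_values)
  Reduce(`+`, vals) / k
}

#' Aggregate parameters by geometric mean
#'
#' Per-parameter geometric mean over the first `k` teams; the natural
#' average when team values can disagree by orders of magnitude, and the
#' minimizer of the squared-log-ratio distance.
#'
#' @param pool A [submission_pool()] with parameters.
#' @param k Number of leading teams to aggregate.
#' @return Named vector of aggregated parameter values.
#' @export
aggregate_parameters <- function(pool, k = length(pool$teams)) {
  stopifnot(!is.null(pool$parameters), k >= 1, k <= length(pool$teams))
  subs <- pool$parameters[seq_len(k)]
  if (any(vapply(subs, function(s) any(s <= 0), logical(1)))) {
    stop("parameter values must be strictly positive")
  }
  nms <- names(subs[[1]])
  logs <- vapply(subs, function(s) log(s[nms]), numeric(length(nms)))
  out <- exp(rowMeans(matrix(logs, nrow = length(nms))))
  setNames(out, nms)
}

#' Consensus links by vote counting
#'
#' Canonicalizes each submitted link (destinations sorted), tallies how
#' often each distinct link was submitted across the pool, and returns the
#' three most popular; ties break lexicographically on (source, sign,
#' destinations) so the result is deterministic.
#'
#' @param pool A [submission_pool()] with links.
#' @return List of up to 3 [link_prediction()]s, with attributes `votes`
#'   (named tally) and `incomplete` (TRUE when fewer than 3 distinct links
#'   were submitted).
#' @export
consensus_links <- function(pool) {
  stopifnot(!is.null(pool$links))
  all_links <- unlist(pool$links, recursive = FALSE)
  if (!length(all_links)) stop("no link submissions in pool")
  keys <- vapply(all_links, link_key, character(1))
  tally <- sort(table(keys), decreasing = TRUE)
  # deterministic tie-break: lexicographic within equal counts
  ord <- order(-as.vector(tally), names(tally))
  tally <- tally[ord]
  top <- head(names(tally), 3L)
  out <- lapply(top, function(k) all_links[[match(k, keys)]])
  attr(out, "votes") <- tally
  attr(out, "incomplete") <- length(out) < 3L
  out
}

#' Aggregation curves: distance versus number of aggregated teams
#'
#' For k = 1..n teams taken in pool order ("forward", typically
#' best-to-worst) and in reverse order, computes the parameter distance of
#' the k-team geometric-mean aggregate and/or the protein distance of the
#' k-team arithmetic-mean aggregate against the gold standard.
#'
#' @param pool A [submission_pool()] ordered best-to-worst.
#' @param gold_params Named true parameter vector (or NULL to skip).
#' @param gold_pred Gold time-by-protein matrix (or NULL to skip).
#' @param nm A [noise_model()] for the protein distance.
#' @return Data frame with columns `k`, `order` (forward/reverse), and
#'   `D_param` / `D_prot` where computable.
#' @export
aggregation_curves <- function(pool, gold_params = NULL, gold_pred = NULL,
                               nm = noise_model()) {
  n <- length(pool$teams)
  rev_pool <- pool
  for (f in c("parameters", "predictions", "links")) {
    if (!is.null(rev_pool[[f]])) rev_pool[[f]] <- rev(rev_pool[[f]])
  }
  rev_pool$teams <- rev(rev_pool$teams)
  one <- function(p, ord) {
    data.frame(
      k = seq_len(n), order = ord,
      D_param = if (!is.null(gold_params) && !is.null(p$parameters)) {
        vapply(seq_len(n), function(k) {
          parameter_distance(aggregate_parameters(p, k), gold_params)
        }, numeric(1))
      } else NA_real_,
      D_prot = if (!is.null(gold_pred) && !is.null(p$predictions)) {
        vapply(seq_len(n), function(k) {
          protein_distance(aggregate_predictions(p, k), gold_pred, nm)
        }, numeric(1))
      } else NA_real_
    )
  }
  rbind(one(pool, "forward"), one(rev_pool, "reverse"))
}

#' Sensitivity of the protein distance to individual parameters
#'
#' For every parameter, the ordinary least-squares R-squared of the teams'
#' submitted values against their protein prediction distances
#' (untransformed), identifying which parameters the scored predictions
#' actually depend on. Also reports the pooled R-squared of a log-log fit
#' of D_param against D_prot across teams.
#'
#' @param pool A [submission_pool()] with parameters and predictions.
#' @param gold_params Named true parameter vector.
#' @param gold_pred Gold time-by-protein matrix.
#' @param nm A [noise_model()].
#' @return List with `per_parameter` (named R-squared vector, `NA` where a
#'   parameter is constant across teams), `overall_r2` (log-log D_param vs
#'   D_prot), and the per-team `D_param` / `D_prot` vectors.
#' @export
parameter_sensitivity <- function(pool, gold_params, gold_pred,
                                  nm = noise_model()) {
  n <- length(pool$teams)
  stopifnot(n >= 3L, !is.null(pool$parameters), !is.null(pool$predictions))
  D_prot <- vapply(seq_len(n), function(i) {
    protein_distance(pool$predictions[[i]], gold_pred, nm)
  }, numeric(1))
  D_param <- vapply(seq_len(n), function(i) {
    parameter_distance(pool$parameters[[i]], gold_params)
  }, numeric(1))
  nms <- names(gold_params)
  r2 <- vapply(nms, function(pn) {
    v <- vapply(pool$parameters, function(s) s[[pn]], numeric(1))
    if (var(v) == 0 || var(D_prot) == 0) return(NA_real_)
    suppressWarnings(summary(lm(D_prot ~ v))$r.squared)
  }, numeric(1))
  lp <- log10(D_param); lq <- log10(D_prot)
  overall <- if (all(is.finite(lp)) && all(is.finite(lq)) &&
                 var(lp) > 0 && var(lq) > 0) {
    suppressWarnings(summary(lm(lp ~ lq))$r.squared)
  } else NA_real_
  list(per_parameter = r2, overall_r2 = overall,
       D_param = D_param, D_prot = D_prot)
}
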