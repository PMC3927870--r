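#' Link prediction
#'
#' One predicted regulatory link: a source gene, a sign, and one or two
#' destination genes (two only within one operon). Destinations are stored
#' sorted so that equivalent links canonicalize identically (used by
#' consensus voting).
#'
#' @param source Source gene id.
#' @param sign `"+"`/`"-"` (or `activation`/`repression`).
#' @param destinations Character vector of 1-2 destination gene ids.
#' @return An object of class `link_prediction`.
#' @export
link_prediction <- function(source, sign, destinations) {
  sign <- switch(sign,
    "+" = "+", "-" = "-", activation = "+", repression = "-",
    stop("sign must be +/-")
  )
  stopifnot(length(destinations) %in% 1:2)
  structure(list(source = source, sign = sign,
                 destinations = sort(destinations)),
            class = "link_prediction")
}

link_key <- function(l) {
  paste(l$source, l$sign, paste(l$destinations, collapse = ","), sep = "|")
}

# Score of one predicted link against one true link.
# L = 6 when source, sign and destination all match (12 when both operon
# destinations are correct); otherwise partial credit N < 6: +1 for the
# correct source gene, and per correct destination gene +1, upgraded to +2
# when the sign is also correct. A correct sign with no correct gene earns
# nothing.
link_pair_score <- function(pred, truth) {
  src_ok <- identical(pred$source, truth$source)
  sign_ok <- identical(pred$sign, truth$sign)
  dest_hits <- intersect(pred$destinations, truth$destinations)
  if (src_ok && sign_ok && setequal(pred$destinations, truth$destinations)) {
    return(if (length(truth$destinations) == 2L) 12 else 6)
  }
  N <- as.numeric(src_ok)
  N + length(dest_hits) * (if (sign_ok) 2 else 1)
}

#' Score a predicted link against the true links
#'
#' A full match of source, sign and destination earns 6 points (12 when the
#' link drives a two-gene operon and both connections are correct);
#' otherwise partial credit below 6 is given per correctly implicated gene,
#' with a correctly signed destination worth 2. Against a set of true links
#' the best pairing is reported.
#'
#' @param pred A [link_prediction()].
#' @param truth A [link_prediction()] or list of them (the true links).
#' @return Score in `{0, ..., 6} U {12}`.
#' @export
link_score <- function(pred, truth) {
  if (inherits(truth, "link_prediction")) truth <- list(truth)
  max(vapply(truth, link_pair_score, numeric(1), pred = pred))
}

#' Score a 3-link submission
#'
#' `s_network = s_1 + s_2 + s_3` under the score-maximal one-to-one
#' assignment of the three predicted links to the three true links (exact
#' search over the 6 permutations; deterministic and invariant to the order
#' links are listed in).
#'
#' @param predictions List of exactly 3 [link_prediction()]s.
#' @param truth List of exactly 3 true [link_prediction()]s.
#' @return Total network score.
#' @export
network_score <- function(predictions, truth) {
  if (length(predictions) != 3L) stop("exactly 3 predicted links required")
  stopifnot(length(truth) == 3L)
  S <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j) {
    link_pair_score(predictions[[i]], truth[[j]])
  }))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  max(vapply(perms, function(pp) sum(S[cbind(1:3, pp)]), numeric(1)))
}

#' Universe of admissible candidate links
#'
#' All links that could be added to a (partial) network under the challenge
#' connection rules: a source gene may establish at most two regulating
#' links in total (counting the visible ones), a destination is a single
#' gene or a whole two-gene operon, and each sign is allowed. Links
#' duplicating a visible regulation's source/destination pair are excluded.
#'
#' @param spec A [network_spec()] (the visible topology).
#' @return List of [link_prediction()]s.
#' @export
link_universe <- function(spec) {
  g <- gene_ids(spec)
  operons <- vapply(spec$genes, function(x) {
    if (is.null(x$operon_id)) NA_character_ else x$operon_id
  }, character(1))
  out_counts <- table(factor(
    vapply(spec$regulations, `[[`, character(1), "source"), levels = g))
  existing <- vapply(spec$regulations, function(r) {
    paste(r$source, paste(sort(r$targets), collapse = ","), sep = "|")
  }, character(1))
  # destination choices: single genes plus complete operons
  dests <- c(as.list(g),
             lapply(unique(operons[!is.na(operons)]),
                    function(o) g[which(operons == o)]))
  dests <- dests[vapply(dests, length, integer(1)) <= 2]
  universe <- list()
  for (src in g[out_counts < 2]) {
    for (d in dests) {
      if (src %in% d) next
      if (paste(src, paste(sort(d), collapse = ","), sep = "|")
          %in% existing) next
      for (sgn in c("+", "-")) {
        universe[[length(universe) + 1L]] <- link_prediction(src, sgn, d)
      }
    }
  }
  universe
}

#' Resampling null p-value for a 3-link submission
#'
#' Scores random admissible 3-link sets (drawn from [link_universe()],
#' keeping each source within its two-outgoing-links allowance) and reports
#' the upper-tail p-value of the team's network score:
#' `p = (1 + #\{s_null >= s_team\}) / (B + 1)` for sampling, or the exact
#' tail proportion over all 3-subsets with `method = "exhaustive"`.
#'
#' @param spec The visible [network_spec()] (with the hidden links removed).
#' @param truth List of the 3 true [link_prediction()]s.
#' @param s_team The team's network score (or a list of 3 predicted links).
#' @param B Number of random 3-link sets.
#' @param seed Optional integer seed.
#' @param method `"sample"` or `"exhaustive"`.
#' @return List with `p`, `s` and `null` (a `null_distribution`).
#' @export
null_pvalue_network <- function(spec, truth, s_team, B = 1e5, seed = NULL,
                                method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  if (is.list(s_team) && !is.numeric(s_team)) {
    s_team <- network_score(s_team, truth)
  }
  universe <- link_universe(spec)
  if (length(universe) < 3L) stop("link universe too small")
  sources <- vapply(universe, `[[`, character(1), "source")
  out_counts <- table(factor(
    vapply(spec$regulations, `[[`, character(1), "source"),
    levels = gene_ids(spec)))
  set_ok <- function(ix) {
    tb <- table(sources[ix])
    all(tb + out_counts[names(tb)] <= 2)
  }
  if (method == "exhaustive") {
    combos <- utils::combn(length(universe), 3L, simplify = FALSE)
    combos <- Filter(set_ok, combos)
    if (!length(combos)) stop("empty admissible 3-link universe")
    s_null <- vapply(combos, function(ix) {
      network_score(universe[ix], truth)
    }, numeric(1))
    p <- mean(s_null >= s_team)
  } else {
    s_null <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        repeat {
          ix <- sample.int(length(universe), 3L)
          if (set_ok(ix)) break
        }
        network_score(universe[ix], truth)
      }, numeric(1))
    })
    p <- (1 + sum(s_null >= s_team)) / (B + 1)
  }
  list(p = p, s = s_team,
       null = structure(list(values = s_null, B = length(s_null),
                             seed = seed), class = "null_distribution"))
}
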