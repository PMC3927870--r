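#' Random network generator
#'
#' Draws a topology obeying the challenge universe rules: each source gene
#' establishes at most two regulating links, each target receives at most
#' two regulations, a two-target link must target a whole operon, no
#' duplicated source/target pair, no self-regulation. Seeded-deterministic.
#'
#' @param n_genes Number of genes.
#' @param n_regulations Number of regulations requested.
#' @param model_class `"mrna_protein"` or `"protein_only"`.
#' @param n_operons Number of two-gene operons (protein_only only; pairs
#'   consecutive genes).
#' @param p_operon_target Probability that a link to an operon member
#'   targets the whole operon.
#' @param seed Optional integer seed.
#' @return A [network_spec()].
#' @export
random_network <- function(n_genes, n_regulations,
                           model_class = "mrna_protein", n_operons = 0,
                           p_operon_target = 0.5, seed = NULL) {
  if (n_regulations > 2 * n_genes) {
    stop("infeasible: at most 2 outgoing links per gene")
  }
  if (model_class == "mrna_protein" && n_operons > 0) {
    stop("mrna_protein models have no operons")
  }
  stopifnot(2 * n_operons <= n_genes)
  with_seed(seed, {
    ids <- paste0("g", seq_len(n_genes))
    operon_of <- setNames(rep(NA_character_, n_genes), ids)
    if (n_operons > 0) {
      for (k in seq_len(n_operons)) {
        operon_of[ids[c(2 * k - 1, 2 * k)]] <- paste0("o", k)
      }
    }
    genes <- lapply(ids, function(g) {
      gene_spec(g, if (is.na(operon_of[[g]])) NULL else operon_of[[g]])
    })
    out_cnt <- setNames(integer(n_genes), ids)
    in_cnt <- setNames(integer(n_genes), ids)
    pairs <- character(0)
    regs <- list()
    tries <- 0
    while (length(regs) < n_regulations) {
      tries <- tries + 1
      if (tries > 500 * n_regulations) {
        stop("infeasible regulation count for this configuration")
      }
      src <- sample(ids[out_cnt < 2], 1)
      tgt1 <- sample(setdiff(ids[in_cnt < 2], src), 1)
      targets <- tgt1
      if (!is.na(operon_of[[tgt1]]) && runif(1) < p_operon_target) {
        mate <- setdiff(ids[which(operon_of == operon_of[[tgt1]])], tgt1)
        if (length(mate) && in_cnt[[mate]] < 2 && mate != src) {
          targets <- c(tgt1, mate)
        }
      }
      key <- paste(src, paste(sort(targets), collapse = ","), sep = "|")
      if (key %in% pairs) next
      pairs <- c(pairs, key)
      out_cnt[src] <- out_cnt[src] + 1L
      in_cnt[targets] <- in_cnt[targets] + 1L
      regs[[length(regs) + 1L]] <- regulation_spec(
        paste0("r", length(regs) + 1L), src, targets,
        sample(c("activation", "repression"), 1))
    }
    network_spec(genes, regs, model_class)
  })
}

#' Random parameter draws for a network
#'
#' Log-uniform draws within per-class ranges chosen to give dynamics on the
#' t in 0..20 horizon: Kd in 0.1..10, Hill coefficient in 1..4, promoter /
#' RBS / synthesis / basal strengths in 0.1..5, degradation rates in
#' 0.1..1.
#'
#' @param spec A [network_spec()].
#' @param ranges Named list of `c(lower, upper)` overrides per class
#'   (`Kd`, `h`, `strength`, `degradation`).
#' @param seed Optional integer seed.
#' @return Named parameter vector satisfying [validate_parameters()].
#' @export
random_parameters <- function(spec, ranges = list(), seed = NULL) {
  rg <- modifyList(list(Kd = c(0.1, 10), h = c(1, 4),
                        strength = c(0.1, 5), degradation = c(0.1, 1)),
                   ranges)
  nms <- parameter_names(spec)
  cls <- function(nm) {
    if (grepl("_Kd$", nm)) "Kd"
    else if (grepl("_h$", nm)) "h"
    else if (grepl("_deg$|degradation", nm)) "degradation"
    else "strength"
  }
  with_seed(seed, {
    vals <- vapply(nms, function(nm) {
      r <- rg[[cls(nm)]]
      exp(runif(1, log(r[1]), log(r[2])))
    }, numeric(1))
    setNames(vals, nms)
  })
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "grnlab", mustWork = TRUE)
}

#' Parameter-estimation benchmark model (9 genes, 45 parameters)
#'
#' A 9-gene `mrna_protein` network with 13 regulations and one unregulated
#' gene (g6), yielding the canonical 45-parameter decomposition (9 promoter
#' + 9 RBS strengths, 13 Kd + 13 Hill coefficients, 1 shared protein
#' degradation rate). Topology and default parameter values are synthetic
#' (implementer-chosen, stored in
#' `inst/extdata/model1_synthetic.json`): the published challenge's hidden
#' gold values are not reproduced here.
#'
#' @return A [model_instance()].
#' @export
model1_fixture <- function() {
  read_model(fixture_path("model1_synthetic.json"))
}

#' Topology-inference benchmark model (11 genes, 61 parameters)
#'
#' An 11-gene `protein_only` network with 16 regulations, two unregulated
#' genes carrying basal rates (g5, g11), one two-gene operon (g6/g7), and a
#' negative-feedback core that produces sustained oscillations from the
#' default parameters. Three designated links (`r9`, `r10`, `r12`; attribute
#' `hidden_links`) are the ones a topology-inference session hides.
#' Synthetic stand-in stored in `inst/extdata/model2_synthetic.json`.
#'
#' @return A [model_instance()] with attribute `hidden_links`.
#' @export
model2_fixture <- function() {
  m <- read_model(fixture_path("model2_synthetic.json"))
  attr(m, "hidden_links") <- c("r9", "r10", "r12")
  m
}

#' Open a challenge session over a hidden model
#'
#' Wraps a truth model behind the virtual-lab surface: participants see the
#' topology (minus the hidden links in topology mode) but never the
#' parameter values; data arrives only through priced, noisy experiments
#' (or exact gel-shift purchases), and scoring happens against the retained
#' truth. All purchase noise flows from one seeded stream so a session
#' replays bit-identically from (model, budget, seed).
#'
#' @param model The truth [model_instance()] (e.g. [model1_fixture()]).
#' @param budget Starting credits (required; the budget is a property of
#'   the study design, not a package default).
#' @param prices A [price_table()].
#' @param seed Integer seed for the session's noise stream.
#' @param hidden_links Regulation ids to hide (defaults to the model's
#'   `hidden_links` attribute; empty = parameter-estimation mode).
#' @return An object of class `grn_challenge`: list of closures
#'   `visible_spec()`, `balance()`, `transactions()`, `initial_data()`,
#'   `buy(perturbations, request)`, `buy_gelshift(regulation)`,
#'   `score_parameters(pred)`, `score_links(predictions)`,
#'   `gold_predictions(perturbations, proteins)`. No closure returns the
#'   hidden parameter values.
#' @export
make_challenge <- function(model, budget, prices = price_table(),
                           seed = 1L,
                           hidden_links = attr(model, "hidden_links")) {
  force(model); force(prices)
  hidden_links <- hidden_links %||% character(0)
  stopifnot(all(hidden_links %in% regulation_ids(model$spec)))
  ledger <- credit_ledger(budget)
  draw <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      # sub-seed derived from the session seed; kept below 2^31
      (seed * 10007L + counter) %% .Machine$integer.max
    }
  })
  visible <- model$spec
  if (length(hidden_links)) {
    keep <- !vapply(visible$regulations, function(r) r$id %in% hidden_links,
                    logical(1))
    visible <- network_spec(visible$genes, visible$regulations[keep],
                            visible$model_class)
  }
  truth_links <- lapply(
    Filter(function(r) r$id %in% hidden_links, model$spec$regulations),
    function(r) link_prediction(
      r$source, if (r$sign == "activation") "+" else "-", r$targets))

  obj <- list(
    visible_spec = function() visible,
    balance = function() ledger$balance,
    transactions = function() ledger$transactions,
    initial_data = function() {
      if (model$spec$model_class != "mrna_protein") {
        stop("initial microarray data exists only for mrna_protein models")
      }
      initial_dataset(model, seed = draw())
    },
    buy = function(perturbations = list(), request) {
      res <- run_experiment(model, perturbations, request, ledger,
                            seed = draw(), prices = prices)
      ledger <<- res$ledger
      res$dataset
    },
    buy_gelshift = function(regulation) {
      if (regulation %in% hidden_links) {
        stop("unknown regulation id: ", regulation) # hidden from the session
      }
      res <- gelshift(model, regulation, ledger, prices)
      ledger <<- res$ledger
      res[c("Kd", "h")]
    },
    score_parameters = function(pred) {
      parameter_distance(pred, model$params)
    },
    score_links = function(predictions) {
      if (!length(truth_links)) stop("no hidden links in this session")
      network_score(predictions, truth_links)
    },
    gold_predictions = function(perturbations = list(),
                                proteins, grid = time_grid(0, 20, 0.5)) {
      pert <- Reduce(apply_perturbation, perturbations, model)
      simulate_model(pert, grid)$values[, proteins, drop = FALSE]
    }
  )
  class(obj) <- "grn_challenge"
  obj
}
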