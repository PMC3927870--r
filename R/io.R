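#' Read a model from its JSON document
#'
#' Schema (version 1): top-level fields `model_class`, `genes` (objects with
#' `id` and optional `operon`), `regulations` (objects with `id`, `source`,
#' `targets`, `sign`), `parameters` (name/value map), and optional
#' `initial_conditions`. Violations raise errors naming the offending field.
#'
#' @param path Path to a model JSON file.
#' @return A [model_instance()].
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("model_class", "genes", "regulations", "parameters")) {
    if (is.null(doc[[f]])) stop("model schema error: missing field '", f, "'")
  }
  genes <- lapply(doc$genes, function(g) {
    if (is.null(g$id)) stop("model schema error: gene without id")
    gene_spec(g$id, g$operon)
  })
  regulations <- lapply(doc$regulations, function(r) {
    for (f in c("id", "source", "targets", "sign")) {
      if (is.null(r[[f]])) {
        stop("model schema error: regulation ",
             r$id %||% "<unnamed>", " missing field '", f, "'")
      }
    }
    regulation_spec(r$id, r$source, unlist(r$targets), r$sign)
  })
  spec <- network_spec(genes, regulations, doc$model_class)
  params <- unlist(doc$parameters)
  ic <- if (!is.null(doc$initial_conditions)) unlist(doc$initial_conditions)
  model_instance(spec, params, ic)
}

#' Write a model to canonical JSON
#'
#' Writes the schema described in [read_model()]; `write_model()` then
#' [read_model()] is the identity on canonical form (sorted destinations,
#' parameters in canonical order, explicit initial conditions).
#'
#' @param model A [model_instance()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  spec <- model$spec
  doc <- list(
    schema_version = 1L,
    model_class = spec$model_class,
    genes = lapply(spec$genes, function(g) {
      out <- list(id = g$id)
      if (!is.null(g$operon_id)) out$operon <- g$operon_id
      out
    }),
    regulations = lapply(spec$regulations, function(r) {
      list(id = r$id, source = r$source, targets = as.list(r$targets),
           sign = r$sign)
    }),
    parameters = as.list(model$params[parameter_names(spec)]),
    initial_conditions = as.list(model$initial_conditions)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a trajectory or dataset as long-format CSV
#'
#' Columns `time`, `species`, `value` (UTF-8, '.' decimal). For datasets a
#' JSON provenance sidecar (`<path>.json`) records perturbations,
#' technology, resolution, cost and noise seed, which suffices to
#' regenerate the dataset from the model.
#'
#' @param x A `trajectory` or `grn_dataset`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_timecourse <- function(x, path) {
  v <- x$values
  df <- data.frame(
    time = rep(x$times, times = ncol(v)),
    species = rep(colnames(v), each = nrow(v)),
    value = as.vector(v)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (inherits(x, "grn_dataset")) {
    side <- list(
      technology = x$technology, resolution = x$resolution,
      cost = x$cost, seed = x$seed,
      perturbations = lapply(x$perturbations, function(p) {
        out <- list(kind = p$kind, target = p$target)
        if (!is.null(p$factor)) out$factor <- p$factor
        out
      })
    )
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a long-format time-course CSV
#' @param path CSV path written by [write_timecourse()].
#' @return List with `times` and a time-by-species `values` matrix.
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "species", "value") %in% names(df)))
  times <- sort(unique(df$time))
  species <- unique(df$species)
  values <- matrix(NA_real_, length(times), length(species),
                   dimnames = list(NULL, species))
  for (s in species) {
    sub <- df[df$species == s, ]
    values[match(sub$time, times), s] <- sub$value
  }
  list(times = times, values = values)
}

# --- SBML Level 3 export (rate-rule encoding; export only) ----------------

mathml_num <- function(x) sprintf("<cn> %s </cn>", format(x, digits = 15))
mathml_ci <- function(x) sprintf("<ci> %s </ci>", x)
mathml_apply <- function(op, ...) {
  sprintf("<apply><%s/>%s</apply>", op, paste0(..., collapse = ""))
}

mathml_hill <- function(p_ci, Kd, h, sign) {
  ratio_pow <- mathml_apply(
    "power", mathml_apply("divide", mathml_ci(p_ci), mathml_num(Kd)),
    mathml_num(h))
  denom <- mathml_apply("plus", mathml_num(1), ratio_pow)
  if (sign == "repression") {
    mathml_apply("divide", mathml_num(1), denom)
  } else {
    mathml_apply("divide", ratio_pow, denom)
  }
}

#' Export a model as SBML Level 3
#'
#' Writes an SBML Level 3 Version 2 document encoding the network ODEs as
#' rate rules over the species (one compartment, unit size). Export only;
#' SBML import is not supported.
#'
#' @param model A [model_instance()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  spec <- model$spec
  p <- model$params
  g <- gene_ids(spec)
  m1 <- spec$model_class == "mrna_protein"
  sp <- species_names(spec)

  rate_rule <- function(s) {
    gid <- sub("^[mp]_", "", s)
    is_m <- startsWith(s, "m_")
    if (gid %in% model$deleted) return(mathml_num(0))
    regs <- regs_targeting(spec, gid)
    terms <- vapply(regs, function(r) {
      mathml_hill(paste0("p_", r$source), p[[paste0(r$id, "_Kd")]],
                  p[[paste0(r$id, "_h")]], r$sign)
    }, character(1))
    if (m1 && is_m) {
      prod <- mathml_apply("times", c(mathml_num(p[[paste0(gid, "_pro")]]),
                                      terms))
      deg <- mathml_apply("times",
                          mathml_num(model$mrna_deg_factor[[gid]]),
                          mathml_ci(s))
      mathml_apply("minus", prod, deg)
    } else if (m1) {
      prod <- mathml_apply("times", mathml_num(p[[paste0(gid, "_rbs")]]),
                           mathml_ci(paste0("m_", gid)))
      deg <- mathml_apply("times", mathml_num(p[["p_degradation_rate"]]),
                          mathml_ci(s))
      mathml_apply("minus", prod, deg)
    } else {
      basal <- if (gid %in% unregulated_genes(spec)) {
        mathml_num(p[[paste0(gid, "_basal")]])
      } else character(0)
      pieces <- c(basal, vapply(seq_along(regs), function(i) {
        mathml_apply("times",
                     mathml_num(p[[paste0(regs[[i]]$id, "_syn")]]),
                     terms[i])
      }, character(1)))
      prod <- if (length(pieces) > 1L) mathml_apply("plus", pieces)
              else if (length(pieces) == 1L) pieces else mathml_num(0)
      deg <- mathml_apply("times", mathml_num(p[[paste0(gid, "_deg")]]),
                          mathml_ci(s))
      mathml_apply("minus", prod, deg)
    }
  }

  species_xml <- paste0(vapply(sp, function(s) sprintf(
    paste0('<species id="%s" compartment="cell" initialConcentration="%s" ',
           'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
           'constant="false"/>'),
    s, format(model$initial_conditions[[s]], digits = 15)), character(1)),
    collapse = "\n      ")
  rules_xml <- paste0(vapply(sp, function(s) sprintf(
    paste0('<rateRule variable="%s">',
           '<math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>',
           '</rateRule>'),
    s, rate_rule(s)), character(1)), collapse = "\n      ")

  doc_txt <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="grn_model" name="gene regulatory network">
    <listOfCompartments>
      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      %s
    </listOfSpecies>
    <listOfRules>
      %s
    </listOfRules>
  </model>
</sbml>', species_xml, rules_xml)
  doc <- xml2::read_xml(doc_txt) # round through xml2 validates well-formedness
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Summarize credit usage from a ledger
#'
#' Histogram of how often each experiment kind was purchased, plus directed
#' transition counts between consecutive purchases (the purchase-sequence
#' edges of a session).
#'
#' @param ledger A [credit_ledger()] (or its `transactions` data frame).
#' @return List with `histogram` (named counts, totalling the number of
#'   purchases) and `transitions` (data frame `from`, `to`, `count`).
#' @export
usage_summary <- function(ledger) {
  tx <- if (inherits(ledger, "credit_ledger")) ledger$transactions else ledger
  if (!nrow(tx)) stop("empty session log")
  kinds <- sub(" .*$", "", tx$description)
  histogram <- table(kinds)
  transitions <- if (length(kinds) > 1L) {
    edges <- data.frame(from = kinds[-length(kinds)], to = kinds[-1])
    agg <- stats::aggregate(list(count = rep(1L, nrow(edges))),
                            by = edges, FUN = sum)
    agg[order(agg$from, agg$to), ]
  } else {
    data.frame(from = character(0), to = character(0), count = integer(0))
  }
  list(histogram = histogram, transitions = transitions)
}
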