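#' Gene specification
#'
#' A gene is identified by an id and may belong to an operon (a group of one
#' or two co-transcribed genes sharing a promoter). A regulation that targets
#' an operon acts on every member gene.
#'
#' @param id Gene identifier (character scalar, e.g. `"g1"`).
#' @param operon_id Optional operon label shared by at most two genes.
#' @return An object of class `gene_spec`.
#' @export
gene_spec <- function(id, operon_id = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, operon_id = operon_id), class = "gene_spec")
}

#' Regulation specification
#'
#' A directed regulatory link from a source gene to one or two target genes
#' (two only when the targets form an operon), with an activating or
#' repressing sign.
#'
#' @param id Regulation identifier (e.g. `"r9"`).
#' @param source Source gene id (the regulator's gene).
#' @param targets Character vector of 1-2 target gene ids.
#' @param sign `"activation"` or `"repression"` (also accepts `"+"`/`"-"`).
#' @return An object of class `regulation_spec`.
#' @export
regulation_spec <- function(id, source, targets, sign) {
  sign <- switch(sign,
    "+" = "activation", "-" = "repression",
    activation = "activation", repression = "repression",
    stop("sign must be activation/repression (+/-), got: ", sign)
  )
  stopifnot(
    is.character(id), length(id) == 1L,
    is.character(source), length(source) == 1L,
    is.character(targets), length(targets) %in% 1:2
  )
  structure(
    list(id = id, source = source, targets = sort(targets), sign = sign),
    class = "regulation_spec"
  )
}

#' Network specification
#'
#' Topology of a gene regulatory network: genes (possibly grouped into
#' operons), directed signed regulations, and the model class.
#'
#' Two model classes are supported:
#' \describe{
#'   \item{`mrna_protein`}{transcription and translation explicit; species
#'     are one mRNA and one protein per gene; a single multiplicative
#'     Hill-regulated promoter per gene; no operons.}
#'   \item{`protein_only`}{proteins only; production is a sum of
#'     per-regulation Hill terms with their own synthesis rates, plus a
#'     basal rate for unregulated genes; operons allowed.}
#' }
#'
#' Structural rules enforced: gene ids unique; referential integrity of all
#' regulation endpoints; each target gene receives at most two regulations;
#' each source gene establishes at most two regulating links; an operon
#' groups at most two genes; two-target regulations must target one operon.
#'
#' @param genes List of [gene_spec()] objects.
#' @param regulations List of [regulation_spec()] objects.
#' @param model_class `"mrna_protein"` or `"protein_only"`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(genes, regulations, model_class) {
  model_class <- match.arg(model_class, c("mrna_protein", "protein_only"))
  gene_ids <- vapply(genes, `[[`, character(1), "id")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  reg_ids <- vapply(regulations, `[[`, character(1), "id")
  if (anyDuplicated(reg_ids)) stop("duplicate regulation ids")

  operons <- vapply(genes, function(g) {
    if (is.null(g$operon_id)) NA_character_ else g$operon_id
  }, character(1))
  if (any(table(operons[!is.na(operons)]) > 2L)) {
    stop("an operon groups at most two genes")
  }
  if (model_class == "mrna_protein" && any(!is.na(operons))) {
    stop("mrna_protein models have no operons")
  }

  for (r in regulations) {
    if (!r$source %in% gene_ids) {
      stop("regulation ", r$id, ": unknown source gene ", r$source)
    }
    if (!all(r$targets %in% gene_ids)) {
      stop("regulation ", r$id, ": unknown target gene")
    }
    if (length(r$targets) == 2L) {
      op <- operons[match(r$targets, gene_ids)]
      if (anyNA(op) || op[1] != op[2]) {
        stop("regulation ", r$id, ": two targets must form one operon")
      }
    }
  }
  src_counts <- table(vapply(regulations, `[[`, character(1), "source"))
  if (any(src_counts > 2L)) {
    stop("a gene may establish at most two regulating links")
  }
  tgt <- unlist(lapply(regulations, `[[`, "targets"))
  if (any(table(tgt) > 2L)) {
    stop("a gene may receive at most two regulations")
  }

  structure(
    list(genes = genes, regulations = regulations, model_class = model_class),
    class = "network_spec"
  )
}

# paste0 recycles zero-length arguments to "", which silently fabricates
# names like "_Kd"; these helpers keep empty id vectors empty.
sfx <- function(ids, suffix) {
  if (!length(ids)) character(0) else paste0(ids, suffix)
}
pre0 <- function(prefix, ids) {
  if (!length(ids)) character(0) else paste0(prefix, ids)
}

gene_ids <- function(spec) vapply(spec$genes, `[[`, character(1), "id")
regulation_ids <- function(spec) {
  vapply(spec$regulations, `[[`, character(1), "id")
}

#' Genes with no incoming regulation
#' @param spec A [network_spec()].
#' @return Character vector of unregulated gene ids.
#' @export
unregulated_genes <- function(spec) {
  regulated <- unique(unlist(lapply(spec$regulations, `[[`, "targets")))
  setdiff(gene_ids(spec), regulated)
}

#' Species names of a model class
#'
#' `mrna_protein` models carry one mRNA (`m_<gene>`) and one protein
#' (`p_<gene>`) per gene; `protein_only` models carry proteins only.
#'
#' @param spec A [network_spec()].
#' @return Character vector of species names, mRNAs first.
#' @export
species_names <- function(spec) {
  g <- gene_ids(spec)
  if (spec$model_class == "mrna_protein") {
    c(pre0("m_", g), pre0("p_", g))
  } else {
    pre0("p_", g)
  }
}

#' Free-parameter names of a network
#'
#' `mrna_protein`: per gene a promoter strength (`<gene>_pro`) and an RBS
#' strength (`<gene>_rbs`); per regulation a dissociation constant
#' (`<reg>_Kd`) and Hill coefficient (`<reg>_h`); one shared protein
#' degradation rate (`p_degradation_rate`). The mRNA degradation rate is
#' fixed at 1 (time is non-dimensional, measured in mRNA half-lives) and is
#' not a free parameter.
#'
#' `protein_only`: per regulation a synthesis rate (`<reg>_syn`), `Kd` and
#' `h`; per gene a degradation rate (`<gene>_deg`); per unregulated gene a
#' basal production rate (`<gene>_basal`).
#'
#' @param spec A [network_spec()].
#' @return Character vector of parameter names.
#' @export
parameter_names <- function(spec) {
  g <- gene_ids(spec)
  r <- regulation_ids(spec)
  if (spec$model_class == "mrna_protein") {
    c(
      sfx(g, "_pro"), sfx(g, "_rbs"),
      as.vector(rbind(sfx(r, "_Kd"), sfx(r, "_h"))),
      "p_degradation_rate"
    )
  } else {
    c(
      as.vector(rbind(sfx(r, "_syn"), sfx(r, "_Kd"), sfx(r, "_h"))),
      sfx(g, "_deg"),
      sfx(unregulated_genes(spec), "_basal")
    )
  }
}

#' Count the free parameters of a network
#'
#' `mrna_protein`: 2 per gene + 2 per regulation + 1 shared protein
#' degradation rate. `protein_only`: 3 per regulation + 1 degradation rate
#' per gene + 1 basal rate per unregulated gene.
#'
#' @param spec A [network_spec()].
#' @return Integer number of free parameters.
#' @examples
#' count_parameters(model1_fixture()$spec) # 45
#' count_parameters(model2_fixture()$spec) # 61
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  length(parameter_names(spec))
}

#' Validate a parameter set against a network
#'
#' Checks coverage (every free parameter present exactly once, nothing
#' extra) and strict positivity.
#'
#' @param spec A [network_spec()].
#' @param params Named numeric vector as laid out by [parameter_names()].
#' @return Invisibly, `params` (reordered canonically).
#' @export
validate_parameters <- function(spec, params) {
  want <- parameter_names(spec)
  missing <- setdiff(want, names(params))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(params), want)
  if (length(extra)) {
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  }
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("all parameters must be finite and strictly positive")
  }
  invisible(params[want])
}
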