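#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` is the in-memory representation of a stoichiometric
#' reconstruction: metabolites, reactions with bounds and
#' gene-protein-reaction (GPR) rules, genes, and an objective reaction.
#' Fluxes are signed net rates in mmol/gDW/h; exchange reactions follow the
#' BiGG convention (negative flux = uptake, positive = secretion).
#'
#' @param model_id Character scalar identifying the model.
#' @param metabolites Data frame with columns `id` and `compartment`.
#' @param reactions Data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr` (character, possibly `""`), and a list column
#'   `metabolites` of named numeric vectors mapping metabolite id to the
#'   signed stoichiometric coefficient (negative = consumed).
#' @param genes Character vector of gene ids.
#' @param objective_reaction Id of the reaction optimized by default (usually
#'   biomass). May be `NA` when the model declares none.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(model_id, metabolites, reactions, genes = character(),
                            objective_reaction = NA_character_) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  model <- structure(
    list(
      model_id = model_id,
      metabolites = metabolites,
      reactions = reactions,
      genes = as.character(genes),
      objective_reaction = objective_reaction
    ),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, that every metabolite referenced by a reaction is
#' declared, that bounds satisfy `lower_bound <= upper_bound`, and that every
#' non-empty GPR rule parses as a boolean expression over gene ids.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly. Errors on the first violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rxn <- model$reactions
  met <- model$metabolites
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  }
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  }
  referenced <- unique(unlist(lapply(rxn$metabolites, names), use.names = FALSE))
  missing <- setdiff(referenced, met$id)
  if (length(missing)) {
    stop("reaction stoichiometry references undeclared metabolite(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(rxn$lower_bound > rxn$upper_bound)
  if (length(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rxn$id[bad], collapse = ", "))
  }
  empty <- which(vapply(rxn$metabolites, length, 1L) == 0L)
  if (length(empty)) {
    stop("empty stoichiometry for reaction(s): ",
         paste(rxn$id[empty], collapse = ", "))
  }
  for (i in seq_len(nrow(rxn))) {
    if (nzchar(rxn$gpr[i]) && !gpr_is_valid(rxn$gpr[i])) {
      stop("malformed GPR rule for reaction ", rxn$id[i], ": ", rxn$gpr[i])
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$model_id, "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  reactions:   ", nrow(x$reactions), "\n",
      "  genes:       ", length(x$genes), "\n",
      "  objective:   ", x$objective_reaction, "\n", sep = "")
  invisible(x)
}

#' Look up a reaction by exact id
#'
#' Matching is exact and case-sensitive; a failed lookup reports the five
#' closest ids by edit distance so mistyped product/biomass/carbon ids give
#' an actionable message.
#'
#' @param model A `metabolic_model`.
#' @param query Reaction id to resolve.
#' @return A one-row data frame (the reaction record).
#' @export
resolve_reaction <- function(model, query) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is.character(query) || length(query) != 1L || is.na(query) || !nzchar(query)) {
    stop("reaction query must be a non-empty character scalar")
  }
  idx <- which(model$reactions$id == query)
  if (length(idx) == 0L) {
    d <- utils::adist(query, model$reactions$id)
    near <- model$reactions$id[order(d)][seq_len(min(5L, nrow(model$reactions)))]
    stop("no reaction with id '", query, "' (matching is case-sensitive); ",
         "closest ids: ", paste(near, collapse = ", "))
  }
  model$reactions[idx, , drop = FALSE]
}

#' Fix the carbon-source uptake rate
#'
#' Sets the lower bound of the named exchange reaction to `-uptake_rate`
#' (exchange convention: negative flux is uptake). All other fields are
#' untouched; a modified copy is returned.
#'
#' @param model A `metabolic_model`.
#' @param exchange_id Id of the carbon-source exchange reaction.
#' @param uptake_rate Maximum uptake rate, nonnegative, mmol/gDW/h.
#' @return A modified copy of `model`.
#' @export
set_carbon_source <- function(model, exchange_id, uptake_rate) {
  stopifnot(inherits(model, "metabolic_model"),
            is.numeric(uptake_rate), length(uptake_rate) == 1L,
            uptake_rate >= 0)
  resolve_reaction(model, exchange_id)  # lookup guard with suggestions
  i <- match(exchange_id, model$reactions$id)
  model$reactions$lower_bound[i] <- -uptake_rate
  model
}

#' Identify exchange (boundary) reactions
#'
#' A reaction is treated as an exchange when it involves a single metabolite,
#' i.e. it imports or exports mass across the system boundary.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  single <- vapply(model$reactions$metabolites, length, 1L) == 1L
  model$reactions$id[single]
}
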