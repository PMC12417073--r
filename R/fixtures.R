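#' Specification for a branched toy model with planted targets
#'
#' The toy network is the smallest topology on which target selection has an
#' analytically known answer: a carbon source feeding a linear trunk into a
#' hub metabolite, from which a product branch and a competing biomass
#' branch diverge. Forcing production must pull flux into the product branch
#' (overexpression targets) and away from the competing branch
#' (downregulation, or knockout when no growth floor protects it). A
#' two-reaction internal cycle disconnected from the carbon flow is included
#' as a decoy whose flux span never responds to enforcement.
#'
#' @param uptake_rate Carbon-source uptake bound, mmol/gDW/h (default 10).
#' @param n_chain Number of trunk reactions between carbon and hub
#'   (default 1).
#' @param branch_yield Product stoichiometry per hub metabolite consumed
#'   (default 1).
#' @param with_cofactor_drain Couple a cofactor byproduct + drain to the
#'   product branch (default `FALSE`).
#' @param seed Optional integer; jitters the bounds of non-planted (decoy)
#'   reactions only, so the ground truth stays analytic.
#' @return A `toy_model_spec` list.
#' @export
toy_model_spec <- function(uptake_rate = 10, n_chain = 1L, branch_yield = 1,
                           with_cofactor_drain = FALSE, seed = NULL) {
  stopifnot(uptake_rate >= 0, n_chain >= 1L, branch_yield > 0)
  structure(
    list(uptake_rate = uptake_rate, n_chain = as.integer(n_chain),
         branch_yield = branch_yield,
         with_cofactor_drain = isTRUE(with_cofactor_drain),
         seed = seed),
    class = "toy_model_spec"
  )
}

#' Build a branched toy model with known ground-truth targets
#'
#' Network (default spec): `EX_A -> R1 -> B`, product branch
#' `R2: B -> branch_yield P` with `EX_P`, competing branch `R3: B -> C`
#' feeding `BIOMASS`, plus a decoy cycle `S1: X -> Y`, `S2: Y -> X` whose
#' bounds are the only thing the seed jitters. With a cofactor drain, `R2`
#' additionally produces cofactor `N` removed by `DRAIN_N`, which therefore
#' tracks production one-for-one.
#'
#' @param spec A [toy_model_spec()].
#' @return List with `model` (a [metabolic_model()]) and `truth`, a list
#'   naming the planted roles: `overexpress` (trunk + product branch ids),
#'   `competing` (`"R3"`), `competing_with_floor` / `competing_no_floor`
#'   (expected intervention `"downregulate"` / `"knockout"`), `decoys`,
#'   `product_id`, `biomass_id`, `carbon_id`, and the analytic
#'   `max_growth` and `mty(biomass_min_fraction)` values at the configured
#'   uptake.
#' @export
build_branched_toy <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  jit <- c(1000, 1000)
  if (!is.null(spec$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    jit <- stats::runif(2, 200, 2000)
  }
  k <- spec$n_chain
  trunk_mets <- if (k > 1L) paste0("I", seq_len(k - 1L)) else character()
  mets <- c("A", trunk_mets, "B", "P", "C", "X", "Y",
            if (spec$with_cofactor_drain) "N")
  metabolites <- data.frame(id = mets, compartment = "c",
                            stringsAsFactors = FALSE)

  trunk_ids <- if (k == 1L) "R1" else paste0("R1_", seq_len(k))
  chain_nodes <- c("A", trunk_mets, "B")
  rxn <- list()
  add <- function(id, name, st, lb, ub, gpr) {
    rxn[[length(rxn) + 1L]] <<- list(id = id, name = name, st = st,
                                     lb = lb, ub = ub, gpr = gpr)
  }
  add("EX_A", "carbon source exchange", c(A = -1), -spec$uptake_rate, 1000, "")
  for (i in seq_len(k)) {
    st <- stats::setNames(c(-1, 1), c(chain_nodes[i], chain_nodes[i + 1L]))
    add(trunk_ids[i], paste0("trunk step ", i), st, 0, 1000,
        paste0("gt", i))
  }
  prod_st <- c(B = -1, P = spec$branch_yield)
  if (spec$with_cofactor_drain) prod_st <- c(prod_st, N = 1)
  add("R2", "product branch", prod_st, 0, 1000, "(g2a and g2b) or g2c")
  add("R3", "competing branch", c(B = -1, C = 1), 0, 1000, "g3")
  add("BIOMASS", "biomass drain", c(C = -1), 0, 1000, "")
  add("EX_P", "product exchange", c(P = -1), 0, 1000, "")
  add("S1", "decoy cycle forward", c(X = -1, Y = 1), 0, jit[1], "gx1")
  add("S2", "decoy cycle reverse", c(Y = -1, X = 1), 0, jit[2], "gx2")
  if (spec$with_cofactor_drain) {
    add("DRAIN_N", "cofactor drain", c(N = -1), 0, 1000, "gn")
  }

  reactions <- data.frame(
    id = vapply(rxn, `[[`, "", "id"),
    name = vapply(rxn, `[[`, "", "name"),
    lower_bound = vapply(rxn, `[[`, 0, "lb"),
    upper_bound = vapply(rxn, `[[`, 0, "ub"),
    gpr = vapply(rxn, `[[`, "", "gpr"),
    stringsAsFactors = FALSE
  )
  reactions$metabolites <- lapply(rxn, `[[`, "st")
  model <- metabolic_model(
    model_id = sprintf("branched_toy_u%g_k%d_y%g%s", spec$uptake_rate, k,
                       spec$branch_yield,
                       if (spec$with_cofactor_drain) "_cof" else ""),
    metabolites = metabolites, reactions = reactions,
    genes = sort(unique(unlist(lapply(reactions$gpr, gpr_genes)))),
    objective_reaction = "BIOMASS"
  )
  truth <- list(
    overexpress = c(trunk_ids, "R2",
                    if (spec$with_cofactor_drain) "DRAIN_N"),
    competing = "R3",
    competing_with_floor = "downregulate",
    competing_no_floor = "knockout",
    decoys = c("S1", "S2"),
    product_id = "EX_P", biomass_id = "BIOMASS", carbon_id = "EX_A",
    max_growth = spec$uptake_rate,
    mty = function(biomass_min_fraction) {
      spec$branch_yield * spec$uptake_rate * (1 - biomass_min_fraction)
    }
  )
  list(model = model, truth = truth)
}
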