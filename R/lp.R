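# Linear-programming layer. All flux optimization problems have the form
#   max/min c'v   s.t.  S v = 0,  lb <= v <= ub
# and are solved with the simplex method (pracma::linprog) after shifting
# variables to the nonnegative orthant. Infinite bounds are replaced by a
# big-M envelope of +/- 1e6; an optimum pinned against that envelope on a
# truly unbounded direction is reported as status "unbounded" (supported
# model dialects use +/-1000 default bounds, far inside the envelope).

LP_BIGM <- 1e6
LP_FEAS_TOL <- 1e-9
LP_OPT_TOL <- 1e-6

# stoichiometric matrix (metabolites x reactions), dense
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    st <- model$reactions$metabolites[[j]]
    S[names(st), j] <- st
  }
  S
}

# core solver; obj is a full-length coefficient vector over reactions
solve_lp <- function(S, lb, ub, obj, maximize = TRUE) {
  n <- ncol(S)
  unbounded_lo <- !is.finite(lb)
  unbounded_hi <- !is.finite(ub)
  lb2 <- pmax(lb, -LP_BIGM)
  ub2 <- pmin(ub, LP_BIGM)
  if (any(lb2 > ub2)) {
    return(list(status = "infeasible", objective_value = NA_real_,
                fluxes = NULL))
  }
  # shift x = v - lb2 >= 0; S v = 0 becomes S x = -S lb2
  beq <- as.numeric(-S %*% lb2)
  # the backend breaks degenerate pivot ties through the global RNG; pin it
  # so repeated solves are bit-identical and the caller's stream is untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(285713L)
  res <- pracma::linprog(cc = obj, A = diag(n), b = ub2 - lb2,
                         Aeq = S, beq = beq, maximize = maximize,
                         maxiter = 1000L + 50L * (n + nrow(S)),
                         bigM = 1e5)
  if (res$errno %in% c(-2L, -4L, -5L)) {
    return(list(status = "infeasible", objective_value = NA_real_,
                fluxes = NULL))
  }
  if (res$errno == -3L) {
    return(list(status = "unbounded", objective_value = NA_real_,
                fluxes = NULL))
  }
  if (res$errno != 1L) {
    stop("simplex failed to converge within the iteration limit")
  }
  v <- as.numeric(res$x) + lb2
  names(v) <- colnames(S)
  value <- sum(obj * v)
  # pinned against the synthetic envelope on a direction the model leaves
  # free => the true LP is unbounded in the objective
  at_env <- (unbounded_hi & v > LP_BIGM * 0.999) |
            (unbounded_lo & v < -LP_BIGM * 0.999)
  if (abs(value) >= LP_BIGM * 0.999 && any(at_env & obj != 0)) {
    return(list(status = "unbounded", objective_value = NA_real_,
                fluxes = NULL))
  }
  list(status = "optimal", objective_value = value, fluxes = v)
}

#' Flux balance analysis: optimize a single reaction flux
#'
#' Maximizes or minimizes the flux through one reaction subject to
#' steady-state mass balance (`S v = 0`) and the model's flux bounds.
#'
#' @param model A `metabolic_model`.
#' @param objective_id Reaction whose flux is optimized.
#' @param sense `"maximize"` or `"minimize"`.
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective_value`, and `fluxes` (a named flux vector;
#'   one optimum among possibly many degenerate ones).
#' @export
optimize_flux <- function(model, objective_id, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  resolve_reaction(model, objective_id)
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(colnames(S) == objective_id)
  solve_lp(S, model$reactions$lower_bound, model$reactions$upper_bound,
           obj, maximize = (sense == "maximize"))
}

# normalize extra_bounds (data.frame id/lb/ub, or list of 3-element vectors)
as_extra_bounds <- function(extra_bounds) {
  if (is.null(extra_bounds) || (is.data.frame(extra_bounds) && !nrow(extra_bounds))) {
    return(data.frame(id = character(), lb = numeric(), ub = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!is.data.frame(extra_bounds)) {
    extra_bounds <- do.call(rbind, lapply(extra_bounds, function(x) {
      data.frame(id = as.character(x[[1]]), lb = as.numeric(x[[2]]),
                 ub = as.numeric(x[[3]]), stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("id", "lb", "ub") %in% names(extra_bounds)))
  if (any(extra_bounds$lb > extra_bounds$ub)) {
    stop("inconsistent extra bound (lb > ub) for: ",
         paste(extra_bounds$id[extra_bounds$lb > extra_bounds$ub], collapse = ", "))
  }
  extra_bounds
}

apply_extra_bounds <- function(model, extra_bounds) {
  eb <- as_extra_bounds(extra_bounds)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  for (k in seq_len(nrow(eb))) {
    i <- match(eb$id[k], model$reactions$id)
    if (is.na(i)) stop("extra bound names unknown reaction: ", eb$id[k])
    lb[i] <- max(lb[i], eb$lb[k])
    ub[i] <- min(ub[i], eb$ub[k])
  }
  list(lb = lb, ub = ub)
}

#' Flux variability analysis
#'
#' For each requested reaction, computes the minimum and maximum feasible
#' flux subject to mass balance and the model bounds, optionally tightened
#' by `extra_bounds`. The result is the reaction's feasible flux interval
#' (flux span) under those constraints.
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions to analyze (default: all).
#' @param extra_bounds Optional data frame with columns `id`, `lb`, `ub`
#'   (or a list of `(id, lb, ub)` triples) intersected with the model
#'   bounds before solving.
#' @return Data frame with columns `reaction_id`, `fraction` (`NA`; set by
#'   the scan driver), `min_flux`, `max_flux`.
#' @export
flux_variability <- function(model, reaction_ids = NULL, extra_bounds = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ",
                            paste(unknown, collapse = ", "))
  bounds <- apply_extra_bounds(model, extra_bounds)
  S <- stoichiometric_matrix(model)
  n <- length(reaction_ids)
  mn <- mx <- numeric(n)
  for (k in seq_len(n)) {
    obj <- as.numeric(colnames(S) == reaction_ids[k])
    lo <- solve_lp(S, bounds$lb, bounds$ub, obj, maximize = FALSE)
    hi <- solve_lp(S, bounds$lb, bounds$ub, obj, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      eb <- as_extra_bounds(extra_bounds)
      stop("FVA ", lo$status, "/", hi$status, " for reaction ",
           reaction_ids[k], " under enforced bounds {",
           paste(sprintf("%s:[%g,%g]", eb$id, eb$lb, eb$ub), collapse = "; "),
           "}")
    }
    mn[k] <- lo$objective_value
    mx[k] <- hi$objective_value
  }
  data.frame(reaction_id = reaction_ids, fraction = NA_real_,
             min_flux = mn, max_flux = mx, stringsAsFactors = FALSE)
}

#' Maximum theoretical yield of a product
#'
#' First maximizes growth to obtain `max_growth`, then maximizes the product
#' flux with the biomass reaction's lower bound held at
#' `biomass_min_fraction * max_growth`. The resulting optimum is the maximum
#' theoretical yield (MTY) of the product under the current medium and
#' growth requirement.
#'
#' @param model A `metabolic_model` whose carbon source has been fixed with
#'   [set_carbon_source()].
#' @param product_id,biomass_id,carbon_id Reaction ids of the product
#'   (exchange or sink), the biomass objective, and the carbon-source
#'   exchange.
#' @param biomass_min_fraction Minimum growth retained while maximizing the
#'   product, as a fraction of `max_growth` (in `[0, 1)`).
#' @return List with `mty` and `max_growth` (mmol/gDW/h and 1/h scales as
#'   encoded in the model).
#' @export
max_theoretical_yield <- function(model, product_id, biomass_id, carbon_id,
                                  biomass_min_fraction = 0.1) {
  stopifnot(biomass_min_fraction >= 0, biomass_min_fraction < 1)
  for (id in c(product_id, biomass_id, carbon_id)) resolve_reaction(model, id)
  growth <- optimize_flux(model, biomass_id, "maximize")
  if (growth$status != "optimal") {
    stop("biomass optimization ", growth$status,
         "; check the model and medium bounds")
  }
  max_growth <- growth$objective_value
  if (max_growth <= LP_OPT_TOL && biomass_min_fraction > 0) {
    stop("maximum growth is zero but a nonzero biomass floor was requested; ",
         "check the medium (carbon-source uptake may be closed)")
  }
  floor_model <- model
  i <- match(biomass_id, model$reactions$id)
  floor_model$reactions$lower_bound[i] <-
    max(floor_model$reactions$lower_bound[i],
        biomass_min_fraction * max_growth)
  prod <- optimize_flux(floor_model, product_id, "maximize")
  if (prod$status != "optimal") {
    stop("product optimization ", prod$status, " with biomass floor ",
         format(biomass_min_fraction * max_growth))
  }
  list(mty = max(prod$objective_value, 0), max_growth = max_growth)
}

#' Enforced-production scan: FVA across fractions of the maximum yield
#'
#' The scan steadily forces flux toward the product: for each fraction `f`
#' of the maximum theoretical yield it raises the product reaction's lower
#' bound to `f * mty` (the upper bound is untouched), keeps the biomass
#' lower bound at `biomass_min_fraction * max_growth`, and records the
#' feasible flux span of every reaction by FVA. Spans at low fractions
#' describe the low-production state; spans at high fractions the
#' high-production state. The input model is not modified.
#'
#' @inheritParams max_theoretical_yield
#' @param fractions Strictly increasing production fractions in `(0, 1]`;
#'   at least 4 (two low + two high states are needed downstream). Default
#'   ten equally spaced fractions 0.1..1.0.
#' @return A `scan_result` list: `mty`, `max_growth`, `fractions`, `spans`
#'   (long data frame `reaction_id`/`fraction`/`min_flux`/`max_flux`,
#'   ordered by reaction then fraction), `reactions` (id/name/gpr/
#'   is_exchange lookup), and `config_echo` with every parameter used.
#' @export
enforced_production_scan <- function(model, product_id, biomass_id, carbon_id,
                                     fractions = seq(0.1, 1, by = 0.1),
                                     biomass_min_fraction = 0.1) {
  stopifnot(inherits(model, "metabolic_model"))
  fractions <- as.numeric(fractions)
  if (length(fractions) < 4L) {
    stop("at least 4 fractions are required (two low + two high states)")
  }
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must be strictly increasing and lie in (0, 1]")
  }
  yields <- max_theoretical_yield(model, product_id, biomass_id, carbon_id,
                                  biomass_min_fraction)
  if (yields$mty <= LP_OPT_TOL) {
    stop("product not producible under current medium (MTY = 0); ",
         "check carbon-source uptake and pathway bounds")
  }
  floor_bounds <- data.frame(
    id = biomass_id, lb = biomass_min_fraction * yields$max_growth,
    ub = Inf, stringsAsFactors = FALSE)
  spans <- vector("list", length(fractions))
  for (k in seq_along(fractions)) {
    f <- fractions[k]
    eb <- rbind(floor_bounds,
                data.frame(id = product_id, lb = f * yields$mty, ub = Inf,
                           stringsAsFactors = FALSE))
    sp <- tryCatch(
      flux_variability(model, extra_bounds = eb),
      error = function(e) stop("scan infeasible at fraction ", f, ": ",
                               conditionMessage(e)))
    sp$fraction <- f
    spans[[k]] <- sp
  }
  spans <- do.call(rbind, spans)
  spans <- spans[order(match(spans$reaction_id, model$reactions$id),
                       spans$fraction), , drop = FALSE]
  rownames(spans) <- NULL
  structure(
    list(
      mty = yields$mty,
      max_growth = yields$max_growth,
      fractions = fractions,
      spans = spans,
      reactions = data.frame(
        id = model$reactions$id,
        name = model$reactions$name,
        gpr = model$reactions$gpr,
        is_exchange = model$reactions$id %in% exchange_reactions(model),
        stringsAsFactors = FALSE
      ),
      config_echo = list(
        model_id = model$model_id,
        product_id = product_id,
        biomass_id = biomass_id,
        carbon_id = carbon_id,
        fractions = fractions,
        biomass_min_fraction = biomass_min_fraction
      )
    ),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> model ", x$config_echo$model_id,
      "\n  MTY: ", format(x$mty), "   max growth: ", format(x$max_growth),
      "\n  fractions: ", paste(format(x$fractions), collapse = " "),
      "\n  reactions scanned: ", nrow(x$reactions), "\n", sep = "")
  invisible(x)
}
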