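#' Filtering and scoring configuration
#'
#' Bundles the tunable knobs of the target-selection step. Tightening
#' `score_cutoff` or `flux_diff_cutoff` makes the search more stringent and
#' can only shrink the returned target list.
#'
#' @param biomass_min_fraction Minimum growth kept during the scan, as a
#'   fraction of maximum growth (default 0.1).
#' @param n_fractions Number of equally spaced production fractions in the
#'   scan grid (default 10, i.e. 0.1, 0.2, ..., 1.0); at least 4.
#' @param flux_diff_cutoff Minimum absolute shift of the mean flux between
#'   low- and high-production states for a reaction to count as a target
#'   (flux units; default 1e-4).
#' @param score_cutoff Minimum score (1/overlap) retained (default 1.0, i.e.
#'   anything with less-than-total overlap).
#' @param knockout_eps Mean flux magnitude at high production below which a
#'   downregulation target is promoted to a knockout (default 1e-6).
#' @param sigma_floor Smallest standard deviation used when a state's flux
#'   span is degenerate (a fixed flux); keeps the gaussian proper
#'   (default 1e-6).
#' @param score_cap Finite ceiling substituted for 1/overlap when the
#'   overlap underflows to zero (default 1e6).
#' @param exclude_exchanges Drop exchange reactions from the report
#'   (default `TRUE`); the product, biomass and carbon reactions are always
#'   dropped.
#' @param exclude_ids Additional reaction ids to drop.
#' @return A `filter_config` list.
#' @export
filter_config <- function(biomass_min_fraction = 0.1,
                          n_fractions = 10L,
                          flux_diff_cutoff = 1e-4,
                          score_cutoff = 1.0,
                          knockout_eps = 1e-6,
                          sigma_floor = 1e-6,
                          score_cap = 1e6,
                          exclude_exchanges = TRUE,
                          exclude_ids = character()) {
  stopifnot(biomass_min_fraction >= 0, biomass_min_fraction < 1,
            n_fractions >= 4L,
            flux_diff_cutoff >= 0, score_cutoff >= 0, knockout_eps >= 0,
            sigma_floor > 0, score_cap > 0)
  structure(
    list(biomass_min_fraction = biomass_min_fraction,
         n_fractions = as.integer(n_fractions),
         flux_diff_cutoff = flux_diff_cutoff,
         score_cutoff = score_cutoff,
         knockout_eps = knockout_eps,
         sigma_floor = sigma_floor,
         score_cap = score_cap,
         exclude_exchanges = isTRUE(exclude_exchanges),
         exclude_ids = as.character(exclude_ids)),
    class = "filter_config"
  )
}

#' Gaussian summary of a production state
#'
#' @param mu Mean flux.
#' @param sigma Standard deviation, nonnegative.
#' @return A `gaussian_summary` list.
#' @export
gaussian_summary <- function(mu, sigma) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  structure(list(mu = mu, sigma = sigma), class = "gaussian_summary")
}

#' Summarize two flux spans as a gaussian state
#'
#' The low- (or high-) production state of a reaction is summarized from the
#' spans of two adjacent scan fractions: the mean is the average of the four
#' interval endpoints (equivalently the mean of the two interval midpoints)
#' and the standard deviation is the overall spread, i.e. the largest
#' maximum minus the smallest minimum across both fractions. A degenerate
#' spread (fixed flux) is raised to `sigma_floor` so the density stays
#' proper.
#'
#' @param span_a,span_b One-row span data frames (`reaction_id`, `fraction`,
#'   `min_flux`, `max_flux`) with `span_a$fraction < span_b$fraction`, for
#'   the same reaction.
#' @param sigma_floor Lower limit on the standard deviation.
#' @return A [gaussian_summary()].
#' @export
summarize_state <- function(span_a, span_b, sigma_floor = 1e-6) {
  if (span_a$reaction_id != span_b$reaction_id) {
    stop("spans belong to different reactions: ",
         span_a$reaction_id, " vs ", span_b$reaction_id)
  }
  if (!is.na(span_a$fraction) && !is.na(span_b$fraction) &&
      !(span_a$fraction < span_b$fraction)) {
    stop("span_a must come from a smaller fraction than span_b")
  }
  mu <- (span_a$min_flux + span_a$max_flux +
         span_b$min_flux + span_b$max_flux) / 4
  sigma <- max(span_a$max_flux, span_b$max_flux) -
           min(span_a$min_flux, span_b$min_flux)
  gaussian_summary(mu, max(sigma, sigma_floor))
}

#' Overlap index of two gaussian densities
#'
#' The overlap index is the integral of the pointwise minimum of the two
#' normal densities: 1 for identical densities, 0 for disjoint ones. The
#' default evaluation is analytic and piecewise, using the crossing points
#' of the two densities (one crossing for equal standard deviations, up to
#' two otherwise) so each piece is a difference of normal CDFs;
#' `method = "quadrature"` integrates the minimum density numerically and
#' serves as an independent cross-check.
#'
#' @param g1,g2 [gaussian_summary()] objects (or lists with `mu`, `sigma`),
#'   both with `sigma > 0`.
#' @param method `"analytic"` (default) or `"quadrature"`.
#' @return Overlap in `[0, 1]`, symmetric in its arguments.
#' @export
overlap_index <- function(g1, g2, method = c("analytic", "quadrature")) {
  method <- match.arg(method)
  m1 <- g1$mu; s1 <- g1$sigma
  m2 <- g2$mu; s2 <- g2$sigma
  stopifnot(s1 > 0, s2 > 0)
  if (method == "quadrature") return(overlap_quadrature(m1, s1, m2, s2))
  # near-equal sigmas: single crossing at the midpoint, closed form
  if (abs(s1 - s2) <= 1e-12 * max(s1, s2)) {
    s <- (s1 + s2) / 2
    return(min(1, 2 * stats::pnorm(-abs(m1 - m2) / (2 * s))))
  }
  # order so that density 1 is the narrower (taller) one; then the minimum
  # of the two densities is density 2 between the crossings and density 1
  # in both tails
  if (s1 > s2) {
    tmp <- m1; m1 <- m2; m2 <- tmp
    tmp <- s1; s1 <- s2; s2 <- tmp
  }
  # crossings solve (x-m1)^2/s1^2 - (x-m2)^2/s2^2 = 2 log(s2/s1)
  a <- 1 / s1^2 - 1 / s2^2                      # > 0 since s1 < s2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log(s2 / s1)
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) {
    # numerically tangent densities; the narrow one sits entirely under
    # the wide one only in the limit, fall back to quadrature
    return(overlap_quadrature(m1, s1, m2, s2))
  }
  r <- sqrt(disc)
  x1 <- (-b - r) / (2 * a)
  x2 <- (-b + r) / (2 * a)
  ov <- stats::pnorm(x1, m1, s1) +                        # narrow, left tail
    (stats::pnorm(x2, m2, s2) - stats::pnorm(x1, m2, s2)) + # wide, middle
    stats::pnorm(x2, m1, s1, lower.tail = FALSE)          # narrow, right tail
  min(max(ov, 0), 1)
}

# the minimum of the two densities is bounded by each of them, so it is
# negligible outside the intersection of their 9-sigma windows; integrating
# only that window keeps the integrand well scaled even for near-disjoint
# densities
overlap_quadrature <- function(m1, s1, m2, s2) {
  lo <- max(m1 - 9 * s1, m2 - 9 * s2)
  hi <- min(m1 + 9 * s1, m2 + 9 * s2)
  if (hi <= lo) return(0)
  f <- function(x) pmin(stats::dnorm(x, m1, s1), stats::dnorm(x, m2, s2))
  val <- tryCatch(
    stats::integrate(f, lower = lo, upper = hi, rel.tol = 1e-10,
                     abs.tol = 1e-12, subdivisions = 1000L)$value,
    error = function(e) {
      # adaptive quadrature can reject an all-but-zero integrand; a dense
      # trapezoid rule on the (narrow) window is accurate and never fails
      x <- seq(lo, hi, length.out = 100001L)
      y <- f(x)
      sum((y[-1] + y[-length(y)]) / 2) * (x[2] - x[1])
    })
  min(max(val, 0), 1)
}

#' Recommended genetic intervention for a reaction
#'
#' The direction of the mean flux shift between the low- and high-production
#' states determines the recommendation: an increasing mean calls for
#' overexpression, a decreasing mean for downregulation — or a knockout when
#' the reaction must be shut off entirely to reach high production. Shifts
#' smaller than `flux_diff_cutoff` yield no recommendation. Comparisons use
#' signed means.
#'
#' The knockout test works on whichever evidence is available. When
#' `final_span` (the reaction's feasible interval at full enforcement,
#' fraction 1.0) is supplied — as [rank_targets()] does — a decreasing
#' reaction is a knockout when that interval is pinned within
#' `knockout_eps` of zero: the reaction cannot carry flux at all at full
#' production. Without it, the high-state mean itself is compared against
#' `knockout_eps`. The span-based test is the sharper one: the two-fraction
#' high-state mean of an active reaction always retains a positive residual
#' from the penultimate fraction, so a mean-only test at a tight epsilon
#' would never fire.
#'
#' @param low,high [gaussian_summary()] states.
#' @param cfg A [filter_config()].
#' @param final_span Optional one-row span data frame at full enforcement.
#' @return One of `"overexpress"`, `"downregulate"`, `"knockout"`, `"none"`.
#' @export
classify_intervention <- function(low, high, cfg = filter_config(),
                                  final_span = NULL) {
  delta <- high$mu - low$mu
  if (abs(delta) < cfg$flux_diff_cutoff) return("none")
  if (delta > 0) return("overexpress")
  pinned_zero <- if (!is.null(final_span)) {
    max(abs(final_span$min_flux), abs(final_span$max_flux)) <= cfg$knockout_eps
  } else {
    abs(high$mu) <= cfg$knockout_eps
  }
  if (pinned_zero) return("knockout")
  "downregulate"
}

#' Score one reaction from its low- and high-production states
#'
#' The score is the reciprocal of the overlap index between the two
#' gaussian states, capped at `cfg$score_cap` (an overlap of zero maps to
#' the cap). A high score means the reaction's feasible flux range must
#' change for the model to reach high production, making it a confident
#' engineering target.
#'
#' @param reaction_id Reaction id.
#' @param low,high [gaussian_summary()] states from [summarize_state()].
#' @param cfg A [filter_config()].
#' @return A `target_score` list: `reaction_id`, `low`, `high`, `overlap`,
#'   `score`, `delta_mu`, `intervention`, `genes` (filled by [map_genes()]),
#'   `gpr`.
#' @export
score_reaction <- function(reaction_id, low, high, cfg = filter_config()) {
  overlap <- overlap_index(low, high)
  score <- if (overlap <= 1 / cfg$score_cap) cfg$score_cap
           else min(1 / overlap, cfg$score_cap)
  structure(
    list(reaction_id = reaction_id, low = low, high = high,
         overlap = overlap, score = score,
         delta_mu = high$mu - low$mu,
         intervention = classify_intervention(low, high, cfg),
         genes = character(), gpr = ""),
    class = "target_score"
  )
}

#' Rank reaction targets from an enforced-production scan
#'
#' For every reaction, the low-production state is summarized from the two
#' smallest scan fractions and the high-production state from the two
#' largest; the reaction is scored by inverse overlap and classified.
#' Reactions are dropped when no intervention is recommended, when the
#' score or mean shift falls below the configured cutoffs, or when excluded
#' (exchanges by default; the product, biomass and carbon reactions
#' always). The survivors are sorted by descending score, ties broken by
#' descending absolute mean shift, then ascending reaction id.
#'
#' @param scan A `scan_result` from [enforced_production_scan()].
#' @param cfg A [filter_config()].
#' @return Data frame with one row per retained target: `rank`,
#'   `reaction_id`, `reaction_name`, `score`, `overlap`, `intervention`,
#'   `mu_low`, `sigma_low`, `mu_high`, `sigma_high`, `delta_mu`, `genes`
#'   (empty until [map_genes()]), `gpr`.
#' @export
rank_targets <- function(scan, cfg = filter_config()) {
  stopifnot(inherits(scan, "scan_result"))
  fr <- sort(scan$fractions)
  if (length(fr) < 4L) stop("scan must cover at least 4 fractions")
  lo_fr <- fr[1:2]
  hi_fr <- fr[c(length(fr) - 1L, length(fr))]
  echo <- scan$config_echo
  always_out <- unique(c(echo$product_id, echo$biomass_id, echo$carbon_id,
                         cfg$exclude_ids))
  rows <- list()
  for (rid in scan$reactions$id) {
    if (rid %in% always_out) next
    if (cfg$exclude_exchanges &&
        scan$reactions$is_exchange[match(rid, scan$reactions$id)]) next
    sp <- scan$spans[scan$spans$reaction_id == rid, , drop = FALSE]
    low <- summarize_state(sp[sp$fraction == lo_fr[1], ],
                           sp[sp$fraction == lo_fr[2], ],
                           sigma_floor = cfg$sigma_floor)
    high <- summarize_state(sp[sp$fraction == hi_fr[1], ],
                            sp[sp$fraction == hi_fr[2], ],
                            sigma_floor = cfg$sigma_floor)
    ts <- score_reaction(rid, low, high, cfg)
    ts$intervention <- classify_intervention(
      low, high, cfg, final_span = sp[sp$fraction == fr[length(fr)], ])
    if (ts$intervention == "none") next
    if (ts$score < cfg$score_cutoff) next
    if (abs(ts$delta_mu) < cfg$flux_diff_cutoff) next
    i <- match(rid, scan$reactions$id)
    rows[[length(rows) + 1L]] <- data.frame(
      reaction_id = rid,
      reaction_name = scan$reactions$name[i],
      score = ts$score, overlap = ts$overlap,
      intervention = ts$intervention,
      mu_low = low$mu, sigma_low = low$sigma,
      mu_high = high$mu, sigma_high = high$sigma,
      delta_mu = ts$delta_mu,
      genes = "", gpr = scan$reactions$gpr[i],
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    out <- data.frame(reaction_id = character(), reaction_name = character(),
                      score = numeric(), overlap = numeric(),
                      intervention = character(), mu_low = numeric(),
                      sigma_low = numeric(), mu_high = numeric(),
                      sigma_high = numeric(), delta_mu = numeric(),
                      genes = character(), gpr = character(),
                      stringsAsFactors = FALSE)
    out <- cbind(rank = integer(), out)
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$score, -abs(out$delta_mu), out$reaction_id)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Attach gene targets to ranked reactions
#'
#' Each target row receives the reaction's verbatim GPR rule and the
#' flattened, deduplicated, sorted list of gene ids it mentions (joined with
#' `";"`). Reactions without a gene association keep an empty gene list and
#' remain valid reaction-level targets. An unparseable rule produces a
#' warning; the raw string is kept and the gene list left empty.
#'
#' @param model The `metabolic_model` the targets came from.
#' @param targets Target data frame from [rank_targets()].
#' @return The target data frame with `genes` and `gpr` columns filled.
#' @export
map_genes <- function(model, targets) {
  stopifnot(inherits(model, "metabolic_model"), is.data.frame(targets))
  for (k in seq_len(nrow(targets))) {
    i <- match(targets$reaction_id[k], model$reactions$id)
    if (is.na(i)) next
    rule <- model$reactions$gpr[i]
    targets$gpr[k] <- rule
    if (nzchar(rule) && !gpr_is_valid(rule)) {
      warning("unparseable GPR for reaction ", targets$reaction_id[k],
              "; keeping raw rule with no gene list")
      targets$genes[k] <- ""
    } else {
      targets$genes[k] <- paste(gpr_genes(rule), collapse = ";")
    }
  }
  targets
}
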