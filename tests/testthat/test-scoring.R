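span_row <- function(rid, fraction, mn, mx) {
  data.frame(reaction_id = rid, fraction = fraction, min_flux = mn,
             max_flux = mx, stringsAsFactors = FALSE)
}

test_that("state summaries follow the endpoint-mean / overall-spread convention", {
  g <- summarize_state(span_row("R", 0.1, 2, 4), span_row("R", 0.2, 3, 5))
  expect_equal(g$mu, 3.5)
  expect_equal(g$sigma, 3)

  # degenerate fixed flux gets the sigma floor
  gf <- summarize_state(span_row("R", 0.1, 7, 7), span_row("R", 0.2, 7, 7),
                        sigma_floor = 1e-6)
  expect_equal(gf$mu, 7)
  expect_equal(gf$sigma, 1e-6)

  # product-branch low state from the worked branched-fixture spans
  gl <- summarize_state(span_row("R2", 0.05, 0, 9), span_row("R2", 0.1, 0.9, 9))
  expect_equal(gl$mu, 4.725)
  expect_equal(gl$sigma, 9)

  expect_error(
    summarize_state(span_row("R2", 0.1, 0, 1), span_row("R3", 0.2, 0, 1)),
    "different reactions")
  expect_error(
    summarize_state(span_row("R", 0.2, 0, 1), span_row("R", 0.1, 0, 1)),
    "smaller fraction")
})

test_that("scores are reciprocal overlaps, capped, with classified interventions", {
  cfg <- filter_config()
  # overlap 1/2 -> score 2: equal sigmas separated so that 2*pnorm(-d/2s) = 0.5
  d <- -2 * stats::qnorm(0.25)
  ts <- score_reaction("R", gaussian_summary(0, 1), gaussian_summary(d, 1), cfg)
  expect_equal(ts$score, 2, tolerance = 1e-6)
  expect_identical(ts$intervention, "overexpress")

  # complete overlap: lowest possible score, nothing to recommend
  same <- gaussian_summary(3, 1)
  ts1 <- score_reaction("R", same, same, cfg)
  expect_equal(ts1$overlap, 1, tolerance = 1e-9)
  expect_equal(ts1$score, 1, tolerance = 1e-9)
  expect_identical(ts1$intervention, "none")

  # near-disjoint states hit the cap; a mean pinned at zero is a knockout
  ts2 <- score_reaction("R", gaussian_summary(5, 0.5), gaussian_summary(0, 0.5),
                        cfg)
  expect_equal(ts2$overlap, 2 * stats::pnorm(-5), tolerance = 1e-9)
  expect_equal(ts2$score, cfg$score_cap)  # 1/overlap = 1.74e6 exceeds the cap
  expect_identical(ts2$intervention, "knockout")
})

test_that("intervention classes follow the signed mean shift", {
  cfg <- filter_config()
  g <- function(mu) gaussian_summary(mu, 1)
  expect_identical(classify_intervention(g(2), g(8), cfg), "overexpress")
  expect_identical(classify_intervention(g(5), g(0), cfg), "knockout")
  expect_identical(classify_intervention(g(5), g(2), cfg), "downregulate")
  expect_identical(classify_intervention(g(3), g(3), cfg), "none")

  # with span evidence, knockout requires being pinned at zero at full
  # enforcement, not a zero two-fraction mean
  expect_identical(
    classify_intervention(g(5), g(0.25), cfg,
                          final_span = span_row("R", 1, 0, 0)),
    "knockout")
  expect_identical(
    classify_intervention(g(5), g(0.25), cfg,
                          final_span = span_row("R", 1, 1, 1)),
    "downregulate")
})

make_manual_scan <- function(ids, spans) {
  structure(list(
    mty = 1, max_growth = 1, fractions = c(0.1, 0.2, 0.9, 1.0),
    spans = spans,
    reactions = data.frame(id = ids, name = "", gpr = "",
                           is_exchange = FALSE, stringsAsFactors = FALSE),
    config_echo = list(model_id = "manual", product_id = "PROD",
                       biomass_id = "BIO", carbon_id = "CARB",
                       fractions = c(0.1, 0.2, 0.9, 1.0),
                       biomass_min_fraction = 0.1)
  ), class = "scan_result")
}

test_that("exact ties are broken lexicographically by reaction id", {
  ids <- c("BBB", "AAA")
  spans <- do.call(rbind, lapply(ids, function(rid) {
    rbind(span_row(rid, 0.1, 0, 4), span_row(rid, 0.2, 1, 5),
          span_row(rid, 0.9, 5, 6), span_row(rid, 1.0, 6, 6))
  }))
  tg <- rank_targets(make_manual_scan(ids, spans))
  expect_identical(tg$reaction_id, c("AAA", "BBB"))
  expect_equal(tg$score[1], tg$score[2])
})

test_that("ranking recovers the planted branches and filters the rest", {
  toy <- build_branched_toy()
  m <- set_carbon_source(toy$model, "EX_A", 10)
  scan <- enforced_production_scan(m, "EX_P", "BIOMASS", "EX_A")
  tg <- rank_targets(scan)
  expect_true(all(c("R2", "R3") %in% tg$reaction_id))
  expect_identical(tg$intervention[tg$reaction_id == "R2"], "overexpress")
  expect_identical(tg$intervention[tg$reaction_id == "R3"], "downregulate")
  # decoy cycle, exchanges, and the enforced reactions never appear
  expect_false(any(c("S1", "S2", "EX_A", "EX_P", "BIOMASS") %in%
                     tg$reaction_id))

  # a cutoff above the cap empties the report
  empty <- rank_targets(scan, filter_config(score_cutoff = 1e6 + 1))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("rank", "reaction_id", "score") %in% names(empty)))

  # explicit exclusion removes a surviving target
  no_r3 <- rank_targets(scan, filter_config(exclude_ids = "R3"))
  expect_false("R3" %in% no_r3$reaction_id)
})

test_that("gene mapping attaches flattened, deduplicated gene lists", {
  toy <- build_branched_toy()
  m <- set_carbon_source(toy$model, "EX_A", 10)
  scan <- enforced_production_scan(m, "EX_P", "BIOMASS", "EX_A")
  tg <- map_genes(m, rank_targets(scan))
  expect_identical(tg$genes[tg$reaction_id == "R2"], "g2a;g2b;g2c")
  expect_identical(tg$gpr[tg$reaction_id == "R2"], "(g2a and g2b) or g2c")
  expect_identical(tg$genes[tg$reaction_id == "R3"], "g3")

  # unparseable rule: warn, keep the raw string, no genes
  m2 <- m
  m2$reactions$gpr[match("R3", m2$reactions$id)] <- "g3 and and g4"
  tg2 <- tg
  expect_warning(tg2 <- map_genes(m2, tg), "unparseable GPR")
  expect_identical(tg2$gpr[tg2$reaction_id == "R3"], "g3 and and g4")
  expect_identical(tg2$genes[tg2$reaction_id == "R3"], "")

  # a reaction without gene association stays a reaction-level target
  m3 <- m
  m3$reactions$gpr[match("R2", m3$reactions$id)] <- ""
  tg3 <- map_genes(m3, rank_targets(scan))
  expect_identical(tg3$genes[tg3$reaction_id == "R2"], "")
  expect_true("R2" %in% tg3$reaction_id)
})

test_that("widening the mean gap at fixed sigma never lowers the score", {
  cfg <- filter_config()
  gaps <- seq(0.1, 15, by = 0.3)
  scores <- vapply(gaps, function(d) {
    score_reaction("R", gaussian_summary(0, 1.3), gaussian_summary(d, 0.6),
                   cfg)$score
  }, 0)
  expect_true(all(diff(scores) >= -1e-9))
})
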