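test_that("JSON fixtures round-trip with full fidelity and canonical form", {
  toy <- build_branched_toy()
  path <- withr::local_tempfile(fileext = ".json")
  write_fixture(toy$model, path, "json")
  reloaded <- load_model(path)

  expect_identical(reloaded$reactions$id, toy$model$reactions$id)
  expect_identical(reloaded$metabolites, toy$model$metabolites)
  expect_equal(reloaded$reactions$lower_bound, toy$model$reactions$lower_bound)
  expect_equal(reloaded$reactions$upper_bound, toy$model$reactions$upper_bound)
  expect_identical(reloaded$reactions$gpr, toy$model$reactions$gpr)
  expect_identical(reloaded$objective_reaction, toy$model$objective_reaction)
  for (j in seq_len(nrow(reloaded$reactions))) {
    a <- toy$model$reactions$metabolites[[j]]
    b <- reloaded$reactions$metabolites[[j]]
    expect_equal(b[order(names(b))], a[order(names(a))])
  }

  # canonical ordering: re-serializing the loaded model is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_fixture(reloaded, path2, "json")
  expect_identical(readLines(path), readLines(path2))
})

test_that("SBML and JSON encodings of the same fixture load identically", {
  toy <- build_branched_toy(toy_model_spec(n_chain = 2L, branch_yield = 0.5))
  pj <- withr::local_tempfile(fileext = ".json")
  ps <- withr::local_tempfile(fileext = ".xml")
  write_fixture(toy$model, pj, "json")
  write_fixture(toy$model, ps, "sbml")
  mj <- load_model(pj)
  ms <- load_model(ps)
  expect_identical(ms$reactions$id, mj$reactions$id)
  expect_equal(ms$reactions$lower_bound, mj$reactions$lower_bound)
  expect_equal(ms$reactions$upper_bound, mj$reactions$upper_bound)
  expect_identical(ms$reactions$gpr, mj$reactions$gpr)
  expect_identical(sort(ms$genes), sort(mj$genes))
  expect_identical(ms$objective_reaction, mj$objective_reaction)
  for (j in seq_len(nrow(ms$reactions))) {
    a <- mj$reactions$metabolites[[j]]
    b <- ms$reactions$metabolites[[j]]
    expect_equal(b[order(names(b))], a[order(names(a))])
  }
})

test_that("SBML output declares the FBC v2 namespace and core structure", {
  toy <- build_branched_toy()
  ps <- withr::local_tempfile(fileext = ".xml")
  write_fixture(toy$model, ps, "sbml")
  doc <- xml2::read_xml(ps)
  nss <- unlist(xml2::xml_ns(doc))
  expect_true("http://www.sbml.org/sbml/level3/version1/fbc/version2" %in% nss)
  expect_true("http://www.sbml.org/sbml/level3/version1/core" %in% nss)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  expect_length(
    xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns),
    nrow(toy$model$reactions))
})

test_that("duplicate ids and malformed files are rejected with clear errors", {
  toy <- build_branched_toy()
  path <- withr::local_tempfile(fileext = ".json")
  write_fixture(toy$model, path, "json")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$reactions[[2]]$id <- doc$reactions[[1]]$id
  dup <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, dup, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(dup), "duplicate reaction id")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_model(bad), "malformed JSON")

  expect_error(load_model(withr::local_tempfile(fileext = ".json")),
               "does not exist")

  # SBML without the FBC extension is out of scope and says so
  old <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
               '<model id="m"/></sbml>'), old)
  expect_error(load_model(old), "FBC v2")
})

test_that("format auto-detection falls back to content sniffing", {
  toy <- build_branched_toy()
  noext <- withr::local_tempfile()
  write_fixture(toy$model, noext, "sbml")
  m <- load_model(noext)
  expect_identical(m$reactions$id, toy$model$reactions$id)
})

test_that("reaction lookup is exact, case-sensitive, and suggests near-misses", {
  toy <- build_branched_toy()
  expect_identical(resolve_reaction(toy$model, "R2")$id, "R2")
  expect_error(resolve_reaction(toy$model, "r2"), "case-sensitive")
  expect_error(resolve_reaction(toy$model, "r2"), "R2")  # suggestion listed
  expect_error(resolve_reaction(toy$model, ""), "non-empty")
})

test_that("set_carbon_source follows the uptake sign convention and is idempotent", {
  toy <- build_branched_toy()
  m <- set_carbon_source(toy$model, "EX_A", 7)
  i <- match("EX_A", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -7)
  expect_equal(m$reactions$upper_bound[i],
               toy$model$reactions$upper_bound[i])
  # input model is not mutated
  expect_equal(toy$model$reactions$lower_bound[i], -10)
  # idempotent for the same rate
  expect_identical(set_carbon_source(m, "EX_A", 7), m)
  # zero shuts uptake off
  m0 <- set_carbon_source(toy$model, "EX_A", 0)
  expect_equal(m0$reactions$lower_bound[i], 0)
  expect_error(set_carbon_source(toy$model, "EX_missing", 10), "closest ids")
})

test_that("model validation catches undeclared metabolites and crossed bounds", {
  toy <- build_branched_toy()
  bad <- toy$model
  bad$reactions$metabolites[[2]] <- c(GHOST = -1)
  expect_error(validate_model(bad), "undeclared metabolite")
  bad2 <- toy$model
  bad2$reactions$lower_bound[3] <- 5
  bad2$reactions$upper_bound[3] <- 1
  expect_error(validate_model(bad2), "lower_bound > upper_bound")
})
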