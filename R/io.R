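#' Load a constraint-based model from SBML-FBC or BiGG-style JSON
#'
#' Supported dialects are SBML Level 3 with the FBC v2 extension (the modern
#' standard for constraint-based models) and the BiGG distribution JSON
#' schema (top-level keys `reactions`, `metabolites`, `genes`; per-reaction
#' `lower_bound`, `upper_bound`, `metabolites`, `gene_reaction_rule`).
#' Bounds and stoichiometric coefficients are parsed as double-precision
#' decimals; no unit conversion is applied (mmol/gDW/h assumed throughout).
#'
#' @param path Path to the model file.
#' @param format `"sbml"`, `"json"`, or `"auto"` (detect by extension, then
#'   by content).
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml"
              else if (ext == "json") "json"
              else {
                head <- trimws(readChar(path, 64L, useBytes = TRUE))
                if (startsWith(head, "<")) "sbml" else "json"
              }
  }
  model <- switch(format,
                  sbml = read_model_sbml(path),
                  json = read_model_json(path))
  validate_model(model)
  model
}

# ---- BiGG-style JSON ------------------------------------------------------

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  for (key in c("metabolites", "reactions")) {
    if (is.null(doc[[key]])) stop("malformed model JSON: missing '", key, "'")
  }
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), ""),
    compartment = vapply(doc$metabolites, function(m) {
      if (is.null(m$compartment)) "" else as.character(m$compartment)
    }, ""),
    stringsAsFactors = FALSE
  )
  stoich <- lapply(doc$reactions, function(r) {
    if (is.null(r$metabolites) || length(r$metabolites) == 0L) {
      stop("malformed model JSON: reaction '", r$id, "' has no metabolites")
    }
    unlist(lapply(r$metabolites, as.numeric))
  })
  obj_coef <- vapply(doc$reactions, function(r) {
    if (is.null(r$objective_coefficient)) 0 else as.numeric(r$objective_coefficient)
  }, 0)
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) as.character(r$id), ""),
    name = vapply(doc$reactions, function(r) {
      if (is.null(r$name)) "" else as.character(r$name)
    }, ""),
    lower_bound = vapply(doc$reactions, function(r) as.numeric(r$lower_bound), 0),
    upper_bound = vapply(doc$reactions, function(r) as.numeric(r$upper_bound), 0),
    gpr = vapply(doc$reactions, function(r) {
      if (is.null(r$gene_reaction_rule)) "" else as.character(r$gene_reaction_rule)
    }, ""),
    stringsAsFactors = FALSE
  )
  rxns$metabolites <- stoich
  genes <- vapply(doc$genes, function(g) as.character(g$id), character(1))
  objective <- if (any(obj_coef != 0)) rxns$id[which(obj_coef != 0)[1L]]
               else NA_character_
  metabolic_model(
    model_id = if (is.null(doc$id)) "model" else as.character(doc$id),
    metabolites = mets, reactions = rxns, genes = genes,
    objective_reaction = objective
  )
}

# numbers are serialized with full double precision so a load/write cycle
# is value-faithful
num_chr <- function(x) sprintf("%.17g", x)

write_model_json <- function(model, path) {
  rxn <- model$reactions
  reactions <- lapply(seq_len(nrow(rxn)), function(i) {
    st <- rxn$metabolites[[i]]
    st <- st[order(names(st))]
    list(
      id = rxn$id[i],
      name = rxn$name[i],
      metabolites = as.list(st),
      lower_bound = rxn$lower_bound[i],
      upper_bound = rxn$upper_bound[i],
      gene_reaction_rule = rxn$gpr[i],
      objective_coefficient =
        if (!is.na(model$objective_reaction) &&
            rxn$id[i] == model$objective_reaction) 1 else 0
    )
  })
  metabolites <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    list(id = model$metabolites$id[i],
         compartment = model$metabolites$compartment[i])
  })
  genes <- lapply(model$genes, function(g) list(id = g))
  doc <- list(id = model$model_id, metabolites = metabolites,
              reactions = reactions, genes = genes)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
  writeLines(json, path)
  invisible(path)
}

# ---- SBML Level 3 / FBC v2 ------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("not an SBML document (root element '", root, "')")
  nss <- xml2::xml_ns(doc)
  if (!any(unlist(nss) == FBC_NS)) {
    stop("SBML Level 3 with the FBC v2 extension is required; ",
         "this file declares no FBC v2 namespace (earlier SBML encodings ",
         "are not supported)")
  }
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, "./s:model", ns)
  if (is.na(model_node)) stop("malformed SBML: no <model> element")
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  species <- xml2::xml_find_all(model_node, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(species, "id"), "M_"),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE
  )

  params <- xml2::xml_find_all(model_node, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(model_node,
                            ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_id <- xml2::xml_attr(gps, "id")
  gp_label <- xml2::xml_attr(gps, "label")
  gp_label[is.na(gp_label)] <- strip_prefix(gp_id[is.na(gp_label)], "G_")
  gene_of <- stats::setNames(gp_label, gp_id)

  rnodes <- xml2::xml_find_all(model_node, ".//s:listOfReactions/s:reaction", ns)
  if (length(rnodes) == 0L) stop("malformed SBML: model declares no reactions")
  n <- length(rnodes)
  ids <- strip_prefix(xml2::xml_attr(rnodes, "id"), "R_")
  names_ <- xml2::xml_attr(rnodes, "name")
  names_[is.na(names_)] <- ""
  lb <- ub <- numeric(n)
  stoich <- vector("list", n)
  gprs <- character(n)
  for (i in seq_len(n)) {
    node <- rnodes[[i]]
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref)) {
      stop("malformed SBML-FBC: reaction ", ids[i],
           " lacks fbc:lowerFluxBound/fbc:upperFluxBound")
    }
    lb[i] <- pval[[lb_ref]]
    ub[i] <- pval[[ub_ref]]
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(reac, "species"), "M_")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(prod, "species"), "M_"))
    )
    if (length(st) == 0L) stop("malformed SBML: reaction ", ids[i],
                               " has no reactants or products")
    stoich[[i]] <- st
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gprs[i] <- if (is.na(gpa)) "" else {
      child <- xml2::xml_find_first(gpa, "./*")
      gpr_tree_to_string(sbml_gpa_to_tree(child, gene_of))
    }
  }
  rxns <- data.frame(id = ids, name = names_, lower_bound = lb,
                     upper_bound = ub, gpr = gprs, stringsAsFactors = FALSE)
  rxns$metabolites <- stoich

  objective <- NA_character_
  act <- xml2::xml_find_first(
    model_node, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (!is.na(act)) {
    objective <- strip_prefix(xml2::xml_attr(act, "reaction"), "R_")
  }

  metabolic_model(model_id = model_id, metabolites = mets, reactions = rxns,
                  genes = sort(unique(unname(gene_of))),
                  objective_reaction = objective)
}

strip_prefix <- function(x, prefix) {
  sub(paste0("^", prefix), "", x)
}

# recursive fbc:and / fbc:or / fbc:geneProductRef -> boolean tree
sbml_gpa_to_tree <- function(node, gene_of) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    g <- gene_of[[ref]]
    if (is.null(g)) g <- strip_prefix(ref, "G_")
    return(g)
  }
  if (name %in% c("and", "or")) {
    kids <- xml2::xml_find_all(node, "./*")
    return(list(op = name, args = lapply(kids, sbml_gpa_to_tree, gene_of = gene_of)))
  }
  stop("malformed SBML-FBC gene association element <", name, ">")
}

# boolean tree -> canonical GPR string ("and" binds tighter than "or")
gpr_tree_to_string <- function(tree) {
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_tree_to_string(a)
    wrap <- !is.character(a) &&
      ((tree$op == "or" && a$op == "and") || (tree$op == "and" && a$op == "or"))
    if (wrap) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

# GPR string -> boolean tree (recursive descent: expr = term {or term},
# term = factor {and factor}, factor = gene | "(" expr ")")
gpr_string_to_tree <- function(gpr) {
  toks <- gpr_tokens(gpr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR rule")
    if (t == "(") {
      e <- parse_expr()
      if (is.na(peek()) || take() != ")") stop("unbalanced parentheses in GPR")
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("unexpected token '", t, "' in GPR rule")
    }
    t
  }
  tree <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR rule")
  tree
}

write_model_sbml <- function(model, path) {
  rxn <- model$reactions
  compartments <- unique(model$metabolites$compartment)
  compartments[!nzchar(compartments)] <- "c"
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', model$model_id, '" fbc:strict="true">'),
    "    <listOfCompartments>",
    paste0('      <compartment id="', unique(compartments),
           '" constant="true"/>'),
    "    </listOfCompartments>",
    "    <listOfSpecies>"
  )
  comp <- model$metabolites$compartment
  comp[!nzchar(comp)] <- "c"
  lines <- c(lines,
    paste0('      <species id="M_', model$metabolites$id, '" compartment="',
           comp, '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
           ' constant="false"/>'),
    "    </listOfSpecies>",
    "    <listOfParameters>")
  for (i in seq_len(nrow(rxn))) {
    lines <- c(lines,
      paste0('      <parameter id="', rxn$id[i], '_lb" value="',
             num_chr(rxn$lower_bound[i]), '" constant="true"/>'),
      paste0('      <parameter id="', rxn$id[i], '_ub" value="',
             num_chr(rxn$upper_bound[i]), '" constant="true"/>'))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(rxn))) {
    st <- rxn$metabolites[[i]]
    st <- st[order(names(st))]
    reactants <- st[st < 0]
    products <- st[st > 0]
    lines <- c(lines, paste0(
      '      <reaction id="R_', rxn$id[i], '" name="',
      xml_escape(rxn$name[i]), '" reversible="',
      tolower(rxn$lower_bound[i] < 0), '" fast="false" fbc:lowerFluxBound="',
      rxn$id[i], '_lb" fbc:upperFluxBound="', rxn$id[i], '_ub">'))
    if (length(reactants)) {
      lines <- c(lines, "        <listOfReactants>",
        paste0('          <speciesReference species="M_', names(reactants),
               '" stoichiometry="', num_chr(-unname(reactants)),
               '" constant="true"/>'),
        "        </listOfReactants>")
    }
    if (length(products)) {
      lines <- c(lines, "        <listOfProducts>",
        paste0('          <speciesReference species="M_', names(products),
               '" stoichiometry="', num_chr(unname(products)),
               '" constant="true"/>'),
        "        </listOfProducts>")
    }
    if (nzchar(rxn$gpr[i])) {
      tree <- gpr_string_to_tree(rxn$gpr[i])
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 gpr_tree_to_sbml(tree, indent = "          "),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (!is.na(model$objective_reaction)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      "        <fbc:listOfFluxObjectives>",
      paste0('          <fbc:fluxObjective fbc:reaction="R_',
             model$objective_reaction, '" fbc:coefficient="1"/>'),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  if (length(model$genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
      paste0('      <fbc:geneProduct fbc:id="G_', model$genes,
             '" fbc:label="', model$genes, '"/>'),
      "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

gpr_tree_to_sbml <- function(tree, indent) {
  if (is.character(tree)) {
    return(paste0(indent, '<fbc:geneProductRef fbc:geneProduct="G_', tree, '"/>'))
  }
  c(paste0(indent, "<fbc:", tree$op, ">"),
    unlist(lapply(tree$args, gpr_tree_to_sbml, indent = paste0(indent, "  "))),
    paste0(indent, "</fbc:", tree$op, ">"))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Write a model to disk in SBML-FBC or BiGG-style JSON
#'
#' Output is loadable by [load_model()] with full fidelity. JSON output uses
#' a canonical key ordering and full double precision, so re-serializing a
#' loaded fixture is byte-identical.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @param format `"json"` or `"sbml"`.
#' @return The path, invisibly.
#' @export
write_fixture <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write fixture, no such directory: ", dir)
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}
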