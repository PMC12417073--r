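#' @title Gene-protein-reaction rule handling
#' @description GPR rules are boolean expressions over gene ids using
#'   `and` / `or` (case-insensitive) and parentheses, e.g.
#'   `"(g1 and g2) or g3"`. The rules are not evaluated for isozyme/complex
#'   logic; the package validates well-formedness and extracts the set of
#'   genes a rule mentions.
#' @name gpr
NULL

# tokenize a GPR into "(", ")", "and", "or", and gene-id tokens
gpr_tokens <- function(gpr) {
  x <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Check that a GPR rule is a well-formed boolean expression
#'
#' @param gpr GPR rule string; the empty string is valid (no gene association).
#' @return `TRUE` or `FALSE`.
#' @export
gpr_is_valid <- function(gpr) {
  if (!is.character(gpr) || length(gpr) != 1L || is.na(gpr)) return(FALSE)
  if (!nzchar(trimws(gpr))) return(TRUE)
  toks <- gpr_tokens(gpr)
  depth <- 0L
  expect_operand <- TRUE  # grammar: operand (op operand)*, parens recurse
  for (t in toks) {
    low <- tolower(t)
    if (t == "(") {
      if (!expect_operand) return(FALSE)
      depth <- depth + 1L
    } else if (t == ")") {
      if (expect_operand || depth == 0L) return(FALSE)
      depth <- depth - 1L
    } else if (low %in% c("and", "or")) {
      if (expect_operand) return(FALSE)
      expect_operand <- TRUE
    } else {
      if (!expect_operand) return(FALSE)
      expect_operand <- FALSE
    }
  }
  depth == 0L && !expect_operand
}

#' Extract the genes mentioned in a GPR rule
#'
#' Flattens the rule to the deduplicated, sorted vector of gene ids it
#' mentions, ignoring the boolean structure.
#'
#' @param gpr GPR rule string.
#' @return Character vector of gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (!is.character(gpr) || length(gpr) != 1L || is.na(gpr) ||
      !nzchar(trimws(gpr))) {
    return(character())
  }
  toks <- gpr_tokens(gpr)
  genes <- toks[!(tolower(toks) %in% c("and", "or")) & !(toks %in% c("(", ")"))]
  sort(unique(genes))
}
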