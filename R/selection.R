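# Atom selection mini-language.
#
# Grammar:
#   expr    := term ("or" term)*
#   term    := factor ("and" factor)*
#   factor  := "not" factor | "(" expr ")" | primary
#   primary := "name" ID+ | "resname" ID+ | "resid" RANGE+ |
#              "protein" | "lipid" | "solvent" | "ion"
#   RANGE   := INT | INT ":" INT
# Selections are deterministic, order-preserving subsets of atom indices.

sel_tokenize <- function(expression) {
  pat <- "\\(|\\)|:|[A-Za-z0-9_'+*-]+"
  m <- gregexpr(pat, expression)[[1]]
  if (m[1] == -1) stopf("selection syntax error at position 1: empty expression")
  tok <- regmatches(expression, gregexpr(pat, expression))[[1]]
  # check nothing but whitespace was skipped
  covered <- unlist(mapply(function(s, l) s:(s + l - 1), m,
                           attr(m, "match.length"), SIMPLIFY = FALSE))
  rest <- setdiff(seq_len(nchar(expression)), covered)
  chars <- if (length(rest)) vapply(rest, function(i) substr(expression, i, i),
                                    character(1)) else character(0)
  bad <- rest[!chars %in% c(" ", "\t")]
  if (length(bad))
    stopf("selection syntax error at position %d: unexpected '%s'",
          bad[1], substr(expression, bad[1], bad[1]))
  list(tok = tok, pos = as.integer(m))
}

#' Select atoms by expression
#'
#' A small boolean selection language over atom names, residue names, residue
#' id ranges and residue classifications, e.g. \code{"name P and lipid"},
#' \code{"resname CHL"}, \code{"protein and resid 631:902"},
#' \code{"not (solvent or ion)"}.
#'
#' @param system a \code{\link{molecular_system}}.
#' @param expression selection string (see Details).
#' @return integer vector of atom indices (row numbers into
#'   \code{system$atoms}), in atom order; empty matches return
#'   \code{integer(0)}, not an error.
#' @export
select_atoms <- function(system, expression) {
  tk <- sel_tokenize(expression)
  toks <- tolower(tk$tok)
  raw <- tk$tok
  pos <- tk$pos
  i <- 0L
  n <- length(toks)
  peek <- function() if (i < n) toks[i + 1L] else NA_character_
  advance <- function() { i <<- i + 1L; raw[i] }
  fail <- function(msg) {
    p <- if (i < n) pos[i + 1L] else nchar(expression) + 1L
    stopf("selection syntax error at position %d: %s", p, msg)
  }
  a <- system$atoms
  keywords <- c("name", "resname", "resid", "protein", "lipid", "solvent",
                "ion", "and", "or", "not", "(", ")")

  parse_primary <- function() {
    kw <- peek()
    if (is.na(kw)) fail("expected a selection keyword")
    if (kw == "name" || kw == "resname") {
      advance()
      vals <- character(0)
      while (!is.na(peek()) && !(peek() %in% keywords)) vals <- c(vals, advance())
      if (!length(vals)) fail(sprintf("'%s' needs at least one value", kw))
      if (kw == "name") toupper(a$name) %in% toupper(vals)
      else toupper(a$resname) %in% toupper(vals)
    } else if (kw == "resid") {
      advance()
      keep <- rep(FALSE, nrow(a))
      got <- FALSE
      while (!is.na(peek()) && grepl("^[0-9]+$", peek())) {
        lo <- as.integer(advance()); hi <- lo
        if (identical(peek(), ":")) {
          advance()
          if (is.na(peek()) || !grepl("^[0-9]+$", peek())) fail("expected integer after ':'")
          hi <- as.integer(advance())
        }
        keep <- keep | (a$resid >= lo & a$resid <= hi)
        got <- TRUE
      }
      if (!got) fail("'resid' needs at least one id or range")
      keep
    } else if (kw == "protein") { advance(); a$class == "protein"
    } else if (kw == "lipid") { advance(); is_lipid_class(a$class)
    } else if (kw == "solvent") { advance(); a$class == "solvent"
    } else if (kw == "ion") { advance(); a$class == "ion"
    } else if (kw == "(") {
      advance()
      v <- parse_expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      v
    } else fail(sprintf("unexpected token '%s'", kw))
  }
  parse_factor <- function() {
    if (identical(peek(), "not")) { advance(); return(!parse_factor()) }
    parse_primary()
  }
  parse_term <- function() {
    v <- parse_factor()
    while (identical(peek(), "and")) { advance(); v <- v & parse_factor() }
    v
  }
  parse_expr <- function() {
    v <- parse_term()
    while (identical(peek(), "or")) { advance(); v <- v | parse_term() }
    v
  }
  v <- parse_expr()
  if (i < n) fail(sprintf("unexpected trailing token '%s'", raw[i + 1L]))
  which(v)
}
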