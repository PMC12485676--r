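# Atom selections.  Two surfaces over the same evaluator: a keyword
# interface (select_atoms) and a small documented query language
# (select_query) for configuration files and the command line.
#
# Query grammar (case-insensitive keywords, values case-sensitive):
#   expr   := term { "or" term }
#   term   := factor { "and" factor }
#   factor := "not" factor | "(" expr ")" | clause
#   clause := key [ "=" ] value { "," value }
#   key    := role | chain | resno | resnum | resname | resid | name |
#             elety | pf | ring | dimer
#   value  := literal, or "a-b" integer range for the integer-valued keys
# Example: "role=alpha and resno 445-450 and resname GLU".

SEL_KEYS <- c(role = "role", chain = "chain", resno = "resno",
              resnum = "resno", resname = "resid", resid = "resid",
              name = "elety", elety = "elety", pf = "pf", ring = "ring",
              dimer = "dimer")

#' Select atoms by attribute
#'
#' Returns the (order-stable, deterministic) indices of atoms matching all
#' supplied filters; each filter accepts a vector of allowed values.
#'
#' @param model a `lattice_model`.
#' @param role subunit role(s) of the owning chain
#'   (`"alpha"`, `"beta"`, `"ligand"`, `"other"`).
#' @param chain chain identifier(s).
#' @param resno author residue number(s).
#' @param resid 3-letter residue name(s).
#' @param elety atom name(s).
#' @param pf,ring,dimer lattice labels of the owning chain.
#' @return increasing integer vector of atom indices.
#' @export
select_atoms <- function(model, role = NULL, chain = NULL, resno = NULL,
                         resid = NULL, elety = NULL, pf = NULL, ring = NULL,
                         dimer = NULL) {
  keep <- rep(TRUE, n_atoms(model))
  lab <- atom_chain_labels(model)
  test <- function(keep, values, field) {
    if (is.null(values)) keep else keep & (field %in% values)
  }
  keep <- test(keep, role, lab$role)
  keep <- test(keep, pf, lab$pf)
  keep <- test(keep, ring, lab$ring)
  keep <- test(keep, dimer, lab$dimer)
  keep <- test(keep, chain, model$atoms$chain)
  keep <- test(keep, resno, model$atoms$resno)
  keep <- test(keep, resid, model$atoms$resid)
  keep <- test(keep, elety, model$atoms$elety)
  which(keep)
}

#' Select atoms with a query string
#'
#' Evaluates a query in the documented selection grammar (see
#' [parse_selection()]) against a model.
#'
#' @param model a `lattice_model`.
#' @param query selection expression, e.g.
#'   `"role=alpha and resno 445-450 and resname GLU"`.
#' @return increasing integer vector of atom indices.
#' @export
select_query <- function(model, query) {
  ast <- parse_selection(query)
  which(eval_selection(ast, model))
}

#' Parse a selection expression
#'
#' Parses the selection grammar into an AST; malformed queries raise a parse
#' error naming the character position of the offending token.
#'
#' @param query selection expression string.
#' @return the parsed expression (an internal AST), invisibly usable with
#'   [select_query()].
#' @export
parse_selection <- function(query) {
  stopifnot(is.character(query), length(query) == 1L)
  m <- gregexpr("[()]|[^\\s()]+", query, perl = TRUE)[[1]]
  if (m[1] == -1) stop("selection parse error: empty query")
  toks <- regmatches(query, gregexpr("[()]|[^\\s()]+", query, perl = TRUE))[[1]]
  pos <- as.integer(m)
  i <- 0L
  peek <- function() if (i < length(toks)) toks[i + 1L] else NA_character_
  advance <- function() { i <<- i + 1L; toks[i] }
  fail <- function(msg, at = i + 1L) {
    p <- if (at <= length(pos)) pos[at] else nchar(query) + 1L
    stop("selection parse error at position ", p, ": ", msg, call. = FALSE)
  }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_expr <- function() {
    node <- parse_term()
    while (is_kw(peek(), "or")) {
      advance()
      node <- list(op = "or", a = node, b = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (is_kw(peek(), "and")) {
      advance()
      node <- list(op = "and", a = node, b = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of query")
    if (is_kw(t, "not")) {
      advance()
      return(list(op = "not", a = parse_factor()))
    }
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(node)
    }
    parse_clause()
  }
  parse_clause <- function() {
    t <- advance()
    key <- tolower(sub("=.*$", "", t))
    if (!key %in% names(SEL_KEYS))
      fail(paste0("unknown selection key '", key, "'"), i)
    field <- SEL_KEYS[[key]]
    if (grepl("=", t, fixed = TRUE)) {
      vals <- sub("^[^=]*=", "", t)
      if (vals == "") fail(paste0("key '", key, "' has no value"), i)
    } else {
      # "resno 445-450" form: value(s) in the next token
      nxt <- peek()
      if (is.na(nxt) || nxt %in% c("(", ")") ||
          tolower(nxt) %in% c("and", "or", "not"))
        fail(paste0("key '", key, "' has no value"), i)
      vals <- advance()
    }
    list(op = "clause", field = field, values = parse_values(vals, field, fail, i))
  }
  parse_values <- function(vals, field, fail, at) {
    parts <- strsplit(vals, ",", fixed = TRUE)[[1]]
    parts <- parts[parts != ""]
    if (!length(parts)) fail("empty value list", at)
    if (field %in% c("resno", "pf", "ring", "dimer")) {
      out <- integer(0)
      for (p in parts) {
        if (grepl("^-?[0-9]+--?[0-9]+$", p) || grepl("^[0-9]+-[0-9]+$", p)) {
          ab <- as.integer(strsplit(p, "(?<=[0-9])-", perl = TRUE)[[1]])
          out <- c(out, seq(ab[1], ab[2]))
        } else if (grepl("^-?[0-9]+$", p)) {
          out <- c(out, as.integer(p))
        } else fail(paste0("expected integer or range, got '", p, "'"), at)
      }
      out
    } else parts
  }

  ast <- parse_expr()
  if (i < length(toks)) fail("trailing tokens")
  ast
}

eval_selection <- function(node, model) {
  switch(node$op,
    "or"  = eval_selection(node$a, model) | eval_selection(node$b, model),
    "and" = eval_selection(node$a, model) & eval_selection(node$b, model),
    "not" = !eval_selection(node$a, model),
    "clause" = {
      lab <- atom_chain_labels(model)
      field <- switch(node$field,
        role = lab$role, pf = lab$pf, ring = lab$ring, dimer = lab$dimer,
        chain = model$atoms$chain, resno = model$atoms$resno,
        resid = model$atoms$resid, elety = model$atoms$elety)
      field %in% node$values
    },
    stop("internal: unknown AST op ", node$op))
}
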