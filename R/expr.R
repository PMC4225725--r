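# Boolean rule language over domain-signature accessions.
#
# Grammar (conventional precedence, `&` binds tighter than `|`):
#   expr   := term ('|' term)*
#   term   := factor ('&' factor)*
#   factor := ACCESSION | '(' expr ')'
# Whitespace is ignored. Accessions are 1-4 letters followed by 4-7 digits
# (InterPro IPR......, Pfam PF....., PROSITE PS....., SMART SM....., ...),
# compared case-insensitively.

#' @keywords internal
ACCESSION_REGEX <- "^[A-Za-z]{1,4}[0-9]{4,7}$"

#' Test whether strings are syntactically valid domain accessions
#'
#' A domain accession is 1-4 letters followed by 4-7 digits, covering
#' InterPro (`IPR003340`), Pfam (`PF02362`), PROSITE (`PS50097`) and SMART
#' (`SM00225`) identifiers. Comparison elsewhere in the package is
#' case-insensitive and version-less.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @examples
#' is_accession(c("IPR003340", "PS50097", "not-an-acc"))
#' @export
is_accession <- function(x) {
  grepl(ACCESSION_REGEX, x)
}

new_expr_atom <- function(acc) {
  structure(list(kind = "atom", acc = acc), class = "dom_expr")
}

new_expr_node <- function(kind, children) {
  stopifnot(kind %in% c("and", "or"), length(children) >= 2)
  structure(list(kind = kind, children = children), class = "dom_expr")
}

parse_error <- function(msg, offset) {
  rlang::abort(
    sprintf("syntax error at offset %d: %s", offset, msg),
    class = "domfam_parse_error",
    offset = offset
  )
}

# Tokenizer; offsets are 0-based character positions into the input string.
tokenize_expr <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
      next
    }
    if (ch %in% c("(", ")", "&", "|")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, offset = i - 1L)
      i <- i + 1L
      next
    }
    if (grepl("[A-Za-z0-9]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9]", chars[[j]])) j <- j + 1L
      tok <- paste(chars[i:(j - 1L)], collapse = "")
      if (!is_accession(tok)) {
        parse_error(sprintf("illegal accession token '%s'", tok), i - 1L)
      }
      toks[[length(toks) + 1L]] <- list(type = "ACC", text = tok, offset = i - 1L)
      i <- j
      next
    }
    parse_error(sprintf("unexpected character '%s'", ch), i - 1L)
  }
  toks
}

#' Parse a must-have / prohibited domain pattern
#'
#' Parses the boolean rule language used to express family prediction
#' logics, e.g. the ARF transcription-factor rule
#' `"(IPR010525|IPR011525)&IPR003340"` ("either IPR010525 or IPR011525, and
#' IPR003340"). `&` binds tighter than `|`; parentheses group; whitespace is
#' ignored. Curated tables should still parenthesize for clarity.
#'
#' @param text A single rule-language string.
#' @return A `dom_expr` abstract syntax tree: a list with `kind` one of
#'   `"atom"` (field `acc`), `"and"` or `"or"` (field `children`, a list of
#'   two or more `dom_expr` nodes).
#' @seealso [evaluate_expression()], [expr_atoms()], [expr_serialize()]
#' @examples
#' parse_expression("(IPR010525|IPR011525)&IPR003340")
#' parse_expression("IPR002100")
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(trimws(text))) {
    parse_error("empty expression", 0L)
  }
  toks <- tokenize_expr(text)
  eof_offset <- nchar(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() {
    tok <- toks[[pos]]
    pos <<- pos + 1L
    tok
  }

  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) {
      parse_error("expected accession or '(' but input ended", eof_offset)
    }
    if (tok$type == "ACC") {
      advance()
      return(new_expr_atom(tok$text))
    }
    if (tok$type == "(") {
      open <- advance()
      inner_tok <- peek()
      if (!is.null(inner_tok) && inner_tok$type == ")") {
        parse_error("empty parentheses", inner_tok$offset)
      }
      inner <- parse_expr()
      close <- peek()
      if (is.null(close)) {
        parse_error("unbalanced parentheses: '(' never closed", open$offset)
      }
      if (close$type != ")") {
        parse_error(sprintf("expected ')' but found '%s'", close$text), close$offset)
      }
      advance()
      return(inner)
    }
    parse_error(sprintf("expected accession or '(' but found '%s'", tok$text), tok$offset)
  }

  parse_term <- function() {
    children <- list(parse_factor())
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      children[[length(children) + 1L]] <- parse_factor()
    }
    if (length(children) == 1L) children[[1L]] else new_expr_node("and", children)
  }

  parse_expr <- function() {
    children <- list(parse_term())
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      children[[length(children) + 1L]] <- parse_term()
    }
    if (length(children) == 1L) children[[1L]] else new_expr_node("or", children)
  }

  ast <- parse_expr()
  trailing <- peek()
  if (!is.null(trailing)) {
    parse_error(sprintf("unexpected '%s'", trailing$text), trailing$offset)
  }
  ast
}

#' Evaluate a domain pattern against an accession set
#'
#' Atoms test (case-insensitive) membership in `accessions`; `and` nodes
#' require all children true; `or` nodes require any child true. The
#' language has no negation, so evaluation is monotone: adding accessions
#' can never turn a true expression false.
#'
#' @param expr A `dom_expr` from [parse_expression()].
#' @param accessions Character vector of domain accessions observed on one
#'   protein (order and duplication irrelevant).
#' @return `TRUE` or `FALSE`.
#' @examples
#' arf <- parse_expression("(IPR010525|IPR011525)&IPR003340")
#' evaluate_expression(arf, c("IPR011525", "IPR003340"))
#' evaluate_expression(arf, "IPR003340")
#' @export
evaluate_expression <- function(expr, accessions) {
  stopifnot(inherits(expr, "dom_expr"))
  acc_up <- unique(toupper(accessions))
  eval_node <- function(node) {
    switch(node$kind,
      atom = toupper(node$acc) %in% acc_up,
      and = all(vapply(node$children, eval_node, logical(1))),
      or = any(vapply(node$children, eval_node, logical(1))),
      stop("invalid expression node kind: ", node$kind)
    )
  }
  eval_node(expr)
}

#' Extract the atoms of a domain pattern
#'
#' @param expr A `dom_expr`.
#' @return Character vector of distinct accessions in first-appearance
#'   order (original case preserved).
#' @examples
#' expr_atoms(parse_expression("(IPR010525|IPR011525)&IPR003340"))
#' @export
expr_atoms <- function(expr) {
  stopifnot(inherits(expr, "dom_expr"))
  walk <- function(node) {
    if (node$kind == "atom") {
      node$acc
    } else {
      unlist(lapply(node$children, walk), use.names = FALSE)
    }
  }
  unique(walk(expr))
}

#' Serialize a domain pattern back to rule-language text
#'
#' Parentheses are emitted wherever a child has lower precedence than its
#' parent, so `parse_expression(expr_serialize(x))` is logically equivalent
#' to `x` (identical truth table over its atoms).
#'
#' @param expr A `dom_expr`.
#' @return A single rule-language string.
#' @examples
#' expr_serialize(parse_expression("A00001|B00002&C00003"))
#' @export
expr_serialize <- function(expr) {
  stopifnot(inherits(expr, "dom_expr"))
  ser <- function(node) {
    switch(node$kind,
      atom = node$acc,
      or = paste(vapply(node$children, ser, character(1)), collapse = "|"),
      and = paste(
        vapply(node$children, function(ch) {
          s <- ser(ch)
          if (ch$kind == "or") paste0("(", s, ")") else s
        }, character(1)),
        collapse = "&"
      )
    )
  }
  ser(expr)
}

#' @export
format.dom_expr <- function(x, ...) {
  expr_serialize(x)
}

#' @export
print.dom_expr <- function(x, ...) {
  cat("<dom_expr> ", expr_serialize(x), "\n", sep = "")
  invisible(x)
}
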