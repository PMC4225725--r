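# Independent brute-force oracle for the rule language: substitute every
# atom with TRUE/FALSE and evaluate the text as base-R code (& and | are
# base operators with the same precedence convention), never touching the
# package's AST machinery.

oracle_atoms <- function(text) {
  unique(unlist(regmatches(text, gregexpr("[A-Za-z]{1,4}[0-9]{4,7}", text))))
}

oracle_eval <- function(text, accessions) {
  atoms <- oracle_atoms(text)
  atoms <- atoms[order(-nchar(atoms))]  # longer tokens first: no partial overlap
  for (a in atoms) {
    val <- if (toupper(a) %in% toupper(accessions)) "TRUE" else "FALSE"
    text <- gsub(a, val, text, fixed = TRUE)
  }
  eval(parse(text = text))
}

# Random fully-parenthesized rule text over a fixed atom pool; independent
# of the package's simulate_rule_table() generator.
random_expr_text <- function(atoms) {
  if (length(atoms) == 1) {
    return(atoms)
  }
  k <- sample(length(atoms) - 1, 1)
  op <- sample(c("&", "|"), 1)
  paste0("(", random_expr_text(atoms[seq_len(k)]), op,
         random_expr_text(atoms[-seq_len(k)]), ")")
}

# All subsets of an atom vector (list of character vectors), 2^k entries.
all_subsets <- function(atoms) {
  k <- length(atoms)
  lapply(seq_len(2^k) - 1, function(mask) {
    atoms[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
  })
}

# Agreement check between evaluate_expression() and the oracle on every
# subset of the expression's atoms; returns number of discrepancies.
count_discrepancies <- function(text) {
  ast <- parse_expression(text)
  atoms <- oracle_atoms(text)
  sum(vapply(all_subsets(atoms), function(s) {
    evaluate_expression(ast, s) != oracle_eval(text, s)
  }, logical(1)))
}
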