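# Family assignment: evaluate every rule's must-have and prohibited
# patterns against each protein's accession set, and orchestrate the full
# FASTA -> prediction pipeline for mixed protein/nucleotide input.

#' Classify annotated proteins into TF/TR/CR families
#'
#' For each protein and each rule, a prediction is emitted iff the
#' must-have pattern evaluates true on the protein's accession set and the
#' prohibited pattern (when present) evaluates false. All qualifying
#' families are reported — ambiguity is resolved by the curated prohibited
#' patterns, not by a ranking heuristic, so any residual multi-assignment
#' is surfaced rather than hidden. An empty result for a protein means it
#' is not predicted as a TF/TR/CR.
#'
#' @param annotations Long tibble with columns `protein_id`, `accession`
#'   (e.g. from [read_domain_table()] or [annotation_sets()]).
#' @param rules A `rule_tbl` from [rule_table()] / [read_rule_table()].
#' @return A prediction tibble with columns `sequence_id`, `family`,
#'   `category`, `satisfied_atoms` (list of must-have atoms present on the
#'   protein), `all_accessions` (list), `frame` (`NA` for protein input)
#'   and `nt_start` (`NA`), ordered by protein first appearance then rule
#'   order.
#' @examples
#' ann <- tibble::tibble(protein_id = "p1",
#'                       accession = c("IPR002100", "IPR002487"))
#' classify_proteins(ann, builtin_rules())
#' @export
classify_proteins <- function(annotations, rules) {
  stopifnot(inherits(rules, "rule_tbl"))
  empty <- tibble::tibble(
    sequence_id = character(0), family = character(0), category = character(0),
    satisfied_atoms = list(), all_accessions = list(),
    frame = character(0), nt_start = integer(0)
  )
  if (nrow(annotations) == 0) {
    return(empty)
  }
  ids <- unique(annotations$protein_id)
  acc_by_id <- split(annotations$accession, factor(annotations$protein_id, levels = ids))
  rows <- purrr::map(ids, function(id) {
    accs <- unique(acc_by_id[[id]])
    hits <- purrr::map(seq_len(nrow(rules)), function(i) {
      if (!evaluate_expression(rules$must_have_expr[[i]], accs)) {
        return(NULL)
      }
      proh <- rules$prohibited_expr[[i]]
      if (!is.null(proh) && evaluate_expression(proh, accs)) {
        return(NULL)
      }
      atoms <- expr_atoms(rules$must_have_expr[[i]])
      tibble::tibble(
        sequence_id = id,
        family = rules$family[i],
        category = rules$category[i],
        satisfied_atoms = list(accs[toupper(accs) %in% toupper(atoms)]),
        all_accessions = list(accs),
        frame = NA_character_,
        nt_start = NA_integer_
      )
    })
    dplyr::bind_rows(hits)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Explain one rule's verdict for one accession set
#'
#' Audit trail for a single (protein, family) decision: which must-have
#' atoms were present or missing, which prohibited atoms fired, and the
#' resulting verdict.
#'
#' @param accessions Character vector: the protein's accession set.
#' @param rules A `rule_tbl`.
#' @param family Name of the rule to explain (case-insensitive).
#' @return A tibble with columns `clause` (`"must_have"` / `"prohibited"`),
#'   `atom`, `present`, and attributes `verdict` (one of `"included"`,
#'   `"excluded_must_have"`, `"excluded_prohibited"`) and `family`.
#' @examples
#' explain_rule(c("IPR002100", "IPR002487"), builtin_rules(), "MADS type1")
#' @export
explain_rule <- function(accessions, rules, family) {
  stopifnot(inherits(rules, "rule_tbl"))
  i <- match(tolower(family), tolower(rules$family))
  if (is.na(i)) {
    rlang::abort(sprintf("no rule for family '%s'", family),
                 class = "domfam_rule_error")
  }
  accs_up <- toupper(unique(accessions))
  must <- rules$must_have_expr[[i]]
  proh <- rules$prohibited_expr[[i]]
  must_atoms <- expr_atoms(must)
  proh_atoms <- if (is.null(proh)) character(0) else expr_atoms(proh)
  out <- tibble::tibble(
    clause = c(rep("must_have", length(must_atoms)),
               rep("prohibited", length(proh_atoms))),
    atom = c(must_atoms, proh_atoms),
    present = toupper(c(must_atoms, proh_atoms)) %in% accs_up
  )
  must_ok <- evaluate_expression(must, accessions)
  proh_fired <- !is.null(proh) && evaluate_expression(proh, accessions)
  verdict <- if (!must_ok) {
    "excluded_must_have"
  } else if (proh_fired) {
    "excluded_prohibited"
  } else {
    "included"
  }
  attr(out, "verdict") <- verdict
  attr(out, "family") <- rules$family[i]
  out
}

#' Classify a batch of protein and/or nucleotide sequences
#'
#' The full pipeline behind the command-line `classify` subcommand.
#' Protein records are looked up directly in the annotation table by
#' `seq_id`. Nucleic records are translated in six reading frames
#' ([six_frame_translate()]); the resulting segments are annotated either
#' by segment id (`parent|frame|nt_start`) found in `annotations`, or via
#' the `annotate` callback; segment predictions are then re-attributed to
#' the parent sequence id with the source frame and nucleotide offset
#' recorded. When several segments of one record match the same family,
#' the segment with the most satisfied must-have atoms is kept (ties:
#' smallest `nt_start`), so one gene never inflates family counts.
#'
#' @param records Tibble from [read_fasta()].
#' @param annotations Long tibble `protein_id`, `accession`, keyed by
#'   record id (protein input) and/or segment id (nucleotide input). May be
#'   `NULL` when `annotate` is given.
#' @param rules A `rule_tbl`.
#' @param min_orf_len Minimum translated-segment length in amino acids
#'   (default 50).
#' @param annotate Optional function; called with the segment tibble
#'   (columns `seq_id`, `peptide`) for nucleic input, and with protein
#'   records lacking annotation rows, it must return a long tibble
#'   `protein_id`, `accession` keyed by `seq_id`. Use this to plug in an
#'   external scanner ([run_external_scanner()]) or a fixture annotator
#'   ([peptide_annotator()]).
#' @return A prediction tibble as in [classify_proteins()], with `frame`
#'   and `nt_start` filled for nucleotide-derived predictions, ordered by
#'   input record order then rule order. Records with no annotation
#'   available are counted in the `n_unannotated` attribute and raise one
#'   summary warning.
#' @export
classify_batch <- function(records, annotations, rules, min_orf_len = 50,
                           annotate = NULL) {
  stopifnot(inherits(rules, "rule_tbl"))
  if (is.null(annotations)) {
    annotations <- tibble::tibble(protein_id = character(0), accession = character(0))
  }
  types <- resolve_sequence_type(records)
  prot_records <- records[types == "protein", , drop = FALSE]
  nuc_records <- records[types == "nucleic", , drop = FALSE]

  unannotated <- character(0)
  results <- list()

  # -- protein records: direct lookup -------------------------------------
  if (nrow(prot_records) > 0) {
    prot_ann <- dplyr::filter(annotations, .data$protein_id %in% prot_records$seq_id)
    missing_ids <- setdiff(prot_records$seq_id, prot_ann$protein_id)
    if (length(missing_ids) > 0 && !is.null(annotate)) {
      extra <- annotate(tibble::tibble(
        seq_id = missing_ids,
        peptide = prot_records$residues[match(missing_ids, prot_records$seq_id)]
      ))
      prot_ann <- dplyr::bind_rows(prot_ann, extra)
      missing_ids <- setdiff(prot_records$seq_id, prot_ann$protein_id)
    }
    unannotated <- c(unannotated, missing_ids)
    pred <- classify_proteins(prot_ann, rules)
    # restore input record order
    pred <- pred[order(match(pred$sequence_id, prot_records$seq_id)), , drop = FALSE]
    results$protein <- pred
  }

  # -- nucleic records: translate, annotate segments, re-attribute --------
  if (nrow(nuc_records) > 0) {
    segments <- six_frame_translate(nuc_records, min_len = min_orf_len)
    if (nrow(segments) > 0) {
      segments$seg_id <- segment_id(segments$parent_id, segments$frame,
                                    segments$nt_start)
      seg_ann <- dplyr::filter(annotations, .data$protein_id %in% segments$seg_id)
      missing_segs <- setdiff(segments$seg_id, seg_ann$protein_id)
      if (length(missing_segs) > 0 && !is.null(annotate)) {
        idx <- match(missing_segs, segments$seg_id)
        extra <- annotate(tibble::tibble(
          seq_id = missing_segs,
          peptide = segments$peptide[idx]
        ))
        seg_ann <- dplyr::bind_rows(seg_ann, extra)
      }
      seg_pred <- classify_proteins(seg_ann, rules)
      if (nrow(seg_pred) > 0) {
        idx <- match(seg_pred$sequence_id, segments$seg_id)
        seg_pred$frame <- segments$frame[idx]
        seg_pred$nt_start <- segments$nt_start[idx]
        seg_pred$sequence_id <- segments$parent_id[idx]
        seg_pred <- dplyr::mutate(seg_pred,
                                  .n_sat = lengths(.data$satisfied_atoms))
        seg_pred <- dplyr::arrange(
          seg_pred,
          match(.data$sequence_id, nuc_records$seq_id),
          match(.data$family, rules$family),
          dplyr::desc(.data$.n_sat),
          .data$nt_start
        )
        seg_pred <- dplyr::distinct(seg_pred, .data$sequence_id, .data$family,
                                    .keep_all = TRUE)
        seg_pred$.n_sat <- NULL
      }
      annotated_parents <- unique(segments$parent_id[segments$seg_id %in% seg_ann$protein_id])
      unannotated <- c(unannotated, setdiff(nuc_records$seq_id, annotated_parents))
      results$nucleic <- seg_pred
    } else {
      unannotated <- c(unannotated, nuc_records$seq_id)
    }
  }

  out <- dplyr::bind_rows(results)
  if (nrow(out) > 0) {
    out <- dplyr::arrange(out,
                          match(.data$sequence_id, records$seq_id),
                          match(.data$family, rules$family))
  } else {
    out <- classify_proteins(
      tibble::tibble(protein_id = character(0), accession = character(0)), rules
    )
  }
  if (length(unannotated) > 0) {
    rlang::warn(sprintf(
      "%d record(s) had no domain annotation and were classified as no-hit: %s",
      length(unannotated), paste(utils::head(unannotated, 5), collapse = ", ")
    ))
  }
  attr(out, "n_unannotated") <- length(unannotated)
  attr(out, "unannotated_ids") <- unannotated
  out
}

#' Summarize a prediction table by family and category
#'
#' @param predictions Prediction tibble from [classify_proteins()] /
#'   [classify_batch()].
#' @return A tibble with columns `scope` (`"family"` or `"category"`),
#'   `name`, `n_sequences`: distinct sequences assigned to each family,
#'   and to each of the TF/TR/CR/Other totals.
#' @export
summarize_predictions <- function(predictions) {
  fam <- dplyr::summarise(
    dplyr::group_by(predictions, name = .data$family),
    n_sequences = dplyr::n_distinct(.data$sequence_id), .groups = "drop"
  )
  cat_ <- dplyr::summarise(
    dplyr::group_by(predictions, name = .data$category),
    n_sequences = dplyr::n_distinct(.data$sequence_id), .groups = "drop"
  )
  dplyr::bind_rows(
    dplyr::mutate(fam, scope = "family"),
    dplyr::mutate(cat_, scope = "category")
  )[, c("scope", "name", "n_sequences")]
}

#' Write a prediction table to TSV
#'
#' Serializes list-columns as comma-joined accessions; absent fields are
#' rendered `-`. Columns: `sequence_id`, `family`, `category`,
#' `satisfied_atoms`, `all_accessions`, `frame`, `nt_start`.
#'
#' @param predictions Prediction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  collapse <- function(x) {
    vapply(x, function(v) {
      if (length(v) == 0) "-" else paste(v, collapse = ",")
    }, character(1))
  }
  out <- tibble::tibble(
    sequence_id = predictions$sequence_id,
    family = predictions$family,
    category = predictions$category,
    satisfied_atoms = collapse(predictions$satisfied_atoms),
    all_accessions = collapse(predictions$all_accessions),
    frame = dplyr::coalesce(predictions$frame, "-"),
    nt_start = dplyr::coalesce(as.character(predictions$nt_start), "-")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
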