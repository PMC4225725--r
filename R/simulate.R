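# Synthetic fixtures with planted ground truth.
#
# Generators emit the same TSV/FASTA dialects the pipeline consumes, over
# a reserved accession namespace (`ZZ#####` for rule atoms, `ZZN####` for
# noise) that cannot collide with real InterPro/Pfam/PROSITE/SMART
# identifiers; noise accessions never appear in any rule. All generators
# are pure functions of their arguments including the seed.

AA_ALPHABET <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")

# codons per amino acid, standard code, stops excluded
codons_for_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Random expression tree over a fixed atom set: every atom is used once.
random_expr_over <- function(atoms) {
  if (length(atoms) == 1) {
    return(new_expr_atom(atoms))
  }
  op <- sample(c("and", "or"), 1)
  k <- if (length(atoms) == 2) 2L else sample(2:3, 1)
  shuffled <- sample(atoms)
  groups <- split(shuffled, sort(rep_len(seq_len(k), length(shuffled))))
  new_expr_node(op, lapply(unname(groups), random_expr_over))
}

# One accession set satisfying `expr`: atoms collect, AND unions children,
# OR picks one child at random.
satisfying_set <- function(expr) {
  switch(expr$kind,
    atom = expr$acc,
    and = unique(unlist(lapply(expr$children, satisfying_set))),
    or = satisfying_set(expr$children[[sample(length(expr$children), 1)]])
  )
}

#' Generate a random family rule table
#'
#' Builds `n_families` rules over the reserved synthetic accession
#' alphabet (`ZZ#####`): per-family atom pools are disjoint, so a positive
#' constructed for one family can never satisfy another family's must-have
#' pattern (unless a subset pair is planted deliberately). A fraction of
#' families receive prohibited patterns built from a sibling family's
#' must-have atoms; `n_subset_pairs` plants must-have subset relations
#' (family 2k's pattern is family 2k-1's AND one extra atom, with no
#' distinguishing prohibition) that [validate_rule_table()] must flag.
#'
#' @param n_families Number of families (>= 1).
#' @param max_atoms Maximum atoms per must-have expression (>= 1).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param prohibited_fraction Fraction of eligible families given a
#'   prohibited pattern (default 0.3).
#' @param n_subset_pairs Number of planted subset-overlap pairs (default
#'   0; requires `n_families >= 2 * n_subset_pairs`).
#' @return A `rule_tbl` with attributes `atom_inventory` (all must-have
#'   atoms) and `planted_overlaps` (tibble `family`, `other_family` of
#'   planted subset pairs).
#' @examples
#' simulate_rule_table(5, max_atoms = 4, seed = 1)
#' @export
simulate_rule_table <- function(n_families, max_atoms = 6, seed = 1,
                                prohibited_fraction = 0.3, n_subset_pairs = 0) {
  stopifnot(n_families >= 1, max_atoms >= 1,
            n_families >= 2 * n_subset_pairs)
  withr::with_seed(seed, {
    atom_counter <- 0L
    fresh_atoms <- function(n) {
      out <- sprintf("ZZ%05d", atom_counter + seq_len(n))
      atom_counter <<- atom_counter + n
      out
    }
    family <- sprintf("FAM%03d", seq_len(n_families))
    category <- sample(c("TF", "TR", "CR"), n_families, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15))
    exprs <- vector("list", n_families)
    pair_a <- integer(0)
    pair_b <- integer(0)
    if (n_subset_pairs > 0) {
      pair_a <- 2 * seq_len(n_subset_pairs) - 1
      pair_b <- 2 * seq_len(n_subset_pairs)
    }
    for (i in seq_len(n_families)) {
      if (i %in% pair_b) {
        base <- exprs[[pair_a[match(i, pair_b)]]]
        exprs[[i]] <- new_expr_node("and", list(base, new_expr_atom(fresh_atoms(1))))
      } else {
        n_atoms <- sample(seq_len(max_atoms), 1)
        exprs[[i]] <- random_expr_over(fresh_atoms(n_atoms))
      }
    }
    must_atoms <- lapply(exprs, expr_atoms)
    prohibited <- rep(NA_character_, n_families)
    # subset-pair "A" families stay prohibition-free so the planted overlap
    # is detectable; others may veto atoms of a random sibling
    eligible <- setdiff(seq_len(n_families), pair_a)
    if (n_families > 1 && prohibited_fraction > 0 && length(eligible) > 0) {
      chosen <- eligible[stats::runif(length(eligible)) < prohibited_fraction]
      for (i in chosen) {
        cands <- setdiff(seq_len(n_families), i)
        sib <- if (length(cands) == 1) cands else sample(cands, 1)
        pool <- must_atoms[[sib]]
        picked <- sample(pool, min(length(pool), sample(1:2, 1)))
        prohibited[i] <- paste(picked, collapse = "|")
      }
    }
    out <- rule_table(
      family = family,
      category = category,
      must_have = vapply(exprs, expr_serialize, character(1)),
      prohibited = prohibited,
      provenance = sprintf("simulated(seed=%d)", seed)
    )
    attr(out, "atom_inventory") <- unique(unlist(must_atoms))
    overlap_a <- family[pair_a]
    overlap_b <- family[pair_b]
    attr(out, "planted_overlaps") <- tibble::tibble(
      family = overlap_a,
      other_family = overlap_b
    )
    out
  })
}

#' Generate domain annotations with planted ground truth
#'
#' For each family, `n_pos_per_family` positive sequences receive an
#' accession set satisfying exactly that family's must-have pattern (one
#' branch of each OR), avoiding its prohibited pattern. Decoys come in two
#' flavours: *miss* decoys drop one must-have atom from a satisfying set
#' (so the must-have fails), and *prohibited* decoys carry a full
#' satisfying set plus atoms firing the family's prohibited pattern (so
#' the veto fires). Every sequence may additionally carry irrelevant noise
#' accessions drawn from the reserved `ZZN####` namespace, which no rule
#' references.
#'
#' @param rules A `rule_tbl` (typically from [simulate_rule_table()]).
#' @param n_pos_per_family Positives per family (default 5).
#' @param n_decoys Total number of decoy sequences (default 0).
#' @param noise_accessions Noise accessions added per sequence (default 0).
#' @param seed Integer seed.
#' @return A list with `annotations` (long tibble `protein_id`,
#'   `accession`) and `truth` (tibble `seq_id`, `role` one of
#'   `"positive"`, `"decoy_miss"`, `"decoy_prohibited"`, `family` — the
#'   intended family for positives, the decoyed family for decoys).
#' @export
simulate_annotations <- function(rules, n_pos_per_family = 5, n_decoys = 0,
                                 noise_accessions = 0, seed = 1) {
  stopifnot(inherits(rules, "rule_tbl"), nrow(rules) >= 1)
  withr::with_seed(seed + 1L, {
    noise_pool <- sprintf("ZZN%04d", 1:1000)
    counter <- 0L
    ann_rows <- list()
    truth_rows <- list()
    add_seq <- function(accs, role, family) {
      counter <<- counter + 1L
      id <- sprintf("seq%05d", counter)
      if (noise_accessions > 0) {
        accs <- c(accs, sample(noise_pool, noise_accessions))
      }
      ann_rows[[length(ann_rows) + 1L]] <<- tibble::tibble(
        protein_id = id, accession = unique(accs)
      )
      truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
        seq_id = id, role = role, family = family
      )
      id
    }

    for (i in seq_len(nrow(rules))) {
      for (k in seq_len(n_pos_per_family)) {
        accs <- satisfying_set(rules$must_have_expr[[i]])
        add_seq(accs, "positive", rules$family[i])
      }
    }

    if (n_decoys > 0) {
      has_proh <- !vapply(rules$prohibited_expr, is.null, logical(1))
      for (d in seq_len(n_decoys)) {
        i <- sample(nrow(rules), 1)
        kind <- if (has_proh[i] && stats::runif(1) < 0.5) "prohibited" else "miss"
        sat <- satisfying_set(rules$must_have_expr[[i]])
        if (kind == "prohibited") {
          extra <- satisfying_set(rules$prohibited_expr[[i]])
          add_seq(unique(c(sat, extra)), "decoy_prohibited", rules$family[i])
        } else {
          accs <- NULL
          for (drop_atom in sample(sat)) {
            cand <- setdiff(sat, drop_atom)
            if (!evaluate_expression(rules$must_have_expr[[i]], cand)) {
              accs <- cand
              break
            }
          }
          if (is.null(accs)) accs <- character(0)
          add_seq(accs, "decoy_miss", rules$family[i])
        }
      }
    }

    list(
      annotations = dplyr::bind_rows(ann_rows),
      truth = dplyr::bind_rows(truth_rows)
    )
  })
}

#' Generate random stop-free peptides for a set of sequence ids
#'
#' @param seq_ids Character vector of ids.
#' @param min_len,max_len Peptide length range in amino acids.
#' @param seed Integer seed.
#' @return Tibble `seq_id`, `peptide`.
#' @export
simulate_peptides <- function(seq_ids, min_len = 60, max_len = 90, seed = 1) {
  withr::with_seed(seed + 2L, {
    tibble::tibble(
      seq_id = seq_ids,
      peptide = vapply(seq_along(seq_ids), function(i) {
        len <- sample(min_len:max_len, 1)
        paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

#' Reverse-translate a peptide into a nucleotide sequence at a chosen frame
#'
#' Encodes `peptide` with uniformly chosen synonymous codons (standard
#' genetic code, no codon-usage bias), embeds the coding stretch so its
#' first codon base falls in reading frame `frame`, and places in-frame
#' stop codons immediately before and after it so the planted segment is
#' stop-delimited. Random flanking nucleotides of length `flank` are added
#' on both sides. The construct is verified: [six_frame_translate()] must
#' recover the peptide in exactly the requested frame (resampled a few
#' times if random flanks spuriously echo it).
#'
#' @param peptide Stop-free amino-acid string (the 20 standard residues).
#' @param frame One of `"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`.
#' @param flank Number of random flanking nucleotides per side (default 0).
#' @param seed Integer seed.
#' @return A nucleotide string.
#' @examples
#' encode_protein_to_dna("MK", "+1", flank = 0, seed = 1)
#' @export
encode_protein_to_dna <- function(peptide, frame = "+1", flank = 0, seed = 1) {
  stopifnot(is.character(peptide), length(peptide) == 1, nchar(peptide) >= 1)
  frame <- match.arg(frame, c("+1", "+2", "+3", "-1", "-2", "-3"))
  aa <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  if (any(aa == "*")) {
    rlang::abort("peptide must be stop-free (contains '*')",
                 class = "domfam_sequence_error")
  }
  codon_map <- codons_for_aa()
  if (!all(aa %in% names(codon_map))) {
    rlang::abort(
      sprintf("peptide contains non-encodable residue(s): %s",
              paste(unique(aa[!aa %in% names(codon_map)]), collapse = ", ")),
      class = "domfam_sequence_error"
    )
  }
  f <- abs(as.integer(frame))
  minus <- startsWith(frame, "-")
  stops <- c("TAA", "TAG", "TGA")
  nt <- c("A", "C", "G", "T")

  withr::with_seed(seed + 3L, {
    for (attempt in 1:25) {
      core <- paste(vapply(aa, function(a) {
        cds <- codon_map[[a]]
        cds[sample(length(cds), 1)]
      }, character(1)), collapse = "")
      pre_flank <- paste(sample(nt, flank, replace = TRUE), collapse = "")
      post_flank <- paste(sample(nt, flank, replace = TRUE), collapse = "")
      # pad so the first core base lands in reading frame f:
      # position = flank + pad + 3 (stop) + 1  must be congruent to f mod 3
      pad_len <- (f - flank - 4) %% 3
      pad <- paste(sample(nt, pad_len, replace = TRUE), collapse = "")
      fwd <- paste0(pre_flank, pad, sample(stops, 1), core, sample(stops, 1),
                    post_flank)
      out <- if (minus) reverse_complement(fwd) else fwd
      segs <- six_frame_translate(
        tibble::tibble(seq_id = "enc", residues = out, declared_type = "nucleic"),
        min_len = length(aa)
      )
      hit_frames <- unique(segs$frame[
        stringr::str_detect(segs$peptide, stringr::fixed(toupper(peptide)))
      ])
      if (identical(hit_frames, frame)) {
        return(out)
      }
    }
    rlang::abort(
      sprintf("could not embed peptide uniquely in frame %s after 25 attempts",
              frame),
      class = "domfam_sequence_error"
    )
  })
}

#' Build a fixture annotator that maps translated segments to annotations
#'
#' Returns an `annotate` callback for [classify_batch()]: segments whose
#' peptide equals a known protein's peptide inherit that protein's
#' accession set. This stands in for an external domain scanner in tests
#' and simulations.
#'
#' @param annotations Long tibble `protein_id`, `accession` keyed by
#'   original protein ids.
#' @param peptides Tibble `seq_id`, `peptide` mapping those ids to their
#'   amino-acid sequences.
#' @return A function of a segment tibble (`seq_id`, `peptide`) returning
#'   a long tibble `protein_id`, `accession` keyed by segment id.
#' @export
peptide_annotator <- function(annotations, peptides) {
  force(annotations)
  force(peptides)
  function(segments) {
    idx <- match(segments$peptide, peptides$peptide)
    hit <- !is.na(idx)
    if (!any(hit)) {
      return(tibble::tibble(protein_id = character(0), accession = character(0)))
    }
    rows <- purrr::map2(segments$seq_id[hit], peptides$seq_id[idx[hit]],
                        function(seg, orig) {
      accs <- annotations$accession[annotations$protein_id == orig]
      tibble::tibble(protein_id = seg, accession = accs)
    })
    dplyr::bind_rows(rows)
  }
}

#' Score predictions against planted truth
#'
#' Precision and recall of predicted (sequence, family) pairs against the
#' planted positives; decoys and negatives must contribute no planted
#' pairs, so any prediction for them counts against precision.
#'
#' @param predictions Prediction tibble ([classify_batch()]).
#' @param truth Truth tibble from [simulate_annotations()].
#' @return One-row tibble `precision`, `recall`, `n_predicted`,
#'   `n_planted`, `n_correct`.
#' @export
score_predictions <- function(predictions, truth) {
  planted <- dplyr::filter(truth, .data$role == "positive")
  planted_keys <- paste(planted$seq_id, tolower(planted$family), sep = "\r")
  pred <- dplyr::distinct(predictions, .data$sequence_id, .data$family)
  pred_keys <- paste(pred$sequence_id, tolower(pred$family), sep = "\r")
  n_correct <- length(intersect(pred_keys, planted_keys))
  tibble::tibble(
    precision = if (length(pred_keys) == 0) NA_real_ else n_correct / length(pred_keys),
    recall = if (length(planted_keys) == 0) NA_real_ else n_correct / length(planted_keys),
    n_predicted = length(pred_keys),
    n_planted = length(planted_keys),
    n_correct = n_correct
  )
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits everything needed to exercise the whole pipeline from the command
#' line: a rule table, a protein FASTA, a nucleotide FASTA (each protein
#' re-encoded at a random frame), a two-column domain table keyed by both
#' protein ids and translated-segment peptide identity, a planted-truth
#' table and a reference assignment table for benchmarking.
#'
#' @param dir Output directory (created if needed).
#' @param n_families,max_atoms,n_pos_per_family,n_decoys,noise_accessions
#'   Passed to [simulate_rule_table()] / [simulate_annotations()].
#' @param min_orf_len Minimum peptide length for the simulated proteins,
#'   so nucleotide-mode translation retains them (default 60).
#' @param seed Integer seed.
#' @return Invisibly, a list with `paths` (named file paths: `rules`,
#'   `proteins`, `nucleotides`, `domain_table`, `truth`, `reference`) and
#'   the in-memory `rules`, `annotations`, `truth` and `peptides` objects.
#' @export
simulate_fixture_bundle <- function(dir, n_families = 5, max_atoms = 4,
                                    n_pos_per_family = 3, n_decoys = 0,
                                    noise_accessions = 0, min_orf_len = 60,
                                    seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rules <- simulate_rule_table(n_families, max_atoms = max_atoms, seed = seed)
  sim <- simulate_annotations(rules, n_pos_per_family = n_pos_per_family,
                              n_decoys = n_decoys,
                              noise_accessions = noise_accessions, seed = seed)
  peptides <- simulate_peptides(sim$truth$seq_id, min_len = min_orf_len,
                                max_len = min_orf_len + 30, seed = seed)
  frames <- withr::with_seed(seed + 4L, {
    sample(c("+1", "+2", "+3", "-1", "-2", "-3"), nrow(peptides), replace = TRUE)
  })
  nts <- vapply(seq_len(nrow(peptides)), function(i) {
    encode_protein_to_dna(peptides$peptide[i], frames[i], flank = 12,
                          seed = seed + i)
  }, character(1))

  paths <- list(
    rules = file.path(dir, "rules.tsv"),
    proteins = file.path(dir, "proteins.fasta"),
    nucleotides = file.path(dir, "nucleotides.fasta"),
    domain_table = file.path(dir, "domain_table.tsv"),
    truth = file.path(dir, "truth.tsv"),
    reference = file.path(dir, "reference.tsv")
  )
  write_rule_table(rules, paths$rules)
  write_fasta(tibble::tibble(seq_id = peptides$seq_id,
                             residues = peptides$peptide), paths$proteins)
  write_fasta(tibble::tibble(seq_id = peptides$seq_id, residues = nts),
              paths$nucleotides)
  write_domain_table(sim$annotations, paths$domain_table)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  ref <- dplyr::filter(sim$truth, .data$role == "positive")
  readr::write_tsv(ref[, c("seq_id", "family")], paths$reference,
                   col_names = FALSE, progress = FALSE)
  invisible(list(paths = paths, rules = rules, annotations = sim$annotations,
                 truth = sim$truth, peptides = peptides))
}
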