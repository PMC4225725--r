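# Family assignment and the batch pipeline.

test_that("prohibited patterns split the MADS superfamily exclusively", {
  rules <- mads_rules()
  only_mads <- classify_proteins(
    tibble::tibble(protein_id = "p1", accession = "IPR002100"), rules
  )
  expect_equal(only_mads$family, "MADS type1")

  with_kbox <- classify_proteins(
    tibble::tibble(protein_id = "p2", accession = c("IPR002100", "IPR002487")),
    rules
  )
  expect_equal(with_kbox$family, "MADS-MICK")

  none <- classify_proteins(
    tibble::tibble(protein_id = character(0), accession = character(0)), rules
  )
  expect_equal(nrow(none), 0)

  # exclusivity over every subset of the involved accessions
  for (s in all_subsets(c("IPR002100", "IPR002487", "QQ00001"))) {
    pred <- classify_proteins(
      tibble::tibble(protein_id = rep("x", length(s)), accession = s), rules
    )
    expect_lte(sum(pred$family %in% c("MADS type1", "MADS-MICK")), 1)
  }
})

test_that("a dual B3+AP2 protein is assigned to RAV only", {
  rules <- b3_ap2_rules()
  dual <- classify_proteins(
    tibble::tibble(protein_id = "At3g25730",
                   accession = c("IPR003340", "IPR001471")),
    rules
  )
  expect_equal(dual$family, "RAV")

  # single-domain proteins keep their own family
  b3_only <- classify_proteins(
    tibble::tibble(protein_id = "b", accession = "IPR003340"), rules)
  expect_equal(b3_only$family, "B3")
  ap2_only <- classify_proteins(
    tibble::tibble(protein_id = "a", accession = "IPR001471"), rules)
  expect_equal(ap2_only$family, "AP2-EREBP")

  # B3 / AP2-EREBP / RAV are mutually exclusive over all relevant subsets
  for (s in all_subsets(c("IPR003340", "IPR001471", "IPR011525"))) {
    pred <- classify_proteins(
      tibble::tibble(protein_id = rep("x", length(s)), accession = s), rules
    )
    expect_lte(sum(pred$family %in% c("B3", "AP2-EREBP", "RAV")), 1)
  }
})

test_that("explain reports matched and fired atoms with a verdict", {
  ex1 <- explain_rule(c("IPR002100", "IPR002487"), mads_rules(), "MADS type1")
  expect_equal(attr(ex1, "verdict"), "excluded_prohibited")
  expect_true(ex1$present[ex1$clause == "prohibited" & ex1$atom == "IPR002487"])

  arf <- builtin_rules()
  ex2 <- explain_rule("IPR003340", arf, "ARF")
  expect_equal(attr(ex2, "verdict"), "excluded_must_have")
  missing_or <- ex2[ex2$clause == "must_have" & !ex2$present, ]
  expect_setequal(missing_or$atom, c("IPR010525", "IPR011525"))

  ex3 <- explain_rule(c("IPR010525", "IPR003340"), arf, "ARF")
  expect_equal(attr(ex3, "verdict"), "included")
  expect_error(explain_rule("IPR003340", arf, "NoSuchFamily"),
               class = "domfam_rule_error")
})

test_that("every emitted prediction re-verifies under the independent oracle", {
  rules <- simulate_rule_table(12, max_atoms = 5, seed = 101,
                               prohibited_fraction = 0.5)
  sim <- simulate_annotations(rules, n_pos_per_family = 3, n_decoys = 10,
                              noise_accessions = 2, seed = 101)
  pred <- classify_proteins(sim$annotations, rules)
  expect_gt(nrow(pred), 0)
  for (i in seq_len(nrow(pred))) {
    accs <- sim$annotations$accession[
      sim$annotations$protein_id == pred$sequence_id[i]]
    ridx <- match(pred$family[i], rules$family)
    expect_true(oracle_eval(rules$must_have[ridx], accs))
    if (!is.na(rules$prohibited[ridx])) {
      expect_false(oracle_eval(rules$prohibited[ridx], accs))
    }
    expect_true(all(pred$satisfied_atoms[[i]] %in% accs))
  }
})

test_that("nucleotide-mode classification equals protein mode with frames recorded", {
  rules <- mads_rules()
  ann <- tibble::tibble(
    protein_id = c("p1", "p2", "p2"),
    accession = c("IPR002100", "IPR002100", "IPR002487")
  )
  peps <- simulate_peptides(c("p1", "p2"), min_len = 55, max_len = 60, seed = 9)
  prot_records <- tibble::tibble(seq_id = peps$seq_id, residues = peps$peptide,
                                 declared_type = "auto")
  prot_pred <- classify_batch(prot_records, ann, rules, min_orf_len = 50)

  for (fr in c("+1", "+2", "+3", "-1", "-2", "-3")) {
    nts <- vapply(seq_len(nrow(peps)), function(i) {
      encode_protein_to_dna(peps$peptide[i], fr, flank = 10, seed = 100 + i)
    }, character(1))
    nuc_records <- tibble::tibble(seq_id = peps$seq_id, residues = nts,
                                  declared_type = "auto")
    nuc_pred <- classify_batch(nuc_records, NULL, rules, min_orf_len = 50,
                               annotate = peptide_annotator(ann, peps))
    expect_equal(nuc_pred[, c("sequence_id", "family", "category")],
                 prot_pred[, c("sequence_id", "family", "category")],
                 info = fr)
    expect_true(all(nuc_pred$frame == fr))
    expect_true(all(!is.na(nuc_pred$nt_start)))
  }
})

test_that("unannotated records warn and are counted as no-hit", {
  rules <- mads_rules()
  records <- tibble::tibble(seq_id = c("known", "mystery"),
                            residues = c("MKVLWEQF", "MKHQRST"),
                            declared_type = "protein")
  ann <- tibble::tibble(protein_id = "known", accession = "IPR002100")
  expect_warning(pred <- classify_batch(records, ann, rules), "no-hit")
  expect_equal(attr(pred, "n_unannotated"), 1L)
  expect_equal(attr(pred, "unannotated_ids"), "mystery")
  expect_equal(pred$sequence_id, "known")
})

test_that("classification output is deterministic", {
  rules <- simulate_rule_table(8, seed = 55)
  sim <- simulate_annotations(rules, n_pos_per_family = 4, n_decoys = 6,
                              noise_accessions = 1, seed = 55)
  p1 <- classify_proteins(sim$annotations, rules)
  p2 <- classify_proteins(sim$annotations, rules)
  expect_identical(p1, p2)
})
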