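# Synthetic fixtures: rule/annotation generators and the DNA encoder.

test_that("generators are deterministic under their seed", {
  r1 <- simulate_rule_table(20, max_atoms = 6, seed = 1)
  r2 <- simulate_rule_table(20, max_atoms = 6, seed = 1)
  expect_identical(r1$must_have, r2$must_have)
  expect_identical(r1$prohibited, r2$prohibited)
  r3 <- simulate_rule_table(20, max_atoms = 6, seed = 2)
  expect_false(identical(r1$must_have, r3$must_have))

  a1 <- simulate_annotations(r1, n_pos_per_family = 3, n_decoys = 5,
                             noise_accessions = 2, seed = 4)
  a2 <- simulate_annotations(r1, n_pos_per_family = 3, n_decoys = 5,
                             noise_accessions = 2, seed = 4)
  expect_identical(a1, a2)
})

test_that("degenerate generator inputs behave", {
  single <- simulate_rule_table(1, max_atoms = 1, seed = 7)
  expect_equal(nrow(single), 1)
  expect_equal(single$must_have_expr[[1]]$kind, "atom")
  expect_true(is.na(single$prohibited[1]))
})

test_that("planted subset overlaps are exactly what the validator reports", {
  rules <- simulate_rule_table(8, max_atoms = 4, seed = 3, n_subset_pairs = 2)
  planted <- attr(rules, "planted_overlaps")
  expect_equal(nrow(planted), 2)
  diags <- validate_rule_table(rules)
  subset_diags <- diags[diags$type == "subset_overlap", ]
  expect_equal(
    sort(paste(subset_diags$family, subset_diags$other_family)),
    sort(paste(planted$family, planted$other_family))
  )
})

test_that("positives are recovered perfectly; noise never hurts precision", {
  rules <- simulate_rule_table(10, max_atoms = 5, seed = 17)
  clean <- simulate_annotations(rules, n_pos_per_family = 3, n_decoys = 0,
                                noise_accessions = 0, seed = 17)
  sc <- score_predictions(classify_proteins(clean$annotations, rules),
                          clean$truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)

  noisy <- simulate_annotations(rules, n_pos_per_family = 3, n_decoys = 0,
                                noise_accessions = 4, seed = 18)
  scn <- score_predictions(classify_proteins(noisy$annotations, rules),
                           noisy$truth)
  expect_equal(scn$precision, 1)
  expect_equal(scn$recall, 1)
})

test_that("decoys are excluded from their decoyed family", {
  rules <- simulate_rule_table(10, max_atoms = 5, seed = 23,
                               prohibited_fraction = 0.6)
  sim <- simulate_annotations(rules, n_pos_per_family = 2, n_decoys = 30,
                              noise_accessions = 1, seed = 23)
  decoys <- sim$truth[sim$truth$role != "positive", ]
  expect_gt(nrow(decoys), 0)
  expect_true(any(sim$truth$role == "decoy_prohibited"))
  pred <- classify_proteins(sim$annotations, rules)
  for (i in seq_len(nrow(decoys))) {
    hit <- pred$family[pred$sequence_id == decoys$seq_id[i]]
    expect_false(decoys$family[i] %in% hit,
                 info = paste(decoys$seq_id[i], decoys$role[i]))
  }
})

test_that("a missing-atom decoy can fall back to the plain superfamily rule", {
  # a MICK-style decoy stripped of the K-box is, by construction, a valid
  # MADS type1 protein
  rules <- mads_rules()
  accs <- "IPR002100"  # satisfying set of MADS-MICK minus IPR002487
  pred <- classify_proteins(tibble::tibble(protein_id = "decoy", accession = accs),
                            rules)
  expect_equal(pred$family, "MADS type1")
})

test_that("the DNA encoder validates input and plants codons at frame +1", {
  nt <- encode_protein_to_dna("MK", "+1", flank = 0, seed = 1)
  # frame +1 construct: pad, stop codon, then the coding codons
  segs <- six_frame_translate(
    tibble::tibble(seq_id = "e", residues = nt, declared_type = "nucleic"),
    min_len = 2
  )
  expect_true("MK" %in% segs$peptide[segs$frame == "+1"])
  expect_error(encode_protein_to_dna("MK*", "+1"),
               class = "domfam_sequence_error")
  expect_error(encode_protein_to_dna("MKB1", "+1"),
               class = "domfam_sequence_error")
})

test_that("fixture bundles round-trip through files and both input modes", {
  dir <- withr::local_tempdir()
  bundle <- simulate_fixture_bundle(dir, n_families = 4, max_atoms = 3,
                                    n_pos_per_family = 2, noise_accessions = 1,
                                    seed = 12)
  expect_true(all(file.exists(unlist(bundle$paths))))
  rules <- read_rule_table(bundle$paths$rules)
  ann <- read_domain_table(bundle$paths$domain_table)
  prot <- classify_batch(read_fasta(bundle$paths$proteins), ann, rules)
  sc <- score_predictions(prot, bundle$truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)

  nuc <- classify_batch(read_fasta(bundle$paths$nucleotides), NULL, rules,
                        min_orf_len = 50,
                        annotate = peptide_annotator(ann, bundle$peptides))
  expect_equal(
    dplyr::arrange(nuc[, c("sequence_id", "family")], sequence_id, family),
    dplyr::arrange(prot[, c("sequence_id", "family")], sequence_id, family)
  )
  expect_true(all(!is.na(nuc$frame)))
})
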