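# FASTA reading, type detection, reverse complement, six-frame translation.

test_that("FASTA records are read, normalized, and checked", {
  path <- write_lines_tmp(c(
    ">g1 some description",
    "atgaaa",
    ">g2",
    "MKVL", "WEQF",  # wrapped lines
    ">g3",
    "MPQR*"
  ), ext = ".fasta")
  recs <- read_fasta(path)
  expect_equal(recs$seq_id, c("g1", "g2", "g3"))
  expect_equal(recs$residues, c("ATGAAA", "MKVLWEQF", "MPQR"))
  expect_equal(recs$declared_type, rep("auto", 3))

  dup <- write_lines_tmp(c(">g1", "ATG", ">g1", "CCC"), ext = ".fasta")
  expect_error(read_fasta(dup), class = "domfam_io_error", regexp = "duplicate")

  empty_rec <- write_lines_tmp(c(">g1", "ATG", ">g2", ""), ext = ".fasta")
  expect_error(read_fasta(empty_rec), class = "domfam_io_error")

  empty <- write_lines_tmp(character(0), ext = ".fasta")
  expect_error(read_fasta(empty), class = "domfam_io_error")
})

test_that("sequence type detection uses the 95% nucleotide-character rule", {
  expect_equal(detect_sequence_type("ATGGCGTTAACC"), "nucleic")
  expect_equal(detect_sequence_type("MKVLWEQF"), "protein")
  # all 20 amino-acid letters: only A/C/G/T/N qualify, far below 95%
  expect_equal(detect_sequence_type("ACDEFGHIKLMNPQRSTVWY"), "protein")
  expect_equal(detect_sequence_type("AUGGCGUUA"), "nucleic")  # RNA
  expect_equal(detect_sequence_type("ATGGCGNNNN"), "nucleic")
  # declared type overrides detection
  recs <- tibble::tibble(seq_id = "x", residues = "ATGATG",
                         declared_type = "protein")
  expect_equal(resolve_sequence_type(recs), "protein")
})

test_that("reverse complement is the reversed Watson-Crick complement", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("AAA"), "TTT")
  expect_equal(reverse_complement("ATGN"), "NCAT")
  expect_equal(reverse_complement("AUG"), "CAT")  # U treated as T
  expect_error(reverse_complement("ATGB"), class = "domfam_sequence_error")
  # involution
  withr::local_seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  expect_equal(reverse_complement(reverse_complement(s)), s)
})

test_that("six-frame translation finds stop-delimited segments in all frames", {
  recs <- tibble::tibble(seq_id = "g1", residues = "ATGAAATAA",
                         declared_type = "nucleic")
  segs <- six_frame_translate(recs, min_len = 2)
  plus1 <- segs[segs$frame == "+1", ]
  expect_equal(plus1$peptide, "MK")  # ATG AAA TAA -> M K stop
  expect_equal(plus1$nt_start, 1L)

  # reverse-complement embedding: "MKH" encoded as ATGAAACAT; the record
  # holding its reverse complement must yield MKH in a negative frame
  rc_rec <- tibble::tibble(seq_id = "g2",
                           residues = reverse_complement("ATGAAACAT"),
                           declared_type = "nucleic")
  segs2 <- six_frame_translate(rc_rec, min_len = 3)
  hit <- segs2[segs2$peptide == "MKH", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$frame, "-1")

  expect_warning(
    out <- six_frame_translate(
      tibble::tibble(seq_id = "tiny", residues = "AT", declared_type = "nucleic"),
      min_len = 1
    ),
    "shorter than one codon"
  )
  expect_equal(nrow(out), 0)

  # N-containing codons translate to X, which is not a stop
  nseg <- six_frame_translate(
    tibble::tibble(seq_id = "gn", residues = "ATGANAAAATAA",
                   declared_type = "nucleic"),
    min_len = 3
  )
  expect_equal(nseg$peptide[nseg$frame == "+1"], "MXK")
})

test_that("translation is strand-symmetric with sign-flipped frames", {
  withr::local_seed(21)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(60:120, 1), replace = TRUE),
               collapse = "")
    fwd <- six_frame_translate(
      tibble::tibble(seq_id = "s", residues = s, declared_type = "nucleic"),
      min_len = 1
    )
    rev <- six_frame_translate(
      tibble::tibble(seq_id = "s", residues = reverse_complement(s),
                     declared_type = "nucleic"),
      min_len = 1
    )
    flip <- function(f) chartr("+-", "-+", f)
    expect_equal(sort(paste(flip(fwd$frame), fwd$peptide)),
                 sort(paste(rev$frame, rev$peptide)))
  }
})

test_that("planted peptides are recovered in exactly their frame", {
  withr::local_seed(31)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  aa_pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "")
  for (rep in 1:25) {
    pep <- paste(sample(aa_pool, sample(8:20, 1), replace = TRUE), collapse = "")
    fr <- sample(frames, 1)
    nt <- encode_protein_to_dna(pep, fr, flank = sample(0:15, 1), seed = rep)
    segs <- six_frame_translate(
      tibble::tibble(seq_id = "p", residues = nt, declared_type = "nucleic"),
      min_len = nchar(pep)
    )
    hit_frames <- unique(segs$frame[grepl(pep, segs$peptide, fixed = TRUE)])
    expect_equal(hit_frames, fr, info = paste(pep, fr))
  }
})
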