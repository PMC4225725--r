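# FASTA input, sequence-type detection, and six-frame translation.

NUCLEOTIDE_CHARS <- c("A", "C", "G", "T", "U", "N")
GAP_CHARS <- c("-", ".")

#' Read sequences from a FASTA file
#'
#' Reads multi-record FASTA (wrapped or single-line; gzip-compressed input
#' is accepted by suffix). The sequence id is the first whitespace-delimited
#' token of each header; residues are uppercased and terminal `*` stop
#' symbols are stripped.
#'
#' @param path Path to a FASTA file.
#' @param declared_type `"auto"` (default) to detect nucleic vs protein per
#'   record, or `"nucleic"` / `"protein"` to override detection.
#' @return A tibble with columns `seq_id`, `residues`, `declared_type`.
#' @export
read_fasta <- function(path, declared_type = c("auto", "nucleic", "protein")) {
  declared_type <- match.arg(declared_type)
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTA file not found: %s", path), class = "domfam_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      rlang::abort(sprintf("cannot read FASTA %s: %s", path, conditionMessage(e)),
                   class = "domfam_io_error", parent = e)
    }
  )
  if (length(set) == 0) {
    rlang::abort(sprintf("FASTA file %s contains no sequences", path),
                 class = "domfam_io_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    rlang::abort(sprintf("FASTA file %s has a record with an empty id", path),
                 class = "domfam_io_error")
  }
  if (anyDuplicated(ids)) {
    rlang::abort(
      sprintf("duplicate sequence id(s) in %s: %s", path,
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      class = "domfam_io_error"
    )
  }
  residues <- toupper(as.character(set))
  residues <- sub("\\*+$", "", sub("^\\*+", "", residues))
  if (any(!nzchar(residues))) {
    rlang::abort(
      sprintf("empty sequence(s) in %s: %s", path,
              paste(ids[!nzchar(residues)], collapse = ", ")),
      class = "domfam_io_error"
    )
  }
  tibble::tibble(seq_id = unname(ids), residues = unname(residues),
                 declared_type = declared_type)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `seq_id` and `residues` (or a named
#'   character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(seq_id = names(seqs), residues = unname(seqs))
  }
  lines <- as.vector(rbind(paste0(">", seqs$seq_id), seqs$residues))
  writeLines(lines, path)
  invisible(path)
}

#' Detect whether residues are nucleic acid or protein
#'
#' A sequence is called nucleic when at least 95% of its non-gap characters
#' are in `{A, C, G, T, U, N}`; otherwise protein. The threshold tolerates
#' occasional IUPAC ambiguity codes in genuine nucleotide input while
#' protein sequences, which use most of the 20 amino-acid letters, fall far
#' below it.
#'
#' @param residues Character vector of residue strings.
#' @return Character vector, `"nucleic"` or `"protein"` per element.
#' @examples
#' detect_sequence_type(c("ATGGCGTTAACC", "MKVLWEQF"))
#' @export
detect_sequence_type <- function(residues) {
  vapply(residues, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    chars <- chars[!chars %in% GAP_CHARS]
    if (length(chars) == 0) {
      return("protein")
    }
    frac <- mean(chars %in% NUCLEOTIDE_CHARS)
    if (frac >= 0.95) "nucleic" else "protein"
  }, character(1), USE.NAMES = FALSE)
}

#' Resolve the effective type of each record
#'
#' Applies `declared_type` overrides: records declared `nucleic` or
#' `protein` keep that type; `auto` records are detected.
#'
#' @param records Tibble from [read_fasta()].
#' @return Character vector of `"nucleic"` / `"protein"`.
#' @export
resolve_sequence_type <- function(records) {
  ifelse(records$declared_type == "auto",
         detect_sequence_type(records$residues),
         records$declared_type)
}

#' Reverse-complement nucleotide strings
#'
#' Standard Watson-Crick complement, reversed; `U` is treated as `T` and
#' `N` is self-complementary.
#'
#' @param residues Character vector of nucleotide strings over
#'   `{A, C, G, T, U, N}` (case-insensitive).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(residues) {
  up <- chartr("u", "U", toupper(residues))
  bad <- grepl(sprintf("[^%s]", paste(NUCLEOTIDE_CHARS, collapse = "")), up)
  if (any(bad)) {
    offending <- gsub(sprintf("[%s]", paste(NUCLEOTIDE_CHARS, collapse = "")), "",
                      up[bad][1])
    rlang::abort(
      sprintf("non-nucleotide character(s) in sequence: %s",
              paste(unique(strsplit(offending, "")[[1]]), collapse = ", ")),
      class = "domfam_sequence_error"
    )
  }
  up <- chartr("U", "T", up)
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# Translate a vector of codons with the standard genetic code
# (translation table 1). Any codon containing a character outside ACGT
# (N or other ambiguity) yields 'X'; 'X' never terminates a segment.
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# Split one frame translation at stop codons into stop-free segments.
# Returns a data frame with columns codon_start (1-based codon index within
# the frame) and peptide.
frame_segments <- function(aa_string, min_len) {
  m <- gregexpr("[^*]+", aa_string)[[1]]
  if (m[1] == -1) {
    return(data.frame(codon_start = integer(0), peptide = character(0)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keep <- lens >= min_len
  data.frame(
    codon_start = starts[keep],
    peptide = regmatches(aa_string, gregexpr("[^*]+", aa_string))[[1]][keep]
  )
}

#' Six-frame translation into candidate protein segments
#'
#' Translates each nucleic record in all three reading frames of both
#' strands with the standard genetic code, splits each frame translation at
#' stop codons, and emits every stop-free segment of at least `min_len`
#' amino acids. No initiator codon is required: domain scans on fragments
#' do not need an ATG, and the length cutoff removes segments too short to
#' carry a domain (`min_len = 1` scans everything).
#'
#' Frames are labelled `+1`, `+2`, `+3` (forward strand, starting at
#' nucleotide 1, 2, 3) and `-1`, `-2`, `-3` (same offsets on the reverse
#' complement). `nt_start` is the 1-based forward-strand position of the
#' first base of the segment's first codon (for negative frames this is the
#' forward-strand position where the minus-strand codon begins, i.e. the
#' 3'-most base on the forward strand). Codons containing `N` translate to
#' `X`, which never acts as a stop and counts toward segment length.
#'
#' @param records Tibble from [read_fasta()] (or any tibble with `seq_id`
#'   and `residues`); all records are assumed nucleic.
#' @param min_len Minimum segment length in amino acids (default 50).
#' @return A tibble with columns `parent_id`, `frame` (character, `"+1"` ..
#'   `"-3"`), `nt_start`, `peptide`. Records shorter than one codon yield no
#'   rows and a warning.
#' @examples
#' recs <- tibble::tibble(seq_id = "g1", residues = "ATGAAATAA",
#'                        declared_type = "nucleic")
#' six_frame_translate(recs, min_len = 2)
#' @export
six_frame_translate <- function(records, min_len = 50) {
  stopifnot(min_len >= 1)
  out <- purrr::pmap(
    list(records$seq_id, records$residues),
    function(seq_id, residues) {
      s <- chartr("U", "T", toupper(residues))
      len <- nchar(s)
      if (len < 3) {
        rlang::warn(sprintf(
          "sequence '%s' is shorter than one codon (%d nt); no translation",
          seq_id, len
        ))
        return(NULL)
      }
      rc <- reverse_complement(s)
      res <- list()
      for (strand in c("+", "-")) {
        src <- if (strand == "+") s else rc
        for (f in 1:3) {
          n_codons <- (len - f + 1) %/% 3
          if (n_codons < 1) next
          starts <- f + 3 * (seq_len(n_codons) - 1)
          codons <- substring(src, starts, starts + 2)
          aa <- paste(translate_codons(codons), collapse = "")
          segs <- frame_segments(aa, min_len)
          if (nrow(segs) == 0) next
          # position of the segment's first codon base within `src`
          pos_in_src <- f + 3 * (segs$codon_start - 1)
          nt_start <- if (strand == "+") pos_in_src else len - pos_in_src + 1
          res[[length(res) + 1L]] <- tibble::tibble(
            parent_id = seq_id,
            frame = paste0(strand, f),
            nt_start = as.integer(nt_start),
            peptide = segs$peptide
          )
        }
      }
      if (length(res) == 0) NULL else dplyr::bind_rows(res)
    }
  )
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    tibble::tibble(parent_id = character(0), frame = character(0),
                   nt_start = integer(0), peptide = character(0))
  } else {
    out
  }
}

# Identifier used for translated segments when they are scanned or looked
# up as standalone proteins: parent|frame|nt_start is unique per segment
# start and reversible.
segment_id <- function(parent_id, frame, nt_start) {
  paste(parent_id, frame, nt_start, sep = "|")
}
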