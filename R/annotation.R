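# Per-protein domain-annotation sets from external scanner output.
#
# Classification is presence/absence over the union of member-database
# signature accessions (Pfam, PROSITE, SMART, ...) and integrated InterPro
# accessions: rule atoms may come from any tier, because some families'
# featured domains exist only in PROSITE/SMART (e.g. BTB/POZ-like as
# PS50097 / SM00225). Hit coordinates and scores are retained for
# reporting but never used to filter.

#' Read InterProScan 5 tab-separated output
#'
#' Parses the standard InterProScan 5 TSV dialect: at least 11 columns
#' (protein id, md5, length, analysis, signature accession, signature
#' description, start, stop, score, status, date) followed by optional
#' InterPro accession, InterPro description, GO and pathway columns; `-`
#' denotes absence. No header line is expected.
#'
#' @param path Path to the TSV file.
#' @return A tibble of hits with columns `protein_id`, `analysis`,
#'   `signature_acc`, `signature_desc`, `start`, `stop`, `score`,
#'   `interpro_acc`, `interpro_desc`.
#' @seealso [annotation_sets()] to reduce hits to per-protein accession
#'   sets.
#' @export
read_interproscan_tsv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("annotation file not found: %s", path),
                 class = "domfam_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    rlang::abort(sprintf("annotation file %s is empty", path),
                 class = "domfam_io_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::imap(fields, function(f, line_no) {
    if (length(f) < 11) {
      rlang::abort(
        sprintf("%s line %d: expected >= 11 tab-separated columns, found %d",
                path, line_no, length(f)),
        class = "domfam_io_error"
      )
    }
    start <- suppressWarnings(as.integer(f[7]))
    stop_ <- suppressWarnings(as.integer(f[8]))
    if (is.na(start) || is.na(stop_)) {
      rlang::abort(
        sprintf("%s line %d: non-numeric start/stop coordinates ('%s', '%s')",
                path, line_no, f[7], f[8]),
        class = "domfam_io_error"
      )
    }
    if (start < 1 || stop_ < start) {
      rlang::abort(
        sprintf("%s line %d: invalid coordinates %d..%d", path, line_no,
                start, stop_),
        class = "domfam_io_error"
      )
    }
    score <- suppressWarnings(as.numeric(f[9]))
    ipr <- if (length(f) >= 12 && nzchar(f[12]) && f[12] != "-") f[12] else NA_character_
    ipr_desc <- if (length(f) >= 13 && nzchar(f[13]) && f[13] != "-") f[13] else NA_character_
    tibble::tibble(
      protein_id = f[1],
      analysis = f[4],
      signature_acc = f[5],
      signature_desc = f[6],
      start = start,
      stop = stop_,
      score = score,
      interpro_acc = ipr,
      interpro_desc = ipr_desc
    )
  })
  dplyr::bind_rows(rows)
}

#' Reduce domain hits to per-protein accession sets
#'
#' The accession set of a protein is the union, over its hits, of the
#' member-database signature accession and (when present) the integrated
#' InterPro accession.
#'
#' @param hits Tibble from [read_interproscan_tsv()].
#' @return A long tibble with columns `protein_id`, `accession`, one row
#'   per distinct (protein, accession) pair, in first-appearance order.
#' @export
annotation_sets <- function(hits) {
  long <- dplyr::bind_rows(
    dplyr::select(hits, "protein_id", accession = "signature_acc"),
    dplyr::filter(
      dplyr::select(hits, "protein_id", accession = "interpro_acc"),
      !is.na(.data$accession)
    )
  )
  dplyr::distinct(dplyr::arrange(long, match(.data$protein_id, hits$protein_id)))
}

#' Read a simplified two-column domain table
#'
#' A minimal annotation format: tab-separated `protein_id<TAB>accession`,
#' one accession per row, `#` comment lines allowed, no header. Repeated
#' rows are idempotent (set semantics).
#'
#' @param path Path to the TSV file.
#' @return A long tibble with columns `protein_id`, `accession`. An empty
#'   file yields an empty tibble with a warning.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("domain table not found: %s", path),
                 class = "domfam_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    rlang::warn(sprintf("domain table %s contains no annotations", path))
    return(tibble::tibble(protein_id = character(0), accession = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("%s: malformed row (expected protein_id<TAB>accession) at data line %d",
              path, bad[1]),
      class = "domfam_io_error"
    )
  }
  dplyr::distinct(tibble::tibble(
    protein_id = vapply(fields, `[`, character(1), 1),
    accession = vapply(fields, `[`, character(1), 2)
  ))
}

#' Write a simplified two-column domain table
#'
#' @param annotations Long tibble with `protein_id`, `accession`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(annotations, path) {
  readr::write_tsv(annotations[, c("protein_id", "accession")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Run an external domain scanner over a FASTA file
#'
#' Domain scanning itself (InterProScan or any program emitting its TSV
#' dialect) is an external, optional dependency; this function only
#' substitutes `{input}` / `{output}` placeholders in a command template,
#' executes it through the shell, and returns the output path on success.
#' The produced TSV must be consumable by [read_interproscan_tsv()].
#'
#' @param fasta_path Input FASTA file.
#' @param command_template Shell command containing `{input}` and
#'   `{output}` placeholders.
#' @param workdir Directory for the scanner output (created if needed).
#' @param timeout Seconds before the scanner is killed (default 3600).
#' @return Path of the scanner's TSV output.
#' @export
run_external_scanner <- function(fasta_path, command_template,
                                 workdir = tempfile("domfam_scan_"),
                                 timeout = 3600) {
  if (!grepl("{input}", command_template, fixed = TRUE) ||
      !grepl("{output}", command_template, fixed = TRUE)) {
    rlang::abort("command template must contain {input} and {output} placeholders",
                 class = "domfam_scanner_error")
  }
  if (!file.exists(fasta_path)) {
    rlang::abort(sprintf("FASTA file not found: %s", fasta_path),
                 class = "domfam_io_error")
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  out_path <- file.path(workdir, "scan.tsv")
  cmd <- gsub("{output}", shQuote(out_path),
              gsub("{input}", shQuote(fasta_path), command_template, fixed = TRUE),
              fixed = TRUE)
  stderr_file <- file.path(workdir, "scanner.stderr")
  status <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = FALSE, stderr = stderr_file,
            timeout = timeout)
  )
  if (!identical(status, 0L)) {
    err <- if (file.exists(stderr_file)) {
      paste(readLines(stderr_file, warn = FALSE), collapse = "\n")
    } else {
      ""
    }
    rlang::abort(
      sprintf("scanner exited with status %s: %s\n%s", status, cmd, err),
      class = "domfam_scanner_error", stderr = err
    )
  }
  if (!file.exists(out_path)) {
    rlang::abort(
      sprintf("scanner succeeded but produced no output file at %s", out_path),
      class = "domfam_scanner_error"
    )
  }
  out_path
}
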