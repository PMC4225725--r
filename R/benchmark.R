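# Prediction-vs-reference benchmarking: matches / conflicts / missed /
# newly predicted, plus three-way set comparison (Venn regions).

#' Read a gene-to-family assignment table
#'
#' Two-column TSV `gene_id<TAB>family`, no header, `#` comments allowed.
#' Repeated `gene_id` rows accumulate into family sets.
#'
#' @param path Path to the TSV file.
#' @param strip_transcript When `TRUE`, a trailing transcript suffix
#'   (`.1`, `.2`, ...) is stripped from gene ids. Off by default: mixing
#'   gene and transcript ids is common, but silent munging is dangerous.
#' @return A long tibble `gene_id`, `family`.
#' @export
read_assignment_table <- function(path, strip_transcript = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("assignment table not found: %s", path),
                 class = "domfam_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    rlang::abort(sprintf("assignment table %s is empty", path),
                 class = "domfam_io_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("%s: malformed row (expected gene_id<TAB>family) at data line %d",
              path, bad[1]),
      class = "domfam_io_error"
    )
  }
  out <- tibble::tibble(
    gene_id = vapply(fields, `[`, character(1), 1),
    family = vapply(fields, `[`, character(1), 2)
  )
  if (strip_transcript) {
    out$gene_id <- sub("\\.[0-9]+$", "", out$gene_id)
  }
  dplyr::distinct(out)
}

#' Read a family synonym map
#'
#' Two-column TSV `alias<TAB>canonical`, no header, `#` comments allowed;
#' matching is case-insensitive.
#'
#' @param path Path to the TSV file.
#' @return A tibble `alias`, `canonical`.
#' @export
read_synonym_map <- function(path) {
  tbl <- read_assignment_table(path)
  tibble::tibble(alias = tbl$gene_id, canonical = tbl$family)
}

apply_synonyms <- function(families, synonyms) {
  if (is.null(synonyms)) {
    return(families)
  }
  idx <- match(tolower(families), tolower(synonyms$alias))
  ifelse(is.na(idx), families, synonyms$canonical[idx])
}

#' Compare predicted against reference gene-family assignments
#'
#' Each gene in either table falls into exactly one of four categories:
#'
#' * **match** — gene present in both tables and the family sets intersect;
#' * **conflict** — gene present in both tables, family sets disjoint;
#' * **missed** — gene present only in the reference;
#' * **newly predicted** — gene present only in the predictions.
#'
#' `matches + conflicts + missed = |reference genes|` always holds, and the
#' four gene lists are pairwise disjoint. A gene counts as a match when the
#' family sets intersect (not strict equality), because predictions may
#' legitimately carry several families; requiring equality would turn
#' multi-assignments into artificial conflicts. Family names are folded
#' through the optional synonym map (case-insensitively) before
#' comparison, and all family comparison is case-insensitive.
#'
#' @param predictions,reference Long tibbles `gene_id`, `family` (e.g. from
#'   [read_assignment_table()], or a prediction tibble — the `sequence_id`
#'   column is accepted as `gene_id`).
#' @param synonyms Optional synonym map (tibble `alias`, `canonical`).
#' @param strip_transcript When `TRUE`, trailing `.N` transcript suffixes
#'   are stripped from gene ids in both tables before comparison.
#' @return A `family_comparison` object: list with `genes` (tibble
#'   `gene_id`, `category`, `pred_families`, `ref_families`) and `summary`
#'   (tibble `category`, `n`). Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' pred <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                        family = c("A", "C", "D"))
#' ref <- tibble::tibble(gene_id = c("g1", "g2"), family = c("A", "B"))
#' compare_assignments(pred, ref)
#' @export
compare_assignments <- function(predictions, reference, synonyms = NULL,
                                strip_transcript = FALSE) {
  norm <- function(tbl) {
    if (!"gene_id" %in% names(tbl) && "sequence_id" %in% names(tbl)) {
      tbl <- dplyr::rename(tbl, gene_id = "sequence_id")
    }
    stopifnot(all(c("gene_id", "family") %in% names(tbl)))
    out <- tibble::tibble(gene_id = as.character(tbl$gene_id),
                          family = as.character(tbl$family))
    if (strip_transcript) {
      out$gene_id <- sub("\\.[0-9]+$", "", out$gene_id)
    }
    out$family <- apply_synonyms(out$family, synonyms)
    dplyr::distinct(out)
  }
  pred <- norm(predictions)
  ref <- norm(reference)
  if (nrow(pred) == 0 || nrow(ref) == 0) {
    rlang::abort("both assignment tables must be non-empty",
                 class = "domfam_benchmark_error")
  }
  pred_sets <- split(pred$family, pred$gene_id)
  ref_sets <- split(ref$family, ref$gene_id)
  all_genes <- union(names(pred_sets), names(ref_sets))

  category <- vapply(all_genes, function(g) {
    in_pred <- g %in% names(pred_sets)
    in_ref <- g %in% names(ref_sets)
    if (in_pred && in_ref) {
      if (length(intersect(tolower(pred_sets[[g]]), tolower(ref_sets[[g]]))) > 0) {
        "match"
      } else {
        "conflict"
      }
    } else if (in_ref) {
      "missed"
    } else {
      "newly_predicted"
    }
  }, character(1))

  genes <- tibble::tibble(
    gene_id = all_genes,
    category = unname(category),
    pred_families = unname(lapply(all_genes, function(g) {
      fams <- pred_sets[[g]]
      if (is.null(fams)) character(0) else sort(unique(fams))
    })),
    ref_families = unname(lapply(all_genes, function(g) {
      fams <- ref_sets[[g]]
      if (is.null(fams)) character(0) else sort(unique(fams))
    }))
  )
  genes <- dplyr::arrange(genes, .data$gene_id)
  cats <- c("match", "conflict", "missed", "newly_predicted")
  summary <- tibble::tibble(
    category = cats,
    n = vapply(cats, function(ct) sum(genes$category == ct), integer(1))
  )
  structure(
    list(genes = genes, summary = summary,
         n_reference = length(ref_sets), n_predicted = length(pred_sets)),
    class = "family_comparison"
  )
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("# Prediction vs reference comparison\n")
  cat(sprintf("  reference genes: %d   predicted genes: %d\n",
              x$n_reference, x$n_predicted))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-16s %d\n", x$summary$category[i], x$summary$n[i]))
  }
  invisible(x)
}

#' @describeIn compare_assignments Per-gene comparison rows (family sets
#'   collapsed to comma-joined strings).
#' @param x A `family_comparison`.
#' @param ... Unused.
#' @method tidy family_comparison
#' @export
tidy.family_comparison <- function(x, ...) {
  dplyr::mutate(
    x$genes,
    pred_families = vapply(.data$pred_families, paste, character(1), collapse = ","),
    ref_families = vapply(.data$ref_families, paste, character(1), collapse = ",")
  )
}

#' @describeIn compare_assignments One-row summary with the four category
#'   counts and table sizes.
#' @method glance family_comparison
#' @export
glance.family_comparison <- function(x, ...) {
  counts <- stats::setNames(as.list(x$summary$n), x$summary$category)
  tibble::tibble(
    matches = counts$match,
    conflicts = counts$conflict,
    missed = counts$missed,
    newly_predicted = counts$newly_predicted,
    n_reference = x$n_reference,
    n_predicted = x$n_predicted
  )
}

#' @describeIn compare_assignments Bar chart of the four category counts.
#' @param object A `family_comparison`.
#' @method autoplot family_comparison
#' @export
autoplot.family_comparison <- function(object, ...) {
  df <- object$summary
  df$category <- factor(df$category,
                        levels = c("match", "conflict", "missed", "newly_predicted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Prediction vs reference assignment") +
    ggplot2::theme_minimal()
}

#' Three-way set comparison (Venn regions)
#'
#' Counts the seven non-empty intersection regions of three gene-id sets,
#' as drawn in a three-set Venn diagram; region counts sum to the size of
#' the union.
#'
#' @param set_a,set_b,set_c Character vectors of gene ids.
#' @param labels Length-3 character vector naming the sets.
#' @return A tibble with columns `region` (e.g. `"A"`, `"A&B"`, `"A&B&C"`,
#'   built from `labels`), `count`, with attribute `labels`; class
#'   `three_way_comparison`.
#' @examples
#' compare_three_way(c("1", "2"), c("2", "3"), "3")
#' @export
compare_three_way <- function(set_a, set_b, set_c, labels = c("A", "B", "C")) {
  stopifnot(length(labels) == 3)
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  cc <- unique(as.character(set_c))
  genes <- union(union(a, b), cc)
  in_a <- genes %in% a
  in_b <- genes %in% b
  in_c <- genes %in% cc
  membership <- paste0(ifelse(in_a, "1", "0"), ifelse(in_b, "1", "0"),
                       ifelse(in_c, "1", "0"))
  patterns <- c("100", "010", "001", "110", "101", "011", "111")
  region_name <- vapply(patterns, function(p) {
    bits <- strsplit(p, "")[[1]] == "1"
    paste(labels[bits], collapse = "&")
  }, character(1))
  out <- tibble::tibble(
    region = unname(region_name),
    count = vapply(patterns, function(p) sum(membership == p), integer(1),
                   USE.NAMES = FALSE)
  )
  attr(out, "labels") <- labels
  class(out) <- c("three_way_comparison", class(out))
  out
}

#' Bar chart of the seven Venn-region counts
#' @param object A `three_way_comparison`.
#' @param ... Unused.
#' @method autoplot three_way_comparison
#' @export
autoplot.three_way_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "intersection region", y = "genes",
                  title = "Three-way prediction overlap") +
    ggplot2::theme_minimal()
}
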