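# Output-directory layout: one subdirectory per enzyme class, per-family
# hit files, per-class and per-EC summaries, and the two top-level summary
# files (family counts and accession-to-families).

KNOWN_CLASSES <- c("CBM", "GH", "GT", "PL", "CE", "AA")

#' Enzyme class of a family name
#'
#' The class is the leading letters of the family name (before the first
#' digit): GH, GT, PL, CE, AA or CBM. Unknown prefixes map to `"OTHER"`.
#'
#' @param family Character vector of family names.
#' @return Character vector of class names.
#' @examples
#' enzyme_class(c("GH5", "CBM2", "XYZ9"))
#' @export
enzyme_class <- function(family) {
  prefix <- toupper(sub("[0-9_].*$", "", family))
  ifelse(prefix %in% KNOWN_CLASSES, prefix, "OTHER")
}

write_tsv_file <- function(df, path) {
  # plain, deterministic TSV: UTF-8, Unix newlines, no quoting, no timestamps
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df) > 0) {
      do.call(paste, c(lapply(df, as.character), sep = "\t"))
    }
  )
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Fig.-4-style per-hit rows: group, accession, score (2 decimals), peptide
# count, the protein sequence, its length, and the matched peptides.
hit_file_rows <- function(hits, proteins) {
  seq_idx <- match(hits$accession, proteins$accession)
  tibble(
    group = hits$group_id,
    accession = hits$accession,
    frequency_score = sprintf("%.2f", hits$frequency_score),
    peptide_count = hits$peptide_count,
    protein_sequence = proteins$sequence[seq_idx],
    sequence_length = nchar(proteins$sequence[seq_idx]),
    matched_peptides = map_chr(hits$matched_peptides, paste0, collapse = ",")
  )
}

functions_column <- function(functions_list) {
  map_chr(functions_list, function(df) {
    if (nrow(df) == 0) return("")
    df <- arrange(df, desc(.data$score), .data$ec)
    paste0(df$ec, ":", df$score, collapse = ";")
  })
}

#' Annotate a proteome and write the full output directory
#'
#' End-to-end annotation run: reads the queries and the pattern bank,
#' annotates with [annotate_proteins()], and writes the output tree — one
#' subdirectory per enzyme class present among the hits (each with
#' per-family hit files, a class `summary.tsv`, and a `functions/`
#' subdirectory with per-EC files and an EC summary), plus the two top-level
#' files `family_summary.tsv` (family, number of annotated proteins) and
#' `accession_families.tsv` (accession, comma-joined families). All output
#' is tab-separated text with Unix newlines and contains no timestamps, so
#' identical inputs give byte-identical output.
#'
#' @param proteins Query proteins: a protein tibble or a FASTA path.
#' @param bank A `pattern_bank` or a path readable by
#'   [read_pattern_bank()].
#' @param out_dir Output directory; created if absent. A non-empty existing
#'   directory is refused unless `force = TRUE`.
#' @param force Overwrite into a non-empty directory.
#' @param log_file Optional path for a run log (the only file that may
#'   contain timestamps).
#' @return The `hotpep_annotations` object, invisibly.
#' @export
run_annotation <- function(proteins, bank, out_dir, force = FALSE,
                           log_file = NULL) {
  t0 <- Sys.time()
  if (is.character(bank) && length(bank) == 1) {
    bank <- read_pattern_bank(bank)
  }
  if (is.character(proteins) && length(proteins) == 1) {
    proteins <- read_fasta(proteins)
  }
  check_proteins(proteins)
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = FALSE)) > 0
      && !force) {
    abort(paste0("output directory is not empty (use force = TRUE): ",
                 out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ann <- annotate_proteins(proteins, bank)
  hits <- ann$hits

  write_tsv_file(ann$family_counts,
                 file.path(out_dir, "family_summary.tsv"))
  write_tsv_file(ann$accession_families,
                 file.path(out_dir, "accession_families.tsv"))

  if (nrow(hits) > 0) {
    hits$class <- enzyme_class(hits$family)
    for (cls in sort(unique(hits$class))) {
      cls_dir <- file.path(out_dir, cls)
      dir.create(cls_dir, showWarnings = FALSE)
      cls_hits <- hits[hits$class == cls, , drop = FALSE]
      for (fam in sort(unique(cls_hits$family))) {
        fam_hits <- cls_hits[cls_hits$family == fam, , drop = FALSE]
        write_tsv_file(hit_file_rows(fam_hits, proteins),
                       file.path(cls_dir, paste0(fam, ".tsv")))
      }
      write_tsv_file(
        cls_hits |> count(.data$family, name = "n_proteins") |>
          arrange(.data$family),
        file.path(cls_dir, "summary.tsv")
      )
      write_class_functions(cls_hits, proteins, cls_dir)
    }
  }

  if (!is.null(log_file)) {
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    writeLines(c(
      sprintf("queries: %d", ann$n_queries),
      sprintf("annotated proteins: %d", nrow(ann$accession_families)),
      sprintf("hits: %d", nrow(hits)),
      sprintf("families: %d", nrow(ann$family_counts)),
      sprintf("elapsed_seconds: %.2f", elapsed),
      sprintf("finished: %s", format(t0 + elapsed, usetz = TRUE))
    ), log_file)
  }
  invisible(ann)
}

write_class_functions <- function(cls_hits, proteins, cls_dir) {
  fun_dir <- file.path(cls_dir, "functions")
  dir.create(fun_dir, showWarnings = FALSE)
  with_fun <- cls_hits[map_int(cls_hits$functions, nrow) > 0, , drop = FALSE]
  long <- if (nrow(with_fun) == 0) {
    tibble(accession = character(0), ec = character(0))
  } else {
    with_fun |>
      select("accession", "family", "group_id", "functions") |>
      unnest("functions")
  }
  write_tsv_file(
    long |> distinct(.data$ec, .data$accession) |>
      count(.data$ec, name = "n_proteins") |> arrange(.data$ec),
    file.path(fun_dir, "summary.tsv")
  )
  if (nrow(long) == 0) return(invisible(NULL))
  for (ec_num in sort(unique(long$ec))) {
    acc <- unique(long$accession[long$ec == ec_num])
    ec_hits <- with_fun[with_fun$accession %in% acc, , drop = FALSE]
    rows <- hit_file_rows(ec_hits, proteins)
    rows$functions <- functions_column(ec_hits$functions)
    write_tsv_file(rows, file.path(fun_dir, paste0(ec_num, ".tsv")))
  }
  invisible(NULL)
}
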