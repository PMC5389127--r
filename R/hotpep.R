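# Hotpep annotation: score query proteins against every group's conserved
# peptide list, apply the three significance criteria, assign each protein
# to the best group per family, and predict function from the winning group.

#' Score one sequence against one group's peptide list
#'
#' Finds all of the group's conserved peptides present in the sequence as
#' exact substrings. The group-specific frequency score is the sum of the
#' stored in-group frequencies of the matched peptides (each distinct
#' peptide counted once, however often it occurs); coverage is the number of
#' distinct residue positions covered by at least one occurrence of at least
#' one matched peptide (all occurrences count).
#'
#' @param sequence A normalized amino-acid string.
#' @param group A `peptide_group`, or a data frame with `peptide` and
#'   `frequency` columns.
#' @return A one-row tibble with `frequency_score`, `peptide_count`,
#'   `coverage` and `matched_peptides` (list of character vectors).
#' @examples
#' g <- tibble::tibble(peptide = c("ACDEFG", "HIKLMN"),
#'                     frequency = c(0.5, 0.8))
#' score_against_group("ACDEFGHIKLMN", g)
#' @export
score_against_group <- function(sequence, group) {
  peps <- if (inherits(group, "peptide_group")) group$peptides else group
  if (!all(c("peptide", "frequency") %in% names(peps))) {
    abort("`group` must have `peptide` and `frequency`")
  }
  sc <- score_one(sequence, peps$peptide, peps$frequency,
                  k = unique(nchar(peps$peptide)))
  tibble(
    frequency_score = sc$frequency_score,
    peptide_count = sc$peptide_count,
    coverage = sc$coverage,
    matched_peptides = list(sc$matched)
  )
}

# Core scorer. All bank peptides share one length k, so matching reduces to
# set membership over the query's k-mer windows; coverage is the union of
# matched windows.
score_one <- function(sequence, peptides, frequencies, k) {
  n <- nchar(sequence)
  if (length(k) > 1) {
    return(score_one_varlen(sequence, peptides, frequencies))
  }
  if (length(peptides) == 0 || n < k) {
    return(list(frequency_score = 0, peptide_count = 0L, coverage = 0L,
                matched = character(0)))
  }
  starts <- 1:(n - k + 1)
  windows <- substring(sequence, starts, starts + k - 1)
  hit <- peptides %in% windows
  matched <- peptides[hit]
  if (length(matched) == 0) {
    return(list(frequency_score = 0, peptide_count = 0L, coverage = 0L,
                matched = character(0)))
  }
  occ <- starts[windows %in% matched]
  cov <- logical(n)
  for (s in occ) cov[s:(s + k - 1)] <- TRUE
  list(
    frequency_score = sum(frequencies[hit]),
    peptide_count = length(matched),
    coverage = sum(cov),
    matched = sort(matched)
  )
}

# Fallback for mixed peptide lengths (not produced by ppr, but the scorer
# stays correct if fed one).
score_one_varlen <- function(sequence, peptides, frequencies) {
  n <- nchar(sequence)
  cov <- logical(n)
  hit <- logical(length(peptides))
  for (i in seq_along(peptides)) {
    m <- gregexpr(peptides[[i]], sequence, fixed = TRUE)[[1]]
    if (m[[1]] == -1) next
    hit[[i]] <- TRUE
    w <- nchar(peptides[[i]])
    for (s in as.integer(m)) cov[s:(s + w - 1)] <- TRUE
  }
  list(
    frequency_score = sum(frequencies[hit]),
    peptide_count = sum(hit),
    coverage = sum(cov),
    matched = sort(peptides[hit])
  )
}

#' Test the three significance criteria for a hit
#'
#' A hit is significant when the query contains three or more conserved
#' peptides from the group, the frequency score is strictly greater than
#' 1.0, and the matched peptides cover at least ten residues of the query.
#' Boundaries: a peptide count of exactly 3 passes, a frequency score of
#' exactly 1.0 fails, a coverage of exactly 10 passes.
#'
#' @param scores A data frame with `frequency_score`, `peptide_count` and
#'   `coverage` columns (e.g. from [score_against_group()]).
#' @param min_peptides,min_score,min_coverage The thresholds.
#' @return A logical vector, one element per row.
#' @export
is_significant <- function(scores, min_peptides = 3L, min_score = 1.0,
                           min_coverage = 10L) {
  scores$peptide_count >= min_peptides &
    scores$frequency_score > min_score &
    scores$coverage >= min_coverage
}

# Pre-split a bank into per-group score vectors for fast repeated annotation.
bank_index <- function(bank) {
  stopifnot(inherits(bank, "pattern_bank"))
  if (nrow(bank$peptides) == 0) return(list())
  split_keys <- paste(bank$peptides$family, bank$peptides$group_id, sep = "\r")
  groups <- split(bank$peptides, split_keys)
  fun_keys <- paste(bank$functions$family, bank$functions$group_id, sep = "\r")
  funs <- split(bank$functions, fun_keys)
  map(groups, function(gdf) {
    key <- paste(gdf$family[[1]], gdf$group_id[[1]], sep = "\r")
    list(
      family = gdf$family[[1]],
      group_id = gdf$group_id[[1]],
      peptides = gdf$peptide,
      frequencies = gdf$frequency,
      k = unique(nchar(gdf$peptide)),
      functions = if (is.null(funs[[key]])) {
        tibble(ec = character(0), score = integer(0))
      } else {
        funs[[key]][, c("ec", "score")]
      }
    )
  })
}

#' Annotate one protein against a pattern bank
#'
#' Scores the protein against every group, keeps significant hits, and
#' retains per family the single group with the highest frequency score
#' (ties broken by larger peptide count, then larger coverage, then lower
#' group id). A multidomain protein can legitimately be annotated in several
#' families; families are never reconciled against each other.
#'
#' @param record A one-row protein tibble (or list with `accession`,
#'   `sequence`).
#' @param bank A `pattern_bank`.
#' @return A tibble of annotations (0 or more rows) with columns
#'   `accession`, `family`, `group_id`, `frequency_score`, `peptide_count`,
#'   `coverage`, `matched_peptides` (list) and `functions` (list of tibbles
#'   `ec`, `score` sorted by decreasing score).
#' @export
annotate_protein <- function(record, bank) {
  idx <- if (inherits(bank, "pattern_bank")) bank_index(bank) else bank
  annotate_one(record$accession[[1]], record$sequence[[1]], idx)
}

annotate_one <- function(accession, sequence, idx) {
  if (length(idx) == 0) return(empty_hits())
  rows <- compact(map(idx, function(g) {
    sc <- score_one(sequence, g$peptides, g$frequencies, g$k)
    if (sc$peptide_count < 3L || sc$frequency_score <= 1.0 ||
        sc$coverage < 10L) {
      return(NULL)
    }
    tibble(
      accession = accession,
      family = g$family,
      group_id = g$group_id,
      frequency_score = sc$frequency_score,
      peptide_count = sc$peptide_count,
      coverage = sc$coverage,
      matched_peptides = list(sc$matched),
      functions = list(g$functions %||%
                         tibble(ec = character(0), score = integer(0)))
    )
  }))
  if (length(rows) == 0) return(empty_hits())
  list_rbind(rows) |>
    arrange(.data$family, desc(.data$frequency_score),
            desc(.data$peptide_count), desc(.data$coverage),
            .data$group_id) |>
    slice_head(n = 1, by = "family")
}

empty_hits <- function() {
  tibble(
    accession = character(0), family = character(0), group_id = integer(0),
    frequency_score = numeric(0), peptide_count = integer(0),
    coverage = integer(0), matched_peptides = list(), functions = list()
  )
}

#' Annotate a protein collection against a pattern bank
#'
#' Runs [annotate_protein()] over every query and collects the per-hit
#' table, the family-count summary and the accession-to-families multimap.
#' Ordering is deterministic: query input order, then family.
#'
#' @param proteins A protein tibble (queries; no deduplication is applied).
#' @param bank A `pattern_bank`.
#' @return A `hotpep_annotations` object: list with `hits` (per-hit tibble,
#'   see [annotate_protein()]), `family_counts` (tibble `family`,
#'   `n_proteins`), `accession_families` (tibble `accession`, `families`
#'   comma-joined), and `n_queries`.
#' @examples
#' \donttest{
#' bm <- generate_benchmark(list(synth_family_spec("GH5", seed = 3)),
#'                          n_negatives = 5, seed = 3)
#' bank <- ppr_train(bm$training, quiet = TRUE)
#' ann <- annotate_proteins(bm$query, bank)
#' glance(ann)
#' }
#' @export
annotate_proteins <- function(proteins, bank) {
  check_proteins(proteins)
  idx <- bank_index(bank)
  hits <- list_rbind(
    map2(proteins$accession, proteins$sequence, annotate_one, idx = idx)
  )
  if (is.null(hits) || nrow(hits) == 0) hits <- empty_hits()
  family_counts <- hits |>
    count(.data$family, name = "n_proteins") |>
    arrange(.data$family)
  accession_families <- hits |>
    summarise(families = paste(sort(unique(.data$family)), collapse = ","),
              .by = "accession")
  structure(
    list(
      hits = hits,
      family_counts = family_counts,
      accession_families = accession_families,
      n_queries = nrow(proteins)
    ),
    class = "hotpep_annotations"
  )
}

#' @export
print.hotpep_annotations <- function(x, ...) {
  cat(sprintf("<hotpep_annotations> %d hit(s) on %d of %d quer%s\n",
              nrow(x$hits), nrow(x$accession_families), x$n_queries,
              if (x$n_queries == 1) "y" else "ies"))
  if (nrow(x$family_counts) > 0) {
    cat("  per family:",
        paste0(x$family_counts$family, "=", x$family_counts$n_proteins,
               collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname annotate_proteins
#' @param x,object A `hotpep_annotations` object.
#' @param ... Unused.
#' @method tidy hotpep_annotations
#' @export
tidy.hotpep_annotations <- function(x, ...) {
  x$hits
}

#' @rdname annotate_proteins
#' @method glance hotpep_annotations
#' @export
glance.hotpep_annotations <- function(x, ...) {
  tibble(
    n_queries = x$n_queries,
    n_annotated = nrow(x$accession_families),
    n_hits = nrow(x$hits),
    n_families = nrow(x$family_counts),
    n_with_function = sum(map_int(x$hits$functions, nrow) > 0)
  )
}

#' @rdname annotate_proteins
#' @method autoplot hotpep_annotations
#' @export
autoplot.hotpep_annotations <- function(object, ...) {
  ggplot2::ggplot(object$family_counts,
                  ggplot2::aes(x = .data$family, y = .data$n_proteins)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "family", y = "annotated proteins",
                  title = "Annotated proteins per family")
}

#' Ranked EC predictions for annotated proteins
#'
#' Expands the function scores of each winning group into a long table,
#' ranked within each hit by decreasing score (ties by EC number). A hit
#' whose group has no experimentally characterized member yields no rows:
#' such proteins are family-annotated but carry no functional prediction.
#'
#' @param annotations A `hotpep_annotations` object, or the `hits` tibble
#'   from one.
#' @return A tibble with `accession`, `family`, `group_id`, `ec`, `score`
#'   and `rank` (1 = best within the hit).
#' @export
predict_function <- function(annotations) {
  hits <- if (inherits(annotations, "hotpep_annotations")) {
    annotations$hits
  } else {
    annotations
  }
  if (nrow(hits) == 0) {
    return(tibble(accession = character(0), family = character(0),
                  group_id = integer(0), ec = character(0),
                  score = integer(0), rank = integer(0)))
  }
  hits |>
    select("accession", "family", "group_id", "functions") |>
    unnest("functions") |>
    arrange_function_ranks()
}

arrange_function_ranks <- function(df) {
  if (nrow(df) == 0) {
    df$rank <- integer(0)
    return(df)
  }
  df |>
    arrange(.data$accession, .data$family, desc(.data$score), .data$ec) |>
    mutate(rank = row_number(), .by = c("accession", "family", "group_id"))
}
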