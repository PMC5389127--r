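# Peptide Pattern Recognition: iterative extraction of groups of proteins
# sharing conserved fixed-length peptides within one enzyme family.

#' PPR discovery parameters
#'
#' Bundles the tunable constraints of Peptide Pattern Recognition. The
#' defaults are the enzyme-family settings found empirically to give the best
#' functional prediction rate: hexapeptides, up to 70 conserved peptides per
#' group, at least 10 conserved peptides per member protein, a minimum
#' in-group peptide frequency of 0.20, and a stop once fewer than five
#' proteins group together. The `"cbm"` preset (30 peptides per group, 3 per
#' protein) suits the short carbohydrate-binding-module domains.
#'
#' @param peptide_len Conserved peptide length in residues (k-mer size).
#' @param peptides_per_group Maximum peptides retained per group (N).
#' @param min_peptides_per_protein Minimum distinct group peptides a member
#'   must contain (m).
#' @param min_peptide_frequency Minimum fraction of group members containing
#'   a retained peptide.
#' @param min_group_size Smallest group extracted; discovery stops below it.
#' @param max_iterations Cap on refinement iterations per group.
#' @param preset `"enzyme"` (defaults above) or `"cbm"` (N = 30, m = 3).
#'   Explicit arguments override the preset.
#' @return An object of class `ppr_params` (a named list).
#' @examples
#' ppr_params()
#' ppr_params(preset = "cbm")
#' @export
ppr_params <- function(peptide_len = 6L,
                       peptides_per_group = 70L,
                       min_peptides_per_protein = 10L,
                       min_peptide_frequency = 0.20,
                       min_group_size = 5L,
                       max_iterations = 100L,
                       preset = c("enzyme", "cbm")) {
  preset <- match.arg(preset)
  if (preset == "cbm") {
    if (missing(peptides_per_group)) peptides_per_group <- 30L
    if (missing(min_peptides_per_protein)) min_peptides_per_protein <- 3L
  }
  p <- list(
    peptide_len = as.integer(peptide_len),
    peptides_per_group = as.integer(peptides_per_group),
    min_peptides_per_protein = as.integer(min_peptides_per_protein),
    min_peptide_frequency = as.numeric(min_peptide_frequency),
    min_group_size = as.integer(min_group_size),
    max_iterations = as.integer(max_iterations)
  )
  if (p$peptide_len < 3) abort("peptide_len must be >= 3")
  if (p$min_peptides_per_protein > p$peptides_per_group) {
    abort("min_peptides_per_protein must not exceed peptides_per_group")
  }
  if (p$min_peptide_frequency <= 0 || p$min_peptide_frequency > 1) {
    abort("min_peptide_frequency must be in (0, 1]")
  }
  if (p$min_group_size < 2) abort("min_group_size must be >= 2")
  structure(p, class = "ppr_params")
}

#' @export
print.ppr_params <- function(x, ...) {
  cat("PPR parameters:\n")
  cat(sprintf("  peptide length           %d\n", x$peptide_len))
  cat(sprintf("  peptides per group (N)   %d\n", x$peptides_per_group))
  cat(sprintf("  peptides per protein (m) %d\n", x$min_peptides_per_protein))
  cat(sprintf("  min peptide frequency    %.2f\n", x$min_peptide_frequency))
  cat(sprintf("  min group size           %d\n", x$min_group_size))
  invisible(x)
}

# Long (accession, peptide) pairs: every distinct length-k window per protein,
# windows containing ambiguous residues (X/B/Z/U) excluded. Presence
# semantics: each (protein, peptide) pair appears once however often the
# peptide occurs.
kmer_pairs <- function(proteins, k) {
  unambiguous <- paste0("^[", paste0(STANDARD_AA, collapse = ""), "]+$")
  rows <- map2(proteins$accession, proteins$sequence, function(acc, seq) {
    n <- nchar(seq)
    if (n < k) return(NULL)
    km <- unique(substring(seq, 1:(n - k + 1), k:n))
    km <- km[grepl(unambiguous, km)]
    if (length(km) == 0) return(NULL)
    tibble(accession = acc, peptide = km)
  })
  out <- list_rbind(compact(rows))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(accession = character(0), peptide = character(0)))
  }
  out
}

#' Count k-mer peptides across a protein collection
#'
#' Enumerates every length-`k` window over standard residues in each protein
#' and records, for each peptide, the set of proteins containing it at least
#' once (presence, not occurrence count). Windows containing ambiguous
#' residues (X/B/Z/U) are excluded: they are not reproducible sequence
#' evidence.
#'
#' @param proteins A protein tibble.
#' @param k Peptide length (>= 3).
#' @return A tibble with columns `peptide`, `n_proteins` and `accessions`
#'   (list of character vectors), sorted by decreasing `n_proteins` then
#'   peptide.
#' @examples
#' p <- tibble::tibble(accession = "a", sequence = "ACDEFGH")
#' count_kmers(p, k = 6)
#' @export
count_kmers <- function(proteins, k = 6L) {
  check_proteins(proteins)
  if (k < 3) abort("k must be >= 3")
  if (nrow(proteins) == 0) abort("`proteins` is empty")
  pairs <- kmer_pairs(proteins, k)
  pairs |>
    summarise(
      n_proteins = n(),
      accessions = list(sort(.data$accession)),
      .by = "peptide"
    ) |>
    arrange(desc(.data$n_proteins), .data$peptide)
}

#' Extract the largest conserved-peptide group from a protein pool
#'
#' One PPR extraction step: finds the largest group of proteins that each
#' contain at least `min_peptides_per_protein` of up to
#' `peptides_per_group` conserved peptides, every retained peptide being
#' present in at least `min_peptide_frequency` of the members. The search is
#' a deterministic fixed-point refinement: the peptide list is seeded with
#' the N k-mers shared by the most proteins (ties lexicographic); members
#' are the proteins containing at least m of the current list; peptide
#' frequencies are recomputed over the members and the N most frequent
#' peptides above the frequency floor are retained (ties lexicographic);
#' membership and list are alternated until the member set is stable. A
#' final prune drops members that fell below m distinct peptides and
#' re-filters the list until all group invariants hold.
#'
#' @param proteins Pool of unassigned proteins (a protein tibble).
#' @param params A [ppr_params()] object.
#' @param family Family name stored on the group.
#' @param group_id Group number stored on the group.
#' @return A `peptide_group` object, or `NULL` when no group of at least
#'   `min_group_size` members exists under the constraints.
#' @export
build_group <- function(proteins, params = ppr_params(),
                        family = "family", group_id = 1L) {
  check_proteins(proteins)
  if (nrow(proteins) == 0) return(NULL)
  pairs <- kmer_pairs(proteins, params$peptide_len)
  if (nrow(pairs) == 0) return(NULL)
  m <- params$min_peptides_per_protein
  N <- params$peptides_per_group

  seed_tbl <- pairs |>
    count(.data$peptide, name = "n_prot") |>
    arrange(desc(.data$n_prot), .data$peptide)
  peptides <- head(seed_tbl$peptide, N)

  members <- character(0)
  for (iter in seq_len(params$max_iterations)) {
    new_members <- pairs |>
      filter(.data$peptide %in% peptides) |>
      count(.data$accession) |>
      filter(.data$n >= m) |>
      pull(.data$accession)
    if (length(new_members) == 0) return(NULL)
    if (setequal(new_members, members)) {
      members <- new_members
      break
    }
    members <- new_members
    freq_tbl <- pairs |>
      filter(.data$accession %in% members) |>
      count(.data$peptide) |>
      mutate(frequency = .data$n / length(members)) |>
      filter(.data$frequency >= params$min_peptide_frequency) |>
      arrange(desc(.data$frequency), .data$peptide)
    peptides <- head(freq_tbl$peptide, N)
    if (length(peptides) == 0) return(NULL)
  }

  # Final prune to a state satisfying all group invariants: members with
  # >= m distinct retained peptides, frequencies exact over members,
  # every frequency >= the floor. Usually a no-op at a true fixed point.
  repeat {
    inside <- pairs |>
      filter(.data$accession %in% members, .data$peptide %in% peptides)
    kept <- inside |>
      count(.data$accession) |>
      filter(.data$n >= m) |>
      pull(.data$accession)
    if (length(kept) == 0) return(NULL)
    freq_tbl <- inside |>
      filter(.data$accession %in% kept) |>
      count(.data$peptide) |>
      mutate(frequency = .data$n / length(kept)) |>
      filter(.data$frequency >= params$min_peptide_frequency) |>
      arrange(desc(.data$frequency), .data$peptide)
    new_peptides <- head(freq_tbl$peptide, N)
    if (setequal(kept, members) && setequal(new_peptides, peptides)) {
      peptides <- new_peptides
      break
    }
    members <- kept
    peptides <- new_peptides
    if (length(peptides) == 0) return(NULL)
  }

  if (length(members) < params$min_group_size) return(NULL)
  freq_final <- freq_tbl |>
    filter(.data$peptide %in% peptides) |>
    select("peptide", "frequency") |>
    arrange(desc(.data$frequency), .data$peptide)
  new_peptide_group(
    family = family,
    group_id = as.integer(group_id),
    peptides = freq_final,
    members = sort(members)
  )
}

new_peptide_group <- function(family, group_id, peptides, members,
                              function_scores = NULL, n_characterized = 0L) {
  structure(
    list(
      family = family,
      group_id = group_id,
      peptides = peptides,                       # tibble(peptide, frequency)
      members = members,                         # character vector
      function_scores = function_scores %||%
        tibble(ec = character(0), score = integer(0)),
      n_characterized = as.integer(n_characterized)
    ),
    class = "peptide_group"
  )
}

#' @export
print.peptide_group <- function(x, ...) {
  cat(sprintf("<peptide_group> %s group %d: %d members, %d peptides\n",
              x$family, x$group_id, length(x$members), nrow(x$peptides)))
  if (nrow(x$function_scores) > 0) {
    cat("  functions:",
        paste0(x$function_scores$ec, ":", x$function_scores$score,
               collapse = " "), "\n")
  }
  invisible(x)
}

#' Partition one family into conserved-peptide groups
#'
#' Iterates [build_group()]: the largest group is extracted and named group
#' 1, its members are removed from the pool, the next largest becomes group
#' 2, and so on until fewer than `min_group_size` proteins group together.
#' Ungrouped proteins are reported via a message.
#'
#' @param proteins Deduplicated protein tibble for one family.
#' @param family_name Family name (e.g. `"GH5"`).
#' @param params A [ppr_params()] object.
#' @param quiet Suppress the ungrouped-count message.
#' @return A list of `peptide_group` objects in extraction order (possibly
#'   empty).
#' @export
partition_family <- function(proteins, family_name, params = ppr_params(),
                             quiet = FALSE) {
  check_proteins(proteins)
  groups <- list()
  pool <- proteins
  gid <- 1L
  repeat {
    g <- build_group(pool, params, family = family_name, group_id = gid)
    if (is.null(g)) break
    groups[[gid]] <- g
    pool <- pool[!pool$accession %in% g$members, , drop = FALSE]
    gid <- gid + 1L
    if (nrow(pool) == 0) break
  }
  if (!quiet) {
    inform(sprintf("%s: %d group(s), %d of %d proteins grouped",
                   family_name, length(groups),
                   nrow(proteins) - nrow(pool), nrow(proteins)))
  }
  groups
}

#' Attach EC function scores to a group
#'
#' For every EC number borne by at least one member, the function score is
#' the sum, over members labeled with that EC, of the number of distinct
#' group peptides each such member contains. A member with several EC labels
#' contributes its peptide count to each. The number of characterized
#' members is recorded so any reporting threshold (e.g. "more than two
#' characterized members") can be applied downstream.
#'
#' @param group A `peptide_group`.
#' @param proteins Protein tibble holding the member sequences and `ec`
#'   labels.
#' @return The group with `function_scores` (tibble `ec`, `score`, sorted by
#'   decreasing score then EC) and `n_characterized` populated.
#' @export
assign_group_functions <- function(group, proteins) {
  check_proteins(proteins)
  proteins <- ensure_ec(proteins)
  idx <- match(group$members, proteins$accession)
  if (anyNA(idx)) {
    abort(paste0("group member missing from `proteins`: ",
                 group$members[is.na(idx)][[1]]))
  }
  mem <- proteins[idx, , drop = FALSE]
  characterized <- lengths(mem$ec) > 0
  group$member_ec <- map_chr(mem$ec, paste0, collapse = ",")
  group$n_characterized <- sum(characterized)
  if (group$n_characterized == 0) {
    group$function_scores <- tibble(ec = character(0), score = integer(0))
    return(group)
  }
  peps <- group$peptides$peptide
  rows <- pmap(
    list(mem$sequence[characterized], mem$ec[characterized]),
    function(seq, ecs) {
      cnt <- sum(vapply(peps, function(p) grepl(p, seq, fixed = TRUE),
                        logical(1)))
      tibble(ec = ecs, score = cnt)
    }
  )
  group$function_scores <- list_rbind(rows) |>
    summarise(score = as.integer(sum(.data$score)), .by = "ec") |>
    arrange(desc(.data$score), .data$ec)
  group
}

#' Discover a pattern bank from training families
#'
#' Runs [partition_family()] on every family in a labeled training set and
#' assembles the groups, members and EC function scores into a
#' [pattern_bank].
#'
#' @param proteins A protein tibble with an additional `family` column
#'   (training sequences, ideally deduplicated per family with
#'   [deduplicate_proteins()]).
#' @param params A [ppr_params()] object.
#' @param provenance Free-text metadata stored on the bank.
#' @param quiet Suppress per-family progress messages.
#' @return A `pattern_bank` object.
#' @examples
#' \donttest{
#' spec <- synth_family_spec("GH5", n_members = 12, seed = 1)
#' fam <- generate_family(spec)
#' train <- dplyr::mutate(fam$proteins, family = "GH5")
#' bank <- ppr_train(train, quiet = TRUE)
#' glance(bank)
#' }
#' @export
ppr_train <- function(proteins, params = ppr_params(),
                      provenance = "ppr_train", quiet = FALSE) {
  check_proteins(proteins)
  if (!"family" %in% names(proteins)) {
    abort("`proteins` must have a `family` column for training")
  }
  proteins <- ensure_ec(proteins)
  groups <- list()
  for (fam in unique(proteins$family)) {
    fam_prot <- proteins[proteins$family == fam, , drop = FALSE]
    fam_groups <- partition_family(fam_prot, fam, params, quiet = quiet)
    fam_groups <- map(fam_groups, assign_group_functions, proteins = fam_prot)
    groups <- c(groups, fam_groups)
  }
  pattern_bank(groups, params = params, provenance = provenance)
}
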