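# Synthetic enzyme families: random background sequence with planted
# hexapeptide motifs at a controlled per-member frequency, optional EC
# labels, and pure-background decoys -- the statistical structure the
# discovery and annotation stages assume, generated offline.

MOTIF_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
BACKGROUND_ALPHABET <- c("M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of one synthetic enzyme family
#'
#' Describes a family of related proteins: i.i.d. background residues with
#' `n_motifs` planted peptides of length `peptide_len`, each present in a
#' member with probability `motif_frequency`, inserted at non-overlapping
#' random positions. By default motifs are drawn from a residue alphabet
#' disjoint from the background alphabet, so a planted motif can never arise
#' in the background by chance and recovery assertions are exact. Passing
#' the full 20-letter alphabet as `background_alphabet` gives an overlapping
#' "hard mode" where such guarantees become statistical.
#'
#' @param name Family name (e.g. `"GH5"`); also the accession prefix.
#' @param n_members Number of proteins in the family.
#' @param n_motifs Number of planted conserved peptides.
#' @param motif_frequency Probability each member carries each motif; must
#'   exceed the discovery frequency floor (0.20) to be learnable.
#' @param seq_len Protein length in residues (constant across members).
#' @param peptide_len Motif length in residues.
#' @param motif_alphabet,background_alphabet Residue sets for motifs and
#'   background (disjoint by default).
#' @param ec_label Optional EC number carried by labeled members.
#' @param labeled_fraction Fraction of members labeled with `ec_label`.
#' @param seed Integer seed; all randomness derives from `(seed, name)` so
#'   adding a family never perturbs another family's sequences.
#' @return A `synth_family_spec` object.
#' @examples
#' synth_family_spec("GH5", seed = 1)
#' @export
synth_family_spec <- function(name,
                              n_members = 20L,
                              n_motifs = 12L,
                              motif_frequency = 0.8,
                              seq_len = 300L,
                              peptide_len = 6L,
                              motif_alphabet = MOTIF_ALPHABET,
                              background_alphabet = BACKGROUND_ALPHABET,
                              ec_label = NULL,
                              labeled_fraction = 0.5,
                              seed = 1L) {
  spec <- list(
    name = name,
    n_members = as.integer(n_members),
    n_motifs = as.integer(n_motifs),
    motif_frequency = as.numeric(motif_frequency),
    seq_len = as.integer(seq_len),
    peptide_len = as.integer(peptide_len),
    motif_alphabet = motif_alphabet,
    background_alphabet = background_alphabet,
    ec_label = ec_label,
    labeled_fraction = as.numeric(labeled_fraction),
    seed = as.integer(seed)
  )
  if (!nzchar(name)) abort("family name must be non-empty")
  if (spec$n_motifs * spec$peptide_len > spec$seq_len) {
    abort("infeasible: n_motifs * peptide_len exceeds seq_len")
  }
  if (spec$motif_frequency < 0 || spec$motif_frequency > 1) {
    abort("motif_frequency must be in [0, 1]")
  }
  if (spec$labeled_fraction < 0 || spec$labeled_fraction > 1) {
    abort("labeled_fraction must be in [0, 1]")
  }
  if (length(spec$motif_alphabet)^spec$peptide_len < spec$n_motifs) {
    abort("motif alphabet too small for the requested number of motifs")
  }
  structure(spec, class = "synth_family_spec")
}

#' @export
print.synth_family_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_family_spec> %s: %d members, %d motifs @ freq %.2f, len %d%s\n",
    x$name, x$n_members, x$n_motifs, x$motif_frequency, x$seq_len,
    if (is.null(x$ec_label)) "" else paste0(", EC ", x$ec_label)
  ))
  invisible(x)
}

# Deterministic 31-bit stream seed from an integer seed plus string tags,
# so each (family, role) pair gets an independent reproducible stream.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (tag in c(...)) {
    for (code in utf8ToInt(as.character(tag))) {
      h <- (h * 131 + code) %% 2147483647
    }
  }
  as.integer(h)
}

with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

random_peptides <- function(n, len, alphabet) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i) {
      paste0(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

# One member: background residues with the present motifs inserted at
# non-overlapping positions (random gap composition, random motif order).
make_member <- function(motifs, present, total_len, background_alphabet) {
  ins <- motifs[present]
  k <- length(ins)
  bg_len <- total_len - sum(nchar(ins))
  bg <- paste0(sample(background_alphabet, bg_len, replace = TRUE),
               collapse = "")
  if (k == 0) return(bg)
  ins <- ins[sample.int(k)]
  gaps <- as.vector(rmultinom(1, bg_len, rep(1, k + 1)))
  pieces <- character(2 * k + 1)
  at <- 0L
  for (j in seq_len(k + 1)) {
    pieces[[2 * j - 1]] <- substr(bg, at + 1L, at + gaps[[j]])
    at <- at + gaps[[j]]
    if (j <= k) pieces[[2 * j]] <- ins[[j]]
  }
  paste0(pieces, collapse = "")
}

#' Generate one synthetic enzyme family
#'
#' @param spec A [synth_family_spec()].
#' @param role Stream tag (`"train"` or `"query"`): the same spec yields
#'   disjoint, reproducible member sets per role.
#' @return A list with `proteins` (protein tibble; labeled members carry
#'   `ec_label`), `motifs` (character vector of planted peptides) and
#'   `truth` (tibble `accession`, `motif`, `present` recording every
#'   Bernoulli draw).
#' @examples
#' fam <- generate_family(synth_family_spec("GH5", n_members = 5, seed = 42))
#' fam$proteins
#' @export
generate_family <- function(spec, role = "train") {
  stopifnot(inherits(spec, "synth_family_spec"))
  with_stream(derive_seed(spec$seed, spec$name, "motifs"), {
    motifs <- random_peptides(spec$n_motifs, spec$peptide_len,
                              spec$motif_alphabet)
  })
  with_stream(derive_seed(spec$seed, spec$name, role), {
    accession <- sprintf("%s_%s%03d", spec$name,
                         if (role == "train") "t" else "q",
                         seq_len(spec$n_members))
    present <- matrix(
      runif(spec$n_members * spec$n_motifs) < spec$motif_frequency,
      nrow = spec$n_members
    )
    sequences <- vapply(seq_len(spec$n_members), function(i) {
      make_member(motifs, present[i, ], spec$seq_len,
                  spec$background_alphabet)
    }, character(1))
    n_labeled <- round(spec$labeled_fraction * spec$n_members)
    labeled <- sort(sample.int(spec$n_members, n_labeled))
  })
  ec <- rep(list(character(0)), spec$n_members)
  if (!is.null(spec$ec_label)) {
    ec[labeled] <- list(spec$ec_label)
  }
  truth <- tibble(
    accession = rep(accession, each = spec$n_motifs),
    motif = rep(motifs, times = spec$n_members),
    present = as.vector(t(present))
  )
  list(
    proteins = tibble(accession = accession, sequence = sequences, ec = ec),
    motifs = motifs,
    truth = truth
  )
}

#' Generate a training set, query set and truth table
#'
#' Builds an end-to-end benchmark: a training set (one fresh draw of members
#' per family, for [ppr_train()]), a disjoint query set drawn from the same
#' specs, and `n_negatives` pure-background decoy sequences. The truth
#' table maps every query accession to its family (or `NA` for decoys) and
#' EC label, enabling sensitivity/precision measurement with
#' [compare_annotations()].
#'
#' @param specs A list of [synth_family_spec()] objects with unique names.
#' @param n_negatives Number of decoy sequences.
#' @param seed Overrides the per-spec seeds when not `NULL`, so one integer
#'   reproduces the whole benchmark.
#' @param decoy_len Decoy length in residues.
#' @return A list with `training` (protein tibble with `family` column),
#'   `query` (protein tibble), `truth` (tibble `accession`, `family`, `ec`)
#'   and `motifs` (named list of planted peptides per family).
#' @export
generate_benchmark <- function(specs, n_negatives = 50L, seed = NULL,
                               decoy_len = 300L) {
  if (inherits(specs, "synth_family_spec")) specs <- list(specs)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("family names must be unique")
  if (!is.null(seed)) {
    specs <- map(specs, function(s) { s$seed <- as.integer(seed); s })
  }
  train <- map(specs, generate_family, role = "train")
  query <- map(specs, generate_family, role = "query")
  training <- list_rbind(imap(train, function(f, i) {
    mutate(f$proteins, family = nm[[i]])
  }))
  query_tbl <- list_rbind(map(query, "proteins"))
  truth_pos <- list_rbind(imap(query, function(f, i) {
    tibble(
      accession = f$proteins$accession,
      family = nm[[i]],
      ec = map_chr(f$proteins$ec, paste0, collapse = ",")
    )
  }))
  base_seed <- if (is.null(seed)) specs[[1]]$seed else as.integer(seed)
  bg <- specs[[1]]$background_alphabet
  with_stream(derive_seed(base_seed, "decoys"), {
    decoys <- tibble(
      accession = sprintf("decoy_%03d", seq_len(n_negatives)),
      sequence = vapply(seq_len(n_negatives), function(i) {
        paste0(sample(bg, decoy_len, replace = TRUE), collapse = "")
      }, character(1)),
      ec = rep(list(character(0)), n_negatives)
    )
  })
  query_all <- bind_rows(query_tbl, decoys)
  truth <- bind_rows(
    truth_pos,
    tibble(accession = decoys$accession, family = NA_character_,
           ec = NA_character_)
  )
  list(training = training, query = query_all, truth = truth,
       motifs = setNames(map(train, "motifs"), nm))
}
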