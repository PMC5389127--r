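# Shared fixture builders. Everything is generated in code; no stored data.

# A protein tibble from named character vector of sequences.
prot_tbl <- function(seqs, ec = NULL) {
  tibble::tibble(
    accession = names(seqs),
    sequence = unname(seqs),
    ec = ec %||% rep(list(character(0)), length(seqs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a FASTA file into a temp path, return the path.
tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Random amino-acid sequence over the given alphabet.
random_seq <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A planted-core family: n_core proteins all carrying the same `motifs`
# (frequency 1.0) separated by background from a disjoint alphabet, plus
# n_noise pure-background proteins. Deterministic under the caller's seed.
planted_family <- function(motifs, n_core, n_noise = 0, gap = 12,
                           bg = strsplit("MNPQRSTVWY", "")[[1]],
                           prefix = "p") {
  core <- vapply(seq_len(n_core), function(i) {
    gaps <- replicate(length(motifs) + 1, random_seq(gap, bg))
    paste0(paste0(gaps[-length(gaps)], motifs, collapse = ""),
           gaps[[length(gaps)]])
  }, character(1))
  noise_len <- if (n_core > 0) nchar(core[[1]]) else {
    gap * (length(motifs) + 1) + 6 * length(motifs)
  }
  noise <- vapply(seq_len(n_noise), function(i) {
    random_seq(noise_len, bg)
  }, character(1))
  seqs <- c(core, noise)
  names(seqs) <- c(sprintf("%s_core%02d", prefix, seq_len(n_core)),
                   if (n_noise > 0) sprintf("%s_noise%02d", prefix,
                                            seq_len(n_noise)))
  prot_tbl(seqs)
}

# Independent naive scorer: position-by-position substring scan, the oracle
# against which the windowed scorer is checked.
naive_score <- function(sequence, peptides, frequencies) {
  n <- nchar(sequence)
  covered <- rep(FALSE, n)
  matched <- character(0)
  score <- 0
  for (i in seq_along(peptides)) {
    p <- peptides[[i]]
    w <- nchar(p)
    found <- FALSE
    if (w <= n) {
      for (s in 1:(n - w + 1)) {
        if (substr(sequence, s, s + w - 1) == p) {
          found <- TRUE
          covered[s:(s + w - 1)] <- TRUE
        }
      }
    }
    if (found) {
      matched <- c(matched, p)
      score <- score + frequencies[[i]]
    }
  }
  list(frequency_score = score, peptide_count = length(matched),
       coverage = sum(covered), matched = sort(matched))
}

# Hexapeptide motifs over the default motif alphabet, distinct.
fixed_motifs <- function(n) {
  base <- c("ACDEFG", "CDEFGH", "DEFGHI", "EFGHIK", "FGHIKL", "GHIKLA",
            "HIKLAC", "IKLACD", "KLACDE", "LACDEF", "AACCDD", "EEFFGG",
            "HHIIKK", "LLAACC", "DDEEFF", "GGHHII")
  stopifnot(n <= length(base))
  base[seq_len(n)]
}
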