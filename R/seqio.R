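# Protein record I/O: FASTA reading/writing, sequence normalization,
# redundancy removal, EC label tables, six-frame ORF extraction.

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AMBIGUOUS_AA <- c("X", "B", "Z", "U")

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tidy protein table. The header token before the
#' first whitespace becomes the accession; the remainder of the header is
#' dropped. Sequences are upper-cased, gap characters (`-`, `.`) and
#' whitespace are removed, and a record is truncated at its first `*` (stop)
#' character, since downstream peptide matching operates on predicted
#' protein sequences.
#'
#' @param path Path to a FASTA-formatted text file.
#' @param type `"protein"` (default) or `"nucleotide"`. Nucleotide input is
#'   upper-cased and validated over A/C/G/T/N but not stop-truncated.
#' @return A tibble with columns `accession` (character), `sequence`
#'   (character) and, for protein input, `ec` (list of character vectors,
#'   initially empty), one row per FASTA entry in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some description", "MKLGHT", ">b", "GHTMKL"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  set <- if (type == "protein") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  if (length(set) == 0) {
    abort(paste0("no sequences in ", path))
  }
  accession <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (any(accession == "")) {
    abort("FASTA entry with empty header")
  }
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0) {
    abort(paste0("duplicate accession: ", dup[[1]]))
  }
  seqs <- unname(as.character(set))
  if (type == "protein") {
    seqs <- normalize_protein(seqs, accession)
    tibble(
      accession = accession,
      sequence = seqs,
      ec = rep(list(character(0)), length(seqs))
    )
  } else {
    seqs <- toupper(gsub("[\\s.-]", "", seqs, perl = TRUE))
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      abort(paste0("non-ACGTN characters in nucleotide record: ",
                   accession[bad][[1]]))
    }
    tibble(accession = accession, sequence = seqs)
  }
}

# Upper-case, strip gaps/whitespace, truncate at first stop, validate alphabet.
normalize_protein <- function(seqs, accession) {
  seqs <- toupper(gsub("[\\s.-]", "", seqs, perl = TRUE))
  seqs <- sub("\\*.*$", "", seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("record has no usable sequence after normalization: ",
                 accession[empty][[1]]))
  }
  allowed <- paste0(c(STANDARD_AA, AMBIGUOUS_AA), collapse = "")
  bad <- grepl(paste0("[^", allowed, "]"), seqs)
  if (any(bad)) {
    abort(paste0("invalid amino-acid characters in record: ",
                 accession[bad][[1]]))
  }
  seqs
}

#' Write a protein table to a FASTA file
#'
#' @param proteins A tibble with `accession` and `sequence` columns.
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  check_proteins(proteins, require_ec = FALSE)
  set <- Biostrings::BStringSet(setNames(proteins$sequence, proteins$accession))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Internal validator for the protein-table contract.
check_proteins <- function(proteins, require_ec = FALSE) {
  if (!is.data.frame(proteins)) {
    abort("`proteins` must be a data frame")
  }
  need <- c("accession", "sequence", if (require_ec) "ec")
  missing <- setdiff(need, names(proteins))
  if (length(missing) > 0) {
    abort(paste0("`proteins` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(proteins$accession)) {
    dup <- proteins$accession[duplicated(proteins$accession)][[1]]
    abort(paste0("duplicate accession: ", dup))
  }
  invisible(proteins)
}

# Ensure an `ec` list-column exists.
ensure_ec <- function(proteins) {
  if (!"ec" %in% names(proteins)) {
    proteins$ec <- rep(list(character(0)), nrow(proteins))
  }
  proteins
}

#' Remove redundant protein sequences
#'
#' Removes sequences that are 100% identical to another sequence or identical
#' to a contiguous part of a longer sequence. When two sequences are
#' identical, the first-encountered accession survives; when one is a proper
#' substring of another, the longer survives. EC labels of removed records
#' are merged into the surviving record so no functional evidence is lost.
#'
#' The containment scan sorts by decreasing length and checks each candidate
#' against current survivors, which is quadratic in the number of sequences —
#' fine at the scale of a curated family, not meant for millions of records.
#'
#' @param proteins A protein tibble (`accession`, `sequence`, optional `ec`).
#' @return A protein tibble of survivors, in original input order.
#' @examples
#' p <- tibble::tibble(
#'   accession = c("a", "b"), sequence = c("MKLGHT", "KLG"),
#'   ec = list(character(0), "3.2.1.8")
#' )
#' deduplicate_proteins(p)
#' @export
deduplicate_proteins <- function(proteins) {
  check_proteins(proteins)
  proteins <- ensure_ec(proteins)
  n <- nrow(proteins)
  if (n <= 1) {
    return(proteins)
  }
  ord <- order(-nchar(proteins$sequence), seq_len(n))
  survivors <- integer(0)      # row indices into `proteins`
  absorbed <- vector("list", n)  # EC labels absorbed per survivor row
  # Processing order: longest first, ties by input order, so an identical
  # duplicate always meets its first-encountered twin already among survivors
  # and a proper substring always meets its (longer) host first.
  for (i in ord) {
    seq_i <- proteins$sequence[[i]]
    host <- NA_integer_
    for (s in survivors) {
      if (grepl(seq_i, proteins$sequence[[s]], fixed = TRUE)) {
        host <- s
        break
      }
    }
    if (is.na(host)) {
      survivors <- c(survivors, i)
    } else {
      absorbed[[host]] <- union(absorbed[[host]], proteins$ec[[i]])
    }
  }
  survivors <- sort(survivors)
  out <- proteins[survivors, , drop = FALSE]
  out$ec <- map2(out$ec, absorbed[survivors], ~ union(.x, .y %||% character(0)))
  out
}

#' Read an EC label table
#'
#' Reads a two-column tab-separated table `accession<TAB>EC[,EC...]` mapping
#' accessions to one or more EC numbers (partial numbers with `-` allowed).
#'
#' @param path Path to the TSV file (no header).
#' @return A tibble with columns `accession` and `ec` (list of character
#'   vectors).
#' @export
read_ec_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(str_trim(lines))]
  if (length(lines) == 0) {
    return(tibble(accession = character(0), ec = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    abort(paste0("malformed EC table line: ", lines[bad][[1]]))
  }
  tibble(
    accession = vapply(parts, `[[`, character(1), 1L),
    ec = map(parts, ~ unique(str_trim(strsplit(.x[[2]], ",", fixed = TRUE)[[1]])))
  )
}

#' Attach EC labels to a protein table
#'
#' Merges an EC label table (see [read_ec_table()]) into a protein table.
#' Labels for accessions absent from the protein table are ignored with a
#' warning.
#'
#' @param proteins A protein tibble.
#' @param ec_table A tibble with `accession` and `ec` (list) columns, or a
#'   path to a TSV readable by [read_ec_table()].
#' @return The protein tibble with the `ec` list-column populated (unioned
#'   with any existing labels).
#' @export
add_ec_labels <- function(proteins, ec_table) {
  check_proteins(proteins)
  proteins <- ensure_ec(proteins)
  if (is.character(ec_table) && length(ec_table) == 1) {
    ec_table <- read_ec_table(ec_table)
  }
  unknown <- setdiff(ec_table$accession, proteins$accession)
  if (length(unknown) > 0) {
    warn(paste0("ignoring EC labels for ", length(unknown),
                " unknown accession(s): ",
                paste(head(unknown, 5), collapse = ", ")))
  }
  idx <- match(proteins$accession, ec_table$accession)
  proteins$ec <- map2(proteins$ec, idx, function(old, i) {
    if (is.na(i)) old else union(old, ec_table$ec[[i]])
  })
  proteins
}

#' Extract open reading frames from nucleotide fragments
#'
#' Six-frame translation with the standard genetic code. Each stop-to-stop
#' segment of at least `min_len` residues is emitted as a protein record with
#' accession `"<parent>|frame<f>|<start>-<end>"`, where the coordinates are
#' 1-based inclusive nucleotide positions on the forward strand (GenBank
#' convention) and `f` is one of `+1,+2,+3,-1,-2,-3`. Codons containing `N`
#' translate to `X` when ambiguous.
#'
#' @param nucleotides A tibble with `accession` and `sequence` columns
#'   (sequences over A/C/G/T/N), e.g. from `read_fasta(type = "nucleotide")`.
#' @param min_len Minimum ORF length in residues.
#' @return A protein tibble (`accession`, `sequence`, `ec` empty).
#' @export
extract_orfs <- function(nucleotides, min_len = 30L) {
  check_proteins(nucleotides, require_ec = FALSE)
  rows <- pmap(list(nucleotides$accession, nucleotides$sequence),
               orfs_one, min_len = min_len)
  out <- list_rbind(rows)
  if (nrow(out) == 0) {
    return(tibble(accession = character(0), sequence = character(0),
                  ec = list()))
  }
  out$ec <- rep(list(character(0)), nrow(out))
  out
}

orfs_one <- function(parent, seq, min_len) {
  L <- nchar(seq)
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  res <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3
      if (n_codons < 1) next
      sub <- Biostrings::subseq(s, off + 1L, off + 3L * n_codons)
      aa <- suppressWarnings(as.character(
        Biostrings::translate(sub, if.fuzzy.codon = "solve")
      ))
      # stop-to-stop segments: runs of non-stop residues
      segs <- segment_runs(aa)
      for (g in segs) {
        len <- g[["end"]] - g[["start"]] + 1L
        if (len < min_len) next
        # nt coords on the reading strand, 1-based
        nt_a <- off + 3L * (g[["start"]] - 1L) + 1L
        nt_b <- off + 3L * g[["end"]]
        if (strand == 1L) {
          fa <- nt_a; fb <- nt_b
          frame_lab <- paste0("+", off + 1L)
        } else {
          fa <- L - nt_b + 1L; fb <- L - nt_a + 1L
          frame_lab <- paste0("-", off + 1L)
        }
        res[[length(res) + 1L]] <- tibble(
          accession = paste0(parent, "|frame", frame_lab, "|", fa, "-", fb),
          sequence = substr(aa, g[["start"]], g[["end"]])
        )
      }
    }
  }
  list_rbind(res)
}

# Runs of non-'*' residues in a translated frame, as (start, end) aa indices.
segment_runs <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  is_stop <- chars == "*"
  if (all(is_stop)) return(list())
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(!r$values)
  map(keep, ~ c(start = starts[[.x]], end = ends[[.x]]))
}
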