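# The pattern bank: all peptide groups for all families, plus the discovery
# parameters. Canonical on-disk form is a single TSV container with
# section markers #PARAMS, #PEPTIDES, #MEMBERS, #FUNCTIONS.

#' Assemble a pattern bank from peptide groups
#'
#' @param groups A list of `peptide_group` objects (e.g. from
#'   [partition_family()]).
#' @param params The [ppr_params()] used for discovery.
#' @param provenance Free-text metadata (date, input description).
#' @return A `pattern_bank`: a list with tibbles `peptides` (family,
#'   group_id, peptide, frequency), `members` (family, group_id, accession,
#'   ec_labels) and `functions` (family, group_id, ec, score), plus `params`
#'   and `provenance`.
#' @export
pattern_bank <- function(groups, params = ppr_params(),
                         provenance = "") {
  if (length(groups) > 0 &&
      !all(vapply(groups, inherits, logical(1), "peptide_group"))) {
    abort("`groups` must be a list of peptide_group objects")
  }
  peptides <- list_rbind(map(groups, function(g) {
    tibble(family = g$family, group_id = g$group_id,
           peptide = g$peptides$peptide, frequency = g$peptides$frequency)
  }))
  members <- list_rbind(map(groups, function(g) {
    tibble(family = g$family, group_id = g$group_id,
           accession = g$members,
           ec_labels = member_ec_string(g))
  }))
  funs <- list_rbind(map(groups, function(g) {
    if (nrow(g$function_scores) == 0) return(NULL)
    tibble(family = g$family, group_id = g$group_id,
           ec = g$function_scores$ec, score = g$function_scores$score)
  }))
  bank <- structure(
    list(
      params = params,
      peptides = peptides %||% empty_peptides(),
      members = members %||% empty_members(),
      functions = funs %||% empty_functions(),
      provenance = provenance
    ),
    class = "pattern_bank"
  )
  if (nrow(bank$peptides) == 0) bank$peptides <- empty_peptides()
  if (nrow(bank$members) == 0) bank$members <- empty_members()
  if (is.null(bank$functions) || nrow(bank$functions) == 0) {
    bank$functions <- empty_functions()
  }
  validate_pattern_bank(bank)
}

empty_peptides <- function() {
  tibble(family = character(0), group_id = integer(0),
         peptide = character(0), frequency = numeric(0))
}
empty_members <- function() {
  tibble(family = character(0), group_id = integer(0),
         accession = character(0), ec_labels = character(0))
}
empty_functions <- function() {
  tibble(family = character(0), group_id = integer(0),
         ec = character(0), score = integer(0))
}

member_ec_string <- function(g) {
  # member EC labels are recorded during function assignment; groups that
  # never saw labels carry "".
  g$member_ec %||% rep("", length(g$members))
}

validate_pattern_bank <- function(bank) {
  mem <- bank$members
  if (nrow(mem) > 0) {
    dup <- mem |>
      distinct(.data$family, .data$group_id, .data$accession) |>
      count(.data$family, .data$accession) |>
      filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0("accession in more than one group of family ",
                   dup$family[[1]], ": ", dup$accession[[1]]))
    }
    bad <- mem |>
      distinct(.data$family, .data$group_id) |>
      summarise(ok = setequal(.data$group_id, seq_along(unique(.data$group_id))),
                .by = "family") |>
      filter(!.data$ok)
    if (nrow(bad) > 0) {
      abort(paste0("group ids not consecutive from 1 in family ",
                   bad$family[[1]]))
    }
  }
  bank
}

#' @export
print.pattern_bank <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pattern_bank> %d famil%s, %d group(s), %d grouped protein(s), %d peptide(s)\n",
              g$n_families, if (g$n_families == 1) "y" else "ies",
              g$n_groups, g$n_proteins, g$n_peptides))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @rdname pattern_bank
#' @param x A `pattern_bank`.
#' @param ... Unused.
#' @method tidy pattern_bank
#' @export
tidy.pattern_bank <- function(x, ...) {
  x$peptides
}

#' @rdname pattern_bank
#' @method glance pattern_bank
#' @export
glance.pattern_bank <- function(x, ...) {
  grp <- x$members |> distinct(.data$family, .data$group_id)
  with_fun <- x$functions |> distinct(.data$family, .data$group_id)
  tibble(
    n_families = length(unique(x$members$family)),
    n_groups = nrow(grp),
    n_proteins = nrow(distinct(x$members, .data$family, .data$accession)),
    n_peptides = nrow(x$peptides),
    prop_groups_with_function =
      if (nrow(grp) == 0) NA_real_ else nrow(with_fun) / nrow(grp)
  )
}

#' @rdname pattern_bank
#' @param object A `pattern_bank`.
#' @method autoplot pattern_bank
#' @export
autoplot.pattern_bank <- function(object, ...) {
  sizes <- object$members |>
    count(.data$family, .data$group_id, name = "n_members")
  ggplot2::ggplot(sizes,
                  ggplot2::aes(x = factor(.data$group_id),
                               y = .data$n_members)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_x") +
    ggplot2::labs(x = "group", y = "members",
                  title = "Conserved-peptide group sizes")
}

#' Serialize a pattern bank to its single-file TSV container
#'
#' Writes the canonical on-disk form: four tab-separated tables concatenated
#' with section markers `#PARAMS`, `#PEPTIDES`, `#MEMBERS`, `#FUNCTIONS`.
#' Frequencies are written with 6 decimal places.
#'
#' @param bank A `pattern_bank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pattern_bank <- function(bank, path) {
  stopifnot(inherits(bank, "pattern_bank"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  emit <- function(df) {
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  }
  writeLines("#PARAMS", con)
  emit(tibble(key = names(unclass(bank$params)),
              value = as.character(unlist(bank$params))))
  writeLines("#PEPTIDES", con)
  pep <- bank$peptides
  pep$frequency <- sprintf("%.6f", pep$frequency)
  emit(pep)
  writeLines("#MEMBERS", con)
  emit(bank$members)
  writeLines("#FUNCTIONS", con)
  emit(bank$functions)
  invisible(path)
}

#' Read a pattern bank from its single-file TSV container
#'
#' @param path Path written by [write_pattern_bank()].
#' @return A `pattern_bank`.
#' @export
read_pattern_bank <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("pattern bank not found: ", path))
  }
  lines <- readLines(path)
  marks <- grep("^#", lines)
  if (length(marks) == 0 || lines[[1]] != "#PARAMS") {
    abort(paste0("not a pattern bank container: ", path))
  }
  section <- function(name, colclasses) {
    i <- match(name, lines[marks])
    if (is.na(i)) abort(paste0("missing section ", name, " in ", path))
    from <- marks[[i]] + 1L
    to <- if (i < length(marks)) marks[[i + 1L]] - 1L else length(lines)
    block <- lines[seq.int(from, length.out = max(0L, to - from + 1L))]
    if (length(block) <= 1) return(NULL)
    as_tibble(read.delim(text = block, sep = "\t", header = TRUE,
                         colClasses = colclasses, check.names = FALSE,
                         na.strings = "", quote = ""))
  }
  par_tbl <- section("#PARAMS", c("character", "character"))
  par <- as.list(setNames(par_tbl$value, par_tbl$key))
  params <- ppr_params(
    peptide_len = as.integer(par$peptide_len),
    peptides_per_group = as.integer(par$peptides_per_group),
    min_peptides_per_protein = as.integer(par$min_peptides_per_protein),
    min_peptide_frequency = as.numeric(par$min_peptide_frequency),
    min_group_size = as.integer(par$min_group_size),
    max_iterations = as.integer(par$max_iterations)
  )
  pep <- section("#PEPTIDES",
                 c("character", "integer", "character", "numeric"))
  mem <- section("#MEMBERS",
                 c("character", "integer", "character", "character"))
  if (!is.null(mem)) {
    mem$ec_labels[is.na(mem$ec_labels)] <- ""
  }
  fun <- section("#FUNCTIONS",
                 c("character", "integer", "character", "integer"))
  bank <- structure(
    list(
      params = params,
      peptides = pep %||% empty_peptides(),
      members = mem %||% empty_members(),
      functions = fun %||% empty_functions(),
      provenance = ""
    ),
    class = "pattern_bank"
  )
  validate_pattern_bank(bank)
}
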