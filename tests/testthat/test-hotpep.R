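# Hotpep scoring, significance, best-group assignment, function prediction.

test_that("scoring sums frequencies once per matched peptide and unions coverage", {
  g <- tibble::tibble(peptide = c("ACDEFG", "HIKLMN", "WWWWWW"),
                      frequency = c(0.5, 0.8, 0.9))
  sc <- score_against_group("ACDEFGHIKLMN", g)
  expect_equal(sc$frequency_score, 1.3)
  expect_equal(sc$peptide_count, 2L)
  expect_equal(sc$coverage, 12L)
  expect_setequal(sc$matched_peptides[[1]], c("ACDEFG", "HIKLMN"))

  # overlapping matches merge in coverage
  g2 <- tibble::tibble(peptide = c("ACDEFG", "CDEFGH"), frequency = c(1, 1))
  sc2 <- score_against_group("ACDEFGH", g2)
  expect_equal(sc2$frequency_score, 2)
  expect_equal(sc2$peptide_count, 2L)
  expect_equal(sc2$coverage, 7L)

  # a repeated peptide scores once but covers all occurrences
  g3 <- tibble::tibble(peptide = "ACDEFG", frequency = 0.7)
  sc3 <- score_against_group("ACDEFGMMMMACDEFG", g3)
  expect_equal(sc3$frequency_score, 0.7)
  expect_equal(sc3$peptide_count, 1L)
  expect_equal(sc3$coverage, 12L)

  # disjoint alphabets never match
  sc4 <- score_against_group(strrep("MNPQRSTVWY", 20), g)
  expect_equal(sc4$frequency_score, 0)
  expect_equal(sc4$peptide_count, 0L)
  expect_equal(sc4$coverage, 0L)
})

test_that("the windowed scorer equals a naive substring-scan oracle on random inputs", {
  withr::with_seed(31, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (rep in 1:200) {
      seq_len_i <- sample(10:120, 1)
      s <- random_seq(seq_len_i, aa)
      n_pep <- sample(1:15, 1)
      # mix of peptides sampled from the sequence itself and random ones
      peps <- unique(c(
        vapply(seq_len(n_pep), function(i) {
          if (seq_len_i >= 6 && runif(1) < 0.5) {
            st <- sample(seq_len_i - 5, 1)
            substr(s, st, st + 5)
          } else {
            random_seq(6, aa)
          }
        }, character(1))
      ))
      freqs <- round(runif(length(peps), 0.2, 1), 3)
      got <- score_against_group(s, tibble::tibble(peptide = peps,
                                                   frequency = freqs))
      want <- naive_score(s, peps, freqs)
      expect_equal(got$frequency_score, want$frequency_score)
      expect_equal(got$peptide_count, want$peptide_count)
      expect_equal(got$coverage, want$coverage)
      expect_equal(got$matched_peptides[[1]], want$matched)
    }
  })
})

test_that("significance applies the three criteria with the stated boundary semantics", {
  sc <- function(score, count, cov) {
    tibble::tibble(frequency_score = score, peptide_count = count,
                   coverage = cov)
  }
  expect_false(is_significant(sc(1.3, 2L, 12L)))   # too few peptides
  expect_false(is_significant(sc(1.0, 3L, 18L)))   # score not > 1.0
  expect_true(is_significant(sc(1.2, 4L, 10L)))    # coverage 10 passes
  expect_true(is_significant(sc(1.01, 3L, 10L)))   # all at their boundaries
  expect_false(is_significant(sc(1.2, 4L, 9L)))    # coverage below 10
})

test_that("appending residues never decreases score, count or coverage", {
  withr::with_seed(32, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    peps <- unique(vapply(1:20, function(i) random_seq(6, aa), character(1)))
    g <- tibble::tibble(peptide = peps,
                        frequency = runif(length(peps), 0.2, 1))
    s <- random_seq(30, aa)
    prev <- score_against_group(s, g)
    for (step in 1:25) {
      s <- paste0(s, random_seq(6, aa))
      cur <- score_against_group(s, g)
      expect_gte(cur$frequency_score, prev$frequency_score)
      expect_gte(cur$peptide_count, prev$peptide_count)
      expect_gte(cur$coverage, prev$coverage)
      prev <- cur
    }
  })
})

# small two-family bank built by hand for assignment-rule tests
toy_bank <- function() {
  mk <- function(family, group_id, peptides, freqs, members,
                 fun = NULL) {
    g <- hotpepr:::new_peptide_group(
      family, as.integer(group_id),
      tibble::tibble(peptide = peptides, frequency = freqs),
      members
    )
    if (!is.null(fun)) g$function_scores <- fun
    g
  }
  pattern_bank(list(
    mk("GH5", 1, c("ACDEFG", "CDEFGH", "GHIKLM", "HIKLMM"),
       c(1, 1, 0.8, 0.3), paste0("m", 1:5),
       fun = tibble::tibble(ec = "3.2.1.4", score = 20L)),
    mk("GH5", 2, c("ACDEFG", "CDEFGH", "KLKLKL"),
       c(0.6, 0.4, 0.25), paste0("n", 1:5)),
    mk("CBM2", 1, c("AAACCC", "CCCAAA", "CAAACC"),
       c(1, 1, 1), paste0("c", 1:5),
       fun = tibble::tibble(ec = c("3.2.1.8", "3.2.1.156"),
                            score = c(65L, 41L)))
  ))
}

test_that("per family only the highest-scoring significant group wins", {
  bank <- toy_bank()
  # matches GH5 groups 1 (score 3.1) and 2 (score 1.25... not significant)
  q <- prot_tbl(c(q1 = "ACDEFGHIKLMM"))
  hits <- annotate_protein(q[1, ], bank)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$family, "GH5")
  expect_equal(hits$group_id, 1L)
  expect_equal(hits$frequency_score, 1 + 1 + 0.8 + 0.3)

  # multidomain protein hits two families independently
  q2 <- prot_tbl(c(q2 = paste0("ACDEFGHIKL", "MMMM", "AAACCCAAACCC")))
  hits2 <- annotate_protein(q2[1, ], bank)
  expect_setequal(hits2$family, c("GH5", "CBM2"))

  # no significant group -> empty
  q3 <- prot_tbl(c(q3 = strrep("WYWYWY", 10)))
  expect_equal(nrow(annotate_protein(q3[1, ], bank)), 0L)
})

test_that("annotate_proteins builds the per-hit table, family counts and multimap", {
  bank <- toy_bank()
  q <- prot_tbl(c(
    p1 = "ACDEFGHIKLMM",                       # GH5 only
    p2 = paste0("ACDEFGHIKL", "MMMM", "AAACCCAAACCC"), # GH5 + CBM2
    p3 = strrep("WYWYWY", 10)                  # nothing
  ))
  ann <- annotate_proteins(q, bank)
  expect_equal(nrow(ann$hits), 3L)
  expect_equal(ann$family_counts,
               tibble::tibble(family = c("CBM2", "GH5"),
                              n_proteins = c(1L, 2L)))
  mm <- ann$accession_families
  expect_equal(mm$families[mm$accession == "p2"], "CBM2,GH5")
  expect_equal(sum(ann$family_counts$n_proteins), nrow(ann$hits))
  g <- glance(ann)
  expect_equal(g$n_queries, 3L)
  expect_equal(g$n_annotated, 2L)

  # empty input is vacuous, not an error
  empty <- annotate_proteins(q[0, ], bank)
  expect_equal(nrow(empty$hits), 0L)
  expect_equal(nrow(empty$family_counts), 0L)
})

test_that("function prediction ranks EC numbers by descending score", {
  bank <- toy_bank()
  q <- prot_tbl(c(p = "AAACCCAAACCC"))
  ann <- annotate_proteins(q, bank)
  pf <- predict_function(ann)
  expect_equal(pf$ec, c("3.2.1.8", "3.2.1.156"))
  expect_equal(pf$score, c(65L, 41L))
  expect_equal(pf$rank, c(1L, 2L))

  # an uncharacterized winning group yields no prediction rows
  q2 <- prot_tbl(c(p2 = "ACDEFGHKLKLKL"))
  ann2 <- annotate_proteins(q2, bank)
  expect_equal(ann2$hits$group_id, 2L)
  expect_equal(nrow(predict_function(ann2)), 0L)
})

test_that("training proteins self-annotate and decoys never annotate", {
  spec <- synth_family_spec("GH5", n_members = 16, n_motifs = 12,
                            motif_frequency = 0.9, ec_label = "3.2.1.4",
                            seed = 33)
  fam <- generate_family(spec)
  train <- dplyr::mutate(fam$proteins, family = "GH5")
  bank <- ppr_train(train, quiet = TRUE)
  ann <- annotate_proteins(fam$proteins, bank)
  # every grouped training protein is annotated back to its own family
  grouped <- bank$members$accession
  expect_true(all(grouped %in% ann$hits$accession))
  expect_true(all(ann$hits$family == "GH5"))

  # decoys from the disjoint background alphabet are never annotated
  withr::with_seed(34, {
    decoys <- prot_tbl(setNames(
      vapply(1:30, function(i) random_seq(300, strsplit("MNPQRSTVWY", "")[[1]]),
             character(1)),
      sprintf("d%02d", 1:30)
    ))
  })
  expect_equal(nrow(annotate_proteins(decoys, bank)$hits), 0L)
})
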