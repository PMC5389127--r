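# Conserved-peptide group discovery (PPR).

test_that("count_kmers enumerates windows, excludes ambiguity, uses presence semantics", {
  p <- prot_tbl(c(a = "ACDEFGH"))
  k6 <- count_kmers(p, 6)
  expect_setequal(k6$peptide, c("ACDEFG", "CDEFGH"))
  expect_equal(k6$accessions, list("a", "a"))

  # no length-6 window avoids the X
  p2 <- prot_tbl(c(a = "ACXDEFGH"))
  expect_equal(nrow(count_kmers(p2, 6)), 0)

  # a peptide present in two proteins maps to both accessions once each
  p3 <- prot_tbl(c(a = "ACDEFG", b = "ACDEFGACDEFG"))
  k3 <- count_kmers(p3, 6)
  row <- k3[k3$peptide == "ACDEFG", ]
  expect_equal(row$n_proteins, 2L)
  expect_equal(row$accessions[[1]], c("a", "b"))
})

test_that("build_group finds a planted core and excludes background proteins", {
  withr::with_seed(21, {
    fam <- planted_family(fixed_motifs(12), n_core = 6, n_noise = 2)
  })
  params <- ppr_params(min_peptides_per_protein = 10, min_group_size = 5)
  g <- build_group(fam, params, family = "GH5")
  expect_s3_class(g, "peptide_group")
  core <- fam$accession[grepl("core", fam$accession)]
  expect_setequal(g$members, core)
  # all 12 planted motifs retained at frequency 1.0
  expect_true(all(fixed_motifs(12) %in% g$peptides$peptide))
  planted <- g$peptides[g$peptides$peptide %in% fixed_motifs(12), ]
  expect_equal(planted$frequency, rep(1, 12))

  # brute-force check of the group contract: every member contains >= m of
  # the returned peptides; no excluded protein satisfies membership
  m <- params$min_peptides_per_protein
  n_in <- vapply(g$members, function(acc) {
    s <- fam$sequence[fam$accession == acc]
    sum(vapply(g$peptides$peptide, grepl, logical(1), x = s, fixed = TRUE))
  }, integer(1))
  expect_true(all(n_in >= m))
  outside <- setdiff(fam$accession, g$members)
  n_out <- vapply(outside, function(acc) {
    s <- fam$sequence[fam$accession == acc]
    sum(vapply(g$peptides$peptide, grepl, logical(1), x = s, fixed = TRUE))
  }, integer(1))
  expect_true(all(n_out < m))
})

test_that("build_group returns NULL below the size floor or without shared peptides", {
  withr::with_seed(22, {
    small <- planted_family(fixed_motifs(12), n_core = 3)
    lonely <- prot_tbl(setNames(
      vapply(1:6, function(i) random_seq(60), character(1)),
      letters[1:6]
    ))
  })
  expect_null(build_group(small, ppr_params(min_group_size = 5)))
  expect_null(build_group(lonely, ppr_params(min_group_size = 2)))
})

test_that("partition_family extracts disjoint subfamilies largest-first and stops", {
  withr::with_seed(23, {
    sub1 <- planted_family(fixed_motifs(16)[1:8], n_core = 8, prefix = "s1")
    sub2 <- planted_family(fixed_motifs(16)[9:16], n_core = 6, prefix = "s2")
    noise <- planted_family(fixed_motifs(1), n_core = 0, n_noise = 3,
                            prefix = "bg")
  })
  fam <- dplyr::bind_rows(sub1, sub2, noise)
  # peptides_per_group below the combined motif count so the seed's top-N
  # truncation separates the two subfamilies instead of merging their lists
  params <- ppr_params(peptides_per_group = 8,
                       min_peptides_per_protein = 6, min_group_size = 5)
  groups <- partition_family(fam, "GH5", params, quiet = TRUE)
  expect_length(groups, 2)
  expect_equal(vapply(groups, function(g) g$group_id, integer(1)), c(1L, 2L))
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  expect_equal(sizes, c(8L, 6L))
  expect_setequal(groups[[1]]$members, sub1$accession[1:8])
  expect_setequal(groups[[2]]$members, sub2$accession[1:6])
  # disjointness across a family's groups
  expect_equal(anyDuplicated(unlist(lapply(groups, `[[`, "members"))), 0L)
  # monotone non-increasing sizes on disjoint subfamilies
  expect_true(all(diff(sizes) <= 0))
})

test_that("a homogeneous family yields one group and then stops; tiny pools yield none", {
  withr::with_seed(24, {
    fam <- planted_family(fixed_motifs(12), n_core = 20)
    tiny <- planted_family(fixed_motifs(12), n_core = 4)
  })
  groups <- partition_family(fam, "GH5", quiet = TRUE)
  expect_length(groups, 1)
  expect_length(groups[[1]]$members, 20)
  expect_length(partition_family(tiny, "GH5", quiet = TRUE), 0)
})

test_that("stored peptide frequencies are exact member-count ratios", {
  withr::with_seed(25, {
    fam <- dplyr::bind_rows(
      planted_family(fixed_motifs(12), n_core = 10, prefix = "a"),
      planted_family(fixed_motifs(16)[5:16], n_core = 7, prefix = "b")
    )
  })
  groups <- partition_family(fam, "GH5", quiet = TRUE)
  for (g in groups) {
    n_members <- length(g$members)
    seqs <- fam$sequence[match(g$members, fam$accession)]
    recount <- vapply(g$peptides$peptide, function(p) {
      sum(vapply(seqs, grepl, logical(1), pattern = p, fixed = TRUE))
    }, integer(1))
    expect_equal(g$peptides$frequency, unname(recount) / n_members)
  }
})

test_that("function scores sum distinct-peptide counts over characterized members", {
  # toy group: 3 proteins, 10 planted peptides each present in all
  withr::with_seed(26, {
    fam <- planted_family(fixed_motifs(10), n_core = 5)
  })
  fam$ec <- list("3.2.1.8", "3.2.1.8", c("3.2.1.8", "3.2.1.156"),
                 character(0), character(0))
  g <- build_group(fam, ppr_params(min_peptides_per_protein = 8,
                                   min_group_size = 5))
  g <- assign_group_functions(g, fam)
  expect_equal(g$n_characterized, 3L)

  # brute-force recount, independent of the implementation
  expected <- list()
  for (i in 1:5) {
    cnt <- sum(vapply(g$peptides$peptide, grepl, logical(1),
                      x = fam$sequence[[i]], fixed = TRUE))
    for (ec in fam$ec[[i]]) {
      expected[[ec]] <- (expected[[ec]] %||% 0L) + cnt
    }
  }
  got <- setNames(g$function_scores$score, g$function_scores$ec)
  expect_mapequal(as.list(got), expected)
  # a member with two EC labels contributed its count to both
  expect_true(all(c("3.2.1.8", "3.2.1.156") %in% g$function_scores$ec))
})

test_that("planted members and motifs are recovered from synthetic families", {
  # parameter-recovery property: motif frequency >= 0.5, >= 2x size floor
  spec <- synth_family_spec("GH5", n_members = 20, n_motifs = 12,
                            motif_frequency = 0.6, seed = 101)
  fam <- generate_family(spec)
  groups <- partition_family(fam$proteins, "GH5",
                             ppr_params(min_peptides_per_protein = 4),
                             quiet = TRUE)
  expect_gte(length(groups), 1)
  g <- groups[[1]]
  member_recovery <- length(intersect(g$members, fam$proteins$accession)) /
    nrow(fam$proteins)
  motif_recovery <- mean(fam$motifs %in% g$peptides$peptide)
  expect_gte(member_recovery, 0.9)
  expect_gte(motif_recovery, 0.9)
})

test_that("ppr_params validates its constraints and applies the CBM preset", {
  expect_error(ppr_params(peptide_len = 2), "peptide_len")
  expect_error(ppr_params(min_peptides_per_protein = 80), "must not exceed")
  expect_error(ppr_params(min_peptide_frequency = 0), "min_peptide_frequency")
  expect_error(ppr_params(min_group_size = 1), "min_group_size")
  cbm <- ppr_params(preset = "cbm")
  expect_equal(cbm$peptides_per_group, 30L)
  expect_equal(cbm$min_peptides_per_protein, 3L)
  std <- ppr_params()
  expect_equal(std$peptides_per_group, 70L)
  expect_equal(std$min_peptides_per_protein, 10L)
  expect_equal(std$min_peptide_frequency, 0.20)
  expect_equal(std$min_group_size, 5L)
})
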