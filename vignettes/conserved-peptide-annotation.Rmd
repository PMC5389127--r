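---
title: "Conserved-peptide discovery and annotation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved-peptide discovery and annotation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotpepr)
```

## The model

Enzyme families such as the CAZyme families are defined by curation, not by
a single similarity threshold, and their members can share less pairwise
identity than a BLAST search tolerates. What they do share are short
conserved peptides. `hotpepr` treats a family as a union of *groups*: sets
of proteins that share a list of conserved fixed-length peptides, each
peptide present in a defined minimum fraction of the group, each member
containing a defined minimum number of the peptides. Because the same
groups often coincide with enzymatic specificity, the experimentally
characterized members of a group let us score candidate EC numbers for
every other member.

The package has three computational layers:

1. **Discovery (PPR)** learns the groups and their peptide lists from a
   training family.
2. **Annotation (Hotpep)** matches a query protein against every learned
   list and applies three significance criteria.
3. **Evaluation** compares any two annotation sets with
   sensitivity / precision / F1.

A synthetic-family generator closes the loop so that all three layers are
testable offline.

## Discovery: the fixed-point refinement

The constraints a group must satisfy are fixed: peptide length $k$ (default
6), at most $N$ peptides per group (default 70), at least $m$ distinct
group peptides per member (default 10), a per-peptide in-group frequency of
at least 0.20, and at least 5 members. These defaults are the values found
empirically (in the work this approach derives from) to give the best
functional prediction rate over $k$ from 3 to 10, $m$ from 5 to 40 and $N$
from 30 to 200; the CBM preset ($N = 30$, $m = 3$) accommodates the short
carbohydrate-binding-module domains. The original description leaves the
*search procedure* open, so `build_group()` fixes a deterministic one:

1. **Seed**: the $N$ $k$-mers contained in the most unassigned proteins
   (ties broken lexicographically).
2. **Members**: all proteins containing at least $m$ distinct peptides of
   the current list.
3. **Refit**: recompute each peptide's frequency over the members; retain
   the $N$ most frequent with frequency ≥ 0.20 (ties lexicographic).
4. Alternate 2–3 until the member set stops changing (or `max_iterations`).
5. **Prune**: drop members that fell below $m$ distinct peptides of the
   final list and re-filter the list, repeating this small prune until all
   invariants hold simultaneously. At a true fixed point the prune is a
   no-op; it exists because a single pass cannot guarantee the member
   constraint after the frequency re-filter, and it converges in one or two
   passes in practice.

`partition_family()` repeats the extraction, numbering groups in order and
removing members from the pool, and stops when no group of ≥ 5 proteins
remains. Two consequences of this design are worth knowing:

- **Determinism over optimality.** The fixed point reached from the single
  most-shared seed is *taken* as the largest group; there is no
  multi-restart search. This is a reimplementation choice made for
  determinism and desk-scale cost, not a claim about the original
  software.
- **The top-$N$ truncation is what separates co-resident subfamilies.**
  If two disjoint subfamilies each carry fewer than $m$ of the *other's*
  motifs the refinement separates them only when $N$ is small enough that
  the seed cannot hold both motif sets. With the default $N = 70$ and small
  synthetic families the first group can legitimately absorb both
  subfamilies; the grouping still satisfies every stated constraint.

Peptides containing ambiguous residues (X/B/Z/U) are excluded from
counting throughout: they are not reproducible sequence evidence.

Function scores are assigned per group: for every EC number borne by at
least one member, the score is the sum over members labeled with that EC of
the number of distinct group peptides each contains; a member with several
EC labels contributes its count to each. The number of characterized
members is recorded alongside, because the reporting threshold ("more than
two characterized members") is best applied downstream without discarding
evidence from singly-characterized groups.

## Annotation: scoring and significance

`score_against_group()` matches the group's peptides as exact substrings.
A matched peptide contributes its stored in-group frequency once to the
frequency score however often it occurs; *coverage* is the union of residue
positions under all occurrences of all matched peptides. The
union-of-positions reading of coverage is a design choice (the alternative,
a sum of peptide lengths, double-counts overlaps); it makes coverage a
physical extent on the query.

A hit is significant iff

- peptide count ≥ 3 (3 passes),
- frequency score > 1.0 (exactly 1.0 fails — strict), and
- coverage ≥ 10 residues (exactly 10 passes — inclusive).

Per family the protein is assigned to the significant group with the
highest frequency score; ties prefer the larger peptide count, then larger
coverage, then the lower group id — deterministic and favoring stronger
evidence. One winner per family, but winners in *different* families are
never reconciled: multidomain proteins (e.g. a GH domain plus a CBM)
legitimately carry several family annotations, and the family summary
counts each (protein, family) pair once.

Since all peptides in a bank share one length, matching reduces to set
membership over the query's $k$-mer windows — $O(L)$ per group after one
windowing pass — rather than per-peptide substring scans. The test suite
holds this scorer equal to a naive position-by-position oracle on a
thousand random inputs.

## Evaluation

`compare_annotations()` reduces each annotation set to hit keys — by
default the protein accession, because the comparison counts *proteins*; an
(accession, family) mode exists for finer audits — and counts TP, FP, FN by
set algebra. `sensitivity()`, `precision()` and `f1()` implement the three
statistics; each raises an error rather than returning a silent `NaN` when
its denominator is zero. Reported tables round at two decimals, half up
(`round_half_up()`), matching how such benchmark tables are conventionally
printed; raw values are always retained.

Combining several datasets into one accuracy number admits two
non-equivalent rules — pooling the raw counts, or averaging the
per-dataset F1 — and published combined figures are not consistently
derivable from either alone. `combine_comparisons()` therefore reports
both and canonizes neither.

## The synthetic generator

`generate_family()` emulates exactly the structure the discovery stage
assumes: i.i.d. background residues with `n_motifs` planted hexapeptides,
each present in a member with probability `motif_frequency`, inserted at
non-overlapping random positions (a random gap composition keeps the total
length exact). The defaults — 20 members, 12 motifs, frequency 0.8, 300
residues, half the members EC-labeled — describe a compact, high-signal
family: large enough to clear the 5-member floor with room to spare, motif
frequency safely above the 0.20 learnability floor, and sequence length in
the range of a typical single-domain enzyme.

Two guarantees make recovery tests exact rather than statistical:

- **Alphabet disjointness.** Motifs are drawn from a 10-residue alphabet
  disjoint from the 10-residue background alphabet, so a planted motif can
  never arise in the background by chance and the truth table (one recorded
  Bernoulli draw per member × motif) is exact. Passing the full 20-letter
  alphabet as `background_alphabet` gives a "hard mode" in which
  assertions become statistical.
- **Per-family streams.** Every random draw derives from a 31-bit stream
  seeded by (seed, family name, role), so adding a family, or generating
  the query set, never perturbs another family's sequences, and
  training/query sets from one spec are disjoint by construction.

What the generator does *not* emulate: phylogenetic correlation between
members, indel evolution, domain architectures, or compositional bias.
Passing tests on synthetic families therefore demonstrate the
*algorithmic* properties (recovery of planted structure, scoring
correctness, specificity against unrelated sequence) — they do not certify
performance on real proteomes, which depends on the quality and coverage
of the training families.

## Numerical and degenerate-input choices

- Peptide frequencies are exact integer ratios in memory; the on-disk
  container prints six decimals, ample for group sizes into the hundreds
  of thousands.
- Sequence normalization upper-cases, strips gap characters, and truncates
  at the first stop (`*`): annotation operates on predicted proteins, so a
  stop means "sequence ends here" rather than "split into segments".
  A record that normalizes to the empty string is an error naming the
  record.
- Redundancy removal (identical sequences, or sequences identical to a
  contiguous part of a longer one) keeps the first-encountered accession
  for exact duplicates and the longer sequence for containments, and merges
  the EC labels of removed records into the survivor — the labels are
  evidence about an identical sequence, and discarding them would silently
  weaken function scores. The containment scan is quadratic; fine for
  curated families, not for millions of records.
- ORF extraction (optional, off the main path) is a plain six-frame
  stop-to-stop translation with 1-based inclusive forward-strand
  coordinates in the accession; fuzzy codons translate to X.
- `compare` statistics error on empty denominators instead of returning
  `NaN`; an empty annotation run writes summary files with headers and no
  rows rather than failing.

## Problem sizes in the tests

The test-suite and acceptance-script runs use 1–2 families of 12–40
members (300-residue proteins), 40 positive and 50 decoy queries, 200 and
1,000 random scorer-oracle pairs, and one 500-member family for the
frequency-calibration check. These sizes were chosen so the planted
structure is statistically unambiguous (recovery thresholds at 90% and F1
at 0.95 sit far from the expected values under the defaults) while the
whole suite stays interactive.

## Known limitations

- The discovery search is a single-seed fixed point; pathological families
  could admit a larger group than the one found.
- Group quality degrades gracefully but observably as `motif_frequency`
  approaches the 0.20 floor; below roughly 0.4 with default $m$ the member
  constraint starts excluding genuine members (lower $m$, as the CBM
  preset does, compensates).
- EC scores rank hypotheses; they are evidence sums, not probabilities,
  and similar scores for two activities (e.g. 65 vs 41) mean the
  prediction is genuinely ambiguous and needs experimental resolution.
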