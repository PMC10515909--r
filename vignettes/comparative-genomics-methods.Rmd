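---
title: "Methods: RIP scanning, domain enrichment and orthogroup occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RIP scanning, domain enrichment and orthogroup occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entorip)
```

This vignette is the package's account of its methods: the statistics it
computes, the defaults it ships, the modelling choices that were genuinely
open, and what its simulation-based tests do and do not demonstrate.

## The RIP composite index

Repeat-induced point mutation (RIP) converts C to T in repetitive DNA,
preferentially at CpA dinucleotides (equivalently TpG on the reverse
strand). Two classical dinucleotide ratios capture this. The *product*
index TpA/ApT rises as RIP creates TpA dinucleotides; the *substrate*
index (CpA+TpG)/(ApC+GpT) falls as the CpA/TpG substrate pool is depleted.
The composite index is their difference; positive values indicate
RIP-altered sequence. Because reverse complementation maps TA→TA, AT→AT,
CA→TG, AC→GT (and vice versa), the composite index is exactly
strand-invariant, which is why `scan_windows()` can compute it on the
forward strand as stored; the test suite asserts this invariance on random
windows.

### Windowing

`rip_scan_params()` defaults to 1,000 bp windows advanced in 500 bp steps,
the standard grain for genome-wide RIP scans: large enough that the four
dinucleotide sums are in the tens-to-hundreds (stable ratios), small
enough to resolve individual repeat copies. Three conventions needed
fixing where any sliding-window scheme is underdetermined:

* **Terminal short windows.** A trailing window shorter than `window_bp`
  is emitted only when (a) it is at least `min_window_fraction` (default
  0.5) of a full window, so tiny fragments with unstable ratios are never
  scored, and (b) the previous full window does not already end exactly at
  the sequence end — in that case the trailing fragment is a strict suffix
  of already-scored sequence and adds no information. A 2,000 bp sequence
  therefore yields exactly the three windows [0,1000), [500,1500),
  [1000,2000), while a 1,800 bp sequence yields [0,1000), [500,1500) and
  the informative short window [1000,1800).
* **Degenerate windows.** A window where ApT = 0 or ApC+GpT = 0 has an
  undefined index. Such windows are flagged non-evaluable rather than
  assigned a sentinel value, and all three indices are `NA`.
* **Ns.** Hard-masked input is expected; dinucleotides containing N are
  simply not counted, so masked windows lose signal gracefully instead of
  erroring.

### The percent-RIPped summary

`summarize_rip()` counts windows whose composite index is strictly greater
than `rip_threshold` (default 0, the conventional cutoff) and reports
100·positives/evaluable. The denominator is *evaluable* windows, not all
windows: non-evaluable windows carry no evidence either way, and counting
them as negatives would deflate the statistic by an amount that depends
only on masking density. Since the choice is not universal, all three
counts (`n_windows`, `n_evaluable`, `n_rip_positive`) are reported and the
per-window TSV retains every window, so the all-windows convention is
recomputable from the output.

## Domain count matrices and enrichment

`build_domain_count_matrix()` counts *proteins carrying at least one
instance* of a domain, not domain instances — the natural unit when asking
"how many BD-FAE enzymes does this genome encode". Instance counts stay
available in the annotation records (the architecture rules use them).
Callers must supply one record set per gene's representative protein
(conventionally the longest isoform); the builder deliberately does not
guess at isoform collapsing, which is annotation-specific.

`pairwise_domain_enrichment()` tests, for each domain present in at least
`min_genomes_present` genomes (default 2 — a domain seen once has no
cross-genome comparison), every unordered genome pair with a two-sided
Fisher exact test on

    [[c_i, T_i − c_i],
     [c_j, T_j − c_j]]

where `T` is the genome's total number of annotated proteins. The total
proteome is the only genome-level denominator that is always available and
puts genomes of very different gene counts on a common footing; the margin
construction is recorded in the output so alternative backgrounds can be
compared. P-values are Bonferroni-corrected *within a domain* (factor
`choose(G, 2)`, the number of pairs actually tested for that domain): the
scientific unit of inference is "is this domain deviant in this genome",
so the family is that domain's pairwise comparisons, and the per-domain
count of significant pairs is the quantity downstream reports use.
Corrected significance is strict (`p_adj < 0.01` by default).

The accompanying effect size is the fold versus the median count across
*all* genomes (including the focal one — medians are robust to the focal
genome's own deviation, and including it keeps the definition symmetric
across genomes). Folds are always reported ≥ 1 with a separate direction
(`up`/`down`/`at_median`); when the smaller of count and median is zero
the fold is infinite and reported as `Inf`. A minimal representation call
(`representation_calls()`): direction `up` plus at least one significant
pair = overrepresented, symmetrically for underrepresented; both the pair
threshold and the rule are adjustable because any such call rule is a
reporting convention, not a statistic.

### The Fisher test itself

`fisher_exact_two_sided()` is implemented by direct hypergeometric
summation: all tables with the observed margins whose probability does not
exceed the observed table's probability (within a relative tolerance of
1e-7, absorbing floating-point ties) contribute to p. The test suite
checks it against exhaustive enumeration over every 2×2 table with
N ≤ 30 and against `stats::fisher.test()`; the package deliberately keeps
its own implementation as the tested unit and uses the library routine
only as a cross-check. Degenerate tables (a zero margin) are errors, not
p = 1: a margin of zero means the comparison was ill-posed upstream.

`chi_squared_2x2()` is the Pearson statistic on 1 df, *without* continuity
correction by default — the convention under which the published secretion
comparison (17/20 vs 45/105 not-secreted families) reproduces
p ≈ 0.00055; Yates' correction is available as a flag.

`gene_set_domain_enrichment()` compares Pfam frequencies in a gene subset
against its universe with the same Fisher test, at a stricter default
threshold (p ≤ 0.001, inclusive, matching the reporting convention for
gene-set screens), odds ratio (a·d)/(b·c) with `Inf` when b·c = 0, and a
`NO_PFAM` pseudo-domain so "genes with no annotation at all" is tested
like any domain. When the 2×2 is degenerate (e.g. set = universe) the row
is flagged and never significant.

## Architecture rules

Rules are data, not code: a label plus conjunctive constraints on
per-protein instance counts, with disjunction expressed as multiple
clauses (`DICER_ALT` = Ribonuclease_3 ∧ (DEAD ∨ PAZ)). The built-ins
cover the circadian clock (FRQ, WC1, WC2, rhodopsin), the RNAi pathway
(RDRP, DICER, AGO, DICER_ALT) and RID candidates (≥ 2 DNA_methylase
instances, the tandem-methylase signature of the RIP-required
methyltransferase). Two readings were open:

* "one GATA and one PAS_3" is read as *at least one* (except the explicit
  "no PAS_9" in WC2, which is exactly zero). Pfam routinely reports
  tandem repeats of a domain, and a strict "exactly one" would silently
  drop biologically identical candidates. The strict reading is one
  constraint edit away since bounds are data.
* Adjacency of the two DNA_methylase instances in RID candidates is *not*
  checked: annotation tables carry no domain coordinates. This is a known,
  documented divergence from coordinate-aware curation.

Proteins may match several labels (a Dicer-dimer protein with
Ribonuclease_3 and DEAD matches both Dicer rules); candidate tallies are
reported per label without a tie-break hierarchy. WC1 and WC2 are mutually
exclusive by construction (PAS_9 ≥ 1 vs = 0), which the suite
property-tests.

## Orthogroup occupancy

Orthogroups (consumed in the de facto `Orthogroups.tsv` dialect) are
classified by the exact set of species with at least one member: core
(all species), species-specific (one), shared subset (otherwise). Genes
are unassigned (no orthogroup), assigned-species-specific, or
assigned-shared; the first two form the potentially species-specific set.
The species universe is an explicit argument so a larger clustering can be
sliced to a defined analysis set deterministically.

The expression-support filter removes potentially species-specific genes
with *summed* estimated counts below 5 across the pooled samples (strict:
4.9 is removed, 5.0 retained). Summing matches a pooled-library threshold;
both the aggregation and the threshold are parameters of
`occupancy_params()` since other designs may want a mean or per-sample
rule. Genes absent from the expression table count as zero — transcript
quantifiers routinely omit zero-count genes, so absence is evidence of
non-expression, not missing data.

`summarize_genome_catalog()` takes the catalog as given (if the input
mixes multiple strains per species, the medians are over strains); even-n
medians are the midpoint of the central order statistics, the convention
of standard statistics software.

## The simulators

The generators exist so that every analysis stage has inputs with known
truth. What they emulate, and what they do not:

* `simulate_genome()` — i.i.d. background at a set GC fraction (default
  0.5) carrying non-overlapping copies of repeat-family master units;
  default 500 kb with 30% repeat content (five 2 kb families × 15
  copies), the repeat density regime of the genomes this analysis style
  targets, at desk scale. RIP is modelled as independent per-site C→T at
  CpA and G→A at TpG (the dominant RIP context) at rate 0.2 in targeted
  copies — exactly the dinucleotide shifts the composite index measures,
  which is what makes parameter-recovery tests interpretable. It does
  *not* simulate LTR element structure, insertion-age divergence
  (Kimura landscapes) or GC heterogeneity; a pass on simulated data shows
  the scanner recovers a planted dinucleotide signal, not that any
  particular real genome is RIPped.
* `simulate_domain_annotations()` — per-(genome, domain) protein counts
  Poisson(λ = 20) over 500 synthetic domains, totals 5,000 proteins per
  genome, with domain occurrences assigned to proteins sampled from the
  genome's protein pool (so proteins carry several domains, as real
  proteins do). Planted enrichments multiply λ in chosen cells; planted
  architectures append proteins with exact rule patterns plus near-miss
  decoys that must not be recovered. Counts are independent across
  domains, which real domain families are not; the null calibration
  therefore checks the test's error control under its own model, not
  under inter-domain correlation.
* `simulate_orthogroups()` — occupancy classes are planted exactly as
  requested; per-gene expression totals follow a zero-inflated log-normal
  (p0 = 0.3, meanlog = log 50, sdlog = 1.5) split across 27 pooled
  samples, mimicking a sparse pooled in vivo RNA-seq profile where a
  substantial minority of annotated genes has no read support.

All randomness flows from one integer seed per simulator call; identical
seeds give byte-identical outputs (asserted in the suite), and internal
sub-streams are derived so adding a stage does not perturb another's
draws.

## Problem sizes and calibration checks

The suite and the acceptance script run at sizes chosen to make every
check complete in seconds to a couple of minutes on one CPU: the Fisher
implementation is verified against exhaustive enumeration over all 2×2
tables with N ≤ 30; the pairwise-enrichment null calibration uses 200
replicates of the 7-genome × 500-domain Poisson table (the family-wise
false-positive fraction at corrected p < 0.01 must stay ≤ 0.015, and
observed values sit well below); planted 8-fold enrichments must be
recovered in ≥ 95% of 200 replicates; RIP recovery uses the default
500 kb genome at rates 0 vs 0.2, requiring ≥ 80% of windows fully inside
mutated repeats to score positive; architecture and occupancy recovery are
exact by construction and asserted exactly.

## Known limitations

* The RIP scanner implements the composite index only; GC-corrected or
  LTR-specific RIP callers are out of scope, as are divergence landscapes.
* Enrichment assumes the protein-total margin; if a different background
  (e.g. only domain-annotated proteins) is wanted, build the matrix with
  those totals.
* Architecture classification is annotation-driven: it can only be as
  good as the domain calls, performs no HMM scanning, and cannot apply
  coordinate-level curation (adjacency, domain order).
* The published cross-phylum genome-catalog medians can only be recomputed
  where that compiled catalog table is available; the package ships the
  operation and its tests, not the third-party table.
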