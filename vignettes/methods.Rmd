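---
title: "Methods: cryptic-splicing quantification and hotspot-resolved cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cryptic-splicing quantification and hotspot-resolved cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptsplice)
```

# Scope

This vignette documents the quantitative model behind each module, the
parameters of the synthetic generators and what they can and cannot stand in
for, and the numerical and design decisions that affect results.

# PSI at constitutive anchors

A splice junction is identified by `chrom:intron_start-intron_end:strand`
(1-based, inclusive intron coordinates, the STAR `SJ.out.tab` convention).
Cryptic splice-site usage is measured *locally*: every junction competes only
with junctions that share its constitutive anchor — the annotated donor
(5' end of the intron: `intron_start` on `+`, `intron_end` on `-`) or
acceptor on the other side.

`build_anchor_groups()` emits an anchor group for every (chrom, strand, side,
position) shared by at least two observed junctions, or by a single junction
when the site belongs to an annotated intron. Junctions with unknown strand
(STAR code 0) inherit the strand of the unique gene span containing them;
a junction whose recorded strand contradicts the annotated intron it matches
is an error, not a silent reinterpretation.

For quantification each junction is assigned to **one** group. Many junctions
touch two groups (their donor's and their acceptor's); the assignment prefers
a group containing a canonical (annotated-intron) member, breaking remaining
ties toward the donor side. This makes the denominator the canonical site the
cryptic junction competes at. Within its assigned group, for sample $s$:

$$\mathrm{PSI}_{j,s} = \frac{n_{j,s}}{\sum_{k \in \mathrm{group}(j)} n_{k,s}}$$

using uniquely-mapping split reads only. If the group total for a sample is
below `min_coverage = 15`, every cell of that group/sample is `NA` (missing,
not zero — an unobserved junction is not evidence of absence at low depth).
Per anchor group the PSIs of informative cells sum to 1 by construction;
`compute_psi(per_group = TRUE)` exposes the per-group detail used to verify
this invariant in the test suite.

# Differential events

`delta_psi()` computes, per junction and non-reference genotype,
$\Delta\mathrm{PSI} = \bar{\mathrm{PSI}}_{\text{mut}} -
\bar{\mathrm{PSI}}_{\text{ref}}$ over informative samples, requiring at least
`min_samples_per_group = 2` informative samples on each side; otherwise the
contrast is `NA` and the row is flagged indeterminate. The ranking score is
the maximum $|\Delta\mathrm{PSI}|$ across genotypes; ties are broken by
(chrom, start, end) so that ranking is deterministic.

## Event classes and frame arithmetic

`classify_event()` compares a cryptic junction with the annotated introns of
the same gene, in this order: *degenerate* (identical to an annotated
intron), *exon skip* (donor of annotated intron $i$ joined to the acceptor of
annotated intron $j > i$ of the same transcript), *alternative 3' acceptor*
(shared donor, shifted acceptor — the canonical SF3B1 lesion), *alternative
5' donor*, *intron retention proxy* (junction strictly inside an annotated
intron), and *other*. `inserted_or_deleted_nt` is the canonical intron length
minus the cryptic intron length (for skips, minus the summed skipped exon
lengths); `frame_shift` is true iff that quantity is not a multiple of 3.

## PTC and the 50-nt NMD rule

`predict_ptc_nmd()` rebuilds the mature transcript as the exon union (plus
any annotated intron the cryptic junction retains part of) minus the cryptic
intron, extracts its sequence (reverse-complemented on `-`), and translates
from the annotated CDS start. A stop is a *premature* termination codon iff
it lies upstream (in cryptic-transcript coordinates) of the canonical stop's
mapped position. NMD is predicted iff the PTC sits strictly more than
`nmd_rule_nt = 50` nt upstream of the last exon–exon junction — the
boundary case at exactly 50 nt does not trigger NMD, and a transcript that
gains no stop is reported `nmd_predicted = FALSE` (not `NA`, which is
reserved for events outside the CDS or with a lost start codon).

## Hotspot specificity

`call_specificity()` declares an event *present* in a genotype when
$\Delta\mathrm{PSI} \ge 0.10$ with at least 2 informative samples, *absent*
when $|\Delta\mathrm{PSI}| \le 0.05$, and *indeterminate* otherwise. Labels
follow: `"<genotype>-specific"` (present in exactly one), `"shared"`,
`"ambiguous"` (indeterminate blocking a call), `"none"`. The deliberate gap
between 0.05 and 0.10 prevents borderline events from flipping between
"specific" and "shared" under resampling noise. The pairwise Jaccard index
of present-sets summarizes how disjoint two hotspots' programs are; the
nonoverlap claim corresponds to Jaccard near 0 between E592K and K700E.

# Synthetic generators

Raw patient RNA-seq and registry records are not redistributable, so seeded
generators produce structurally faithful substitutes. They are study
conditions, not tuning knobs.

## Junction counts

`simulate_junction_counts()` draws, per sample and planted event, an anchor
total $N \sim \mathrm{Poisson}(\texttt{depth\_per\_anchor} = 200)$ and a
cryptic count $k \sim \mathrm{Binomial}(N, p)$ with
$p \sim \mathrm{Beta}$ parameterized by mean `psi` and intra-class
correlation `dispersion` $\rho = 0.01$ (clone-to-clone variability;
$\rho = 0$ degenerates to a pure binomial). Defaults follow the experimental
design being modelled: genotypes WT / K700E / E592K with four independent
clones per genotype, baseline cryptic usage 0.02 in non-target genotypes, and
planted $\mathrm{PSI}_{\text{mut}} = 0.5$. Every simulation emits a truth
table, and `write_fixtures()` persists annotation, junction tables, sample
map, truth and cohort as plain text that regenerates byte-identically from
the same seed. The generator reproduces realistic *count noise* and
*genotype-specific usage*; it does not model mapping artifacts, GC bias,
unannotated transcription, or linked events on one transcript.

## Clinical cohort

`simulate_cohort()` assigns variants with probabilities proportional to
published case counts (K700E 1820 : K666N 198 : E622D 102 : K666R 85 :
E592K 29), then draws a diagnosis from per-variant distributions matching the
published partition (e.g. E592K splits roughly evenly across MDS-SLD/MLD,
MDS-EB and AML with almost no MDS-RS, while E622D is overwhelmingly MDS-RS).
Co-mutations are Bernoulli per gene with probabilities contrasting E592K
(ASXL1 0.83, RUNX1 0.51, STAG2 0.29, DNMT3A 0.029) against exon 14–16
hotspots (0.09, 0.11, 0.03, 0.21); ring-sideroblast percentages are normal
with mean 37, SD 15 for canonical hotspots versus mean 0.5 for E592K, with
20% missing; 80% of cases carry the full 35-gene panel and 20% a reduced
panel, exercising the panel-aware denominators. Survival times are
exponential with medians 1.5 y (OS) / 0.9 y (LFS) for E592K versus 5 y / 4 y
otherwise; censoring uses a competing exponential calibrated to the
configured censoring fraction. Exponential survival is a simplification —
real registry hazards are not constant — but it preserves the ordering,
medians, and censoring structure the statistics consume.

# Cohort statistics

* **Partitioning** — `partition_distribution()` tabulates each variant's
  share of each diagnosis and tests every diagnosis pair with a two-sided
  Fisher exact test on (variant vs all other variants) × (diagnosis A vs B).
  Percentages print half-up to one decimal, switching to two decimals below
  0.1% so rare variants do not print as "0.0" (1/1327 → "0.08").
* **Fisher convention** — `fisher_exact_two_sided()` sums hypergeometric
  probabilities not exceeding the observed table's (relative tolerance 1e-7,
  the standard convention). A zero margin is degenerate with p = 1 by
  convention and flagged. The odds ratio is the sample ad/bc when all cells
  are positive; with a zero cell the conditional-MLE and a 0.5-corrected
  ratio are reported instead, since the sample ratio is 0 or infinite.
* **Co-mutation landscape** — per-gene frequencies with a case contributing
  to a gene's denominator only when its sequencing panel covered that gene;
  Fisher p-values, star tiers on raw p, and Benjamini–Hochberg q-values
  across the tested genes.
* **RS criteria** — WHO 2016 thresholds are strict inequalities: the
  SF3B1-mutated pathway requires > 5% ring sideroblasts, the unmutated
  pathway > 15%; unknown RS propagates as NA rather than ineligible.
* **Clinical comparisons** — `compare_clinical()` uses the two-sided
  Mann–Whitney test: exact for small untied samples (matching an explicit
  permutation enumeration), otherwise the tie-corrected normal approximation
  without continuity correction; all-tied data is degenerate (p = 1), not an
  error.
* **Survival** — `km_estimate()` is the product-limit estimator with the
  median defined as the smallest observed time with $S(t) \le 0.5$ (NA if
  the curve never reaches 0.5, e.g. under heavy censoring);
  `logrank_test()` is the 1-df Mantel–Cox test, undefined (flagged) when no
  events occur.

# Numerical choices

* Half-up rounding (`round_half_up`) is used for printed percentages because
  R's banker's rounding would print 2.25 as "2.2".
* All PSI arithmetic is double precision with invariants verified to 1e-9;
  no rounding occurs before statistics, only at printing.
* Exact tests are delegated to `stats::fisher.test` / `stats::wilcox.test`
  and survival to the `survival` package; the test suite verifies each
  against independent hand-rolled oracles (hypergeometric enumeration,
  permutation enumeration, product-limit and O−E/V recomputation).
* Seeded routines restore the caller's RNG state, so simulations compose
  without side effects on user code.

# Problem sizes

The defaults target desk-scale runs: tens of genes, hundreds of junctions,
12 samples, cohorts of a few hundred to a few thousand cases. Everything is
vectorized per junction table; the full pipeline at default settings runs in
seconds and the complete test suite, including the simulation-based recovery
and type-I-error checks, in a few minutes on one CPU.
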