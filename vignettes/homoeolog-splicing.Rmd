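---
title: "Homoeolog expression and splicing in reciprocal-cross hybrids: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homoeolog expression and splicing in reciprocal-cross hybrids: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeosplice)
```

This vignette is the package's own account of its methods: the models
and rules it implements, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## 1. The measurement model

A reciprocal-cross hybrid carries one gene copy from each parental
species (BSB and TC). A short read can be attributed to its subgenome
of origin only at **species-specific SNPs**: aligned columns of the
per-gene pairwise coordinate map where the two parents' allele sets are
*disjoint*. Disjointness is the operative notion — a heterozygous
parental locus {G,T} against {A} is still diagnostic, while {A,G}
against {G} is not, because a read showing G there proves nothing. The
caller therefore emits a column iff

1. the observed allele sets of the two parents are disjoint,
2. each parent's set is identical across its three biological
   replicates (a `majority` mode relaxes this to majority-of-3),
3. coverage is at least one read in all six parental libraries, and
4. the column is not an indel column of the map.

A base enters a replicate's allele set only if its within-column
fraction is at least `min_minor_frac = 0.2`; RNA-seq error rates are
two orders of magnitude below this, so the rule suppresses error bases
without excluding genuine heterozygous alleles (expected fraction 0.5).
The value is a parameter of `call_species_snps()`.

**Read partitioning.** A short read is called for the parent matched by
a strict majority of its calls at covered SNPs; ties, zero coverage and
majorities matching neither set are ambiguous. Long reads use a
stricter inclusive 85% concordance threshold: with per-read error rates
of long-read platforms, a simple majority would misassign too easily,
and 17/20 matches is accepted while 16/20 is not. Base calls at
positions absent from the SNP table are skipped (counted and
reported), not an error: the discovery filters legitimately drop loci,
and partitioning then uses the loci that survived. A `strict = TRUE`
mode turns unknown positions into a hard data-integrity error for use
with frozen SNP tables.

**Gene-level counts.** Per-gene homoeolog expression is the sum of
parent-allele read counts over all of the gene's species-specific SNPs.
A read covering several SNPs contributes to each of them; this matches
the field's SNP-sum convention and preserves the homoeolog *ratio*, but
it makes the per-gene totals over-dispersed relative to read counts —
one reason the differential-expression layer estimates its dispersion
from the data rather than assuming Poisson noise.

## 2. The mean ± 2 SD outlier filter

Abnormal per-SNP counts (mapping artifacts, hybrid-specific mutations)
are discarded when they fall outside mean ± 2 sample standard
deviations. The axis of the rule matters. Applied literally across the
three biological replicates of one SNP, the rule can never fire: for
$n$ values, $\max_i |x_i - \bar x| \le \frac{n-1}{\sqrt n}\, s$, which
is $2/\sqrt 3 \approx 1.15$ sample SDs at $n = 3$ (and $\sqrt{n-1} =
1.41$ with the population SD) — below 2 in either convention. The
package therefore defaults to filtering **across the SNPs of one gene
within one library**, where a single inflated locus genuinely sticks
out, and ships the literal `across_replicates` mode with a unit test
proving its vacuity. The same bound shows the rule cannot fire for any
group smaller than six values, so genes with few SNPs pass unfiltered;
the planted-outlier simulations accordingly evaluate removal on genes
with at least eight SNPs. Sample SD ($n-1$) is used throughout.

## 3. The exact negative-binomial test

Differential expression of each homoeolog between the two hybrids is a
two-group comparison of three replicates against three. The test is
the conditional exact test on NB counts: with a common dispersion
$\varphi$, a group of $n$ replicates with per-replicate mean $\mu$ has
an NB-distributed sum with size $n/\varphi$; conditioning on the pooled
total $T$, the probability of a split $(y, T-y)$ is the normalised
product of the two sum densities at the pooled mean estimate, and the
two-sided p-value sums the probabilities of all splits no more probable
than the observed one (summation, not doubling — the standard
exact-test convention; at $\varphi = 0$ this reduces to the binomial
split of a Poisson total). The conditional argument requires
exchangeable library sizes, so counts are first scaled to the
geometric-mean library size of the stratum and rounded; the rounding
error is negligible at the count depths where the test has power.

$\varphi$ is estimated by pooled method of moments: per gene and group,
$(s^2 - m)/m^2$ on library-scaled counts, averaged within genes across
groups (so planted differences do not inflate it), clamped at zero, and
averaged over genes. On simulated data this recovers $\varphi = 0.1$
within $\pm 0.03$ at 2000 genes, and the resulting test is calibrated:
type-I error $5.0\% \pm 1\%$ at $p < 0.05$ over 5000 null genes at
$\mu = 200$, with BH-realised FDR under 7% and sensitivity above 90%
for $|\log_2 \mathrm{FC}| = 2$. Tagwise (per-gene) dispersion shrinkage
and trended dispersion are deliberately out of scope: with a common
simulated dispersion they would add machinery without changing the
calibration being verified. The FDR layer is `stats::p.adjust("BH")`
behind `bh_adjust()`, with DEGs at FDR ≤ 0.05 inclusive.

## 4. Alternative-splicing event classification

Isoforms are **exon chains**: sorted, disjoint 0-based half-open
intervals. All unordered chain pairs of a gene are compared; the event
rules, stated once and unit-tested from every direction, are:

* **SE** — an exon of one chain absent from the other, whose intron
  spans it with both outer splice sites shared.
* **RI** — an intron of one chain lying inside a single exon of the
  other with the outer exon edges shared.
* **A5SS / A3SS** — two introns sharing one boundary and differing at
  the other; the side (donor vs acceptor) is strand-aware, and the
  alternative-boundary exons must share their far edge — without that
  guard every skipped exon would also register as a spurious splice-site
  shift.
* **MXE** — two internal exons, each exclusive to one chain,
  non-overlapping, with both flanking splice sites shared.
* **AP** — the chains share every intron and differ only at the
  transcript-terminal boundaries (alternative first-exon start or
  last-exon end). This operationalises the "alternative position /
  alternative site" category as terminal-boundary differences.
* **OTHER** — a chain pair that differs but matches none of the named
  patterns yields one OTHER event anchored at the hull of the
  differing region, so *distinct chains always produce at least one
  event*.

Named events and OTHER are mutually exclusive per pair: OTHER is the
catch-all for otherwise unclassified pairs, not a residual on top of
named events. Events are deduplicated by `(gene, type, anchor
coordinates)` — the unit counted in the summary tables is the event,
not the supporting chain pair. Classification is symmetric in the two
chains, and flipping the strand exchanges A5SS and A3SS with identical
anchors. The whole rule set is verified event-for-event against an
independently written brute-force implementation on over a thousand
random chain pairs, and planted events of all six named types are
recovered with precision = recall = 1 on clean chains.

**Cross-homoeolog sharing** maps every anchor coordinate of a BSB event
through the pairwise coordinate map (interval ends map via the
preceding column plus one) and requires an exact type-and-coordinates
match on the TC side. **High-AS genes** are those with ≥ 5
deduplicated events (inclusive), with a helper for the cross-tissue
intersection.

**Full-length reads** require strictly more than 300 bp plus 5′ primer,
3′ primer and poly(A) tail, mirroring long-read library structure.

## 5. The synthetic cohort

`sim_config()` fixes the study conditions; `simulate_cohort()` builds
the whole study deterministically from one seed (the acceptance script
re-derives all sub-seeds from `--seed`).

| parameter | default | why |
|---|---|---|
| `n_genes` | 150 | desk-scale stand-in for the genome-wide ortholog set |
| `exons_per_gene` | 4–14 | brackets the parental means (≈ 9 exons/gene) |
| `exon_len`, `intron_len` | 80–300, 80–400 bp | kilobase-scale CDS at ~9 exons |
| `snp_rate` | 0.02 /bp | fixed differences between well-diverged congeners |
| `het_rate` | 0.05 | some parental loci heterozygous but still diagnostic |
| `depth` | 50 /gene/replicate | typical bulk RNA-seq per-gene coverage |
| `tissues`, replicates | 3 × 3 | the study design: gonad, liver, muscle |
| `bias_frac`, `bias_log2` | 0.2, 1 | a minority of genes with 2:1 homoeolog bias |
| `de_frac`, `de_log2` | 0.1, 2 | planted maternal-effect DE, 4-fold |
| `error_rate` | 0.002 | Illumina-scale substitution error |
| `fl_rate` | 0.9 | matches ~88–90% full-length read fractions |
| `long_read_depth` | 20 /gene/hybrid | isoform-level support without bulk |

Ortholog pairs share exon structure; TC introns are independently
lengthened (at `intron_indel_rate`) and the extra columns are flagged
as indels in the coordinate map, which is exact elsewhere — planted
SNPs are exonic and therefore never on indel columns. Within-pair CDS
lengths differ through independent UTR trims. Hybrid short reads are
emitted as already-aligned records in the pair's BSB coordinate frame
with base calls at covered SNP columns; no read aligner is involved,
because alignment is an external-tool stage and the package's
computation starts downstream of it. Read counts are Poisson; the NB
noise used to calibrate the exact test comes from the separate
`simulate_nb_counts()` generator, which is the right tool for that
question (known $\varphi$, no SNP-sum convolution). Planted outlier
cells duplicate the reads covering one SNP in one library at 10-fold
inflation, with the artifact calls confined to that locus. Maternal
origin is a label plus mitochondrial reads mapping exclusively to one
mitogenome — enough to exercise the ≥ 95% maternal-origin call without
modelling organelle biology.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: alignment and mapping bias
(reads arrive pre-assigned to genes), realistic error profiles and
quality scores, intergenic sequence and genome contiguity, isoform
abundance structure, GC or length biases, and biological dispersion
beyond the planted effects. Conclusions about the *rules* (SNP calling,
partitioning, event classification, test calibration) transfer;
conclusions about aligner-dependent artifacts do not.

## 6. Numerical and design choices

* **Coordinates** are 0-based half-open internally; GTF export converts
  to 1-based inclusive, BED export stays 0-based half-open.
* **Percentages** are rounded half-even to two decimals (R's `round()`),
  which reproduces the published renderings (88.29, 18.96, 90.78, …)
  and makes every table emission bit-reproducible; each summary table
  self-audits its totals on construction.
* **Thresholds are inclusive** where stated as minima: 85% long-read
  concordance (17/20 assigns), FDR ≤ 0.05, ≥ 5 counts in all
  replicates, ≥ 5 events for high-AS genes; the full-length length rule
  is strict (> 300 bp).
* **Ties** for the best hit in reciprocal-best-hit pairing exclude the
  gene (with a warning) rather than picking arbitrarily; ties in
  short-read majority votes are ambiguous.
* The comparative structure statistics use the **Wilcoxon signed-rank
  test** on paired exon-number and CDS-length differences — a robust
  choice for counts and lengths where the original significance test is
  unnamed — and Pearson correlation with its t-test p-value.
* Exact-test p-values compare split probabilities with a relative
  tolerance of $10^{-10}$ so that floating-point noise cannot exclude
  the observed split from its own tail sum.
* The similarity scorer for synthetic orthology is k-mer containment
  (k = 10) with `evalue_like = 1 - score`; it stands in for an external
  aligner whose selection logic — unique mutual best hits above a
  significance threshold — is the implemented content.

## 7. Problem sizes used in the tests

The shipped test-suite and acceptance runs use cohorts of 12–50 genes,
an oracle comparison over 1000+ random chain pairs, 35 genes × 6
planted event types (≥ 30 of each) for recovery, depth 200 with 30
genes for ratio recovery (mean absolute log2 error ≈ 0.10, the
binomial-sampling floor at ~600 reads/gene; the ±0.15 criterion is an
aggregate bound because a per-gene bound is unattainable at that
depth), and 5000 null + 500 DE genes for test calibration. These sizes
were chosen as the smallest at which each property is measured well
away from its noise floor.

## 8. Known limitations

* The SNP-sum counting convention inflates gene-level variance through
  multi-SNP reads; the common-dispersion estimate absorbs the average
  effect but per-gene multiplicity differences remain, so cohort-level
  DEG lists are slightly anticonservative compared with the clean NB
  calibration. Real analyses share this property.
* With more than one AP event planted on the same gene, pairwise
  comparison of the two AP variants creates a third, unplanted terminal
  difference; the generator therefore plants at most one AP per gene.
* The `across_replicates` filter mode exists to document its own
  vacuity; it is not a usable filter at n = 3.
* The orthology module pairs genes one-to-one; paralogous expansions
  beyond unique-best exclusion are out of scope.
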