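---
title: "breedsnp: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breedsnp: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsnp)
```

This vignette is the package's own account of the statistics it
implements, the conventions it fixes, and the design choices that were
genuinely open. The pipeline turns per-sample RNA-seq SNP call tables from
a breeds × ages × replicates cattle cohort into filtered, breed-resolved
SNP databases, counts candidate-gene hits, validates markers with exact
population-genetics tests, and checks breed clustering with a
neighbor-joining phylogeny.

## Data model and conventions

A **call** is one single-base substitution observed in one library:
chromosome, 1-based position, reference base (`A/C/G/T/N`), called
alternate base, total read depth, alternate-supporting depth, and the
derived *accuracy* `100 × alt_depth / total_depth` (percent). Indel
records are parsed, counted, and excluded from every downstream stage.

Conventions fixed at the boundary, because the surrounding literature
mixes them freely:

* **Coordinates** are 1-based inclusive internally (VCF convention). BED
  input (0-based half-open) is converted on read (`start + 1`), and the
  conversion round-trips.
* **Chromosome names** are normalized by stripping a leading `chr` or
  `BTA` prefix and upper-casing, so `chr25`, `BTA25` and `25` are the same
  chromosome.
* **Site identity** for all cross-sample set algebra is
  `(chrom, pos, alt_base)`. The reference base is carried but not part of
  the key, and multi-allelic VCF records are split into one call per
  alternate so the set algebra stays per-allele.
* Parsers **reject** records violating the call invariants
  (`1 ≤ alt_depth ≤ total_depth`, consistent accuracy, alternate different
  from reference unless the reference is N, duplicate keys) rather than
  repairing them silently; errors name the offending line.

## The two stringent filters

The filter retains a call iff it has at least `min_alt_reads` supporting
reads *and* meets the accuracy criterion — either `accuracy ≥ threshold`
or, for the exact filter, `accuracy = threshold`. The two study filters
are `filter_spec(10, 90)` and
`filter_spec(10, 100, accuracy_is_exact = TRUE)`.

Two readings of "10 SNP reads per base" are defensible: ten reads
supporting the variant, or ten reads of total coverage. The phrase
modifies the variant-supporting reads, so `depth_on = "alt"` is the
default; `depth_on = "total"` is available, and under the exact-100 %
filter the two coincide (all reads support the variant). Accuracy
comparisons are done on integers (`100 · alt ≥ threshold · total`), never
on floating-point quotients, so "exactly 100 %" means
`alt_depth == total_depth` with no epsilon.

Reported percentages follow the reporting conventions of the tables they
mirror: retention/reduction percentages are rounded half-up to 1 decimal,
mapping percentages to 2 decimals, and the per-bull average count is a
*truncated* quotient (`per_bull_average()` exposes `"truncate"` and
`"round"`). These conventions are what make the published figures —
95.7 %/96.4 % reduction, the per-breed 4.6/4.0, 4.5/3.6, 3.8/3.1
retentions, 93.04 %/94.39 % properly-paired, 765,326 SNPs per bull —
reproducible to the printed digit from the published count tables, which
ship in `inst/extdata/`. The Hereford mapping table is included as
printed, but its properly-paired percentage is not asserted anywhere: its
published columns are internally inconsistent (no column-sum convention
reproduces the printed 83.46 %), so it is displayed, not validated.

## Occurrence categorization

`tabulate_occurrence()` counts, per site and breed, the carrier samples;
`categorize()` derives the four designations: *ANY* (≥ 1 carrier),
*breed-specific* (all of the breed's samples), *ANY UNIQUE* and
*breed-specific UNIQUE* (additionally absent from every sample of every
other breed). "All samples" means all of that breed in the cohort at
hand — six in the study design, but taken from the sample metadata, never
hard-coded. The implication chain
(`all_unique ⇒ all ⇒ any`, `all_unique ⇒ any_unique ⇒ any`) is a tested
invariant.

One definition was genuinely open: against *which* database is
"absent from every other breed" evaluated? The default is the **raw**
(unfiltered) occurrence — a site is disqualified from UNIQUE status if any
other-breed sample carries it at any depth. This is the stricter reading
and guards against a low-coverage other-breed observation being filtered
away and thereby manufacturing uniqueness. `unique_vs = "filtered"` gives
the laxer reading. The same reasoning is visible in the synthetic checks:
with realistic per-read error, planted breed-unique sites are frequently
disqualified under the raw rule by stray error reads in other breeds —
which is exactly the artifact the stringent filters exist to control.

**De-novo SNPs** are filtered calls whose reference base is N (unresolved
assembly regions). Counts are reported per filter; whether a "both
filters" figure pools or intersects them is ambiguous in the source
analyses, so both are computable. **Reference-error candidates** are sites
carried by *every* sample of *every* breed with the *same* alternate
allele, every call passing the active filter; a discordant alternate at
the position disqualifies it (a true reference error implies one true
base). The all-samples-same-allele rule is this package's explicit
interpretation of "correction by successive annotation", and outputs label
it as such.

## Candidate-gene hits

A call hits a gene iff the normalized chromosomes match and
`start ≤ pos ≤ end` (both ends inclusive); overlapping genes each receive
the hit. Interval overlap runs on `GenomicRanges::findOverlaps()`. Hits
default to call-level events (a site carried by k samples counts k), with
`distinct_sites = TRUE` counting unique site keys per cell, because the
per-age hit tables this mirrors do not say which they use; both modes are
exported. Ranking is by total hits, descending, with lexicographic
tie-break so results are deterministic. The shipped 76-locus panel
(`qtl_cg_loci_synthetic.tsv`) uses the six gene symbols named in the
motivating analysis plus bovine growth/development gene symbols, with
*synthetic coordinates* — it is a schema-complete stand-in, and users
substitute their own interval table.

## Exact population-genetics tests

All tests are *probability* tests (the Genepop default): the p-value is
the total conditional probability of outcomes no more probable than the
observed one.

**Hardy–Weinberg.** Conditional on allele counts `(n_A, n_B)` in a sample
of `n` diploids, a genotype array `(n_AA, n_AB, n_BB)` has probability
`n! / (n_AA! n_AB! n_BB!) · 2^{n_AB} · n_A! n_B! / (2n)!`. Enumeration
iterates every feasible heterozygote count (the parity class of `n_A`),
which is exact, deterministic, and cheap at validation-cohort sizes — it
is the default. The Markov-chain estimator (a Metropolis chain proposing
`n_AB ± 2`) exists for parity with the cited methodology and reports a
batch-mean standard error; its defaults follow Genepop-like settings
(dememorization 1000, 20 batches × 5000 iterations), all configurable and
recorded in the result object. Monomorphic input returns p = 1 with a
flag.

**Genic/genotypic differentiation.** Under the null of identical
distributions across breeds, a breeds × alleles (or breeds × genotypes)
table with fixed margins is multivariate hypergeometric:
`P = (Π rowᵢ!)(Π colⱼ!) / (N! Π cellᵢⱼ!)`. Small tables are enumerated
recursively with margin pruning; `method = "auto"` switches to a
Metropolis chain over 2×2 rectangle moves (acceptance ratio
`b·d / ((a+1)(e+1))`) when a table-count bound exceeds `enum_limit`
(default 2·10⁵). Rows with zero observations are dropped with a warning; a
table with a single observed category returns p = 1 (no differentiation
is testable).

**Numerics.** Factorials are `lfactorial()` throughout; "no more probable
than observed" uses an additive log-scale tie tolerance of 10⁻⁹ —
comfortably above the ~10⁻¹² accumulation noise of log-factorial sums and
far below any genuine probability gap at these sample sizes, so exact ties
(e.g. mirror tables) are always included and non-ties never are.
`stats::fisher.test()` implements the same tail definition for r × c
tables and serves as an independent oracle in the test suite; it is
deliberately not the implementation, so the two routes stay independent.

**Fisher's combined test** over L loci uses `−2 Σ ln pᵢ` against
χ²(2L). Zero p-values (possible only from Monte-Carlo estimates) are
floored at a configurable 10⁻¹⁶ with a warning; at L = 1 the chi-square
identity returns the input p exactly, which is tested.

## Phylogeny

Per-sample SNP databases are presence/allele calls, not genotypes, so the
distance is the Hamming fraction of the site-key universe on which two
samples' presence differs (allele mismatches at a position are two
differing keys). Tree building is classical neighbor joining via
`ape::nj()`; NJ is exact on additive distances, which the tests exploit by
reconstructing random 5–8-taxon trees from their cophenetic matrices.
Negative branches (possible on non-additive input) are clamped to zero
with the deficit moved to a sister edge, preserving path lengths through
the parent. Bootstrap resamples universe sites with replacement and counts
bipartition recovery with `ape::prop.clades(rooted = FALSE)`; supports are
integer percents on node labels and the whole procedure is deterministic
given a seed. Breed monophyly asks whether a breed's leaves form one side
of a bipartition of the unrooted tree (trivially true for singleton or
all-but-one sets). Likelihood tree inference is intentionally out of
scope: the clustering claim under test is topological, and NJ with site
bootstrap tests it deterministically at desk scale.

## The synthetic cohort generator

`cohort_design()` defaults *are* the emulated study conditions: 3 breeds ×
ages {6, 9, 12} months × 2 biological replicates (18 libraries, 6 bulls
per breed).

| parameter | default | meaning |
|---|---|---|
| `n_sites` | 5000 | variant sites; matches the scale used in the recovery checks |
| `frac_breed_unique_fixed` | 0.10 | sites fixed-alternate in exactly one breed (round-robin owner) |
| `frac_ref_N` | 0.02 | sites with reference base N (de-novo ground truth) |
| `fst` | 0.3 | Balding–Nichols divergence; breed frequency ~ `Beta(p(1−F)/F, (1−p)(1−F)/F)` around ancestral `p ~ U(0.05, 0.95)` |
| `mean_depth` | 50 | negative-binomial read depth per site |
| `depth_dispersion` | 5 | NB size; RNA-seq depth is strongly overdispersed |
| `min_depth` | 0 | optional depth floor; set ≥ the filter's read threshold for guaranteed planted-truth recovery |
| `error_rate` | 0.005 | per-read miscall probability, Illumina-scale |

Genotypes are drawn per sample under within-breed Hardy–Weinberg
proportions (`Binomial(2, freq)`); alternate-supporting reads are
`Binomial(depth, (g/2)(1−e) + (1−g/2)e)`; a call is emitted only with ≥ 1
supporting read. One master seed drives everything, with per-sample
substreams derived from a deterministic hash of `(seed, sample_id)` so
output does not depend on sample ordering, and a fixed seed reproduces the
simulation byte for byte.

Two points about what passing these checks does and does not show:

* Planted-truth recovery is *conditional on depth*: with NB depth at mean
  50, a few sites per thousand fall below the 10-read threshold in some
  sample, so the recovery checks run with `min_depth = 10`, which is the
  stated precondition of the recovery property, not a tuning knob.
* With ~4500 Balding–Nichols shared sites, a handful realize genotype
  patterns (fixed-alternate in all six samples of one breed, absent
  elsewhere) that are *by construction* indistinguishable from planted
  breed-unique sites. Recovery is therefore asserted two ways: every
  planted site is recovered, and the recovered set exactly equals the
  brute-force evaluation of the all-unique predicate on the realized
  genotype ground truth.

The generator does **not** emulate: read-level artifacts (mapping bias,
strand bias, base-quality structure), linkage disequilibrium between
sites, expression-level variation in depth across genes, or allele-specific
expression. Tests passing on this generator validate the *set algebra,
filtering arithmetic and statistics*, not robustness to those artifacts.

## Problem sizes and runtime choices

The shipped checks use sizes chosen to exercise each property well past
its small-sample regime while staying desk-scale: 10,000 random calls for
the filter oracle; a 5,000-site, 18-sample cohort for categorization
recovery and phylogeny (200 bootstrap replicates); 200 random allele
configurations for the HWE normalization identity; 50 random genotype
tables for chain-vs-enumeration consistency; 1,000 HWE-true loci of 50
individuals at allele frequency 0.3 for the type-I error check (exact
tests are conservative, so the rejection rate at α = 0.05 sits at or
below nominal).

## Known limitations

* The VCF reader requires per-sample `AD` annotations and one sample per
  file; multi-sample VCFs must be split upstream.
* Per-locus differentiation p-values are reported raw, with Fisher's
  combined statistic as the only across-locus aggregation — no per-locus
  multiplicity correction is applied, matching the validation methodology
  this mirrors.
* The distance is presence-based; heterozygote/homozygote information is
  not used in the phylogeny.
* `enumerate_tail_prob()` is exponential in table size; `method = "auto"`
  exists precisely because large tables must go through the chain.
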