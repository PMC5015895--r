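# breedsnp

Breed-specific SNP database construction and validation from RNA-seq
variant calls.

## The problem

RNA-seq of a tissue yields, per library, millions of candidate
single-nucleotide substitutions, most of them sequencing noise. For a
multi-breed cattle cohort (three breeds of young bulls, sampled at 6, 9 and
12 months with two biological replicates per cell — 18 libraries), the
analysis this package implements turns those raw per-sample call tables
into a small, highly reliable, breed-resolved SNP database and then
validates it:

1. **Stringent filtering.** Two filters on each call: at least 10
   variant-supporting reads with call *accuracy* (alternate reads / total
   reads × 100) ≥ 90 %, and the same read threshold with accuracy exactly
   100 %. Reduction and retention percentages are reported globally and as
   per-bull breed averages.
2. **Four-way occurrence categorization.** For each breed, a site is
   **ANY** (detected in ≥ 1 of the breed's samples), **breed-specific**
   (detected in all of them), **ANY UNIQUE** (ANY, and absent from every
   sample of every other breed) or **breed-specific UNIQUE** (both).
3. **De-novo and reference-error flags.** Filtered calls at positions where
   the reference base is unknown (N) are de-novo SNP candidates; sites
   where *every* sample of *every* breed carries the same alternate allele
   are putative reference/annotation errors.
4. **Candidate-gene/QTL hits.** Filtered calls are counted inside a panel
   of 76 growth-and-development gene intervals (1-based, inclusive at both
   ends) per breed and age, and genes are ranked by total hits.
5. **Population-genetics validation** (Genepop-style, on KASP genotype
   tables): exact Hardy–Weinberg probability tests conditional on allele
   counts, with the genotype-array probability
   `P = n! / (n_AA! n_AB! n_BB!) · 2^n_AB · n_A! n_B! / (2n)!`,
   by full enumeration or a Markov chain with batch-mean standard errors;
   exact genic/genotypic differentiation on breeds × alleles (genotypes)
   contingency tables under the multivariate hypergeometric null; and
   Fisher's combined probability `−2 Σ ln p_i ~ χ²(2L)` over loci.
6. **Phylogeny.** Per-sample site-presence Hamming distances, a
   neighbor-joining tree with site bootstrap, and a breed-monophyly check.

A synthetic cohort generator (`simulate_cohort()`) draws per-breed allele
frequencies from a Balding–Nichols beta model around ancestral
frequencies, plants breed-unique fixed variants and reference-N sites, and
emits read-level calls through a negative-binomial depth / binomial
miscall model — so every downstream stage can be tested against known
ground truth.

## Worked example

```r
library(breedsnp)

design <- cohort_design(n_sites = 2000, fst = 0.3, seed = 42)
sim <- simulate_cohort(design)
sim
#> cohort_sim: 2000 sites, 18 samples, 24601 emitted calls

spec90 <- filter_spec(10, 90)            # >=10 alt reads, accuracy >= 90%
filtered <- apply_filter(sim$db, spec90)
reduction_report(sim$db, filtered)
#> reduction_report: 24,601 raw -> 13,215 filtered (retention 53.7%, reduction 46.3%)
#>       breed n_samples raw_avg filtered_avg retention_pct
#> 1  Hereford         6    1365          740          54.2
#> 2  PolishHF         6    1375          734          53.4
#> 3 PolishRed         6    1358          728          53.6

category_counts(categorize_breed_specific(sim$db, spec90))
#>       breed  any all any_unique all_unique
#> 1  Hereford 1177 359          4          3
#> 2  PolishHF 1169 339          8          6
#> 3 PolishRed 1167 348          7          5

# published-table arithmetic: Hereford per-bull averages 754,719 raw and
# 34,658 filtered SNPs give the printed 4.6% retention
retention_pct_by_breed(754719, 34658)
#> [1] 4.6

# exact Hardy-Weinberg probability test, (n_AA, n_AB, n_BB)
hwe_exact(c(12, 20, 18))
#> exact test (enumeration): p = 0.248476

# genic differentiation between two breeds' allele counts
contingency_exact_test(rbind(PolishHF = c(25, 7), PolishRed = c(6, 22)))
#> exact test (enumeration): p = 2.15558e-05

tree <- bootstrap_support(filtered, replicates = 100, seed = 42)
is_breed_monophyletic(tree, sim$db$samples)
#>  Hereford  PolishHF PolishRed
#>      TRUE      TRUE      TRUE
```

The simulated cohort's calls retain ~54 % under the ≥ 90 % filter (mild
simulated noise); the `all_unique` rows recover the planted breed-unique
sites that survive sampling; and with divergence `fst = 0.3` the three
breeds cluster as clades.

A thin command-line wrapper over the same functions ships in
`inst/scripts/breedsnp` (subcommands `import`, `simulate`, `filter`,
`categorize`, `cg-hits`, `popgen`, `phylo`).

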