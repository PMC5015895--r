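# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A random calls table (not necessarily passing any filter) for oracle
# tests; depths chosen to straddle the 10-read / 90% / 100% thresholds.
random_calls <- function(n, samples = sprintf("s%02d", 1:6), seed = 1) {
  withr::with_seed(seed, {
    total <- sample(1:40, n, replace = TRUE)
    alt <- pmax(1L, rbinom(n, total, runif(n, 0.3, 1)))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt_base <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    data.frame(
      sample_id = sample(samples, n, replace = TRUE),
      chrom = as.character(sample(1:29, n, replace = TRUE)),
      pos = sample.int(5e7, n),                    # distinct keys w.h.p.
      ref_base = ref, alt_base = unname(alt_base),
      total_depth = total, alt_depth = alt,
      accuracy_pct = 100 * alt / total,
      stringsAsFactors = FALSE)
  })
}

# Cohort sample sheet: 3 breeds x 3 ages x 2 replicates (18 libraries).
study_samples <- function(breeds = c("A", "B", "C")) {
  grid <- expand.grid(replicate = 1:2, age_months = c(6L, 9L, 12L),
                      breed = breeds, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s%02d", grid$breed, seq_len(nrow(grid))),
             breed = grid$breed, age_months = grid$age_months,
             replicate = grid$replicate, stringsAsFactors = FALSE)
}

# One call row, defaulting to a clean filter-passing SNP.
call_row <- function(sample_id, chrom = "1", pos = 100L, ref = "G",
                     alt = "C", total = 12L, alt_d = 12L) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref_base = ref, alt_base = alt, total_depth = as.integer(total),
             alt_depth = as.integer(alt_d),
             accuracy_pct = 100 * alt_d / total, stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "breedsnp")
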