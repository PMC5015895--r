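#' Cohort design for the synthetic multi-breed generator
#'
#' Describes a breeds x ages x replicates RNA-seq cohort and the parameters
#' of the variant-site simulation. Defaults mirror the study layout this
#' package targets: 3 cattle breeds, bulls sampled at 6, 9 and 12 months,
#' two biological replicates per cell (6 bulls per breed, 18 libraries).
#'
#' Sites are of three kinds: `shared` sites whose per-breed allele
#' frequencies diverge from an ancestral frequency under a Balding-Nichols
#' beta model with divergence `fst`; `breed_unique_fixed` sites planted
#' fixed-alternate in exactly one breed and fixed-reference elsewhere (the
#' ground truth for breed-specific UNIQUE recovery); and `ref_N` sites whose
#' reference base is unknown (N), emulating unresolved assembly regions that
#' give rise to de-novo SNP candidates.
#'
#' @param breeds ordered breed labels.
#' @param ages_months ordered ages at sampling.
#' @param replicates_per_cell biological replicates per breed x age cell.
#' @param n_sites number of variant sites to simulate.
#' @param frac_breed_unique_fixed fraction of sites planted breed-unique.
#' @param frac_ref_N fraction of sites with reference base N.
#' @param fst divergence parameter in [0, 1).
#' @param mean_depth expected reads per site (negative binomial).
#' @param depth_dispersion negative-binomial size parameter; RNA-seq depth
#'   is strongly overdispersed, default 5.
#' @param min_depth floor applied to simulated depths (0 = none); set it at
#'   or above the filter's read threshold to guarantee exact
#'   planted-truth recovery under zero error.
#' @param error_rate per-read miscall probability in [0, 0.5).
#' @param seed integer master seed; per-sample substreams are derived
#'   deterministically from `(seed, sample_id)` so results do not depend on
#'   sample order.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(breeds = c("Hereford", "PolishRed", "PolishHF"),
                          ages_months = c(6, 9, 12),
                          replicates_per_cell = 2,
                          n_sites = 5000,
                          frac_breed_unique_fixed = 0.1,
                          frac_ref_N = 0.02,
                          fst = 0.3,
                          mean_depth = 50,
                          depth_dispersion = 5,
                          min_depth = 0,
                          error_rate = 0.005,
                          seed = 1) {
  stopifnot(length(breeds) >= 1, !anyDuplicated(breeds),
            replicates_per_cell >= 1, n_sites >= 0,
            frac_breed_unique_fixed >= 0, frac_ref_N >= 0,
            frac_breed_unique_fixed + frac_ref_N <= 1,
            fst >= 0, fst < 1, mean_depth > 0, depth_dispersion > 0,
            min_depth >= 0, error_rate >= 0, error_rate < 0.5)
  structure(list(breeds = breeds, ages_months = ages_months,
                 replicates_per_cell = as.integer(replicates_per_cell),
                 n_sites = as.integer(n_sites),
                 frac_breed_unique_fixed = frac_breed_unique_fixed,
                 frac_ref_N = frac_ref_N, fst = fst,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 min_depth = as.integer(min_depth),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "cohort_design")
}

# Deterministic 31-bit hash of a string, combined with the master seed to
# derive per-sample RNG substreams.
string_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + seed) %% 2147483647)
}

#' Simulate a multi-breed RNA-seq SNP cohort with known ground truth
#'
#' Generates per-sample SNP calls, a matching genotype matrix, and a
#' ground-truth table for a [cohort_design()].
#'
#' Per site: an ancestral allele frequency is drawn uniformly on
#' (0.05, 0.95) and per-breed frequencies from
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)` (Balding-Nichols;
#' `fst = 0` copies the ancestral frequency). Planted breed-unique sites are
#' fixed alternate (frequency 1) in their owner breed and absent elsewhere.
#' Per sample and site: a true genotype dosage `g ~ Binomial(2, freq)` under
#' within-breed Hardy-Weinberg proportions; read depth from a negative
#' binomial (`mu = mean_depth`, `size = depth_dispersion`, floored at
#' `min_depth`); and alternate-supporting reads
#' `Binomial(depth, g/2 (1 - e) + (1 - g/2) e)` with per-read miscall rate
#' `e`. A call record is emitted only when at least one read supports the
#' alternate. Output is byte-identical for a fixed seed, and per-sample
#' draws use substreams derived from `(seed, sample_id)`.
#'
#' @param design a [cohort_design()].
#' @return list of class `cohort_sim` with elements `db` (a [snp_db()]),
#'   `genotypes` (a [genotype_matrix()] of the true genotypes),
#'   and `truth` (data.frame: site, category, ancestral and per-breed
#'   frequencies, with the dosage matrix as attribute `dosage`).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  grid <- expand.grid(replicate = seq_len(d$replicates_per_cell),
                      age_months = d$ages_months, breed = d$breeds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%02dm_R%d", grid$breed, grid$age_months,
                        grid$replicate),
    breed = grid$breed, age_months = as.integer(grid$age_months),
    replicate = as.integer(grid$replicate), stringsAsFactors = FALSE)

  n <- d$n_sites
  empty_calls <- data.frame(sample_id = character(), chrom = character(),
                            pos = integer(), ref_base = character(),
                            alt_base = character(), total_depth = integer(),
                            alt_depth = integer(), accuracy_pct = double(),
                            stringsAsFactors = FALSE)
  if (n == 0L) {
    truth <- data.frame(chrom = character(), pos = integer(),
                        ref_base = character(), alt_base = character(),
                        category = character(), owner_breed = character(),
                        ancestral_freq = double(), stringsAsFactors = FALSE)
    gm <- genotype_matrix(
      matrix(character(), nrow(samples), 0),
      samples[, c("sample_id", "breed")],
      data.frame(locus = character(), allele_normal = character(),
                 allele_mutant = character(), stringsAsFactors = FALSE))
    return(structure(list(db = snp_db(empty_calls, samples),
                          genotypes = gm, truth = truth),
                     class = "cohort_sim"))
  }

  # --- ground truth, drawn in the master stream ---
  truth <- with_seed(d$seed, {
    n_unique <- round(d$frac_breed_unique_fixed * n)
    n_refN <- round(d$frac_ref_N * n)
    category <- rep("shared", n)
    if (n_unique > 0) category[seq_len(n_unique)] <- "breed_unique_fixed"
    if (n_refN > 0) category[n_unique + seq_len(n_refN)] <- "ref_N"
    owner <- rep(NA_character_, n)
    if (n_unique > 0)
      owner[seq_len(n_unique)] <- rep_len(d$breeds, n_unique)
    chrom <- as.character(sample.int(29L, n, replace = TRUE))
    pos <- sample.int(120000000L, n)  # distinct positions, collision-free keys
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    ref[category == "ref_N"] <- "N"
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    p_anc <- stats::runif(n, 0.05, 0.95)
    tr <- data.frame(chrom = chrom, pos = pos, ref_base = ref,
                     alt_base = unname(alt), category = category,
                     owner_breed = owner, ancestral_freq = p_anc,
                     stringsAsFactors = FALSE)
    for (b in d$breeds) {
      f <- if (d$fst == 0) p_anc else
        stats::rbeta(n, p_anc * (1 - d$fst) / d$fst,
                     (1 - p_anc) * (1 - d$fst) / d$fst)
      f[category == "breed_unique_fixed"] <-
        ifelse(owner[category == "breed_unique_fixed"] == b, 1, 0)
      tr[[paste0("freq_", b)]] <- f
    }
    tr
  })

  # --- per-sample substreams: genotypes, depths, alt reads ---
  dosage <- matrix(0L, n, nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  call_list <- vector("list", nrow(samples))
  for (k in seq_len(nrow(samples))) {
    sid <- samples$sample_id[k]
    f <- truth[[paste0("freq_", samples$breed[k])]]
    call_list[[k]] <- with_seed(string_seed(d$seed, sid), {
      g <- stats::rbinom(n, 2L, f)
      dosage[, k] <- g
      depth <- stats::rnbinom(n, size = d$depth_dispersion, mu = d$mean_depth)
      depth <- pmax(depth, d$min_depth)
      e <- d$error_rate
      p_alt <- (g / 2) * (1 - e) + (1 - g / 2) * e
      alt_reads <- stats::rbinom(n, depth, p_alt)
      emit <- alt_reads >= 1L
      data.frame(sample_id = sid, chrom = truth$chrom[emit],
                 pos = truth$pos[emit], ref_base = truth$ref_base[emit],
                 alt_base = truth$alt_base[emit],
                 total_depth = depth[emit], alt_depth = alt_reads[emit],
                 accuracy_pct = 100 * alt_reads[emit] / depth[emit],
                 stringsAsFactors = FALSE)
    })
  }
  calls <- do.call(rbind, call_list)
  if (is.null(calls) || nrow(calls) == 0L) calls <- empty_calls
  db <- snp_db(calls, samples)

  codes <- c("AA", "AB", "BB")
  gm <- genotype_matrix(
    matrix(codes[t(dosage) + 1L], nrow(samples), n),
    samples[, c("sample_id", "breed")],
    data.frame(locus = site_key(truth$chrom, truth$pos, truth$alt_base),
               allele_normal = truth$ref_base,
               allele_mutant = truth$alt_base, stringsAsFactors = FALSE))
  attr(truth, "dosage") <- dosage
  structure(list(db = db, genotypes = gm, truth = truth),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("cohort_sim:", nrow(x$truth), "sites,", nrow(x$db$samples),
      "samples,", nrow(x$db$calls), "emitted calls\n")
  invisible(x)
}

#' Count ground-truth sites by planted category
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @return named integer vector over `breed_unique_fixed`, `ref_N`,
#'   `shared`; sums to the design's `n_sites`.
#' @export
truth_category_counts <- function(truth) {
  lv <- c("breed_unique_fixed", "ref_N", "shared")
  tab <- table(factor(truth$category, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

#' Simulate genotypes under exact Hardy-Weinberg equilibrium
#'
#' Draws each individual's genotype at each locus as
#' `Binomial(2, p)` allele dosages — the HWE-true null used to check the
#' exact test's type-I error.
#'
#' @param n_ind individuals.
#' @param n_loci loci.
#' @param p alternate-allele frequency (scalar or per-locus vector).
#' @param seed RNG seed.
#' @param breed breed label attached to all individuals.
#' @return a [genotype_matrix()].
#' @export
simulate_hwe_genotypes <- function(n_ind, n_loci, p, seed = NULL,
                                   breed = "sim") {
  p <- rep_len(p, n_loci)
  g <- with_seed(seed, {
    matrix(stats::rbinom(n_ind * n_loci, 2L, rep(p, each = n_ind)),
           n_ind, n_loci)
  })
  codes <- c("AA", "AB", "BB")
  genotype_matrix(
    matrix(codes[g + 1L], n_ind, n_loci),
    data.frame(sample_id = sprintf("ind%04d", seq_len(n_ind)), breed = breed,
               stringsAsFactors = FALSE),
    data.frame(locus = sprintf("locus%05d", seq_len(n_loci)),
               allele_normal = "A", allele_mutant = "B",
               stringsAsFactors = FALSE))
}
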