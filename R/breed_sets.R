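#' Tabulate per-breed site occurrence
#'
#' Collapses a (typically filtered) SNP database to one row per distinct site
#' key `(chrom, pos, alt_base)` and counts, for each breed, how many of its
#' samples carry the site. The counts support Venn-style shared/exclusive
#' summaries across breeds and all four occurrence categories.
#'
#' @param db a `snp_db` whose samples carry breed labels.
#' @return data.frame of class `site_occurrence`: columns `chrom`, `pos`,
#'   `ref_base`, `alt_base` plus one carrier-count column `n_<breed>` per
#'   breed; breed sample totals are attached as attribute `breed_totals`.
#' @export
tabulate_occurrence <- function(db) {
  stopifnot(inherits(db, "snp_db"))
  totals <- breed_sample_totals(db)
  breeds <- names(totals)
  cc <- db$calls
  key <- site_key(cc$chrom, cc$pos, cc$alt_base)
  ukey <- unique(key)
  idx1 <- match(ukey, key)
  out <- data.frame(chrom = cc$chrom[idx1], pos = cc$pos[idx1],
                    ref_base = cc$ref_base[idx1], alt_base = cc$alt_base[idx1],
                    stringsAsFactors = FALSE)
  breed_of <- stats::setNames(db$samples$breed, db$samples$sample_id)
  call_breed <- breed_of[cc$sample_id]
  for (b in breeds) {
    tab <- table(factor(key[call_breed %in% b], levels = ukey))
    out[[paste0("n_", b)]] <- as.integer(tab)
  }
  attr(out, "breed_totals") <- totals
  class(out) <- c("site_occurrence", "data.frame")
  out
}

# Venn-region counts over breeds: names are "+"-joined breed subsets.
#' Venn-style breed sharing counts
#'
#' Counts distinct sites by the exact subset of breeds in which they occur
#' (at least one carrier sample per breed), the summary behind the
#' three-breed sharing diagram.
#'
#' @param occ a [tabulate_occurrence()] result.
#' @return named integer vector; names are `+`-joined breed subsets.
#' @export
venn_counts <- function(occ) {
  stopifnot(inherits(occ, "site_occurrence"))
  totals <- attr(occ, "breed_totals")
  breeds <- names(totals)
  pres <- sapply(breeds, function(b) occ[[paste0("n_", b)]] > 0L)
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = nrow(occ))
  lab <- apply(pres, 1L, function(r) paste(breeds[r], collapse = "+"))
  subsets <- unlist(lapply(seq_along(breeds), function(k)
    utils::combn(breeds, k, paste, collapse = "+")))
  tab <- table(factor(lab, levels = subsets))
  stats::setNames(as.integer(tab), subsets)
}

#' Categorize sites into the four breed-occurrence types
#'
#' For each site and breed, assigns the four designations used to trim the
#' SNP database:
#' \describe{
#'   \item{any}{detected in at least one of the breed's samples (ANY).}
#'   \item{all}{detected in all of the breed's samples (breed-specific).}
#'   \item{any_unique}{ANY, and absent from every sample of every other
#'     breed (ANY UNIQUE).}
#'   \item{all_unique}{breed-specific and absent from every other breed
#'     (breed-specific UNIQUE).}
#' }
#' Uniqueness is evaluated against carrier counts in `occ_reference`, which
#' defaults to `occ` itself; pass the occurrence of the unfiltered database
#' to disqualify sites carried by other breeds at any depth (the stricter
#' default of [categorize_breed_specific()]).
#'
#' @param occ a [tabulate_occurrence()] result (usually of a filtered db).
#' @param occ_reference occurrence table used for the "absent from other
#'   breeds" condition; defaults to `occ`.
#' @return data.frame of class `categorized_sites`: site columns plus
#'   logical columns `any_<breed>`, `all_<breed>`, `any_unique_<breed>`,
#'   `all_unique_<breed>`.
#' @export
categorize <- function(occ, occ_reference = NULL) {
  stopifnot(inherits(occ, "site_occurrence"))
  totals <- attr(occ, "breed_totals")
  if (any(totals == 0L)) stop("breed with zero samples")
  breeds <- names(totals)
  if (is.null(occ_reference)) occ_reference <- occ
  stopifnot(identical(names(attr(occ_reference, "breed_totals")), breeds))
  key <- site_key(occ$chrom, occ$pos, occ$alt_base)
  rkey <- site_key(occ_reference$chrom, occ_reference$pos, occ_reference$alt_base)
  ridx <- match(key, rkey)
  out <- occ[, c("chrom", "pos", "ref_base", "alt_base"), drop = FALSE]
  for (b in breeds) {
    n <- occ[[paste0("n_", b)]]
    others <- setdiff(breeds, b)
    other_ref <- rowSums(as.matrix(
      occ_reference[ridx, paste0("n_", others), drop = FALSE]))
    other_ref[is.na(other_ref)] <- 0   # site absent from reference table
    out[[paste0("any_", b)]] <- n > 0L
    out[[paste0("all_", b)]] <- n == totals[[b]]
    out[[paste0("any_unique_", b)]] <- n > 0L & other_ref == 0
    out[[paste0("all_unique_", b)]] <- n == totals[[b]] & other_ref == 0
  }
  attr(out, "breed_totals") <- totals
  class(out) <- c("categorized_sites", "data.frame")
  out
}

#' Filter and categorize in one step
#'
#' Convenience wrapper: applies `spec` to `db`, tabulates occurrence, and
#' categorizes. With `unique_vs = "raw"` (default) a site is disqualified
#' from the UNIQUE categories if any other-breed sample carries it in the
#' unfiltered database at any depth, guarding against depth artifacts;
#' `unique_vs = "filtered"` evaluates uniqueness on the filtered calls only.
#'
#' @param db the raw `snp_db`.
#' @param spec a [filter_spec()].
#' @param unique_vs `"raw"` or `"filtered"`.
#' @return a `categorized_sites` data.frame (sites of the filtered db).
#' @export
categorize_breed_specific <- function(db, spec, unique_vs = c("raw", "filtered")) {
  unique_vs <- match.arg(unique_vs)
  occ_f <- tabulate_occurrence(apply_filter(db, spec))
  ref <- if (unique_vs == "raw") tabulate_occurrence(db) else NULL
  categorize(occ_f, ref)
}

#' Per-breed category counts
#'
#' @param cats a [categorize()] result.
#' @return data.frame with one row per breed and columns `any`, `all`,
#'   `any_unique`, `all_unique`.
#' @export
category_counts <- function(cats) {
  stopifnot(inherits(cats, "categorized_sites"))
  breeds <- names(attr(cats, "breed_totals"))
  do.call(rbind, lapply(breeds, function(b) data.frame(
    breed = b,
    any = sum(cats[[paste0("any_", b)]]),
    all = sum(cats[[paste0("all_", b)]]),
    any_unique = sum(cats[[paste0("any_unique_", b)]]),
    all_unique = sum(cats[[paste0("all_unique_", b)]]),
    stringsAsFactors = FALSE)))
}

#' Flag de-novo SNPs at reference-N positions
#'
#' Regions of the reference assembly whose base is unknown (N) cannot carry
#' annotated variants; a filtered call at such a position is a de-novo SNP
#' candidate. Counts are reported per filter; candidates under both filters
#' can be pooled or intersected by the caller.
#'
#' @param db the raw `snp_db`.
#' @param spec a [filter_spec()].
#' @return data.frame of distinct flagged sites: `chrom`, `pos`, `ref_base`,
#'   `alt_base`, `n_samples` (carriers after filtering), `de_novo = TRUE`.
#' @export
flag_de_novo <- function(db, spec) {
  f <- apply_filter(db, spec)
  cc <- f$calls[f$calls$ref_base == "N", , drop = FALSE]
  if (nrow(cc) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      n_samples = integer(), de_novo = logical(),
                      stringsAsFactors = FALSE))
  key <- site_key(cc$chrom, cc$pos, cc$alt_base)
  tab <- table(key)
  idx <- match(names(tab), key)
  data.frame(chrom = cc$chrom[idx], pos = cc$pos[idx],
             ref_base = cc$ref_base[idx], alt_base = cc$alt_base[idx],
             n_samples = as.integer(tab), de_novo = TRUE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag reference-error candidate sites
#'
#' A site where every sample of every breed carries the same alternate
#' allele, each call passing the active filter, suggests the assembly base
#' itself is wrong rather than a segregating variant. A site is disqualified
#' if any filtered call at the same position reports a different alternate
#' allele (a reference error implies one true base). This all-samples,
#' same-allele rule is this package's explicit interpretation of
#' annotation-based reference-error correction.
#'
#' @param db the raw `snp_db` (all cohort samples).
#' @param spec a [filter_spec()].
#' @return data.frame of flagged sites with `ref_error_candidate = TRUE`.
#' @export
flag_ref_error_candidates <- function(db, spec) {
  f <- apply_filter(db, spec)
  n_all <- nrow(f$samples)
  cc <- f$calls
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      ref_error_candidate = logical(), stringsAsFactors = FALSE)
  if (nrow(cc) == 0L) return(empty)
  key <- site_key(cc$chrom, cc$pos, cc$alt_base)
  carriers <- table(key)
  cand <- names(carriers)[as.integer(carriers) == n_all]
  if (!length(cand)) return(empty)
  # discordant alternates at the same position disqualify
  poskey <- paste(cc$chrom, cc$pos)
  idx <- match(cand, key)
  n_alts_at_pos <- tapply(cc$alt_base, poskey,
                          function(a) length(unique(a)))
  ok <- n_alts_at_pos[poskey[idx]] == 1L
  idx <- idx[ok]
  if (!length(idx)) return(empty)
  data.frame(chrom = cc$chrom[idx], pos = cc$pos[idx],
             ref_base = cc$ref_base[idx], alt_base = cc$alt_base[idx],
             ref_error_candidate = TRUE, stringsAsFactors = FALSE,
             row.names = NULL)
}
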