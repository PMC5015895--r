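#' Normalize a chromosome name
#'
#' Strips a leading `"chr"` or `"BTA"` prefix (case-insensitively) and
#' upper-cases the remainder, so that `"chr25"`, `"BTA25"` and `"25"` all
#' compare equal. Cattle loci are reported interchangeably in BTA-style and
#' bare styles, so every chromosome entering the package passes through this
#' normalization.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @examples
#' normalize_chrom(c("chr25", "BTA25", "25", "X"))
#' @export
normalize_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  sub("^(CHR|BTA)", "", x)
}

#' Site key for cross-sample SNP comparison
#'
#' The identity of a SNP site for all cross-sample set algebra is
#' `(chrom, pos, alt_base)`; the reference base is carried along but is not
#' part of the key.
#'
#' @param chrom,pos,alt_base vectors of equal length.
#' @return character vector of keys.
#' @export
site_key <- function(chrom, pos, alt_base) {
  paste(normalize_chrom(chrom), pos, alt_base, sep = ":")
}

.VALID_BASES <- c("A", "C", "G", "T")

# Validate a calls data.frame against the call-record invariants; returns the
# (possibly re-typed) data.frame or stops with an informative message.
validate_snp_calls <- function(calls) {
  req <- c("sample_id", "chrom", "pos", "ref_base", "alt_base",
           "total_depth", "alt_depth", "accuracy_pct")
  miss <- setdiff(req, names(calls))
  if (length(miss))
    stop("calls is missing column(s): ", paste(miss, collapse = ", "))
  calls <- calls[, req, drop = FALSE]
  if (nrow(calls) == 0L) return(calls)
  calls$pos <- as.integer(calls$pos)
  calls$total_depth <- as.integer(calls$total_depth)
  calls$alt_depth <- as.integer(calls$alt_depth)
  if (any(calls$pos < 1L)) stop("pos must be >= 1")
  if (!all(calls$ref_base %in% c(.VALID_BASES, "N")))
    stop("ref_base must be one of A, C, G, T, N")
  if (!all(calls$alt_base %in% .VALID_BASES))
    stop("alt_base must be one of A, C, G, T")
  bad <- calls$alt_base == calls$ref_base
  if (any(bad))
    stop("alt_base equals ref_base at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(calls$alt_depth < 1L))
    stop("alt_depth must be >= 1 (a call needs at least one supporting read)")
  if (any(calls$alt_depth > calls$total_depth))
    stop("alt_depth cannot exceed total_depth")
  expected <- 100 * calls$alt_depth / calls$total_depth
  if (any(abs(calls$accuracy_pct - expected) > 1e-9))
    stop("accuracy_pct must equal 100 * alt_depth / total_depth")
  key <- paste(calls$sample_id, site_key(calls$chrom, calls$pos, calls$alt_base))
  if (anyDuplicated(key))
    stop("duplicate call key (sample_id, chrom, pos, alt_base): ",
         key[which(duplicated(key))[1]])
  calls
}

#' Construct a per-sample SNP database
#'
#' A `snp_db` bundles per-sample SNP call records with the cohort's sample
#' metadata. Calls are keyed by `(sample_id, chrom, pos, alt_base)`;
#' multi-allelic records are represented as one call per alternate allele.
#'
#' @param calls data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref_base`, `alt_base`, `total_depth`, `alt_depth`, `accuracy_pct`.
#'   Chromosomes are normalized with [normalize_chrom()].
#' @param samples data.frame with columns `sample_id`, `breed`, `age_months`,
#'   `replicate` (one row per library). If `NULL`, a skeleton is built from
#'   the sample ids seen in `calls`, with `NA` metadata.
#' @param n_skipped_indels integer count of indel records dropped while
#'   reading (only SNP substitutions are retained downstream).
#' @return an object of class `snp_db`: a list with elements `calls`,
#'   `samples` and `n_skipped_indels`.
#' @seealso [read_snp_calls()], [write_snp_db()], [apply_filter()]
#' @export
snp_db <- function(calls, samples = NULL, n_skipped_indels = 0L) {
  calls$chrom <- normalize_chrom(calls$chrom)
  calls <- validate_snp_calls(calls)
  if (is.null(samples)) {
    ids <- unique(calls$sample_id)
    samples <- data.frame(sample_id = ids,
                          breed = rep(NA_character_, length(ids)),
                          age_months = rep(NA_integer_, length(ids)),
                          replicate = rep(NA_integer_, length(ids)),
                          stringsAsFactors = FALSE)
  }
  req <- c("sample_id", "breed", "age_months", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("samples is missing column(s): ", paste(miss, collapse = ", "))
  samples <- samples[, req, drop = FALSE]
  if (anyDuplicated(samples$sample_id))
    stop("sample_id must be unique within a cohort")
  orphan <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(orphan))
    stop("calls reference sample_id(s) absent from samples: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  rownames(calls) <- NULL
  rownames(samples) <- NULL
  structure(list(calls = calls, samples = samples,
                 n_skipped_indels = as.integer(n_skipped_indels)),
            class = "snp_db")
}

#' @export
print.snp_db <- function(x, ...) {
  cat("snp_db:", nrow(x$calls), "calls across", nrow(x$samples), "samples\n")
  br <- x$samples$breed
  if (!all(is.na(br))) {
    tab <- table(br, useNA = "no")
    cat("  breeds:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  if (x$n_skipped_indels > 0L)
    cat("  indel records skipped on read:", x$n_skipped_indels, "\n")
  invisible(x)
}

#' Attach sample metadata to a SNP database
#'
#' @param db a `snp_db`.
#' @param samples data.frame with columns `sample_id`, `breed`, `age_months`,
#'   `replicate`; must cover every sample present in the calls.
#' @return the `snp_db` with metadata replaced.
#' @export
set_sample_meta <- function(db, samples) {
  stopifnot(inherits(db, "snp_db"))
  snp_db(db$calls, samples, db$n_skipped_indels)
}

#' Combine per-sample SNP database fragments
#'
#' @param ... `snp_db` objects (e.g. one per library, as returned by
#'   [read_snp_calls()]).
#' @return a single `snp_db` whose calls and samples are the union of the
#'   inputs. Duplicate call keys across fragments are an error.
#' @export
bind_snp_db <- function(...) {
  dbs <- list(...)
  if (length(dbs) == 1L && is.list(dbs[[1]]) && !inherits(dbs[[1]], "snp_db"))
    dbs <- dbs[[1]]
  stopifnot(length(dbs) >= 1L, all(vapply(dbs, inherits, TRUE, "snp_db")))
  calls <- do.call(rbind, lapply(dbs, `[[`, "calls"))
  samples <- unique(do.call(rbind, lapply(dbs, `[[`, "samples")))
  if (anyDuplicated(samples$sample_id))
    stop("conflicting sample metadata for the same sample_id")
  snp_db(calls, samples,
         sum(vapply(dbs, `[[`, 0L, "n_skipped_indels")))
}

# Number of samples per breed, as a named integer vector.
breed_sample_totals <- function(db) {
  s <- db$samples
  s <- s[!is.na(s$breed), , drop = FALSE]
  if (nrow(s) == 0L) stop("no breed labels in sample metadata")
  tab <- table(s$breed)
  stats::setNames(as.integer(tab), names(tab))
}
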