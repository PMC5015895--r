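#' Round half-up at a fixed number of decimals
#'
#' Reported percentages follow commercial rounding (half away from zero for
#' positive values), the convention used for the published retention,
#' reduction and mapping percentages, rather than R's banker's rounding.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Stringent SNP filter specification
#'
#' The two filters applied to the raw SNP database are (i) a minimum of 10
#' variant-supporting reads with call accuracy >= 90 percent and (ii) a
#' minimum of 10 variant-supporting reads with accuracy exactly 100 percent.
#' Accuracy is the percentage of reads at the site supporting the called
#' alternate base. "10 SNP reads per base" is interpreted as reads
#' supporting the alternate allele (for the 100-percent filter the two
#' readings coincide); set `depth_on = "total"` for the total-coverage
#' reading.
#'
#' @param min_alt_reads minimum supporting reads (default 10).
#' @param min_accuracy_pct accuracy threshold in percent (90 or 100 in the
#'   study design).
#' @param accuracy_is_exact if `TRUE`, accuracy must equal the threshold
#'   exactly (the "= 100 percent" filter); comparison is done on integers
#'   (`100 * alt_depth == threshold * total_depth`), never on floats.
#' @param depth_on `"alt"` (default) or `"total"`: which depth the read-count
#'   threshold applies to.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(min_alt_reads = 10, min_accuracy_pct = 90,
                        accuracy_is_exact = FALSE,
                        depth_on = c("alt", "total")) {
  depth_on <- match.arg(depth_on)
  stopifnot(min_alt_reads >= 1, min_accuracy_pct > 0, min_accuracy_pct <= 100)
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 min_accuracy_pct = min_accuracy_pct,
                 accuracy_is_exact = isTRUE(accuracy_is_exact),
                 depth_on = depth_on),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("filter_spec: >=%d %s reads, accuracy %s %g%%\n",
              x$min_alt_reads, x$depth_on,
              if (x$accuracy_is_exact) "=" else ">=", x$min_accuracy_pct))
  invisible(x)
}

# The per-call retention predicate, exposed for oracle-style testing.
filter_predicate <- function(calls, spec) {
  depth <- if (spec$depth_on == "alt") calls$alt_depth else calls$total_depth
  acc_ok <- if (spec$accuracy_is_exact) {
    100 * calls$alt_depth == spec$min_accuracy_pct * calls$total_depth
  } else {
    100 * calls$alt_depth >= spec$min_accuracy_pct * calls$total_depth
  }
  depth >= spec$min_alt_reads & acc_ok
}

#' Apply a stringent filter to a SNP database
#'
#' Retains exactly the calls satisfying the read-count and accuracy
#' thresholds of `spec`. Idempotent, and monotone in both thresholds: the
#' accuracy-exactly-100 set is always a subset of the accuracy->=90 set at
#' equal read-count threshold.
#'
#' @param db a `snp_db`.
#' @param spec a [filter_spec()].
#' @return the filtered `snp_db` (same sample metadata).
#' @export
apply_filter <- function(db, spec) {
  stopifnot(inherits(db, "snp_db"), inherits(spec, "filter_spec"))
  keep <- filter_predicate(db$calls, spec)
  snp_db(db$calls[keep, , drop = FALSE], db$samples, db$n_skipped_indels)
}

#' Per-bull average call count
#'
#' Total calls divided by the number of bulls; the published per-bull
#' averages truncate the quotient, so truncation is the default and
#' half-up rounding is available as an option.
#'
#' @param total total call count.
#' @param n_samples number of bulls.
#' @param average `"truncate"` or `"round"`.
#' @return averaged count.
#' @export
per_bull_average <- function(total, n_samples, average = c("truncate", "round")) {
  average <- match.arg(average)
  if (n_samples < 1) stop("n_samples must be >= 1")
  q <- total / n_samples
  if (average == "truncate") floor(q + 1e-9) else round_half_up(q, 0)
}

#' Reduction report for a filtering pass
#'
#' Summarizes how much of the raw SNP database a stringent filter removed:
#' global retention and reduction percentages (half-up, 1 decimal) and
#' per-breed per-bull average counts before and after filtering.
#'
#' @param raw the unfiltered `snp_db`.
#' @param filtered the filtered `snp_db` (must be a key-subset of `raw`).
#' @param average per-bull averaging convention, see [per_bull_average()].
#' @return an object of class `reduction_report`: list with `raw_count`,
#'   `filtered_count`, `retention_pct`, `reduction_pct`, and a `per_breed`
#'   data.frame (`breed`, `n_samples`, `raw_avg`, `filtered_avg`,
#'   `retention_pct`).
#' @export
reduction_report <- function(raw, filtered, average = c("truncate", "round")) {
  stopifnot(inherits(raw, "snp_db"), inherits(filtered, "snp_db"))
  average <- match.arg(average)
  if (nrow(raw$calls) == 0L)
    stop("raw database is empty: reduction percentage is undefined")
  key <- function(d) paste(d$calls$sample_id,
                           site_key(d$calls$chrom, d$calls$pos, d$calls$alt_base))
  if (!all(key(filtered) %in% key(raw)))
    stop("filtered is not a subset of raw")
  rc <- nrow(raw$calls); fc <- nrow(filtered$calls)
  per_breed <- NULL
  if (!all(is.na(raw$samples$breed))) {
    totals <- breed_sample_totals(raw)
    breed_of <- stats::setNames(raw$samples$breed, raw$samples$sample_id)
    rtab <- table(factor(breed_of[raw$calls$sample_id], levels = names(totals)))
    ftab <- table(factor(breed_of[filtered$calls$sample_id],
                         levels = names(totals)))
    raw_avg <- mapply(per_bull_average, as.numeric(rtab), totals,
                      MoreArgs = list(average = average))
    filt_avg <- mapply(per_bull_average, as.numeric(ftab), totals,
                       MoreArgs = list(average = average))
    per_breed <- data.frame(
      breed = names(totals), n_samples = as.integer(totals),
      raw_avg = raw_avg, filtered_avg = filt_avg,
      retention_pct = ifelse(raw_avg > 0,
                             round_half_up(100 * filt_avg / raw_avg, 1), NA),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(raw_count = rc, filtered_count = fc,
                 retention_pct = round_half_up(100 * fc / rc, 1),
                 reduction_pct = round_half_up(100 * (rc - fc) / rc, 1),
                 per_breed = per_breed),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("reduction_report: %s raw -> %s filtered (retention %.1f%%, reduction %.1f%%)\n",
              format(x$raw_count, big.mark = ","),
              format(x$filtered_count, big.mark = ","),
              x$retention_pct, x$reduction_pct))
  if (!is.null(x$per_breed)) print(x$per_breed)
  invisible(x)
}

#' Breed-level retention percentage from per-bull averages
#'
#' @param raw_avg per-bull average raw SNP count for the breed.
#' @param filtered_avg per-bull average filtered SNP count.
#' @return `100 * filtered_avg / raw_avg`, half-up rounded to 1 decimal.
#' @examples
#' retention_pct_by_breed(754719, 34658)  # 4.6
#' @export
retention_pct_by_breed <- function(raw_avg, filtered_avg) {
  if (any(raw_avg <= 0)) stop("raw_avg must be positive")
  round_half_up(100 * filtered_avg / raw_avg, 1)
}

#' Properly-paired read percentage per breed
#'
#' Sums a breed's per-age mapping rows and reports the percentage of reads
#' that aligned as proper pairs, half-up rounded to 2 decimals.
#'
#' @param summary a [read_mapping_summary()] data.frame (or any data.frame
#'   with `breed`, `total_reads`, `mapped`, `properly_paired`).
#' @param denominator `"total"` (default, total sequenced reads) or
#'   `"mapped"`.
#' @return data.frame with one row per breed: summed totals plus
#'   `properly_paired_pct`.
#' @export
properly_paired_pct <- function(summary, denominator = c("total", "mapped")) {
  denominator <- match.arg(denominator)
  req <- c("breed", "total_reads", "mapped", "properly_paired")
  stopifnot(all(req %in% names(summary)))
  agg <- stats::aggregate(summary[c("total_reads", "mapped", "properly_paired")],
                          by = list(breed = summary$breed), FUN = sum)
  den <- if (denominator == "total") agg$total_reads else agg$mapped
  if (any(den <= 0)) stop("zero read totals: percentage undefined")
  agg$properly_paired_pct <- round_half_up(100 * agg$properly_paired / den, 2)
  agg
}
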