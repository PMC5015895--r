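#' Count SNP hits inside candidate-gene / QTL intervals
#'
#' A call hits a gene iff it lies on the same (normalized) chromosome and
#' `start <= pos <= end`, both ends inclusive; overlapping genes each
#' receive the hit. Counts are grouped by breed and age from the cohort's
#' sample metadata. By default hits are call-level events (the same site
#' carried by k samples contributes k); `distinct_sites = TRUE` counts each
#' distinct site key once per gene x breed x age cell instead.
#'
#' @param db a (typically filtered) `snp_db` with breed/age metadata.
#' @param intervals a [read_gene_intervals()] table (1-based inclusive).
#' @param distinct_sites count unique sites rather than calls.
#' @return data.frame of class `gene_hit_table` with the full
#'   gene x breed x age grid and a `hits` column.
#' @export
count_hits <- function(db, intervals, distinct_sites = FALSE) {
  stopifnot(inherits(db, "snp_db"))
  s <- db$samples[!is.na(db$samples$breed), , drop = FALSE]
  breeds <- sort(unique(s$breed))
  ages <- sort(unique(s$age_months))
  grid <- expand.grid(gene = unique(intervals$gene), breed = breeds,
                      age_months = ages, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$hits <- 0L
  cc <- db$calls
  if (nrow(cc) > 0L && nrow(intervals) > 0L) {
    ichrom <- normalize_chrom(intervals$chrom)
    gr_calls <- GenomicRanges::GRanges(cc$chrom,
                                       IRanges::IRanges(cc$pos, cc$pos))
    gr_genes <- GenomicRanges::GRanges(ichrom,
                                       IRanges::IRanges(intervals$start,
                                                        intervals$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_calls, gr_genes))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      meta <- db$samples[match(cc$sample_id[qh], db$samples$sample_id), ]
      hit <- data.frame(gene = intervals$gene[sh], breed = meta$breed,
                        age_months = meta$age_months,
                        key = site_key(cc$chrom[qh], cc$pos[qh],
                                       cc$alt_base[qh]),
                        stringsAsFactors = FALSE)
      hit <- hit[!is.na(hit$breed), , drop = FALSE]
      if (distinct_sites)
        hit <- unique(hit[, c("gene", "breed", "age_months", "key")])
      if (nrow(hit)) {
        cell <- paste(hit$gene, hit$breed, hit$age_months, sep = "\r")
        tab <- table(cell)
        gcell <- paste(grid$gene, grid$breed, grid$age_months, sep = "\r")
        m <- match(gcell, names(tab))
        grid$hits <- ifelse(is.na(m), 0L, as.integer(tab)[m])
      }
    }
  }
  class(grid) <- c("gene_hit_table", "data.frame")
  grid
}

#' Total hits per gene
#'
#' @param table a [count_hits()] result.
#' @return data.frame `gene`, `total_hits`, sorted by gene.
#' @export
gene_totals <- function(table) {
  stopifnot(inherits(table, "gene_hit_table"))
  agg <- stats::aggregate(list(total_hits = table$hits),
                          by = list(gene = table$gene), FUN = sum)
  agg[order(agg$gene), , drop = FALSE]
}

#' Rank genes by total SNP hits
#'
#' Genes are sorted by total hit count, descending; ties are broken
#' lexicographically by gene symbol so the ranking is deterministic.
#'
#' @param table a [count_hits()] result.
#' @param top_n how many genes to return (default all).
#' @return data.frame `rank`, `gene`, `total_hits`.
#' @export
rank_genes <- function(table, top_n = NULL) {
  tot <- gene_totals(table)
  if (is.null(top_n)) top_n <- nrow(tot)
  if (top_n < 1) stop("top_n must be >= 1")
  ord <- order(-tot$total_hits, tot$gene)
  tot <- tot[ord, , drop = FALSE]
  tot <- utils::head(tot, top_n)
  data.frame(rank = seq_len(nrow(tot)), gene = tot$gene,
             total_hits = tot$total_hits, stringsAsFactors = FALSE,
             row.names = NULL)
}
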