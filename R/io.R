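#' Read per-sample SNP calls
#'
#' Reads one library's variant calls into a [snp_db()] fragment. Two dialects
#' are supported:
#' \describe{
#'   \item{`pileup_tsv`}{a whitespace-separated table with columns
#'     `chrom, pos, ref, alt, total_depth, alt_depth, sample_id` and a
#'     `#`-prefixed header, as produced downstream of samtools mpileup.}
#'   \item{`vcf`}{a VCF 4.x file with per-sample `AD` (allelic depth)
#'     annotations; multi-allelic records are split into one call per
#'     alternate allele.}
#' }
#' Indel records (reference or alternate allele longer than one base) are
#' skipped and counted in `n_skipped_indels`: only single-base substitutions
#' enter the SNP database.
#'
#' @param path file path.
#' @param dialect `"pileup_tsv"` or `"vcf"`.
#' @param sample_id sample identifier override; for `vcf`, defaults to the
#'   genotype column name, for `pileup_tsv` to the file's `sample_id` column.
#' @return a `snp_db` fragment (skeleton sample metadata; attach the cohort
#'   sheet with [set_sample_meta()]).
#' @export
read_snp_calls <- function(path, dialect = c("pileup_tsv", "vcf"),
                           sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         pileup_tsv = read_pileup_tsv(path, sample_id),
         vcf = read_vcf_calls(path, sample_id))
}

read_pileup_tsv <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  n_indel <- 0L
  if (length(lines) == 0L) {
    empty <- data.frame(sample_id = character(), chrom = character(),
                        pos = integer(), ref_base = character(),
                        alt_base = character(), total_depth = integer(),
                        alt_depth = integer(), accuracy_pct = double(),
                        stringsAsFactors = FALSE)
    return(snp_db(empty))
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 7L))
    stop("malformed line ", lineno[which(nf != 7L)[1]], " in ", path,
         ": expected 7 fields, found ", nf[which(nf != 7L)[1]])
  m <- matrix(unlist(parts), ncol = 7L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  td <- suppressWarnings(as.integer(m[, 5]))
  ad <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(pos) | is.na(td) | is.na(ad))
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": non-numeric pos/depth field")
  ref <- toupper(m[, 1 + 2])
  alt <- toupper(m[, 4])
  is_indel <- nchar(ref) > 1L | nchar(alt) > 1L | alt == "*" | ref == "*"
  n_indel <- sum(is_indel)
  keep2 <- !is_indel
  calls <- data.frame(
    sample_id = if (is.null(sample_id)) m[keep2, 7] else sample_id,
    chrom = m[keep2, 1], pos = pos[keep2],
    ref_base = ref[keep2], alt_base = alt[keep2],
    total_depth = td[keep2], alt_depth = ad[keep2],
    accuracy_pct = 100 * ad[keep2] / td[keep2],
    stringsAsFactors = FALSE)
  snp_db(calls, n_skipped_indels = n_indel)
}

read_vcf_calls <- function(path, sample_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcf@gt
  if (is.null(dim(fix)))    # single-record files drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype columns; per-sample AD depths are required")
  sample_col <- colnames(gt)[2]
  if (ncol(gt) > 2L)
    stop("VCF contains multiple samples; split per library before import")
  fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  vals <- strsplit(gt[, sample_col], ":", fixed = TRUE)
  sid <- if (is.null(sample_id)) sample_col else sample_id
  rows <- vector("list", nrow(fix))
  n_indel <- 0L
  for (i in seq_len(nrow(fix))) {
    ad_idx <- match("AD", fmt[[i]])
    if (is.na(ad_idx))
      stop("VCF record ", i, " lacks the AD (allelic depth) FORMAT field")
    ad <- suppressWarnings(as.integer(strsplit(vals[[i]][ad_idx], ",")[[1]]))
    if (anyNA(ad))
      stop("VCF record ", i, ": unparseable AD field")
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    if (length(ad) != length(alts) + 1L)
      stop("VCF record ", i, ": AD length does not match allele count")
    total <- sum(ad)
    out <- list()
    for (k in seq_along(alts)) {
      if (nchar(ref) > 1L || nchar(alts[k]) > 1L || alts[k] == "*") {
        n_indel <- n_indel + 1L
        next
      }
      if (ad[k + 1L] < 1L) next   # alternate allele without read support
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref_base = ref, alt_base = alts[k],
        total_depth = total, alt_depth = ad[k + 1L],
        accuracy_pct = 100 * ad[k + 1L] / total, stringsAsFactors = FALSE)
    }
    if (length(out)) rows[[i]] <- do.call(rbind, out)
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(calls))
    calls <- data.frame(sample_id = character(), chrom = character(),
                        pos = integer(), ref_base = character(),
                        alt_base = character(), total_depth = integer(),
                        alt_depth = integer(), accuracy_pct = double(),
                        stringsAsFactors = FALSE)
  snp_db(calls, n_skipped_indels = n_indel)
}

#' Write a SNP database in the pileup_tsv dialect
#'
#' Writes calls grouped by sample, ordered by chromosome and position. The
#' file round-trips: [read_snp_calls()] on the output reproduces the key set
#' and all fields exactly.
#'
#' @param db a `snp_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snp_db <- function(db, path) {
  stopifnot(inherits(db, "snp_db"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines("#chrom\tpos\tref\talt\ttotal_depth\talt_depth\tsample_id", con)
  cc <- db$calls
  if (nrow(cc)) {
    cc <- cc[order(cc$sample_id, cc$chrom, cc$pos, cc$alt_base), , drop = FALSE]
    writeLines(paste(cc$chrom, cc$pos, cc$ref_base, cc$alt_base,
                     cc$total_depth, cc$alt_depth, cc$sample_id, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read candidate-gene / QTL intervals
#'
#' Reads a table of gene loci. Two layouts are recognized by column content:
#' \describe{
#'   \item{BED}{columns `chrom, start, end, gene` with 0-based half-open
#'     coordinates, converted to the internal 1-based inclusive convention
#'     (`start + 1`, `end`).}
#'   \item{native}{columns `gene, chrom, start, end`, already 1-based
#'     inclusive.}
#' }
#'
#' @param path file path to a tab-separated table with a header line.
#' @param format `"auto"` (decide from the header), `"bed"` or `"native"`.
#' @return data.frame of class `gene_intervals` with columns `gene`, `chrom`
#'   (normalized), `start`, `end` (1-based inclusive).
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "native")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  names(df) <- sub("^X\\.", "", tolower(names(df)))  # tolerate '#chrom'
  if (format == "auto")
    format <- if (names(df)[1] %in% c("chrom", "chr")) "bed" else "native"
  if (format == "bed") {
    names(df)[1:4] <- c("chrom", "start", "end", "gene")
    out <- data.frame(gene = df$gene, chrom = normalize_chrom(df$chrom),
                      start = as.integer(df$start) + 1L,
                      end = as.integer(df$end), stringsAsFactors = FALSE)
  } else {
    req <- c("gene", "chrom", "start", "end")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("interval table missing column(s): ", paste(miss, collapse = ", "))
    out <- data.frame(gene = df$gene, chrom = normalize_chrom(df$chrom),
                      start = as.integer(df$start), end = as.integer(df$end),
                      stringsAsFactors = FALSE)
  }
  bad <- which(out$start > out$end)
  if (length(bad))
    stop("interval with start > end at row ", bad[1], " (", out$gene[bad[1]], ")")
  class(out) <- c("gene_intervals", "data.frame")
  out
}

#' Construct a biallelic genotype matrix
#'
#' KASP-style genotype container: individuals x loci, each locus biallelic
#' with a declared (normal, mutant) allele pair; genotypes are coded `"AA"`
#' (normal homozygote), `"AB"` (heterozygote), `"BB"` (mutant homozygote) or
#' `NA` (missing).
#'
#' @param genotypes character matrix (individuals x loci) with entries in
#'   `{"AA","AB","BB", NA}`; dimnames give sample and locus ids.
#' @param individuals data.frame with columns `sample_id`, `breed` in matrix
#'   row order.
#' @param loci data.frame with columns `locus`, `allele_normal`,
#'   `allele_mutant` in matrix column order.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, individuals, loci) {
  stopifnot(is.matrix(genotypes),
            nrow(genotypes) == nrow(individuals),
            ncol(genotypes) == nrow(loci))
  ok <- genotypes %in% c("AA", "AB", "BB") | is.na(genotypes)
  if (!all(ok)) stop("genotype codes must be AA, AB, BB or NA")
  dimnames(genotypes) <- list(individuals$sample_id, loci$locus)
  structure(list(genotypes = genotypes,
                 individuals = as.data.frame(individuals),
                 loci = as.data.frame(loci)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "loci;",
      length(unique(x$individuals$breed)), "breed group(s)\n")
  invisible(x)
}

#' Read a genotype matrix with sample and locus sidecars
#'
#' The main table is tab-separated with a `sample_id` column followed by one
#' column per locus; cells hold raw allele pairs such as `"GG"` or `"GC"`,
#' or `"--"` for missing. Each cell is re-coded against the locus's declared
#' (normal, mutant) allele pair; an undeclared allele is an error.
#'
#' @param path genotype table path.
#' @param meta_path sample metadata sidecar (`sample_id`, `breed`, and
#'   optionally `age_months`).
#' @param loci_path locus sidecar (`locus`, `allele_normal`, `allele_mutant`).
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, meta_path, loci_path) {
  gt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  loci <- utils::read.table(loci_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("sample_id" %in% names(gt),
            all(c("sample_id", "breed") %in% names(meta)),
            all(c("locus", "allele_normal", "allele_mutant") %in% names(loci)))
  locus_cols <- setdiff(names(gt), "sample_id")
  miss <- setdiff(locus_cols, loci$locus)
  if (length(miss))
    stop("loci sidecar missing locus declaration(s): ",
         paste(miss, collapse = ", "))
  loci <- loci[match(locus_cols, loci$locus), , drop = FALSE]
  m <- matrix(NA_character_, nrow(gt), length(locus_cols))
  for (j in seq_along(locus_cols)) {
    a <- loci$allele_normal[j]; b <- loci$allele_mutant[j]
    raw <- toupper(trimws(gt[[locus_cols[j]]]))
    code <- rep(NA_character_, length(raw))
    code[raw %in% c(paste0(a, a))] <- "AA"
    code[raw %in% c(paste0(a, b), paste0(b, a))] <- "AB"
    code[raw %in% c(paste0(b, b))] <- "BB"
    bad <- !(raw %in% c("--", "", "NA")) & is.na(code)
    if (any(bad))
      stop("locus ", locus_cols[j], ": genotype '", raw[which(bad)[1]],
           "' uses an allele not declared (", a, "/", b, ")")
    m[, j] <- code
  }
  ind <- meta[match(gt$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(ind$sample_id))
    stop("sample metadata sidecar missing sample(s): ",
         paste(gt$sample_id[is.na(ind$sample_id)], collapse = ", "))
  genotype_matrix(m, ind, loci)
}

#' Read a transcriptome mapping summary table
#'
#' Flagstat-style per-breed, per-age read-mapping totals, in millions of
#' reads.
#'
#' @param path tab-separated table with columns `breed`, `age_months`,
#'   `total_reads`, `mapped`, `properly_paired`.
#' @return data.frame of class `mapping_summary`.
#' @export
read_mapping_summary <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("breed", "age_months", "total_reads", "mapped", "properly_paired")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("mapping summary missing column(s): ", paste(miss, collapse = ", "))
  # allow rounding to 2 decimals in the published tables
  if (any(df$properly_paired > df$mapped + 0.01) ||
      any(df$mapped > df$total_reads + 0.01))
    stop("expected properly_paired <= mapped <= total_reads")
  class(df) <- c("mapping_summary", "data.frame")
  df
}
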