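# Exact population-genetics tests on KASP-style genotype matrices:
# Hardy-Weinberg probability tests (full enumeration or Markov chain) and
# exact genic/genotypic differentiation on breeds x alleles(genotypes)
# contingency tables, plus Fisher's combined probability over loci.
#
# All of these are "probability tests": the p-value is the total conditional
# probability (given the margins / allele counts) of outcomes no more
# probable than the observed one. Factorials are handled in log space;
# probability ties use an additive log-scale tolerance.

.TIE_TOL <- 1e-9   # log-scale tie tolerance for "no more probable than"

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards; seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

exact_test_result <- function(p_value, method, mc_std_error = 0,
                              settings = NULL, monomorphic = FALSE) {
  structure(list(p_value = p_value, method = method,
                 mc_std_error = mc_std_error, settings = settings,
                 monomorphic = monomorphic),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat(sprintf("exact test (%s): p = %.6g", x$method, x$p_value))
  if (x$method == "markov_chain")
    cat(sprintf(" (MC s.e. %.2g)", x$mc_std_error))
  if (x$monomorphic) cat(" [monomorphic]")
  cat("\n")
  invisible(x)
}

#' Per-breed genotype and allele counts for one locus
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus identifier (column of the matrix).
#' @return data.frame with one row per breed: `n_AA`, `n_AB`, `n_BB`,
#'   `n_A`, `n_B` (missing genotypes excluded).
#' @export
locus_counts <- function(gm, locus) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(locus, gm$loci$locus)
  if (is.na(j)) stop("unknown locus: ", locus)
  g <- gm$genotypes[, j]
  breeds <- sort(unique(gm$individuals$breed))
  out <- do.call(rbind, lapply(breeds, function(b) {
    gb <- g[gm$individuals$breed == b]
    n_AA <- sum(gb == "AA", na.rm = TRUE)
    n_AB <- sum(gb == "AB", na.rm = TRUE)
    n_BB <- sum(gb == "BB", na.rm = TRUE)
    data.frame(breed = b, n_AA = n_AA, n_AB = n_AB, n_BB = n_BB,
               n_A = 2L * n_AA + n_AB, n_B = 2L * n_BB + n_AB,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-breed, per-locus allele frequencies
#'
#' Frequency of the normal (A) allele, `n_A / (n_A + n_B)`, with missing
#' genotypes excluded from the denominators. A breed with no called
#' genotypes at a locus gets `NA` and is flagged.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame: `locus`, `breed`, `n_A`, `n_B`, `freq_A`, `freq_B`,
#'   `undefined`.
#' @export
allele_frequencies <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- do.call(rbind, lapply(gm$loci$locus, function(l) {
    lc <- locus_counts(gm, l)
    tot <- lc$n_A + lc$n_B
    data.frame(locus = l, breed = lc$breed, n_A = lc$n_A, n_B = lc$n_B,
               freq_A = ifelse(tot > 0, lc$n_A / tot, NA_real_),
               freq_B = ifelse(tot > 0, lc$n_B / tot, NA_real_),
               undefined = tot == 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Log conditional probability of a genotype array (n_AA, n_AB, n_BB) given
# its allele counts: n! / (n_AA! n_AB! n_BB!) * 2^n_AB * n_A! n_B! / (2n)!
hwe_log_prob <- function(n_AB, n, n_A) {
  n_B <- 2L * n - n_A
  n_AA <- (n_A - n_AB) / 2
  n_BB <- (n_B - n_AB) / 2
  lfactorial(n) - lfactorial(n_AA) - lfactorial(n_AB) - lfactorial(n_BB) +
    n_AB * log(2) + lfactorial(n_A) + lfactorial(n_B) - lfactorial(2 * n)
}

# Feasible heterozygote counts for given (n, n_A): same parity as n_A.
hwe_feasible_nAB <- function(n, n_A) {
  n_B <- 2L * n - n_A
  seq.int(n_A %% 2L, min(n_A, n_B), by = 2L)
}

#' Exact Hardy-Weinberg probability test
#'
#' Tests departure from Hardy-Weinberg genotype proportions for one breed at
#' one biallelic locus, conditional on the observed allele counts. The
#' p-value is the summed conditional probability of all genotype arrays with
#' the same allele counts whose probability does not exceed the observed
#' array's. `method = "enumeration"` iterates every feasible heterozygote
#' count (exact and deterministic); `method = "markov_chain"` estimates the
#' same quantity with a Metropolis chain over heterozygote counts, reporting
#' a batch-mean standard error (Genepop-style chain defaults:
#' dememorization 1000, 20 batches of 5000 iterations).
#'
#' @param counts genotype counts, a length-3 vector `(n_AA, n_AB, n_BB)`.
#' @param method `"enumeration"` or `"markov_chain"`.
#' @param dememorization,batches,iterations Markov-chain settings.
#' @param seed RNG seed for the chain (restores the caller's RNG state).
#' @return an `exact_test_result`; monomorphic loci return p = 1 with the
#'   `monomorphic` flag set.
#' @examples
#' hwe_exact(c(1, 0, 1))$p_value   # 1/3
#' @export
hwe_exact <- function(counts, method = c("enumeration", "markov_chain"),
                      dememorization = 1000, batches = 20, iterations = 5000,
                      seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  counts <- as.integer(counts)
  n <- sum(counts)
  if (n < 1L) stop("at least one genotype is required")
  n_A <- 2L * counts[1] + counts[2]
  n_B <- 2L * counts[3] + counts[2]
  if (n_A == 0L || n_B == 0L)
    return(exact_test_result(1, method, monomorphic = TRUE))
  states <- hwe_feasible_nAB(n, n_A)
  lp <- hwe_log_prob(states, n, n_A)
  lp_obs <- lp[match(counts[2], states)]
  in_tail <- lp <= lp_obs + .TIE_TOL
  if (method == "enumeration") {
    p <- sum(exp(lp[in_tail] - lp_obs)) * exp(lp_obs)
    return(exact_test_result(min(p, 1), "enumeration"))
  }
  settings <- list(dememorization = dememorization, batches = batches,
                   iterations = iterations, seed = seed)
  with_seed(seed, {
    i <- match(counts[2], states)
    K <- length(states)
    total <- dememorization + batches * iterations
    # proposals (nAB +/- 2, i.e. index +/- 1) and acceptance draws up front
    prop <- sample(c(-1L, 1L), total, replace = TRUE)
    lu <- log(stats::runif(total))
    hits <- integer(batches)
    h <- 0L
    for (t in seq_len(total)) {
      j <- i + prop[t]
      if (j >= 1L && j <= K && lu[t] <= lp[j] - lp[i]) i <- j
      if (t > dememorization) {
        if (in_tail[i]) h <- h + 1L
        if ((t - dememorization) %% iterations == 0L) {
          hits[(t - dememorization) %/% iterations] <- h
          h <- 0L
        }
      }
    }
    bm <- hits / iterations
    exact_test_result(mean(bm), "markov_chain",
                      mc_std_error = stats::sd(bm) / sqrt(batches),
                      settings = settings)
  })
}

# Log probability of an r x c table with fixed margins under the
# multivariate hypergeometric null:
# prod(row!) prod(col!) / (N! prod(cell!)).
table_log_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

# Enumerate all tables with the given margins, accumulating the total
# probability of tables with log-probability <= lp_obs + tol. Recursion is
# over rows; within a row over the first c-1 cells. Feasibility pruning via
# remaining column sums keeps this tractable for the small validation-scale
# tables it is used on.
enumerate_tail_prob <- function(row_sums, col_sums, lp_obs) {
  r <- length(row_sums); c <- length(col_sums)
  const <- sum(lfactorial(row_sums)) + sum(lfactorial(col_sums)) -
    lfactorial(sum(row_sums))
  total <- 0
  fill_row <- function(i, col_rem, lcells) {
    if (i == r) {
      # last row forced by column remainders
      if (any(col_rem < 0)) return()
      lp <- const + lcells - sum(lfactorial(col_rem))
      if (lp <= lp_obs + .TIE_TOL) total <<- total + exp(lp)
      return()
    }
    fill_cell <- function(j, rem, col_rem, lcells) {
      if (j == c) {
        # last cell of the row is forced by the row remainder
        if (rem > col_rem[c]) return()
        v <- rep(0, c); v[c] <- rem
        fill_row(i + 1L, col_rem - v, lcells - lfactorial(rem))
        return()
      }
      for (x in 0:min(rem, col_rem[j])) {
        v <- rep(0, c); v[j] <- x
        fill_cell(j + 1L, rem - x, col_rem - v, lcells - lfactorial(x))
      }
    }
    fill_cell(1L, row_sums[i], col_rem, lcells)
  }
  fill_row(1L, col_sums, 0)
  total
}

# Rough upper bound on the number of tables with the given margins, used to
# pick enumeration vs Markov chain under method = "auto".
table_count_bound <- function(row_sums, col_sums) {
  c <- length(col_sums)
  prod(vapply(row_sums[-length(row_sums)],
              function(s) choose(s + c - 1, c - 1), 0))
}

#' Exact probability test on a contingency table with fixed margins
#'
#' Fisher-style exact probability test on an r x c table (breeds x alleles
#' or breeds x genotypes): under the null of identical distributions across
#' rows, the table probability given its margins is multivariate
#' hypergeometric, and the p-value sums the probability of every table with
#' the same margins that is no more probable than the observed one.
#' Enumeration is exact; for larger tables a Metropolis chain over 2x2
#' rectangle moves (Raymond & Rousset style) estimates the same tail
#' probability with a batch-mean standard error.
#'
#' @param tab integer matrix of counts (rows: populations).
#' @param method `"auto"`, `"enumeration"` or `"markov_chain"`; `"auto"`
#'   enumerates when the table-count bound is below `enum_limit`.
#' @param enum_limit table-count bound above which `"auto"` switches to the
#'   chain.
#' @param dememorization,batches,iterations Markov-chain settings.
#' @param seed RNG seed for the chain.
#' @return an `exact_test_result`.
#' @examples
#' contingency_exact_test(rbind(c(10, 0), c(0, 10)))$p_value  # 2/choose(20,10)
#' @export
contingency_exact_test <- function(tab, method = c("auto", "enumeration",
                                                   "markov_chain"),
                                   enum_limit = 2e5,
                                   dememorization = 1000, batches = 20,
                                   iterations = 5000, seed = NULL) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  if (any(tab < 0)) stop("counts must be non-negative")
  zero_rows <- rowSums(tab) == 0
  if (any(zero_rows)) {
    warning("dropping ", sum(zero_rows), " population(s) with zero observations")
    tab <- tab[!zero_rows, , drop = FALSE]
  }
  if (nrow(tab) < 2L) stop("need at least two populations with observations")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L)   # single observed category: no differentiation possible
    return(exact_test_result(1, "enumeration", monomorphic = TRUE))
  lp_obs <- table_log_prob(tab)
  if (method == "auto")
    method <- if (table_count_bound(rowSums(tab), colSums(tab)) <= enum_limit)
      "enumeration" else "markov_chain"
  if (method == "enumeration") {
    p <- enumerate_tail_prob(rowSums(tab), colSums(tab), lp_obs)
    return(exact_test_result(min(p, 1), "enumeration"))
  }
  settings <- list(dememorization = dememorization, batches = batches,
                   iterations = iterations, seed = seed)
  with_seed(seed, {
    cur <- tab
    lp <- lp_obs
    r <- nrow(tab); cl <- ncol(tab)
    total <- dememorization + batches * iterations
    # rectangle move: pick two rows and two columns, +1 on one diagonal and
    # -1 on the other; P'/P = (b * d) / ((a + 1) * (e + 1)) (Metropolis)
    ri <- matrix(replicate(total, sample.int(r, 2L)), nrow = 2L)
    ci <- matrix(replicate(total, sample.int(cl, 2L)), nrow = 2L)
    lu <- log(stats::runif(total))
    hits <- integer(batches)
    h <- 0L
    for (t in seq_len(total)) {
      i1 <- ri[1L, t]; i2 <- ri[2L, t]; j1 <- ci[1L, t]; j2 <- ci[2L, t]
      a <- cur[i1, j1]; b <- cur[i1, j2]
      d <- cur[i2, j1]; e <- cur[i2, j2]
      if (b >= 1L && d >= 1L) {
        dlp <- log(b) + log(d) - log(a + 1) - log(e + 1)
        if (lu[t] <= dlp) {
          cur[i1, j1] <- a + 1L; cur[i1, j2] <- b - 1L
          cur[i2, j1] <- d - 1L; cur[i2, j2] <- e + 1L
          lp <- lp + dlp
        }
      }
      if (t > dememorization) {
        if (lp <= lp_obs + .TIE_TOL) h <- h + 1L
        if ((t - dememorization) %% iterations == 0L) {
          hits[(t - dememorization) %/% iterations] <- h
          h <- 0L
        }
      }
    }
    bm <- hits / iterations
    exact_test_result(mean(bm), "markov_chain",
                      mc_std_error = stats::sd(bm) / sqrt(batches),
                      settings = settings)
  })
}

#' Genic differentiation across breeds
#'
#' Exact probability test of allele-frequency homogeneity across breeds at
#' each locus: the breeds x alleles table of allele counts is tested with
#' [contingency_exact_test()].
#'
#' @param gm a [genotype_matrix()].
#' @param loci loci to test (default all).
#' @param ... passed to [contingency_exact_test()].
#' @return named list of `exact_test_result`, one per locus.
#' @export
genic_differentiation <- function(gm, loci = NULL, ...) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(loci)) loci <- gm$loci$locus
  res <- lapply(loci, function(l) {
    lc <- locus_counts(gm, l)
    tab <- as.matrix(lc[, c("n_A", "n_B")])
    rownames(tab) <- lc$breed
    contingency_exact_test(tab, ...)
  })
  stats::setNames(res, loci)
}

#' Genotypic differentiation across breeds
#'
#' Same exact probability-test logic as [genic_differentiation()], on the
#' wider breeds x genotypes (AA/AB/BB) table.
#'
#' @inheritParams genic_differentiation
#' @return named list of `exact_test_result`, one per locus.
#' @export
genotypic_differentiation <- function(gm, loci = NULL, ...) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(loci)) loci <- gm$loci$locus
  res <- lapply(loci, function(l) {
    lc <- locus_counts(gm, l)
    tab <- as.matrix(lc[, c("n_AA", "n_AB", "n_BB")])
    rownames(tab) <- lc$breed
    contingency_exact_test(tab, ...)
  })
  stats::setNames(res, loci)
}

#' Fisher's combined probability test over loci
#'
#' Aggregates per-locus p-values into a global test:
#' `chi_square = -2 * sum(log(p_i))` referred to a chi-square distribution
#' with `2 L` degrees of freedom. Zero p-values (possible only from
#' Monte-Carlo estimates) are floored at `p_floor` with a warning.
#'
#' @param p_values numeric vector of per-locus p-values in (0, 1].
#' @param p_floor floor applied to zero p-values (default 1e-16).
#' @return list of class `combined_test_result`: `chi_square`, `df`,
#'   `p_value`.
#' @examples
#' fisher_combined(c(0.5, 0.5))   # chi-square 2.77 on 4 df
#' @export
fisher_combined <- function(p_values, p_floor = 1e-16) {
  if (length(p_values) == 0L) stop("no p-values to combine")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("zero p-value(s) floored at ", p_floor)
    p_values[p_values == 0] <- p_floor
  }
  chi <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  structure(list(chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE)),
            class = "combined_test_result")
}

#' @export
print.combined_test_result <- function(x, ...) {
  cat(sprintf("Fisher combined test: chi-square = %.4f on %d df, p = %.6g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}
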