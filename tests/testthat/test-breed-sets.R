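# Build a small cohort db where presence is fully controlled: each entry of
# `sites` says which samples carry which site (all calls pass the default
# filters).
make_db <- function(sites, samples = study_samples()) {
  rows <- list()
  for (s in names(sites)) {
    parts <- strsplit(s, ":")[[1]]
    for (id in sites[[s]])
      rows[[length(rows) + 1]] <- call_row(id, parts[1],
                                           as.integer(parts[2]),
                                           ref = "A", alt = parts[3])
  }
  snp_db(do.call(rbind, rows), samples)
}

test_that("occurrence counts carriers per breed", {
  samp <- study_samples()
  a_ids <- samp$sample_id[samp$breed == "A"]
  db <- make_db(list("1:100:C" = a_ids[1],
                     "1:200:G" = samp$sample_id))
  occ <- tabulate_occurrence(db)
  r1 <- occ[occ$pos == 100, ]
  expect_equal(c(r1$n_A, r1$n_B, r1$n_C), c(1L, 0L, 0L))
  r2 <- occ[occ$pos == 200, ]
  expect_equal(c(r2$n_A, r2$n_B, r2$n_C), c(6L, 6L, 6L))

  empty <- snp_db(call_row("A01")[0, ], samp)
  expect_equal(nrow(tabulate_occurrence(empty)), 0L)
})

test_that("the four designations follow their definitions", {
  samp <- study_samples()
  ids <- split(samp$sample_id, samp$breed)
  db <- make_db(list("1:100:C" = ids$A,                    # all of A only
                     "1:200:G" = c(ids$A, ids$B),          # all of A and B
                     "1:300:T" = ids$A[1]))                # one A sample
  cats <- categorize(tabulate_occurrence(db))
  at <- function(pos) cats[cats$pos == pos, ]
  x <- at(100)
  expect_true(x$any_A && x$all_A && x$any_unique_A && x$all_unique_A)
  expect_false(x$any_B || x$any_C)
  y <- at(200)
  expect_true(y$all_A && y$all_B)
  expect_false(y$any_unique_A || y$any_unique_B || y$all_unique_A)
  z <- at(300)
  expect_true(z$any_A && z$any_unique_A)
  expect_false(z$all_A || z$all_unique_A)
})

test_that("category flags equal brute-force predicate evaluation on a random fixture", {
  samp <- study_samples()
  set.seed(77)
  # 200 sites, each carried by a random subset of samples
  sites <- list()
  for (i in 1:200) {
    carriers <- sample(samp$sample_id, sample(1:18, 1))
    sites[[sprintf("%d:%d:C", sample(1:5, 1), 1000 + i)]] <- carriers
  }
  db <- make_db(sites, samp)
  occ <- tabulate_occurrence(db)
  cats <- categorize(occ)

  key <- site_key(cats$chrom, cats$pos, cats$alt_base)
  cc <- db$calls
  ckey <- site_key(cc$chrom, cc$pos, cc$alt_base)
  breed_of <- setNames(samp$breed, samp$sample_id)
  for (i in seq_along(key)) {                       # brute force per site
    carriers <- cc$sample_id[ckey == key[i]]
    nb <- table(factor(breed_of[carriers], levels = c("A", "B", "C")))
    for (b in c("A", "B", "C")) {
      others <- sum(nb[setdiff(c("A", "B", "C"), b)])
      expect_equal(cats[[paste0("any_", b)]][i], nb[[b]] > 0)
      expect_equal(cats[[paste0("all_", b)]][i], nb[[b]] == 6)
      expect_equal(cats[[paste0("any_unique_", b)]][i],
                   nb[[b]] > 0 && others == 0)
      expect_equal(cats[[paste0("all_unique_", b)]][i],
                   nb[[b]] == 6 && others == 0)
    }
  }

  # implication chain and count ordering on every site
  for (b in c("A", "B", "C")) {
    expect_true(all(cats[[paste0("all_unique_", b)]] <= cats[[paste0("all_", b)]]))
    expect_true(all(cats[[paste0("all_", b)]] <= cats[[paste0("any_", b)]]))
    expect_true(all(cats[[paste0("all_unique_", b)]] <=
                      cats[[paste0("any_unique_", b)]]))
    expect_true(all(cats[[paste0("any_unique_", b)]] <= cats[[paste0("any_", b)]]))
  }
  ct <- category_counts(cats)
  expect_true(all(ct$all_unique <= ct$any_unique &
                    ct$any_unique <= ct$any &
                    ct$all_unique <= ct$all & ct$all <= ct$any))

  # Venn regions agree with brute-force set intersections over sample sets
  vc <- venn_counts(occ)
  pres <- sapply(c("A", "B", "C"), function(b)
    tapply(breed_of[cc$sample_id] == b, ckey, any))
  lab <- apply(pres, 1, function(r) paste(c("A", "B", "C")[r], collapse = "+"))
  expect_equal(vc[vc > 0], table(lab)[names(vc[vc > 0])],
               ignore_attr = TRUE)
})

test_that("counts are invariant under sample and breed reordering", {
  set.seed(42)
  calls <- random_calls(500, samples = study_samples()$sample_id, seed = 6)
  samp <- study_samples()
  db1 <- snp_db(calls, samp)
  perm <- sample(nrow(calls))
  db2 <- snp_db(calls[perm, ], samp[sample(nrow(samp)), ])
  c1 <- category_counts(categorize(tabulate_occurrence(db1)))
  c2 <- category_counts(categorize(tabulate_occurrence(db2)))
  expect_equal(c1[order(c1$breed), ], c2[order(c2$breed), ],
               ignore_attr = TRUE)
})

test_that("uniqueness against the raw database is stricter than against filtered", {
  samp <- study_samples()
  ids <- split(samp$sample_id, samp$breed)
  calls <- do.call(rbind, lapply(ids$A, function(id)
    call_row(id, "1", 100, "A", "C", 20, 20)))
  # one B sample carries the site below the filter thresholds
  calls <- rbind(calls, call_row(ids$B[1], "1", 100, "A", "C", 8, 4))
  db <- snp_db(calls, samp)
  spec <- filter_spec(10, 90)
  vs_raw <- categorize_breed_specific(db, spec, unique_vs = "raw")
  vs_filt <- categorize_breed_specific(db, spec, unique_vs = "filtered")
  expect_false(vs_raw$all_unique_A)
  expect_true(vs_filt$all_unique_A)
  expect_true(vs_raw$all_A)   # the breed-specific flag is unaffected
})

test_that("de-novo flags are exactly the reference-N sites passing the filter", {
  spec <- filter_spec(10, 90)
  calls <- rbind(call_row("A01", "1", 10, ref = "N", alt = "C", 12, 12),
                 call_row("A01", "1", 20, ref = "A", alt = "C", 12, 12),
                 call_row("A01", "1", 30, ref = "N", alt = "T", 8, 8))
  db <- snp_db(calls, study_samples())
  dn <- flag_de_novo(db, spec)
  expect_equal(dn$pos, 10L)          # ref A never de novo; 8 reads fails depth
  expect_true(all(dn$de_novo))

  d <- cohort_design(n_sites = 400, frac_ref_N = 0.05, error_rate = 0,
                     mean_depth = 50, min_depth = 10, seed = 13)
  sim <- simulate_cohort(d)
  planted <- sim$truth[sim$truth$category == "ref_N", ]
  dn2 <- flag_de_novo(sim$db, spec)
  # flagged sites = planted reference-N sites that are actually segregating
  # (an alternate read exists in some sample at >= threshold depth)
  expect_true(all(site_key(dn2$chrom, dn2$pos, dn2$alt_base) %in%
                    site_key(planted$chrom, planted$pos, planted$alt_base)))
  dos <- attr(sim$truth, "dosage")
  seg <- planted[rowSums(dos[sim$truth$category == "ref_N", , drop = FALSE] >=
                           1) > 0, ]
  # every planted N site carried hom-alt by some sample must be recovered
  hom <- planted[rowSums(dos[sim$truth$category == "ref_N", , drop = FALSE] ==
                           2) > 0, ]
  expect_true(all(site_key(hom$chrom, hom$pos, hom$alt_base) %in%
                    site_key(dn2$chrom, dn2$pos, dn2$alt_base)))
})

test_that("reference-error candidates need every sample to share one alternate", {
  samp <- study_samples()
  all18 <- lapply(samp$sample_id, function(id)
    call_row(id, "2", 500, "A", "G", 15, 15))
  db <- snp_db(do.call(rbind, all18), samp)
  spec <- filter_spec(10, 90)
  flagged <- flag_ref_error_candidates(db, spec)
  expect_equal(flagged$pos, 500L)
  expect_equal(flagged$alt_base, "G")

  # absent in one sample: not flagged
  db17 <- snp_db(do.call(rbind, all18[-1]), samp)
  expect_equal(nrow(flag_ref_error_candidates(db17, spec)), 0L)

  # a discordant alternate allele in one sample disqualifies the site
  disc <- rbind(do.call(rbind, all18),
                call_row(samp$sample_id[1], "2", 500, "A", "T", 12, 12))
  expect_equal(nrow(flag_ref_error_candidates(snp_db(disc, samp), spec)), 0L)
})
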