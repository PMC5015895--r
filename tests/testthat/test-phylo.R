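# Random tree with positive branch lengths; its cophenetic distances are
# additive, so NJ must reconstruct it exactly.
random_additive <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
    tr
  })
}

test_that("presence distances match brute-force pairwise comparison", {
  samp <- study_samples()
  calls <- random_calls(300, samples = samp$sample_id, seed = 12)
  db <- snp_db(calls, samp)
  D <- snp_distance(db)
  cc <- db$calls
  key <- site_key(cc$chrom, cc$pos, cc$alt_base)
  universe <- sort(unique(key))
  for (i in c(1, 5, 9)) for (j in c(2, 7, 18)) {
    si <- universe %in% key[cc$sample_id == samp$sample_id[i]]
    sj <- universe %in% key[cc$sample_id == samp$sample_id[j]]
    expect_equal(D[samp$sample_id[i], samp$sample_id[j]],
                 mean(si != sj), tolerance = 1e-12)
  }
  expect_equal(diag(D), setNames(rep(0, 18), samp$sample_id))
  expect_equal(D, t(D))
})

test_that("identical and disjoint samples hit the distance extremes", {
  samp <- study_samples()[1:3, ]
  # s1 and s2 identical; s3 disjoint from both
  calls <- rbind(call_row(samp$sample_id[1], "1", 1),
                 call_row(samp$sample_id[1], "1", 2),
                 call_row(samp$sample_id[2], "1", 1),
                 call_row(samp$sample_id[2], "1", 2),
                 call_row(samp$sample_id[3], "1", 3))
  db <- snp_db(calls, samp)
  D <- snp_distance(db)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)
  expect_error(snp_distance(snp_db(calls[1:2, ], samp[1, ])), "3 samples")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["A"]], 1)
  expect_equal(len[["B"]], 1)
  expect_equal(len[["C"]], 3)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)))
})

test_that("NJ reconstructs additive distances exactly", {
  for (seed in 1:6) {
    n <- sample(5:8, 1)
    tr0 <- random_additive(n, seed)
    D <- ape::cophenetic.phylo(tr0)
    tr <- neighbor_joining(D)
    expect_equal(ape::dist.topo(tr, tr0), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  # all-zero distances: a tree with all zero branch lengths
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(neighbor_joining(z)$edge.length == 0))
})

test_that("negative NJ branches are clamped without losing path length", {
  d <- matrix(c(0, 1, 6, 6, 1, 0, 6, 6, 6, 6, 0, 0.2, 6, 6, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("breed monophyly detection matches the bipartition definition", {
  meta <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                     breed = c("A", "A", "B", "B"))
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  expect_equal(is_breed_monophyletic(tr, meta), c(A = TRUE, B = TRUE))
  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_equal(is_breed_monophyletic(tr2, meta), c(A = FALSE, B = FALSE))
  expect_error(
    is_breed_monophyletic(tr, data.frame(sample_id = "zz", breed = "Z")),
    "absent")

  # brute-force oracle: remove each internal edge and compare components
  for (seed in 7:9) {
    tr3 <- random_additive(7, seed)
    meta3 <- data.frame(sample_id = tr3$tip.label,
                        breed = sample(c("X", "Y"), 7, replace = TRUE))
    if (length(unique(meta3$breed)) < 2) next
    got <- is_breed_monophyletic(tr3, meta3)
    for (b in unique(meta3$breed)) {
      s <- sort(meta3$sample_id[meta3$breed == b])
      want <- length(s) <= 1 || length(s) >= 6
      if (!want) {
        ntip <- 7L
        for (e in which(tr3$edge[, 2] > ntip)) {
          # tips below the child node of edge e
          stack <- tr3$edge[e, 2]; below <- integer(0)
          while (length(stack)) {
            nd <- stack[1]; stack <- stack[-1]
            kids <- tr3$edge[tr3$edge[, 1] == nd, 2]
            below <- c(below, kids[kids <= ntip])
            stack <- c(stack, kids[kids > ntip])
          }
          tipset <- sort(tr3$tip.label[below])
          if (identical(tipset, s) ||
              identical(sort(setdiff(tr3$tip.label, tipset)), s)) {
            want <- TRUE; break
          }
        }
      }
      expect_equal(got[[b]], want)
    }
  }
})

test_that("site bootstrap is deterministic and degenerate at one replicate", {
  d <- cohort_design(n_sites = 400, fst = 0.4, error_rate = 0,
                     mean_depth = 40, min_depth = 10, seed = 19)
  sim <- simulate_cohort(d)
  f <- apply_filter(sim$db, filter_spec(10, 90))
  t1 <- bootstrap_support(f, replicates = 25, seed = 7)
  t2 <- bootstrap_support(f, replicates = 25, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  one <- bootstrap_support(f, replicates = 1, seed = 1)
  supp <- attr(one, "bootstrap_pct")
  expect_true(all(supp[!is.na(supp)] %in% c(0, 100)))
})

test_that("newick round-trip preserves topology, lengths and supports", {
  d <- cohort_design(n_sites = 300, fst = 0.4, error_rate = 0,
                     mean_depth = 40, min_depth = 10, seed = 20)
  sim <- simulate_cohort(d)
  f <- apply_filter(sim$db, filter_spec(10, 90))
  tr <- bootstrap_support(f, replicates = 10, seed = 2)
  fn <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, fn)
  back <- ape::read.tree(fn)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_setequal(setdiff(back$node.label, ""), setdiff(tr$node.label, ""))
  co <- ape::cophenetic.phylo(tr)
  expect_equal(ape::cophenetic.phylo(back)[rownames(co), colnames(co)], co,
               tolerance = 1e-9)
})

test_that("diverged breeds come out monophyletic with high support", {
  d <- cohort_design(n_sites = 600, fst = 0.5, error_rate = 0,
                     mean_depth = 40, min_depth = 10, seed = 21)
  sim <- simulate_cohort(d)
  f <- apply_filter(sim$db, filter_spec(10, 90))
  tr <- bootstrap_support(f, replicates = 50, seed = 5)
  mono <- is_breed_monophyletic(tr, sim$db$samples)
  expect_true(all(mono))
})
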