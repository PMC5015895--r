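# Sample-level SNP phylogeny: presence/absence Hamming distances over the
# filtered site universe, neighbor-joining (via ape) with negative-branch
# clamping, site bootstrap, and a breed-monophyly check. Distance-based NJ
# replaces likelihood tree building: per-sample SNP databases are
# presence/allele calls, not genotypes, and NJ is exact on additive
# distances, which is what the clustering claim needs.

# samples x sites logical presence matrix over a site-key universe
presence_matrix <- function(db, universe = NULL) {
  cc <- db$calls
  key <- site_key(cc$chrom, cc$pos, cc$alt_base)
  if (is.null(universe)) universe <- sort(unique(key))
  ids <- db$samples$sample_id
  P <- matrix(FALSE, length(ids), length(universe),
              dimnames = list(ids, universe))
  idx <- cbind(match(cc$sample_id, ids), match(key, universe))
  idx <- idx[!is.na(idx[, 2]), , drop = FALSE]
  P[idx] <- TRUE
  P
}

dist_from_presence <- function(P) {
  m <- ncol(P)
  Pn <- P * 1
  D <- (Pn %*% t(1 - Pn) + (1 - Pn) %*% t(Pn)) / max(m, 1L)
  diag(D) <- 0
  D
}

#' Pairwise SNP presence distance between samples
#'
#' Distance between two samples is the fraction of sites in the shared
#' universe (by default, the union of all site keys in `db`) at which their
#' presence differs. Sites with the same position but different alternate
#' alleles are distinct universe entries, so allele disagreements count on
#' both keys.
#'
#' @param db a (typically filtered) `snp_db` with at least 3 samples.
#' @param universe optional character vector of site keys to compare over.
#' @return symmetric numeric matrix in [0, 1] with zero diagonal.
#' @export
snp_distance <- function(db, universe = NULL) {
  stopifnot(inherits(db, "snp_db"))
  if (nrow(db$samples) < 3L) stop("need at least 3 samples for a phylogeny")
  dist_from_presence(presence_matrix(db, universe))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ agglomeration. Negative branch lengths, which NJ can
#' produce on non-additive input, are clamped to zero with the clamped
#' amount transferred to the sister edge so path lengths through the parent
#' are preserved.
#'
#' @param d symmetric distance matrix with at least 3 labelled taxa.
#' @return an unrooted `phylo` tree (class from \pkg{ape}).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tr)
}

# Zero out negative edges, moving the deficit onto a sister edge (same
# parent node) so the tree keeps non-negative lengths.
clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    amt <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sisters)) {
      s <- sisters[1]
      tr$edge.length[s] <- tr$edge.length[s] + amt
    } else break
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with site-bootstrap support
#'
#' Builds the NJ tree on the full site universe, then resamples universe
#' sites with replacement `replicates` times, rebuilding the tree each time;
#' the support of each internal edge is the percentage of replicates
#' containing the same bipartition. Deterministic for a fixed seed.
#'
#' @param db a (typically filtered) `snp_db`, >= 3 samples.
#' @param replicates bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param universe optional site-key universe.
#' @return a `phylo` tree whose `node.label` holds integer percent supports
#'   (`NA` on the root node).
#' @export
bootstrap_support <- function(db, replicates = 100, seed = NULL,
                              universe = NULL) {
  stopifnot(replicates >= 1)
  P <- presence_matrix(db, universe)
  if (nrow(P) < 3L) stop("need at least 3 samples")
  main <- neighbor_joining(dist_from_presence(P))
  boots <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      idx <- sample.int(ncol(P), ncol(P), replace = TRUE)
      neighbor_joining(dist_from_presence(P[, idx, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  supp <- round(100 * counts / replicates)
  main$node.label <- as.character(supp)
  main$node.label[is.na(supp)] <- ""
  attr(main, "bootstrap_pct") <- supp
  main
}

#' Breed monophyly on an unrooted tree
#'
#' A breed is monophyletic iff its samples' leaves form one side of a
#' bipartition of the unrooted tree (equivalently, a clade of the tree under
#' some rooting). Trivially true for breeds with one sample or all samples.
#'
#' @param tree a `phylo` tree whose tips are sample ids.
#' @param meta data.frame with columns `sample_id`, `breed` covering the
#'   tree's tips.
#' @return named logical vector, one element per breed.
#' @export
is_breed_monophyletic <- function(tree, meta) {
  stopifnot(inherits(tree, "phylo"),
            all(c("sample_id", "breed") %in% names(meta)))
  breeds <- sort(unique(meta$breed[!is.na(meta$breed)]))
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  part_sets <- lapply(parts, function(p) sort(labels[p]))
  res <- vapply(breeds, function(b) {
    s <- meta$sample_id[meta$breed %in% b]
    if (!all(s %in% tips))
      stop("breed ", b, " has sample(s) absent from the tree")
    s <- sort(s)
    if (length(s) <= 1L || length(s) >= length(tips) - 1L) return(TRUE)
    comp <- sort(setdiff(tips, s))
    any(vapply(part_sets, identical, TRUE, s)) ||
      any(vapply(part_sets, identical, TRUE, comp))
  }, TRUE)
  stats::setNames(res, breeds)
}
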