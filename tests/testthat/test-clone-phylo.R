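# Clone member collection, center-star alignment and Fitch parsimony trees.

test_that("clone members need >= 2 reads in at least one sample, with origin labels", {
  base <- paste(rep("A", 30), collapse = "")
  A <- base
  B <- sub("^A", "C", base)
  C <- sub("^AA", "GG", base)
  sig <- mk_signature(A)
  diag <- mk_rep(c(A, B, C), c(5L, 2L, 1L), id = "diag")
  rel <- mk_rep(c(A, B), c(9L, 3L), id = "rel")
  mem <- collect_clone_members(sig, diag, rel)
  expect_setequal(mem$seq, c(A, B))     # C excluded by min_count
  expect_equal(mem$origin, c("both", "both"))

  # disjoint member sets are all single-origin
  D <- sub("^AAA", "TTT", base)
  mem2 <- collect_clone_members(sig, mk_rep(c(A, B), c(4L, 2L), id = "d"),
                                mk_rep(D, 3L, id = "r"))
  expect_setequal(mem2$origin, c("diagnosis-only", "relapse-only"))

  expect_error(collect_clone_members(sig, mk_rep(A, 1L, id = "d"),
                                     mk_rep(base, 1L, id = "r")),
               class = "bcrmrd_insufficient_data")
})

test_that("planted diagnosis-relapse sharing is recovered within 3 s.e.", {
  cfg <- sim_config(seed = 77, cloud_size = 80L)
  db <- simulate_germline(cfg)
  pair <- simulate_diag_relapse(cfg, db, share = 0.8)
  sig <- define_signatures(pair$diagnosis)[[1L]]
  mem <- collect_clone_members(sig, pair$diagnosis, pair$relapse)
  ss <- structure_summary(align_members(mem))
  n_diag <- sum(mem$origin != "relapse-only")
  se <- sqrt(0.8 * 0.2 / n_diag)
  expect_lt(abs(ss$overlap - 0.8), 3 * se)
})

test_that("center-star alignment is the identity on equal lengths and gaps deletions", {
  base <- "ACGTACGTACGTACGTACGT"
  mem <- data.frame(seq = c(base, mutate_at(base, 5L)),
                    count_diag = c(9L, 2L), count_rel = c(4L, 1L),
                    origin = "both", stringsAsFactors = FALSE)
  aln <- align_members(mem)
  expect_equal(unname(aln$aligned), mem$seq)   # no gaps introduced
  expect_equal(aln$central_seq, base)          # highest summed count wins

  # a 3-base deletion introduces exactly 3 gap columns
  del <- paste0(substr(base, 1L, 8L), substr(base, 12L, 20L))
  mem2 <- data.frame(seq = c(base, del), count_diag = c(9L, 2L),
                     count_rel = c(0L, 0L), origin = "diagnosis-only",
                     stringsAsFactors = FALSE)
  aln2 <- align_members(mem2)
  expect_equal(nchar(aln2$aligned[[1L]]), 20L)
  expect_equal(sum(strsplit(aln2$aligned[[del]], "")[[1L]] == "-"), 3L)
})

test_that("center-star sum-of-pairs cost respects the 2-approximation bound", {
  # lower bound on the optimal SP cost: sum of pairwise edit distances
  sp_cost <- function(aligned) {
    mat <- do.call(rbind, strsplit(unname(aligned), ""))
    tot <- 0
    for (i in seq_len(nrow(mat) - 1L)) {
      for (j in (i + 1L):nrow(mat)) {
        keep <- !(mat[i, ] == "-" & mat[j, ] == "-")
        tot <- tot + sum(mat[i, keep] != mat[j, keep])
      }
    }
    tot
  }
  withr::local_seed(55)
  for (case in 1:10) {
    center <- random_seq(30)
    variants <- vapply(1:4, function(i) {
      v <- mutate_at(center, sample.int(30L, 1L))
      if (runif(1) < 0.5) v <- paste0(substr(v, 1L, 10L), substr(v, 13L, nchar(v)))
      v
    }, "")
    mem <- data.frame(seq = unique(c(center, variants)),
                      count_diag = c(10L, rep(1L, length(unique(c(center, variants))) - 1L)),
                      count_rel = 0L, origin = "diagnosis-only",
                      stringsAsFactors = FALSE)
    aln <- align_members(mem)
    lens <- nchar(unname(aln$aligned))
    expect_length(unique(lens), 1L)
    lower <- sum(utils::combn(mem$seq, 2L, function(p) utils::adist(p[1L], p[2L])))
    expect_lte(sp_cost(aln$aligned), 2L * lower)
  }
})

test_that("two-tip and forced-star parsimony cases are exact", {
  mem <- data.frame(seq = c("AAAA", "AATT"), count_diag = c(3L, 1L),
                    count_rel = 0L, origin = "diagnosis-only",
                    stringsAsFactors = FALSE)
  pt <- build_parsimony_tree(align_members(mem))
  expect_equal(pt$total_length, 2L)
  expect_equal(sum(pt$tree$edge.length), 2)

  # central sequence plus two single-mutation variants at different sites
  mem3 <- data.frame(seq = c("AAAAAA", "TAAAAA", "AAATAA"),
                     count_diag = c(10L, 1L, 1L), count_rel = 0L,
                     origin = "diagnosis-only", stringsAsFactors = FALSE)
  pt3 <- build_parsimony_tree(align_members(mem3))
  expect_equal(pt3$total_length, 2L)
})

test_that("heuristic parsimony equals the exhaustive optimum on small instances", {
  skip_if_not_installed("phangorn")
  withr::local_seed(66)
  for (case in 1:10) {
    n <- sample(4:6, 1L)
    center <- random_seq(25)
    seqs <- unique(c(center, vapply(seq_len(n - 1L), function(i) {
      s <- center
      for (k in seq_len(sample(1:4, 1L))) s <- mutate_at(s, sample.int(25L, 1L))
      s
    }, "")))
    if (length(seqs) < 3L) next
    mem <- data.frame(seq = seqs, count_diag = c(10L, rep(1L, length(seqs) - 1L)),
                      count_rel = 0L, origin = "diagnosis-only",
                      stringsAsFactors = FALSE)
    aln <- align_members(mem)
    pt <- build_parsimony_tree(aln)
    # independent oracle: exhaustive Fitch over all unrooted topologies
    dat <- phangorn::phyDat(t(sapply(strsplit(unname(aln$aligned), ""), identity)),
                            type = "DNA")
    names(dat) <- paste0("t", seq_along(aln$aligned))
    all_trees <- phangorn::allTrees(length(seqs), rooted = FALSE,
                                    tip.label = names(dat))
    best <- min(vapply(all_trees, function(tr) phangorn::parsimony(tr, dat), 0))
    expect_equal(pt$total_length, best)
  }
})

test_that("parsimony score obeys its lower bounds and branch-length identity", {
  withr::local_seed(91)
  for (case in 1:5) {
    seqs <- unique(replicate(6, random_seq(15)))
    mem <- data.frame(seq = seqs, count_diag = rep(2L, length(seqs)),
                      count_rel = 0L, origin = "diagnosis-only",
                      stringsAsFactors = FALSE)
    aln <- align_members(mem)
    pt <- build_parsimony_tree(aln)
    mat <- do.call(rbind, strsplit(unname(aln$aligned), ""))
    max_pair <- max(utils::combn(nrow(mat), 2L,
                                 function(p) sum(mat[p[1L], ] != mat[p[2L], ])))
    n_variable <- sum(apply(mat, 2L, function(col) length(unique(col)) > 1L))
    expect_gte(pt$total_length, max_pair)
    expect_gte(pt$total_length, n_variable)
    expect_equal(sum(pt$tree$edge.length), pt$total_length)
  }
})

test_that("star-like clones place the central BCR adjacent to most tips", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 1000L + s, cloud_size = 12L, cloud_geom_mean = 1)
    db <- simulate_germline(cfg)
    clone <- simulate_clone(cfg, db)
    tr <- attr(clone, "truth")
    mem <- data.frame(seq = tr$seq, count_diag = tr$count, count_rel = 0L,
                      origin = "diagnosis-only", stringsAsFactors = FALSE)
    aln <- align_members(mem)
    pt <- build_parsimony_tree(aln)
    # the tree is binary, so "adjacent to the center" means reachable from
    # the central tip through zero-length internal branches
    central_label <- names(pt$tip_seqs)[pt$tip_seqs == aln$central_seq]
    tipid <- match(central_label, pt$tree$tip.label)
    n <- length(pt$tree$tip.label)
    dmat <- ape::dist.nodes(pt$tree)
    pendant <- vapply(seq_len(n), function(t) {
      pt$tree$edge.length[pt$tree$edge[, 2L] == t]
    }, 0)
    others <- setdiff(seq_len(n), tipid)
    internal_path <- dmat[tipid, others] - pendant[tipid] - pendant[others]
    n_adjacent <- sum(internal_path <= 0)
    n_adjacent >= (pt$n_tips - 1L) / 2
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("structure summaries report overlap, shells and frequency correlation", {
  s <- function(i) paste0(paste(rep("A", i), collapse = ""),
                          paste(rep("C", 10L - i), collapse = ""))
  mem <- data.frame(seq = c(s(1), s(2), s(3), s(4), s(5)),
                    count_diag = c(4L, 3L, 2L, 1L, 0L),
                    count_rel = c(4L, 3L, 2L, 0L, 1L),
                    origin = c("both", "both", "both", "diagnosis-only",
                               "relapse-only"),
                    stringsAsFactors = FALSE)
  aln <- align_members(mem)
  ss <- structure_summary(aln)
  expect_equal(ss$overlap, 0.75)  # 3 of 4 diagnosis members resampled
  expect_equal(sum(ss$shells$n_diag), 4L)
  expect_equal(sum(ss$shells$n_rel), 4L)

  # identical frequency vectors give R^2 = 1 on both scales
  mem2 <- mem
  mem2$count_rel <- mem$count_diag * 3L
  ss2 <- structure_summary(align_members(mem2))
  expect_equal(ss2$r2_raw, 1)
  expect_equal(ss2$r2_cuberoot, 1)
})

test_that("trees and alignments export to newick and FASTA", {
  mem <- data.frame(seq = c("AAAAAA", "TAAAAA", "AAATAA"),
                    count_diag = c(10L, 1L, 1L), count_rel = 0L,
                    origin = "diagnosis-only", stringsAsFactors = FALSE)
  aln <- align_members(mem)
  pt <- build_parsimony_tree(aln)
  tf <- tempfile(fileext = ".nwk")
  export_tree(pt, tf)
  reread <- ape::read.tree(tf)
  expect_setequal(reread$tip.label, pt$tree$tip.label)
  expect_equal(sum(reread$edge.length), pt$total_length)
  fa <- tempfile(fileext = ".fasta")
  export_alignment(aln, fa)
  expect_length(Biostrings::readBStringSet(fa), 3L)
})

test_that("bootstrap support is high for well-separated clades", {
  base <- paste(rep("A", 40), collapse = "")
  far <- paste0(paste(rep("T", 20), collapse = ""), substr(base, 21L, 40L))
  mem <- data.frame(seq = c(base, mutate_at(base, 2L), far, mutate_at(far, 39L)),
                    count_diag = c(10L, 2L, 8L, 2L), count_rel = 0L,
                    origin = "diagnosis-only", stringsAsFactors = FALSE)
  bs <- parsimony_bootstrap(align_members(mem), reps = 30L, seed = 4L)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  expect_gte(max(bs$support), 0.7)
})
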