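# Mutational combinatorics, hypergeometric overlap, shared-mutation
# baseline, and 96-context trinucleotide profiles.

test_that("mutational combinations count variant shells exactly", {
  expect_equal(mutational_combinations(300, 0), 1)  # only the central sequence
  expect_equal(mutational_combinations(1, 1), 3)    # three other bases
  expect_equal(mutational_combinations(4, 2), oracle_count_at_distance(4, 2))
  expect_equal(mutational_combinations(4, 2), 54)
  expect_error(mutational_combinations(3, 4), class = "bcrmrd_domain_error")
  expect_equal(log_mutational_combinations(300, 8),
               log(choose(300, 8)) + 8 * log(3))
})

test_that("overlap p-value is the exact hypergeometric upper tail", {
  expect_equal(overlap_pvalue(100, 10, 10, 0), 1)       # P(X >= 0)
  expect_equal(overlap_pvalue(54, 2, 2, 1), 105 / 1431) # exact tail
  expect_equal(overlap_pvalue(10, 10, 4, 4), 1)         # forced total overlap

  # matches naive pmf summation on random feasible parameter sets
  withr::local_seed(12)
  for (i in 1:25) {
    N <- sample(20:10000, 1L)
    n1 <- sample.int(min(N, 200L), 1L)
    n2 <- sample.int(min(N, 200L), 1L)
    k <- sample(max(0L, n1 + n2 - N):min(n1, n2), 1L)
    expect_equal(overlap_pvalue(N, n1, n2, k), oracle_hyper_tail(N, n1, n2, k),
                 tolerance = 1e-12)
  }
  # log-safe at astronomically large N
  p <- overlap_pvalue(mutational_combinations(300, 6), 20, 20, 3)
  expect_true(p > 0 && p < 1e-30)
  expect_error(overlap_pvalue(10, 20, 5, 2), class = "bcrmrd_infeasible_test")
})

test_that("Fisher combination and per-shell feasibility flags behave", {
  expect_equal(fisher_combine(0.5), 0.5, tolerance = 1e-12)
  expect_lt(fisher_combine(c(1e-10, 1e-10)), 1e-15)

  # shells with more observed members than possible variants are flagged
  base <- paste(rep("A", 6), collapse = "")
  vars <- c("TAAAAA", "ATAAAA", "AATAAA", "AAATAA", "AAAATA", "AAAAAT",
            "CAAAAA", "ACAAAA", "AACAAA", "AAACAA", "AAAACA", "AAAAAC",
            "GAAAAA", "AGAAAA", "AAGAAA", "AAAGAA", "AAAAGA", "AAAAAG",
            "TTAAAA")
  mem <- data.frame(seq = c(base, vars),
                    count_diag = c(50L, rep(2L, 19L)),
                    count_rel = c(50L, rep(2L, 19L)),
                    origin = "both", stringsAsFactors = FALSE)
  ov <- diag_relapse_overlap(align_members(mem))
  expect_true(all(ov$shells$feasible[ov$shells$d == 1L]))  # N = 18 = n_diag
  expect_equal(ov$shells$N[ov$shells$d == 1L], 18)
  expect_true(ov$combined_p <= 1)
})

test_that("shared-mutation fractions hit the 0/1 boundaries and the m/L collision rate", {
  db <- toy_germline()
  vlen <- nchar(db$V[[1L]])
  # build a 7-member Hamming-1 star whose V region carries fixed mutations
  mk_clone_rep <- function(v_muts, j = 1L, id = "h1", n1 = "GGA") {
    s <- toy_read(db, v = 1L, j = j, n1 = n1)$seq
    for (p in v_muts) s <- mutate_at(s, p)
    stem_off <- nchar(s) - 3L  # mutate near the end (J region) for variants
    members <- c(s, vapply(0:5, function(k) mutate_at(s, stem_off - k), ""))
    mk_rep(unique(members), rep(3L, length(unique(members))), id = id)
  }
  withr::local_seed(40)
  repA <- mk_clone_rep(c(5L, 10L), j = 1L, id = "h1")
  repB <- mk_clone_rep(c(20L, 25L), j = 2L, id = "h1", n1 = "TCA")
  bl <- shared_mutation_baseline(list(repA, repB), db, min_score_v = 15)
  expect_equal(bl$shared_fraction, 0)        # disjoint V mutations
  expect_equal(bl$source, "sameV_diffJ")

  repC <- mk_clone_rep(c(5L, 10L), j = 2L, id = "h2", n1 = "TCA")
  blC <- shared_mutation_baseline(list(repA, repC), db, min_score_v = 15)
  expect_equal(blC$shared_fraction, 1)       # identical V mutation sets

  expect_error(shared_mutation_baseline(list(repA), db, min_score_v = 15),
               class = "bcrmrd_insufficient_data")

  # independent uniform mutations collide at rate ~ m/L
  m <- 6L
  reps <- lapply(1:12, function(i) {
    mk_clone_rep(sample.int(vlen - 2L, m) + 1L, j = 1L, id = paste0("ind", i))
  })
  bl2 <- shared_mutation_baseline(reps, db, min_score_v = 10)
  n_ind <- 12L
  se <- sd(bl2$shared_fraction) / sqrt(n_ind)
  expect_lt(abs(mean(bl2$shared_fraction) - m / vlen), 3 * se + 0.02)
})

test_that("one-sided Mann-Whitney comparison is exact for small groups", {
  r <- compare_shared_mutations(c(0, 0, 0.1), c(0.5, 0.6))
  expect_equal(r$p_value, 0.1)               # 1 / choose(5, 2)
  expect_equal(r$method, "exact enumeration")

  # wrong-direction one-sided test cannot be significant
  expect_gte(compare_shared_mutations(c(0.5, 0.6, 0.7), c(0.1, 0.2))$p_value, 0.5)
  # identical groups sit near the null center
  expect_equal(compare_shared_mutations(c(1, 2, 3), c(1, 2, 3))$p_value, 0.65,
               tolerance = 0.2)

  # large-sample path agrees with the exact path on a borderline case
  withr::local_seed(3)
  base <- runif(15)
  obs <- runif(10) + 0.3
  exact <- compare_shared_mutations(base[1:10], obs[1:10])
  expect_true(exact$p_value > 0 && exact$p_value <= 1)
  large <- compare_shared_mutations(c(base, base), c(obs, obs))
  expect_equal(large$method, "normal approximation (tie-corrected)")
})

test_that("triplet profiles classify mutations pyrimidine-centrically", {
  p <- triplet_profile("AACGA", "AATGA")
  expect_equal(p$total, 1)
  expect_equal(unname(p$counts[["A[C>T]G"]]), 1)

  # terminal mutations are excluded and counted
  p2 <- triplet_profile("AACGA", "TACGA")
  expect_equal(p2$total, 0)
  expect_equal(p2$n_terminal_excluded, 1)

  # purine reference positions strand-collapse to the reverse complement
  p3 <- triplet_profile("AAGAA", "AATAA")  # G>T at pos 3, context A[G>T]A
  expect_equal(unname(p3$counts[["T[C>A]T"]]), 1)

  # read-count weighting
  p4 <- triplet_profile("AACGA", c("AATGA", "AAGGA"), counts = c(5L, 2L))
  expect_equal(p4$total, 7)
  expect_equal(unname(p4$counts[["A[C>T]G"]]), 5)
  expect_equal(unname(p4$counts[["A[C>G]G"]]), 2)
})

test_that("planted WRC/GYW hotspot mutations enrich AID motif positions", {
  cfg <- sim_config(seed = 19, hotspot_multiplier = 8, cloud_size = 200L)
  db <- simulate_germline(cfg)
  clone <- simulate_clone(cfg, db)
  tr <- attr(clone, "truth")
  anc <- strsplit(tr$seq[1L], "")[[1L]]
  L <- length(anc)
  # independent motif scan of the ancestor: WRC-mutable C / GYW-mutable G
  is_hot <- vapply(seq_len(L), function(i) {
    (anc[i] == "C" && i >= 3L && anc[i - 2L] %in% c("A", "T") &&
       anc[i - 1L] %in% c("A", "G")) ||
      (anc[i] == "G" && i <= L - 2L && anc[i + 1L] %in% c("C", "T") &&
         anc[i + 2L] %in% c("A", "T"))
  }, TRUE)
  pos <- unlist(attr(clone, "mutation_positions"))
  # planted-rate oracle: uniform placement hits hotspots at rate h/L
  bt <- binom.test(sum(is_hot[pos]), length(pos), p = mean(is_hot),
                   alternative = "greater")
  expect_lt(bt$p.value, 0.005)
  # and the resulting triplet profile concentrates in C-type contexts
  prof <- triplet_profile(tr$seq[1L], tr$seq[-1L])
  c_type <- grepl("\\[C>", names(prof$counts))
  expect_gt(sum(prof$counts[c_type]) / prof$total, 0.5)
})

test_that("profile comparison finds planted differences and respects Bonferroni", {
  mk_prof <- function(counts) {
    tab <- setNames(numeric(96), names(triplet_profile("AACGA", "AACGA")$counts))
    tab[seq_along(counts)] <- counts
    structure(list(counts = tab, total = sum(tab), n_terminal_excluded = 0,
                   n_ambiguous_skipped = 0), class = "mutation_profile")
  }
  p1 <- mk_prof(rep(10, 10))
  cmp_same <- compare_profiles(p1, p1)
  expect_equal(attr(cmp_same, "n_significant_raw"), 0L)

  # all mutations in one context vs a flat profile: Bonferroni-significant
  p_conc <- mk_prof(c(100))
  p_flat <- mk_prof(rep(1, 96))
  cmp <- compare_profiles(p_conc, p_flat)
  expect_true(cmp$significant_bonferroni[1L])
  # cross-check that context's p against the exact 2x2 hypergeometric
  p_manual <- fisher.test(matrix(c(100, 0, 1, 95), 2L))$p.value
  expect_equal(cmp$p[1L], p_manual, tolerance = 1e-6)
})

test_that("error-site overlap is null for disjoint sites and extreme when shared", {
  t1 <- paste(rep("A", 300), collapse = "")
  mk_ctrl <- function(sites, id) {
    vars <- vapply(sites, function(p) mutate_at(t1, p), "")
    mk_rep(c(t1, vars), c(50L, rep(1L, length(vars))), id = id)
  }
  withr::local_seed(61)
  r1 <- mk_ctrl(1:5, "c1")
  r2 <- mk_ctrl(11:15, "c2")
  out <- error_site_overlap(list(r1, r2))
  expect_equal(out$k, 0L)
  expect_equal(out$p, 1)

  r3 <- mk_ctrl(1:5, "c3")  # identical error sites
  out2 <- error_site_overlap(list(r1, r3))
  expect_equal(out2$k, 5L)
  expect_lt(out2$p, 1e-9)
  expect_equal(out2$p, 1 / choose(300, 5), tolerance = 1e-9)

  # uniform random error sites: Bonferroni-significant fraction stays small
  ctrls <- lapply(1:15, function(i) mk_ctrl(sample.int(300L, 5L), paste0("u", i)))
  res <- error_site_overlap(ctrls)
  n_sig <- sum(pmin(1, res$p * nrow(res)) < 0.05)
  expect_equal(n_sig, 0L)
})
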