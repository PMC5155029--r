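# Statistical layer: mutational-combination counting, hypergeometric
# diagnosis-relapse overlap tests, independent-clone shared-mutation
# baseline, and 96-context trinucleotide mutation profiles.

#' Number of possible sequences at a given distance from a central sequence
#'
#' For a sequence of length `l`, each of the `choose(l, d)` position sets can
#' mutate to any of three other bases per position, so the number of distinct
#' sequences at Hamming distance exactly `d` is `choose(l, d) * 3^d`. Exact
#' integer recurrences are used; the returned double is exact whenever the
#' value is below 2^53.
#'
#' @param l Sequence length (nucleotides).
#' @param d Substitution distance, `0 <= d <= l`.
#' @return The count as a double.
#' @export
mutational_combinations <- function(l, d) {
  stopifnot(length(l) == 1L, length(d) == 1L)
  if (is.na(l) || is.na(d) || l < 0 || d < 0 || d > l || l != floor(l) || d != floor(d)) {
    bcrmrd_error("need integers 0 <= d <= l", "bcrmrd_domain_error")
  }
  v <- 1
  for (i in seq_len(d)) {
    v <- round(v * (l - i + 1) / i)  # C(l, i) is integral at every step
  }
  v * 3^d
}

#' Log of [mutational_combinations()]
#'
#' Log-scale companion used inside hypergeometric tails when the population
#' of possible variants is astronomically large.
#'
#' @inheritParams mutational_combinations
#' @return `log(choose(l, d) * 3^d)`.
#' @export
log_mutational_combinations <- function(l, d) {
  stopifnot(d >= 0, d <= l)
  lchoose(l, d) + d * log(3)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing `k` or more shared sequences when `n_diag` and
#' `n_rel` sequences are drawn independently from a population of `N`
#' possible sequences: `P(X >= k)` for `X ~ Hypergeometric(N, n_diag,
#' n_rel)`. Computed as an exact tail sum in log space, so it is stable for
#' populations as large as the variant-shell counts produced by
#' [mutational_combinations()].
#'
#' @param N Population size (possible sequences).
#' @param n_diag,n_rel Unique sequence counts in the two samples.
#' @param k Observed shared count.
#' @return The p-value in (0, 1\].
#' @export
overlap_pvalue <- function(N, n_diag, n_rel, k) {
  stopifnot(N >= 0, n_diag >= 0, n_rel >= 0, k >= 0)
  if (n_diag > N || n_rel > N || k > min(n_diag, n_rel)) {
    bcrmrd_error(sprintf("infeasible hypergeometric parameters: N=%g, n_diag=%g, n_rel=%g, k=%g",
                         N, n_diag, n_rel, k), "bcrmrd_infeasible_test")
  }
  if (k <= max(0, n_diag + n_rel - N)) return(1)
  xs <- k:min(n_diag, n_rel)
  lp <- lchoose(n_diag, xs) + lchoose(N - n_diag, n_rel - xs) - lchoose(N, n_rel)
  min(1, exp(logsumexp(lp)))
}

#' Combine independent p-values by Fisher's method
#'
#' @param p Numeric vector of p-values.
#' @return Combined p-value from the chi-squared distribution with
#'   `2 * length(p)` degrees of freedom.
#' @export
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1L, all(p > 0), all(p <= 1))
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Per-shell diagnosis-relapse overlap test
#'
#' For each distance shell `d` from the central BCR, the population of
#' possible variants is `N = choose(l, d) * 3^d` (substitution-only model
#' with alignment length `l`); the probability that the observed number of
#' shared members arose by chance is the hypergeometric upper tail. Shells
#' where `N` is smaller than an observed member count are infeasible under
#' the substitution-only model (indel variants) and are flagged and excluded
#' from the Fisher-combined p-value, as are shells where either sample has
#' no members.
#'
#' @param aln A `clone_alignment` from [align_members()].
#' @return List with `shells` (data frame `d`, `N`, `n_diag`, `n_rel`, `k`,
#'   `p`, `feasible`) and `combined_p` (Fisher's method over feasible,
#'   populated shells with `d >= 1`).
#' @export
diag_relapse_overlap <- function(aln) {
  ss <- structure_summary(aln)
  l <- nchar(aln$central_aligned)
  sh <- ss$shells[ss$shells$d >= 1L, , drop = FALSE]
  if (nrow(sh) == 0L) {
    bcrmrd_error("no members away from the central BCR", "bcrmrd_insufficient_data")
  }
  rows <- lapply(seq_len(nrow(sh)), function(i) {
    d <- sh$d[i]
    N <- mutational_combinations(l, d)
    feasible <- N >= sh$n_diag[i] && N >= sh$n_rel[i]
    p <- if (feasible) overlap_pvalue(N, sh$n_diag[i], sh$n_rel[i], sh$n_both[i]) else NA_real_
    data.frame(d = d, N = N, n_diag = sh$n_diag[i], n_rel = sh$n_rel[i],
               k = sh$n_both[i], p = p, feasible = feasible)
  })
  shells <- do.call(rbind, rows)
  use <- shells$feasible & shells$n_diag > 0 & shells$n_rel > 0
  combined <- if (any(use)) fisher_combine(shells$p[use]) else NA_real_
  list(shells = shells, combined_p = combined)
}

# --- independent-clone shared-mutation baseline ---------------------------

#' Baseline shared-mutation frequency between independent clones
#'
#' In each healthy repertoire, clusters of more than six unique sequences
#' are treated as clones; every member is V-annotated and its mismatch
#' positions against the best germline V (in germline coordinates) are
#' pooled per clone. For every pair of independent clones — same V gene but
#' a different J gene, or same V gene in different individuals — the
#' fraction of shared mutation positions (intersection over the mean set
#' size) is recorded. This is the chance level against which
#' diagnosis-relapse mutation sharing is compared.
#'
#' @param healthy_reps List of healthy [repertoire()]s.
#' @param db A `germline_db`.
#' @param min_cluster_size Minimum unique sequences per cluster (default 7,
#'   i.e. more than six).
#' @param ... Passed to [annotate_repertoire()].
#' @return A data frame (`sample_i`, `sample_j`, `v_gene`, `source`,
#'   `shared_fraction`) of class `shared_mutation_baseline`.
#' @export
shared_mutation_baseline <- function(healthy_reps, db, min_cluster_size = 7L, ...) {
  if (inherits(healthy_reps, "repertoire")) healthy_reps <- list(healthy_reps)
  clones <- list()
  for (rep in healthy_reps) {
    net <- build_network(rep)
    stats <- cluster_stats(net)
    elig <- stats$cluster_id[stats$n_vertices >= min_cluster_size]
    for (cid in elig) {
      seqs <- net$vertices$seq[net$membership == cid]
      ann <- annotate_repertoire(seqs, db, ...)
      ann <- ann[ann$annotated, , drop = FALSE]
      if (nrow(ann) == 0L) next
      vg <- names(sort(table(ann$v_gene), decreasing = TRUE))[1L]
      jg <- names(sort(table(ann$j_gene), decreasing = TRUE))[1L]
      muts <- v_mutation_positions(ann$seq[ann$v_gene == vg], db$V[[vg]])
      clones[[length(clones) + 1L]] <- list(sample = rep$meta$sample_id,
                                            v_gene = vg, j_gene = jg,
                                            muts = muts)
    }
  }
  pairs <- list()
  if (length(clones) >= 2L) {
    for (i in seq_len(length(clones) - 1L)) {
      for (j in (i + 1L):length(clones)) {
        a <- clones[[i]]; b <- clones[[j]]
        if (a$v_gene != b$v_gene) next
        src <- if (a$sample != b$sample) "sameV_diffIndividual"
        else if (a$j_gene != b$j_gene) "sameV_diffJ"
        else next  # same individual, same V and J: not independent
        if (length(a$muts) == 0L && length(b$muts) == 0L) next
        frac <- length(intersect(a$muts, b$muts)) /
          mean(c(length(a$muts), length(b$muts)))
        pairs[[length(pairs) + 1L]] <- data.frame(
          sample_i = a$sample, sample_j = b$sample, v_gene = a$v_gene,
          source = src, shared_fraction = frac, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pairs) == 0L) {
    bcrmrd_error("no eligible independent clone pairs", "bcrmrd_insufficient_data")
  }
  out <- do.call(rbind, pairs)
  class(out) <- c("shared_mutation_baseline", class(out))
  out
}

# Union of mismatch positions (on germline V coordinates) of clone member
# sequences against their germline V gene, from local alignments.
v_mutation_positions <- function(seqs, v_seq) {
  sub_mat <- vj_substitution_matrix()
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs),
    subject = Biostrings::DNAString(v_seq),
    type = "local", substitutionMatrix = sub_mat,
    gapOpening = 3, gapExtension = 1)
  mt <- Biostrings::mismatchTable(pa)
  sort(unique(mt$SubjectStart))
}

#' Compare observed mutation sharing against the independent baseline
#'
#' One-sided Mann-Whitney test of whether diagnosis-relapse shared-mutation
#' fractions exceed the independent-clone baseline. Exact for combined
#' sample sizes up to 20 (full enumeration of rank assignments, which
#' handles ties exactly); normal approximation with tie correction
#' otherwise.
#'
#' @param baseline Numeric vector (or [shared_mutation_baseline()] result)
#'   of baseline shared fractions.
#' @param observed Numeric vector of diagnosis-relapse shared fractions.
#' @return List with `p_value`, `method`, `statistic` (the observed
#'   rank-sum of `observed`).
#' @export
compare_shared_mutations <- function(baseline, observed) {
  if (inherits(baseline, "shared_mutation_baseline")) {
    baseline <- baseline$shared_fraction
  }
  stopifnot(length(baseline) > 0L, length(observed) > 0L)
  n <- length(observed)
  m <- length(baseline)
  if (n + m <= 20L) {
    vals <- c(observed, baseline)
    r <- rank(vals)
    w_obs <- sum(r[seq_len(n)])
    sets <- combn(n + m, n)
    w_all <- colSums(matrix(r[sets], nrow = n))
    p <- mean(w_all >= w_obs - 1e-9)
    list(p_value = p, method = "exact enumeration", statistic = w_obs)
  } else {
    wt <- suppressWarnings(wilcox.test(observed, baseline,
                                       alternative = "greater", exact = FALSE,
                                       correct = TRUE))
    list(p_value = wt$p.value, method = "normal approximation (tie-corrected)",
         statistic = unname(wt$statistic) + n * (n + 1) / 2)
  }
}

# --- 96-context trinucleotide profiles ------------------------------------

profile_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1L, 1L)
    for (up in bases) for (down in bases) {
      out <- c(out, sprintf("%s[%s]%s", up, s, down))
    }
  }
  out
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' 96-context trinucleotide mutation profile
#'
#' Classifies every mismatch between the central sequence and its variants
#' by pyrimidine-centric substitution type (purine reference positions are
#' strand-collapsed to their reverse complement) and the flanking bases of
#' the central sequence. Mutations at terminal positions (no flank) are
#' excluded and counted, as are positions involving non-ACGT characters.
#'
#' @param central The central (reference) sequence.
#' @param variants Character vector of variant sequences, same length as
#'   `central` (aligned).
#' @param counts Optional read counts weighting each variant's mutations
#'   (default: each variant counted once).
#' @return A `mutation_profile`: list with `counts` (named vector over the
#'   96 canonical contexts), `total`, `n_terminal_excluded`,
#'   `n_ambiguous_skipped`.
#' @export
triplet_profile <- function(central, variants, counts = NULL) {
  stopifnot(all(nchar(variants) == nchar(central)))
  if (is.null(counts)) counts <- rep(1L, length(variants))
  stopifnot(length(counts) == length(variants))
  ctx_names <- profile_contexts()
  tab <- setNames(numeric(96L), ctx_names)
  cen <- strsplit(central, "")[[1L]]
  L <- length(cen)
  n_terminal <- 0
  n_ambiguous <- 0
  for (vi in seq_along(variants)) {
    var <- strsplit(variants[vi], "")[[1L]]
    w <- counts[vi]
    for (pos in which(var != cen)) {
      if (pos == 1L || pos == L) {
        n_terminal <- n_terminal + w
        next
      }
      ref <- cen[pos]; alt <- var[pos]
      up <- cen[pos - 1L]; down <- cen[pos + 1L]
      if (!all(c(ref, alt, up, down) %in% c("A", "C", "G", "T"))) {
        n_ambiguous <- n_ambiguous + w
        next
      }
      if (ref %in% c("A", "G")) {  # strand-collapse to pyrimidine reference
        tmp <- up
        up <- comp_base(down)
        down <- comp_base(tmp)
        ref <- comp_base(ref)
        alt <- comp_base(alt)
      }
      key <- sprintf("%s[%s>%s]%s", up, ref, alt, down)
      tab[key] <- tab[key] + w
    }
  }
  structure(list(counts = tab, total = sum(tab),
                 n_terminal_excluded = n_terminal,
                 n_ambiguous_skipped = n_ambiguous),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("<mutation_profile> %g mutations over 96 contexts (%g terminal excluded)\n",
              x$total, x$n_terminal_excluded))
  invisible(x)
}

#' Compare two 96-context mutation profiles
#'
#' Per-context Fisher exact test on the 2x2 table of context count versus
#' all other mutations in each profile, with Bonferroni correction over the
#' 96 contexts. Distinguishes, e.g., AID-driven somatic hypermutation from
#' PCR/sequencing error.
#'
#' @param p1,p2 `mutation_profile` objects with positive totals.
#' @param alpha Significance level (default 0.005).
#' @return Data frame (`context`, `count1`, `count2`, `p`, `p_bonferroni`,
#'   `significant_raw`, `significant_bonferroni`) with attributes
#'   `n_significant_raw` and `n_significant_bonferroni`.
#' @export
compare_profiles <- function(p1, p2, alpha = 0.005) {
  stopifnot(inherits(p1, "mutation_profile"), inherits(p2, "mutation_profile"),
            p1$total > 0, p2$total > 0)
  ctx <- profile_contexts()
  p <- vapply(ctx, function(cc) {
    m <- matrix(c(p1$counts[[cc]], p1$total - p1$counts[[cc]],
                  p2$counts[[cc]], p2$total - p2$counts[[cc]]), 2L)
    fisher.test(m)$p.value
  }, 0)
  p_bonf <- pmin(1, p * 96)
  out <- data.frame(context = ctx,
                    count1 = unname(p1$counts), count2 = unname(p2$counts),
                    p = unname(p), p_bonferroni = unname(p_bonf),
                    significant_raw = unname(p < alpha),
                    significant_bonferroni = unname(p_bonf < alpha),
                    stringsAsFactors = FALSE)
  attr(out, "n_significant_raw") <- sum(out$significant_raw)
  attr(out, "n_significant_bonferroni") <- sum(out$significant_bonferroni)
  out
}

#' Random-overlap test of PCR/sequencing error sites between control samples
#'
#' In each control repertoire the true sequence is taken to be the most
#' frequent sequence; mismatch positions of the other (equal-length)
#' sequences against it are its error sites. For every pair of samples with
#' equal true-sequence length the shared error-site count is tested with
#' the hypergeometric upper tail over the `N = L` positions. Under random
#' error placement no pair should show significant overlap.
#'
#' @param control_reps List of control [repertoire()]s.
#' @return Data frame (`sample_i`, `sample_j`, `L`, `n_i`, `n_j`, `k`, `p`).
#' @export
error_site_overlap <- function(control_reps) {
  if (inherits(control_reps, "repertoire")) control_reps <- list(control_reps)
  site_sets <- lapply(control_reps, function(rep) {
    sq <- rep$sequences
    true_candidates <- sq$seq[sq$count == max(sq$count)]
    true_seq <- sort(true_candidates)[1L]
    tru <- utf8ToInt(true_seq)
    sites <- integer(0)
    for (s in sq$seq[sq$seq != true_seq]) {
      if (nchar(s) != length(tru)) next
      sites <- union(sites, which(utf8ToInt(s) != tru))
    }
    list(sample = rep$meta$sample_id, L = length(tru), sites = sort(sites))
  })
  rows <- list()
  ns <- length(site_sets)
  for (i in seq_len(max(0L, ns - 1L))) {
    for (j in (i + 1L):ns) {
      a <- site_sets[[i]]; b <- site_sets[[j]]
      if (a$L != b$L) next
      k <- length(intersect(a$sites, b$sites))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_i = a$sample, sample_j = b$sample, L = a$L,
        n_i = length(a$sites), n_j = length(b$sites), k = k,
        p = overlap_pvalue(a$L, length(a$sites), length(b$sites), k),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    bcrmrd_error("no comparable control pairs", "bcrmrd_insufficient_data")
  }
  do.call(rbind, rows)
}
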