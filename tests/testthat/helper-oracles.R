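# Independent oracles and fixture builders used across the test suite.
# These deliberately avoid the package's own code paths: components are
# found by brute-force all-pairs BFS, hypergeometric tails by naive pmf
# summation, combination counts by exhaustive string enumeration.

# Brute-force single-mismatch connected components (all-pairs + BFS).
oracle_components <- function(seqs) {
  n <- length(seqs)
  lens <- nchar(seqs)
  ints <- lapply(seqs, utf8ToInt)
  adj <- vector("list", n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (lens[i] == lens[j] && sum(ints[[i]] != ints[[j]]) == 1L) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# Canonical partition labels (first-occurrence order) so two labelings of
# the same partition compare identical.
canonical_partition <- function(x) {
  as.integer(factor(x, levels = unique(x)))
}

# Naive hypergeometric upper tail by direct pmf summation (dhyper is the
# independent pmf; the tail is summed term by term).
oracle_hyper_tail <- function(N, n1, n2, k) {
  xs <- max(0, k):min(n1, n2)
  sum(stats::dhyper(xs, n1, N - n1, n2))
}

# Exhaustive count of sequences at Hamming distance exactly d from a fixed
# l-mer, by enumerating every l-mer over ACGT.
oracle_count_at_distance <- function(l, d) {
  bases <- c("A", "C", "G", "T")
  ref <- rep("A", l)
  grid <- do.call(expand.grid, rep(list(bases), l))
  sum(apply(grid, 1L, function(row) sum(row != ref)) == d)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_at <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1L]]
  chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
  paste(chars, collapse = "")
}

# Random repertoire with planted single-mismatch chains among random k-mers.
random_repertoire_with_chains <- function(n_base, chain_len, seq_len,
                                          sample_id = "rnd") {
  seqs <- character(0)
  for (i in seq_len(n_base)) {
    s <- random_seq(seq_len)
    seqs <- c(seqs, s)
    cur <- s
    for (j in seq_len(chain_len)) {
      cur <- mutate_at(cur, sample.int(seq_len, 1L))
      seqs <- c(seqs, cur)
    }
  }
  seqs <- unique(seqs)
  repertoire(seqs, sample.int(20L, length(seqs), replace = TRUE),
             sample_meta(sample_id, "pt", 0L, "synthetic", "RNA"))
}

# Tiny toy germline and a read builder for annotation tests.
toy_germline <- function() {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">IGHV1", "ACGTACGTACGTACGTACGTACGTACGTAC",
               ">IGHV2", "TTGACCTTGACCTTGACCTTGACCTTGACC",
               ">IGHD1", "GGGAACCCGGTT",
               ">IGHJ1", "CCATTGGCAATGGCCATTGG",
               ">IGHJ2", "TGCCAGTACTGGCAGTAAGG"), tf)
  load_germline(tf)
}

# Build a V + N + D + N + J read from a germline db; returns seq and the
# expected stem under the 3bp-downstream rule.
toy_read <- function(db, v = 1L, d = 1L, j = 1L, n1 = "GGA", n2 = "TT") {
  vseq <- db$V[[v]]
  s <- paste0(vseq, n1, db$D[[d]], n2, db$J[[j]])
  list(seq = s, stem = substr(s, nchar(vseq) + 4L, nchar(s)), v_end = nchar(vseq))
}

mk_meta <- function(id = "s1", patient = "p1", day = 0L, external = NA_real_) {
  sample_meta(id, patient, day, "synthetic", "RNA", external)
}

mk_rep <- function(seqs, counts, id = "s1", patient = "p1", day = 0L,
                   external = NA_real_) {
  repertoire(seqs, counts, mk_meta(id, patient, day, external))
}

# Signature object built directly (bypasses network construction) for
# focused mining tests.
mk_signature <- function(members, clone_id = 1L, patient = "p1",
                         fraction = 0.5) {
  structure(list(patient_id = patient, clone_id = clone_id,
                 member_seqs = members,
                 dominant_seq = members[[1L]],
                 index_fraction = fraction,
                 index_sample_id = "idx"),
            class = "clonotype_signature")
}
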