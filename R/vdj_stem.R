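# V/J segment annotation by local alignment and D-J "stem" extraction.
#
# The stem is the N-IgHD-N-IgHJ region starting 3 bp downstream of the IgHV
# gene boundary. It is invariant under secondary V rearrangements (V
# replacement re-uses the existing D-J join), so it acts as a clone barcode
# that survives changes of V gene.

# Scoring scheme for local V/J alignment: match +1, mismatch -1, a gap of
# length k costs 4 + (k - 1). N mismatches everything, including N.
vj_substitution_matrix <- function() {
  alpha <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5L, 5L, dimnames = list(alpha, alpha))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}

# Vectorized local alignment of all reads against one gene segment.
# Returns per-read score, read-coordinate start/end, and alignment width.
align_gene <- function(seqs, gene_seq, sub_mat) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs),
    subject = Biostrings::DNAString(gene_seq),
    type = "local", substitutionMatrix = sub_mat,
    gapOpening = 3, gapExtension = 1)
  rng <- Biostrings::pattern(pa)
  data.frame(score = Biostrings::score(pa),
             start = BiocGenerics::start(rng),
             end = BiocGenerics::end(rng),
             width = BiocGenerics::width(rng))
}

# Best gene per read with deterministic tie-breaking:
# higher score, then longer alignment, then alphabetical gene name
# (genes are visited alphabetically and ties keep the incumbent).
best_gene <- function(seqs, genes, sub_mat) {
  gene_names <- sort(names(genes))
  n <- length(seqs)
  score <- rep(-Inf, n)
  width <- rep(-1L, n)
  gidx <- start <- end <- rep(NA_integer_, n)
  for (k in seq_along(gene_names)) {
    cur <- align_gene(seqs, genes[[gene_names[k]]], sub_mat)
    better <- cur$score > score | (cur$score == score & cur$width > width)
    score[better] <- cur$score[better]
    width[better] <- cur$width[better]
    gidx[better] <- k
    start[better] <- cur$start[better]
    end[better] <- cur$end[better]
  }
  data.frame(gene = gene_names[gidx], score = score, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Annotate V and J gene segments on a set of sequences
#'
#' Local alignment (match +1, mismatch -1, affine gaps: a length-k gap costs
#' 4 + (k - 1)) of every germline V and J gene against each read; the
#' highest-scoring gene wins, with ties broken by longer alignment then
#' alphabetical gene name. The stem is the read suffix starting 3 bases
#' after the last V-aligned position (boundary-uncertain bases excluded).
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param db A `germline_db` from [load_germline()].
#' @param min_score_v,min_score_j Alignment score floors below which a read
#'   is unannotatable (defaults 20 and 10).
#' @return Data frame with one row per input sequence: `seq`, `annotated`,
#'   `v_gene`, `v_score`, `v_end` (1-based last V-aligned position),
#'   `j_gene`, `j_score`, `j_start`, `stem` (`NA` when unannotatable).
#' @export
annotate_repertoire <- function(seqs, db, min_score_v = 20, min_score_j = 10) {
  stopifnot(inherits(db, "germline_db"), length(seqs) > 0L)
  seqs <- canonical_seq(seqs)
  sub_mat <- vj_substitution_matrix()
  v <- best_gene(seqs, as.list(db$V), sub_mat)
  j <- best_gene(seqs, as.list(db$J), sub_mat)
  len <- nchar(seqs)
  stem_start <- v$end + 4L  # skip exactly 3 bases downstream of the V boundary
  ok <- v$score >= min_score_v & j$score >= min_score_j &
    j$start > v$end & stem_start <= len
  stem <- ifelse(ok, substr(seqs, stem_start, len), NA_character_)
  data.frame(seq = seqs, annotated = ok,
             v_gene = ifelse(ok, v$gene, NA_character_),
             v_score = v$score, v_end = v$end,
             j_gene = ifelse(ok, j$gene, NA_character_),
             j_score = j$score, j_start = j$start,
             stem = stem, stringsAsFactors = FALSE)
}

#' Annotate a single sequence
#'
#' @inheritParams annotate_repertoire
#' @param seq A single nucleotide sequence.
#' @return A one-row data frame as in [annotate_repertoire()]; an
#'   unannotatable sequence raises an error of class `bcrmrd_unannotatable`.
#' @export
annotate_vj <- function(seq, db, min_score_v = 20, min_score_j = 10) {
  ann <- annotate_repertoire(seq, db, min_score_v, min_score_j)
  if (!ann$annotated[1L]) {
    bcrmrd_error(sprintf("sequence cannot be V/J annotated (V score %.4g, J score %.4g)",
                         ann$v_score[1L], ann$j_score[1L]), "bcrmrd_unannotatable")
  }
  ann
}

#' Extract stem sequences from the clonal clusters of a repertoire
#'
#' Captures sequences represented by more than two reads inside clusters
#' holding at least `min_cluster_fraction` of the repertoire (default 2.5%),
#' annotates them, and reports their stems.
#'
#' @param rep A [repertoire()].
#' @param db A `germline_db`.
#' @param net Optional precomputed [build_network()] result for `rep`.
#' @param min_count Minimum read count for a sequence to contribute a stem
#'   (default 3, i.e. strictly more than 2 reads).
#' @param min_cluster_fraction Cluster read-fraction floor (default 0.025).
#' @param ... Passed to [annotate_repertoire()].
#' @return Data frame (`sample_id`, `cluster_id`, `seq`, `count`, `v_gene`,
#'   `stem`), one row per contributing sequence; unannotatable sequences are
#'   dropped and counted in attribute `n_unannotatable`.
#' @export
extract_stems <- function(rep, db, net = NULL, min_count = 3L,
                          min_cluster_fraction = 0.025, ...) {
  stopifnot(inherits(rep, "repertoire"))
  if (is.null(net)) net <- build_network(rep)
  stats <- cluster_stats(net)
  qual <- stats$cluster_id[stats$fraction >= min_cluster_fraction]
  keep <- net$membership %in% qual & net$vertices$count >= min_count
  if (!any(keep)) {
    out <- data.frame(sample_id = character(), cluster_id = integer(),
                      seq = character(), count = integer(),
                      v_gene = character(), stem = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_unannotatable") <- 0L
    return(out)
  }
  ann <- annotate_repertoire(net$vertices$seq[keep], db, ...)
  out <- data.frame(sample_id = rep$meta$sample_id,
                    cluster_id = net$membership[keep],
                    seq = net$vertices$seq[keep],
                    count = net$vertices$count[keep],
                    v_gene = ann$v_gene, stem = ann$stem,
                    stringsAsFactors = FALSE)
  attr(out, "n_unannotatable") <- sum(!ann$annotated)
  out[ann$annotated, , drop = FALSE]
}

#' Cluster stem sequences by single-base similarity
#'
#' Single-linkage components under equal-length Hamming distance 1 (the same
#' substitution-only rule as the sequence network): every member of a group
#' is within one substitution of at least one other member; singleton stems
#' form their own group. Groups are ordered by descending member count, ties
#' by lexicographically smallest member.
#'
#' @param stems Character vector of stem strings (duplicates tolerated).
#' @return List of `stem_group` objects (`group_id`, `members`).
#' @export
cluster_stems <- function(stems) {
  stems <- unique(stems[!is.na(stems)])
  if (length(stems) == 0L) return(list())
  edges <- .hamming1_edges(stems)
  if (nrow(edges) > 0L) {
    g <- igraph::make_empty_graph(length(stems), directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(stems)
  }
  groups <- split(stems, memb)
  first <- vapply(groups, function(m) sort(m)[1L], "")
  ord <- order(-lengths(groups), first)
  lapply(seq_along(ord), function(i) {
    structure(list(group_id = i, members = sort(groups[[ord[i]]])),
              class = "stem_group")
  })
}

#' @export
print.stem_group <- function(x, ...) {
  cat(sprintf("<stem_group> %d: %d member stem(s), length %s\n", x$group_id,
              length(x$members), paste(unique(nchar(x$members)), collapse = "/")))
  invisible(x)
}

# Logical index of repertoire sequences containing any member stem as an
# exact substring.
stem_hits <- function(members, seqs) {
  hit <- rep(FALSE, length(seqs))
  for (m in members) hit <- hit | grepl(m, seqs, fixed = TRUE)
  hit
}

#' V-gene usage attached to a stem group
#'
#' Scans each repertoire for sequences containing any member stem as an
#' exact substring, annotates their V genes, and tallies read counts per V.
#' A stem combined with many distinct V genes is the signature of secondary
#' rearrangement (independent V rearrangements or V replacement on one
#' pre-existing D-J join).
#'
#' @param group A `stem_group`.
#' @param reps List of [repertoire()]s to scan.
#' @param db A `germline_db`.
#' @param ... Passed to [annotate_repertoire()].
#' @return List with `v_usage` (named read-count vector, descending),
#'   `n_distinct_v`, and `n_unannotatable`.
#' @export
v_usage_per_stem <- function(group, reps, db, ...) {
  stopifnot(inherits(group, "stem_group"), length(group$members) > 0L)
  if (inherits(reps, "repertoire")) reps <- list(reps)
  usage <- numeric(0)
  n_un <- 0L
  for (rep in reps) {
    hit <- stem_hits(group$members, rep$sequences$seq)
    if (!any(hit)) next
    ann <- annotate_repertoire(rep$sequences$seq[hit], db, ...)
    n_un <- n_un + sum(!ann$annotated)
    cnt <- rep$sequences$count[hit][ann$annotated]
    for (i in seq_along(cnt)) {
      g <- ann$v_gene[ann$annotated][i]
      usage[g] <- (if (g %in% names(usage)) usage[g] else 0) + cnt[i]
    }
  }
  usage <- sort(usage, decreasing = TRUE)
  list(v_usage = usage, n_distinct_v = length(usage), n_unannotatable = n_un)
}

#' Per-sample frequency of a stem group
#'
#' @param group A `stem_group`.
#' @param reps List of [repertoire()]s.
#' @return Named numeric vector: fraction of reads in each sample containing
#'   a member stem as an exact substring.
#' @export
stem_frequencies <- function(group, reps) {
  if (inherits(reps, "repertoire")) reps <- list(reps)
  vapply(reps, function(rep) {
    hit <- stem_hits(group$members, rep$sequences$seq)
    setNames(sum(rep$sequences$count[hit]) / total_reads(rep),
             rep$meta$sample_id)
  }, 0)
}

#' Healthy-background threshold for a stem group
#'
#' Computes the stem group's frequency in each healthy repertoire and the
#' empirical `q`-quantile (default the 99th percentile) used as the
#' false-positive threshold: a patient observation is flagged only when it
#' exceeds this background.
#'
#' @param group A `stem_group`.
#' @param healthy_reps List of at least two healthy [repertoire()]s.
#' @param q Background quantile (default 0.99).
#' @return List with `frequencies` (per healthy sample), `threshold`, `q`.
#' @export
stem_background <- function(group, healthy_reps, q = 0.99) {
  if (length(healthy_reps) < 2L) {
    bcrmrd_error("need >= 2 healthy repertoires", "bcrmrd_insufficient_data")
  }
  freqs <- stem_frequencies(group, healthy_reps)
  list(frequencies = freqs, threshold = healthy_percentile(freqs, q), q = q)
}

#' Stem false-detection rate in unrelated patients
#'
#' The chance that a signature stem arises in an unrelated individual:
#' reads in unrelated repertoires containing any signature stem, divided by
#' total unrelated reads.
#'
#' @param stems Character vector of signature stem strings.
#' @param unrelated_reps List of [repertoire()]s from unrelated patients.
#' @return A single fraction in \[0, 1\].
#' @export
false_detection_rate <- function(stems, unrelated_reps) {
  if (inherits(unrelated_reps, "repertoire")) unrelated_reps <- list(unrelated_reps)
  stems <- unique(stems[!is.na(stems)])
  hit_reads <- 0
  tot <- 0
  for (rep in unrelated_reps) {
    hit <- stem_hits(stems, rep$sequences$seq)
    hit_reads <- hit_reads + sum(rep$sequences$count[hit])
    tot <- tot + total_reads(rep)
  }
  hit_reads / tot
}
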