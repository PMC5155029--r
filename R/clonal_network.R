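#' Build the unique-sequence similarity network
#'
#' Each vertex is a unique sequence (vertex size proportional to its read
#' count); edges join vertices that differ by a single nucleotide non-indel
#' difference, i.e. equal-length sequences at Hamming distance exactly 1.
#' Sequences of different length are never joined, and N mismatches every
#' base including N. Clusters are the connected components of this graph and
#' serve as clone proxies: a clone plus its mutational variant cloud.
#'
#' Clusters are numbered deterministically: descending total reads, ties by
#' the lexicographically smallest dominant sequence.
#'
#' @param rep A [repertoire()].
#' @return A `sequence_network`: list with `vertices` (data frame `seq`,
#'   `count`), `edges` (two-column index matrix), `membership` (cluster id per
#'   vertex), `n_clusters`, `total_reads`.
#' @export
build_network <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  seqs <- rep$sequences$seq
  counts <- rep$sequences$count
  n <- length(seqs)
  edges <- .hamming1_edges(seqs)
  if (nrow(edges) > 0L) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(n)
  }
  # deterministic renumbering: descending reads, tie lexicographic dominant seq
  comp_reads <- tapply(counts, memb, sum)
  dominant <- vapply(split(seq_len(n), memb), function(ix) {
    cand <- ix[counts[ix] == max(counts[ix])]
    sort(seqs[cand])[1L]
  }, "")
  ord <- order(-comp_reads, dominant)
  relabel <- setNames(seq_along(ord), names(comp_reads)[ord])
  membership <- as.integer(relabel[as.character(memb)])
  structure(list(vertices = rep$sequences, edges = edges,
                 membership = membership,
                 n_clusters = length(ord),
                 total_reads = sum(counts),
                 meta = rep$meta),
            class = "sequence_network")
}

#' @export
print.sequence_network <- function(x, ...) {
  cat(sprintf("<sequence_network> %d vertices, %d edges, %d clusters, %d reads\n",
              nrow(x$vertices), nrow(x$edges), x$n_clusters, x$total_reads))
  invisible(x)
}

#' Per-cluster summary statistics
#'
#' @param net A `sequence_network` from [build_network()].
#' @return Data frame (largest cluster first) with columns `cluster_id`,
#'   `n_vertices`, `reads`, `fraction` (reads over total repertoire reads),
#'   `dominant_seq` (highest-count vertex, ties by lexicographic order).
#' @export
cluster_stats <- function(net) {
  stopifnot(inherits(net, "sequence_network"))
  seqs <- net$vertices$seq
  counts <- net$vertices$count
  ids <- sort(unique(net$membership))
  rows <- lapply(ids, function(cid) {
    ix <- which(net$membership == cid)
    cand <- ix[counts[ix] == max(counts[ix])]
    data.frame(cluster_id = cid, n_vertices = length(ix),
               reads = sum(counts[ix]),
               fraction = sum(counts[ix]) / net$total_reads,
               dominant_seq = sort(seqs[cand])[1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call clonality from cluster statistics
#'
#' A sample is clonal when its largest cluster holds at least `threshold` of
#' all repertoire reads (default 2.5%, chosen above the 95th percentile of
#' the healthy largest-cluster range; the threshold is inclusive).
#'
#' @param stats Data frame from [cluster_stats()].
#' @param threshold Read-fraction cutoff (default 0.025).
#' @return List with `clonal` (logical) and `largest_fraction`.
#' @export
is_clonal <- function(stats, threshold = 0.025) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0L)
  largest <- max(stats$fraction)
  list(clonal = largest >= threshold, largest_fraction = largest,
       threshold = threshold)
}

#' Empirical quantile of healthy largest-cluster fractions
#'
#' Linear interpolation between order statistics (the default sample-quantile
#' definition), used to place a clonality cutoff above the healthy range.
#'
#' @param healthy_fractions Numeric vector of largest-cluster fractions from
#'   at least two healthy samples.
#' @param q Quantile in (0, 1), e.g. 0.95.
#' @return The empirical `q`-quantile.
#' @export
healthy_percentile <- function(healthy_fractions, q) {
  if (length(healthy_fractions) < 2L) {
    bcrmrd_error("need >= 2 healthy samples", "bcrmrd_insufficient_data")
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    bcrmrd_error("`q` must lie strictly inside (0, 1)", "bcrmrd_invalid_quantile")
  }
  unname(quantile(healthy_fractions, q, type = 7))
}

#' Gini coefficient of vertex read counts
#'
#' Optional repertoire-inequality summary (not used in any decision rule).
#'
#' @param net A `sequence_network`.
#' @return Gini coefficient in \[0, 1).
#' @export
vertex_gini <- function(net) {
  x <- sort(as.numeric(net$vertices$count))
  n <- length(x)
  if (n == 1L) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Export the network edge list for external viewers
#'
#' @param net A `sequence_network`.
#' @param path Output TSV path (columns `source_seq`, `target_seq`).
#' @return `path`, invisibly.
#' @export
export_edges <- function(net, path) {
  df <- data.frame(source_seq = net$vertices$seq[net$edges[, 1L]],
                   target_seq = net$vertices$seq[net$edges[, 2L]],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
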