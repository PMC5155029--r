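#' Define clonotype signatures from an index sample
#'
#' Identifies every cluster holding at least `threshold` (default 2.5%) of
#' the index repertoire's reads and freezes its full vertex set as a
#' clonotype signature for longitudinal mining. Clone ids are assigned by
#' descending index fraction.
#'
#' @param index_rep Index-sample [repertoire()] (typically diagnosis).
#' @param threshold Clonality read-fraction cutoff (inclusive; default 0.025).
#' @return List of `clonotype_signature` objects (empty, with a warning, when
#'   no cluster qualifies).
#' @export
define_signatures <- function(index_rep, threshold = 0.025) {
  stopifnot(inherits(index_rep, "repertoire"))
  net <- build_network(index_rep)
  stats <- cluster_stats(net)
  qual <- stats[stats$fraction >= threshold, , drop = FALSE]
  if (nrow(qual) == 0L) {
    warning(sprintf("no cluster reaches %.3g of reads in index sample %s; no signatures defined",
                    threshold, index_rep$meta$sample_id))
    return(list())
  }
  qual <- qual[order(-qual$fraction, qual$dominant_seq), , drop = FALSE]
  sigs <- lapply(seq_len(nrow(qual)), function(i) {
    cid <- qual$cluster_id[i]
    members <- net$vertices$seq[net$membership == cid]
    structure(list(patient_id = index_rep$meta$patient_id,
                   clone_id = i,
                   member_seqs = members,
                   dominant_seq = qual$dominant_seq[i],
                   index_fraction = qual$fraction[i],
                   index_sample_id = index_rep$meta$sample_id),
              class = "clonotype_signature")
  })
  sigs
}

#' @export
print.clonotype_signature <- function(x, ...) {
  cat(sprintf("<clonotype_signature> patient %s clone %d: %d member sequences, index fraction %.4g\n",
              x$patient_id, x$clone_id, length(x$member_seqs), x$index_fraction))
  invisible(x)
}

#' Mine a sample for sequences matching a clonotype signature
#'
#' A repertoire sequence matches when its minimum equal-length Hamming
#' distance to any signature member is at most `max_mismatch` (default 8,
#' inclusive); sequences of a different length never match under the default
#' substitution-only rule. `method = "levenshtein"` applies the same cutoff
#' to edit distance (indels allowed) instead.
#'
#' @param sig A `clonotype_signature`.
#' @param rep Sample [repertoire()] to mine.
#' @param max_mismatch Mismatch budget (default 8).
#' @param method `"hamming"` (default) or `"levenshtein"`.
#' @return An `mrd_result`: list with the summary fields (`sample_id`,
#'   `clone_id`, `matched_reads`, `total_reads`, `fraction`, `detected`) and
#'   `matches`, a data frame of matching unique sequences with counts and
#'   distances.
#' @export
mine_sample <- function(sig, rep, max_mismatch = 8L,
                        method = c("hamming", "levenshtein")) {
  method <- match.arg(method)
  stopifnot(inherits(sig, "clonotype_signature"), inherits(rep, "repertoire"),
            max_mismatch >= 0L)
  seqs <- rep$sequences$seq
  if (method == "hamming") {
    d <- .min_hamming_to_set(seqs, sig$member_seqs, as.integer(max_mismatch))
  } else {
    d <- apply(utils::adist(seqs, sig$member_seqs), 1L, min)
  }
  hit <- !is.na(d) & d <= max_mismatch
  matched_reads <- sum(rep$sequences$count[hit])
  tot <- total_reads(rep)
  structure(list(sample_id = rep$meta$sample_id,
                 clone_id = sig$clone_id,
                 matched_reads = matched_reads,
                 total_reads = tot,
                 fraction = matched_reads / tot,
                 detected = matched_reads >= 1L,
                 matches = data.frame(seq = seqs[hit],
                                      count = rep$sequences$count[hit],
                                      dist = d[hit],
                                      stringsAsFactors = FALSE)),
            class = "mrd_result")
}

#' @export
print.mrd_result <- function(x, ...) {
  cat(sprintf("<mrd_result> sample %s clone %d: %d/%d reads (%.4g%%), %s\n",
              x$sample_id, x$clone_id, x$matched_reads, x$total_reads,
              100 * x$fraction, if (x$detected) "detected" else "not detected"))
  invisible(x)
}

#' Track clonotype signatures across a patient's samples
#'
#' Mines every sample for every signature. A sequence within the mismatch
#' budget of several signatures is assigned to the signature at the smallest
#' distance (ties to the lower clone id), so matched-read fractions never
#' double-count.
#'
#' @param sigs List of `clonotype_signature` objects for one patient.
#' @param samples List of [repertoire()]s, all from that patient.
#' @param max_mismatch Mismatch budget (default 8).
#' @return Data frame sorted by day then clone with columns `patient_id`,
#'   `clone_id`, `sample_id`, `day`, `matched_reads`, `total_reads`,
#'   `fraction`, `detected`, `external_mrd`.
#' @export
track_patient <- function(sigs, samples, max_mismatch = 8L) {
  stopifnot(length(sigs) > 0L, length(samples) > 0L)
  pids <- unique(c(vapply(sigs, `[[`, "", "patient_id"),
                   vapply(samples, function(s) s$meta$patient_id, "")))
  if (length(pids) != 1L) {
    bcrmrd_error(sprintf("signatures/samples mix patients: %s",
                         paste(pids, collapse = ", ")), "bcrmrd_mixed_patients")
  }
  member_sets <- lapply(sigs, `[[`, "member_seqs")
  rows <- lapply(samples, function(rep) {
    asg <- .argmin_hamming_groups(rep$sequences$seq, member_sets,
                                  as.integer(max_mismatch))
    tot <- total_reads(rep)
    do.call(rbind, lapply(seq_along(sigs), function(g) {
      hit <- asg$group == g
      matched <- sum(rep$sequences$count[hit])
      data.frame(patient_id = pids, clone_id = sigs[[g]]$clone_id,
                 sample_id = rep$meta$sample_id, day = rep$meta$day,
                 matched_reads = matched, total_reads = tot,
                 fraction = matched / tot, detected = matched >= 1L,
                 external_mrd = rep$meta$external_mrd,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out[order(out$day, out$clone_id), , drop = FALSE]
}

#' Correlate sequencing MRD with an external MRD measurement
#'
#' Ordinary least-squares R-squared between log10 clonotypic read fraction
#' and log10 external MRD (e.g. qPCR T/C ratio or % blasts), over samples
#' where both values are positive; zero or missing pairs are excluded and
#' counted.
#'
#' @param results Tracking table from [track_patient()] (one clone), or any
#'   data frame with columns `fraction` and `external_mrd`.
#' @return List with `r_squared`, `n_pairs`, `n_excluded`, `degenerate`
#'   (TRUE with `r_squared = 0` when either variable is constant on the log
#'   scale, leaving the slope undefined).
#' @export
correlate_external <- function(results) {
  stopifnot(all(c("fraction", "external_mrd") %in% names(results)))
  x <- results$fraction
  y <- results$external_mrd
  ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  n_excluded <- sum(!ok)
  if (sum(ok) < 3L) {
    bcrmrd_error(sprintf("need >= 3 paired positive observations, have %d", sum(ok)),
                 "bcrmrd_insufficient_data")
  }
  lx <- log10(x[ok]); ly <- log10(y[ok])
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) {
    return(list(r_squared = 0, n_pairs = sum(ok), n_excluded = n_excluded,
                degenerate = TRUE))
  }
  # OLS R^2 of the simple log-log regression = squared Pearson correlation
  list(r_squared = stats::cor(lx, ly)^2, n_pairs = sum(ok),
       n_excluded = n_excluded, degenerate = FALSE)
}
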