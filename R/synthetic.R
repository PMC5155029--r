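# Seeded synthetic repertoire generator: germline segments, V(D)J
# recombination with N-additions, somatic hypermutation with optional
# WRC/GYW hotspot weighting, leukemic clones with star-like variant clouds,
# secondary rearrangements sharing a D-J stem, dilution series and per-base
# sequencing error. Every read carries a ground-truth record, which makes
# each pipeline stage testable without external data.

#' Simulation configuration
#'
#' Defaults emulate the study regimes the pipeline targets: polyclonal
#' healthy repertoires whose largest cluster stays well under the 2.5%
#' clonality cutoff, monoclonal/biclonal leukemic expansions with star-like
#' variant clouds within 8 substitutions of the ancestor, and dilution
#' series with per-base sequencing error.
#'
#' @param seed Mandatory integer seed; all stage functions derive their own
#'   sub-seed from it, so stages are independently reproducible.
#' @param n_v,n_d,n_j Number of germline V/D/J segments.
#' @param v_len,d_len,j_len Segment lengths (nt).
#' @param n_add_mean Mean geometric length of non-templated N additions at
#'   each junction.
#' @param n_cells Healthy polyclonal cell count.
#' @param read_sdlog Log-normal sdlog of per-cell read counts.
#' @param shm_rate Somatic hypermutation probability per base.
#' @param hotspot_multiplier Rate multiplier at WRC/GYW AID hotspot motifs.
#' @param clone_fraction Read fraction(s) of leukemic clone(s) when mixed
#'   into a background.
#' @param cloud_size Number of SHM variants in a clone's star-like cloud.
#' @param cloud_geom_mean Mean of the truncated geometric distance of cloud
#'   variants from the ancestor.
#' @param cloud_max_d Maximum variant distance from the ancestor (default 8).
#' @param n_secondary Secondary rearrangements to plant (upstream V genes on
#'   the same D-J stem).
#' @param error_rate Per-base substitution sequencing/PCR error rate.
#' @param dilution_ratios Clone dilution ratios for serial dilution series.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_v = 8L, n_d = 4L, n_j = 3L,
                       v_len = 150L, d_len = 21L, j_len = 30L,
                       n_add_mean = 4, n_cells = 3000L, read_sdlog = 1,
                       shm_rate = 0.002, hotspot_multiplier = 1,
                       clone_fraction = 0.3, cloud_size = 60L,
                       cloud_geom_mean = 2, cloud_max_d = 8L,
                       n_secondary = 0L, error_rate = 0.001,
                       dilution_ratios = 10^-(1:5)) {
  if (missing(seed)) bcrmrd_error("`seed` is mandatory", "bcrmrd_invalid_config")
  rates <- c(shm_rate, error_rate)
  if (any(rates < 0 | rates > 1)) {
    bcrmrd_error("rates must lie in [0, 1]", "bcrmrd_invalid_config")
  }
  if (sum(clone_fraction) > 1) {
    bcrmrd_error("clone fractions must sum to <= 1", "bcrmrd_invalid_config")
  }
  stopifnot(n_v >= 1L, n_d >= 1L, n_j >= 1L, n_cells >= 100L)
  structure(list(seed = as.integer(seed), n_v = n_v, n_d = n_d, n_j = n_j,
                 v_len = v_len, d_len = d_len, j_len = j_len,
                 n_add_mean = n_add_mean, n_cells = n_cells,
                 read_sdlog = read_sdlog, shm_rate = shm_rate,
                 hotspot_multiplier = hotspot_multiplier,
                 clone_fraction = clone_fraction, cloud_size = cloud_size,
                 cloud_geom_mean = cloud_geom_mean, cloud_max_d = cloud_max_d,
                 n_secondary = n_secondary, error_rate = error_rate,
                 dilution_ratios = dilution_ratios),
            class = "sim_config")
}

# Deterministic per-stage sub-seed (kept below 2^31; numeric arithmetic
# avoids 32-bit integer overflow for large user seeds).
sub_seed <- function(cfg, stage) {
  as.integer((as.numeric(cfg$seed) * 97 + stage * 7919) %% 2147483629)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a germline V/D/J reference
#'
#' Random segments, rejection-sampled so that within each class all pairs
#' differ at no less than 20% of positions — making annotation unambiguous.
#' V gene names encode locus order: `IGHV1` is the most upstream (furthest
#' from the D locus), so V replacement can only move to a lower index.
#'
#' @param cfg A [sim_config()].
#' @param max_attempts Rejection-sampling budget per segment.
#' @return A `germline_db` with `v_order`.
#' @export
simulate_germline <- function(cfg, max_attempts = 1000L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seed(cfg, 1L), {
    draw_class <- function(n, len, min_frac = 0.2) {
      out <- character(0)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          cand <- random_bases(len)
          dists <- vapply(out, function(s) hamming(cand, s), 0L)
          if (length(dists) == 0L || min(dists) >= min_frac * len) {
            out <- c(out, cand)
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          bcrmrd_error("germline rejection sampling failed; segments too short/numerous",
                       "bcrmrd_invalid_config")
        }
      }
      out
    }
    db <- list(V = setNames(draw_class(cfg$n_v, cfg$v_len), paste0("IGHV", seq_len(cfg$n_v))),
               D = setNames(draw_class(cfg$n_d, cfg$d_len), paste0("IGHD", seq_len(cfg$n_d))),
               J = setNames(draw_class(cfg$n_j, cfg$j_len), paste0("IGHJ", seq_len(cfg$n_j))))
    db$v_order <- setNames(seq_len(cfg$n_v), names(db$V))
    structure(db, class = "germline_db")
  })
}

# One V(D)J recombination event; returns the sequence and its truth record.
vdj_event <- function(cfg, db, v_name = NULL) {
  if (is.null(v_name)) v_name <- sample(names(db$V), 1L)
  d_name <- sample(names(db$D), 1L)
  j_name <- sample(names(db$J), 1L)
  p_geom <- 1 / (1 + cfg$n_add_mean)
  n1 <- rgeom(1L, p_geom)
  n2 <- rgeom(1L, p_geom)
  v <- db$V[[v_name]]
  seqq <- paste0(v, if (n1 > 0) random_bases(n1) else "",
                 db$D[[d_name]], if (n2 > 0) random_bases(n2) else "",
                 db$J[[j_name]])
  v_end <- nchar(v)  # 1-based last V position
  list(seq = seqq, v_name = v_name, d_name = d_name, j_name = j_name,
       v_end = v_end, stem = substr(seqq, v_end + 4L, nchar(seqq)))
}

# Per-position mutation weights, optionally up-weighting AID hotspots:
# WRC (W=A/T, R=A/G, mutable C) and its reverse complement GYW (mutable G).
hotspot_weights <- function(seq, multiplier) {
  chars <- strsplit(seq, "")[[1L]]
  w <- rep(1, length(chars))
  if (multiplier == 1) return(w)
  L <- length(chars)
  for (i in seq_len(L)) {
    if (chars[i] == "C" && i >= 3L &&
        chars[i - 2L] %in% c("A", "T") && chars[i - 1L] %in% c("A", "G")) {
      w[i] <- multiplier
    } else if (chars[i] == "G" && i <= L - 2L &&
               chars[i + 1L] %in% c("C", "T") && chars[i + 2L] %in% c("A", "T")) {
      w[i] <- multiplier
    }
  }
  w
}

# Mutate `seq` at exactly `k` distinct positions (weighted), each to one of
# the three other bases.
mutate_k <- function(seq, k, weights = NULL) {
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  k <- min(k, L)
  pos <- if (is.null(weights)) sample.int(L, k)
  else sample.int(L, k, prob = weights)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), positions = sort(pos))
}

# Binomial per-base SHM.
mutate_rate <- function(seq, rate, weights = NULL) {
  L <- nchar(seq)
  if (is.null(weights)) {
    k <- rbinom(1L, L, rate)
    if (k == 0L) return(list(seq = seq, positions = integer(0)))
    mutate_k(seq, k)
  } else {
    hit <- runif(L) < rate * weights
    if (!any(hit)) return(list(seq = seq, positions = integer(0)))
    chars <- strsplit(seq, "")[[1L]]
    for (p in which(hit)) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    list(seq = paste(chars, collapse = ""), positions = which(hit))
  }
}

#' Simulate a healthy polyclonal repertoire
#'
#' Independent V(D)J events per cell (uniform segment choice, geometric
#' N-additions), log-normal per-cell read counts, light SHM applied per
#' cell. The generator verifies that the emitted largest network cluster
#' stays below the 2.5% clonality cutoff and resamples on violation
#' (attempts counted in attribute `n_resampled`).
#'
#' @param cfg A [sim_config()].
#' @param db A `germline_db` from [simulate_germline()].
#' @param sample_id,patient_id Metadata identifiers.
#' @param max_resample Maximum regeneration attempts (default 10).
#' @return A [repertoire()] with attribute `truth`: data frame of per-unique-
#'   sequence provenance (`seq`, `count`, `cell`, `v_name`, `d_name`,
#'   `j_name`, `v_end`, `stem`, `n_mutations`).
#' @export
simulate_healthy <- function(cfg, db, sample_id = "healthy1",
                             patient_id = "healthy1", max_resample = 10L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(db, "germline_db"))
  with_seed(sub_seed(cfg, 2L), {
    for (attempt in seq_len(max_resample)) {
      cells <- lapply(seq_len(cfg$n_cells), function(i) {
        ev <- vdj_event(cfg, db)
        mut <- mutate_rate(ev$seq, cfg$shm_rate)
        ev$seq <- mut$seq
        ev$stem <- substr(ev$seq, ev$v_end + 4L, nchar(ev$seq))
        ev$n_mutations <- length(mut$positions)
        ev$count <- as.integer(max(1, round(rlnorm(1L, 0, cfg$read_sdlog))))
        ev
      })
      seqs <- vapply(cells, `[[`, "", "seq")
      counts <- vapply(cells, `[[`, 0L, "count")
      # collapse identical recombination products
      agg <- tapply(counts, seqs, sum)
      first_idx <- which(!duplicated(seqs))
      useqs <- seqs[first_idx]
      ucounts <- as.integer(agg[useqs])
      meta <- sample_meta(sample_id, patient_id, 0L, "synthetic", "RNA")
      rep_out <- repertoire(useqs, ucounts, meta)
      net <- build_network(rep_out)
      largest <- max(cluster_stats(net)$fraction)
      if (largest < 0.025) {
        truth <- data.frame(seq = useqs, count = ucounts,
                            cell = first_idx,
                            v_name = vapply(cells, `[[`, "", "v_name")[first_idx],
                            d_name = vapply(cells, `[[`, "", "d_name")[first_idx],
                            j_name = vapply(cells, `[[`, "", "j_name")[first_idx],
                            v_end = vapply(cells, `[[`, 0L, "v_end")[first_idx],
                            stem = vapply(cells, `[[`, "", "stem")[first_idx],
                            n_mutations = vapply(cells, `[[`, 0L, "n_mutations")[first_idx],
                            stringsAsFactors = FALSE)
        attr(rep_out, "truth") <- truth
        attr(rep_out, "n_resampled") <- attempt - 1L
        return(rep_out)
      }
    }
    bcrmrd_error("healthy simulation exceeded resampling budget", "bcrmrd_invalid_config")
  })
}

#' Simulate a leukemic clone with a star-like variant cloud
#'
#' One ancestral V(D)J event plus `cloud_size` variants, each the ancestor
#' with `d` substitutions (`d` from a geometric truncated at `cloud_max_d`,
#' optionally hotspot-weighted). The ancestor always carries the plurality
#' of reads, mirroring the central-BCR structure of leukemic clusters.
#'
#' @param cfg A [sim_config()].
#' @param db A `germline_db`.
#' @param sample_id,patient_id Metadata identifiers.
#' @param stage_salt Integer varied to draw independent clones from one
#'   config (e.g. a relapse resampling of the same ancestor).
#' @return A [repertoire()] with attribute `truth` (`seq`, `count`, `role`,
#'   `d`, `v_name`, `d_name`, `j_name`, `v_end`, `stem`) and attribute
#'   `ancestor` (the truth row of the ancestor).
#' @export
simulate_clone <- function(cfg, db, sample_id = "clone1", patient_id = "patientS",
                           stage_salt = 0L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(db, "germline_db"))
  with_seed(sub_seed(cfg, 3L + 31L * stage_salt), {
    anc <- vdj_event(cfg, db)
    weights <- if (cfg$hotspot_multiplier != 1)
      hotspot_weights(anc$seq, cfg$hotspot_multiplier) else NULL
    p_geom <- 1 / (1 + cfg$cloud_geom_mean)
    n_var <- cfg$cloud_size
    seqs <- anc$seq
    counts <- 0L
    roles <- "ancestor"
    dists <- 0L
    mut_positions <- list(integer(0))
    if (n_var > 0L) {
      for (i in seq_len(n_var)) {
        d <- 1L + (rgeom(1L, p_geom) %% cfg$cloud_max_d)
        mut <- mutate_k(anc$seq, d, weights)
        cnt <- max(1L, round(rlnorm(1L, log(5), 1)))
        hit <- match(mut$seq, seqs)
        if (is.na(hit)) {
          seqs <- c(seqs, mut$seq)
          counts <- c(counts, cnt)
          roles <- c(roles, "variant")
          dists <- c(dists, length(mut$positions))
          mut_positions <- c(mut_positions, list(mut$positions))
        } else {
          counts[hit] <- counts[hit] + cnt
        }
      }
    }
    counts[1L] <- max(counts[-1L], 0L) * 5L + 50L  # ancestor plurality
    meta <- sample_meta(sample_id, patient_id, 0L, "synthetic", "RNA")
    rep_out <- repertoire(seqs, counts, meta)
    truth <- data.frame(seq = seqs, count = counts, role = roles, d = dists,
                        v_name = anc$v_name, d_name = anc$d_name,
                        j_name = anc$j_name, v_end = anc$v_end,
                        stem = anc$stem, stringsAsFactors = FALSE)
    attr(rep_out, "truth") <- truth
    attr(rep_out, "mutation_positions") <- mut_positions
    attr(rep_out, "ancestor") <- truth[1L, , drop = FALSE]
    rep_out
  })
}

#' Plant secondary rearrangements on a clone's D-J stem
#'
#' Adds `k` subclones that re-use the clone ancestor's D-J join and
#' N-additions (hence an identical stem) with distinct, strictly upstream V
#' genes — emulating V replacement.
#'
#' @param clone_rep A [simulate_clone()] repertoire (with truth attribute).
#' @param db The `germline_db` used to simulate it.
#' @param k Number of subclones to add.
#' @param subclone_fraction Read fraction of each subclone relative to the
#'   existing clone reads (default 0.5).
#' @return Extended [repertoire()]; truth gains `role = "secondary"` rows.
#' @export
add_secondary_rearrangement <- function(clone_rep, db, k, subclone_fraction = 0.5) {
  truth <- attr(clone_rep, "truth")
  stopifnot(!is.null(truth), k >= 1L)
  anc <- truth[truth$role == "ancestor", , drop = FALSE][1L, ]
  ord <- db$v_order
  upstream <- names(ord)[ord < ord[[anc$v_name]]]
  if (length(upstream) < k) {
    bcrmrd_error(sprintf("need %d upstream V genes, only %d available upstream of %s",
                         k, length(upstream), anc$v_name),
                 "bcrmrd_invalid_config")
  }
  # most proximal upstream genes first (highest order index below ancestor)
  upstream <- upstream[order(-ord[upstream])][seq_len(k)]
  old_v <- db$V[[anc$v_name]]
  tail_seq <- substr(anc$seq, nchar(old_v) + 1L, nchar(anc$seq))
  new_rows <- lapply(upstream, function(vn) {
    seqq <- paste0(db$V[[vn]], tail_seq)
    data.frame(seq = seqq,
               count = max(1L, round(sum(truth$count) * subclone_fraction / k)),
               role = "secondary", d = NA_integer_, v_name = vn,
               d_name = anc$d_name, j_name = anc$j_name,
               v_end = nchar(db$V[[vn]]),
               stem = substr(seqq, nchar(db$V[[vn]]) + 4L, nchar(seqq)),
               stringsAsFactors = FALSE)
  })
  new_truth <- rbind(truth, do.call(rbind, new_rows))
  out <- repertoire(new_truth$seq, new_truth$count, clone_rep$meta)
  attr(out, "truth") <- new_truth
  attr(out, "ancestor") <- anc
  out
}

#' Dilute a clone into a healthy background and sequence with error
#'
#' Draws `depth` reads: each read is a clone molecule with probability
#' `ratio` (then multinomial over the clone's internal frequencies) and a
#' background molecule otherwise, after which independent per-base
#' substitution errors are applied. Expected clone read count is
#' `depth * ratio`.
#'
#' @param clone_rep Clone [repertoire()].
#' @param healthy_rep Background [repertoire()].
#' @param ratio Clone molecule fraction in (0, 1].
#' @param depth Total reads to draw.
#' @param error_rate Per-base substitution error probability.
#' @param seed RNG seed.
#' @param sample_id Identifier for the emitted sample.
#' @return A [repertoire()] with attribute `truth`: data frame per unique
#'   emitted sequence with `clone_reads` and `background_reads`.
#' @export
dilute_and_sequence <- function(clone_rep, healthy_rep, ratio, depth,
                                error_rate = 0, seed = 1L,
                                sample_id = "diluted") {
  stopifnot(ratio > 0, ratio <= 1, depth >= 1)
  with_seed(seed, {
    cseq <- clone_rep$sequences$seq
    cw <- clone_rep$sequences$count / sum(clone_rep$sequences$count)
    hseq <- healthy_rep$sequences$seq
    hw <- healthy_rep$sequences$count / sum(healthy_rep$sequences$count)
    pool <- c(cseq, hseq)
    probs <- c(ratio * cw, (1 - ratio) * hw)
    idx <- sample.int(length(pool), depth, replace = TRUE, prob = probs)
    reads <- pool[idx]
    from_clone <- idx <= length(cseq)
    if (error_rate > 0) {
      lens <- nchar(reads)
      n_err <- rbinom(depth, lens, error_rate)
      for (i in which(n_err > 0L)) {
        reads[i] <- mutate_k(reads[i], n_err[i])$seq
      }
    }
    tab <- table(reads)
    useqs <- names(tab)
    clone_counts <- tapply(as.integer(from_clone), reads, sum)
    meta <- sample_meta(sample_id, clone_rep$meta$patient_id, 0L,
                        "synthetic", "RNA")
    out <- repertoire(useqs, as.integer(tab), meta)
    attr(out, "truth") <- data.frame(
      seq = useqs, count = as.integer(tab),
      clone_reads = as.integer(clone_counts[useqs]),
      background_reads = as.integer(tab) - as.integer(clone_counts[useqs]),
      stringsAsFactors = FALSE)
    attr(out, "n_clone_reads") <- sum(from_clone)
    out
  })
}

#' Simulate a diagnosis/relapse pair with planted variant sharing
#'
#' One ancestral clone; each diagnostic cloud variant is retained at relapse
#' independently with probability `share`, and the relapse sample adds its
#' own novel variants. The planted shared fraction of unique diagnosis
#' members (ancestor included, since it always persists) is therefore
#' `share` up to binomial noise.
#'
#' @param cfg A [sim_config()].
#' @param db A `germline_db`.
#' @param share Retention probability of each diagnosis variant (default 0.8).
#' @param novel_fraction Relapse-only variants as a fraction of `cloud_size`
#'   (default 0.2).
#' @param patient_id Identifier.
#' @return List with `diagnosis` and `relapse` repertoires (each with truth)
#'   and `planted_share`.
#' @export
simulate_diag_relapse <- function(cfg, db, share = 0.8, novel_fraction = 0.2,
                                  patient_id = "patientS") {
  diag_rep <- simulate_clone(cfg, db, sample_id = "diagnosis",
                             patient_id = patient_id, stage_salt = 0L)
  truth <- attr(diag_rep, "truth")
  with_seed(sub_seed(cfg, 5L), {
    is_var <- truth$role == "variant"
    kept <- rep(TRUE, nrow(truth))
    kept[is_var] <- runif(sum(is_var)) < share
    rel_truth <- truth[kept, , drop = FALSE]
    # resample relapse read counts
    rel_truth$count <- vapply(rel_truth$count, function(cn) {
      as.integer(max(1, round(cn * exp(stats::rnorm(1L, 0, 0.3)))))
    }, 0L)
    # novel relapse-only variants from the same ancestor
    anc <- truth[truth$role == "ancestor", , drop = FALSE][1L, ]
    weights <- if (cfg$hotspot_multiplier != 1)
      hotspot_weights(anc$seq, cfg$hotspot_multiplier) else NULL
    p_geom <- 1 / (1 + cfg$cloud_geom_mean)
    n_novel <- round(novel_fraction * cfg$cloud_size)
    for (i in seq_len(n_novel)) {
      d <- 1L + (rgeom(1L, p_geom) %% cfg$cloud_max_d)
      mut <- mutate_k(anc$seq, d, weights)
      if (mut$seq %in% rel_truth$seq || mut$seq %in% truth$seq) next
      rel_truth <- rbind(rel_truth,
                         data.frame(seq = mut$seq,
                                    count = as.integer(max(2, round(rlnorm(1L, log(5), 1)))),
                                    role = "novel", d = length(mut$positions),
                                    v_name = anc$v_name, d_name = anc$d_name,
                                    j_name = anc$j_name, v_end = anc$v_end,
                                    stem = anc$stem, stringsAsFactors = FALSE))
    }
    meta <- sample_meta("relapse", patient_id, 900L, "synthetic", "RNA")
    relapse <- repertoire(rel_truth$seq, rel_truth$count, meta)
    attr(relapse, "truth") <- rel_truth
    list(diagnosis = diag_rep, relapse = relapse, planted_share = share)
  })
}
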