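# Clone phylogenetics: collect diagnosis/relapse clone members, align them
# around the central BCR (the most frequent sequence, taken as the clone's
# common ancestor), and fit unrooted maximum parsimony trees.

#' Collect clone member sequences from a diagnosis/relapse pair
#'
#' Mines both samples with one clonotype signature and keeps sequences
#' observed at least `min_count` times in at least one sample (singletons are
#' excluded to reduce the risk of including sequencing errors). Each member
#' is labeled by origin: `both`, `diagnosis-only`, or `relapse-only`.
#'
#' @param sig A `clonotype_signature`.
#' @param diag_rep,relapse_rep Diagnosis and relapse [repertoire()]s.
#' @param max_mismatch Mining mismatch budget (default 8).
#' @param min_count Minimum read count in at least one sample (default 2).
#' @return Data frame (`seq`, `count_diag`, `count_rel`, `origin`).
#' @export
collect_clone_members <- function(sig, diag_rep, relapse_rep,
                                  max_mismatch = 8L, min_count = 2L) {
  md <- mine_sample(sig, diag_rep, max_mismatch)$matches
  mr <- mine_sample(sig, relapse_rep, max_mismatch)$matches
  seqs <- union(md$seq, mr$seq)
  cd <- setNames(rep(0L, length(seqs)), seqs)
  cr <- cd
  cd[md$seq] <- md$count
  cr[mr$seq] <- mr$count
  keep <- cd >= min_count | cr >= min_count
  if (sum(keep) < 2L) {
    bcrmrd_error(sprintf("only %d clone member(s) pass min_count = %d; need >= 2",
                         sum(keep), min_count), "bcrmrd_insufficient_data")
  }
  seqs <- seqs[keep]
  origin <- ifelse(cd[seqs] > 0L & cr[seqs] > 0L, "both",
                   ifelse(cd[seqs] > 0L, "diagnosis-only", "relapse-only"))
  out <- data.frame(seq = seqs, count_diag = unname(cd[seqs]),
                    count_rel = unname(cr[seqs]), origin = origin,
                    stringsAsFactors = FALSE)
  out[order(-(out$count_diag + out$count_rel), out$seq), , drop = FALSE]
}

# Parse one global pairwise alignment (member vs central) into per-slot
# insertion strings and per-central-base characters. Slot i holds what the
# member inserts before central base i (slot L+1: after the last base).
parse_star_alignment <- function(member_aln, central_aln, L) {
  pc <- strsplit(member_aln, "")[[1L]]
  sc <- strsplit(central_aln, "")[[1L]]
  ins <- character(L + 1L)
  base_char <- character(L)
  slot <- 1L
  for (col in seq_along(sc)) {
    if (sc[col] == "-") {
      ins[slot] <- paste0(ins[slot], pc[col])
    } else {
      base_char[slot] <- pc[col]
      slot <- slot + 1L
    }
  }
  list(ins = ins, base_char = base_char)
}

#' Align clone members around the central BCR
#'
#' Center-star multiple alignment: every member is globally aligned to the
#' central BCR (the member with the highest summed count; ties to the
#' lexicographically smallest sequence) with affine gap costs, and the
#' pairwise alignments are merged column-wise under "once a gap, always a
#' gap". When all members share one length the alignment is the identity.
#'
#' @param members Data frame from [collect_clone_members()] (columns `seq`,
#'   `count_diag`, `count_rel`, `origin`).
#' @return A `clone_alignment`: list with `members`, `aligned` (named
#'   character vector of equal-length rows), `central_seq`,
#'   `central_aligned`.
#' @export
align_members <- function(members) {
  stopifnot(is.data.frame(members), nrow(members) >= 2L)
  tot <- members$count_diag + members$count_rel
  cand <- members$seq[tot == max(tot)]
  central <- sort(cand)[1L]
  seqs <- members$seq
  if (length(unique(nchar(seqs))) == 1L) {
    aligned <- setNames(seqs, seqs)
  } else {
    L <- nchar(central)
    sub_mat <- vj_substitution_matrix()
    others <- setdiff(seqs, central)
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(others),
      subject = Biostrings::DNAString(central),
      type = "global", substitutionMatrix = sub_mat,
      gapOpening = 3, gapExtension = 1)
    pats <- as.character(Biostrings::alignedPattern(pa))
    subs <- as.character(Biostrings::alignedSubject(pa))
    parsed <- lapply(seq_along(others),
                     function(i) parse_star_alignment(pats[i], subs[i], L))
    ins_len <- vapply(parsed, function(p) nchar(p$ins), integer(L + 1L))
    if (is.null(dim(ins_len))) ins_len <- matrix(ins_len, nrow = L + 1L)
    profile <- apply(ins_len, 1L, max)
    pad <- function(s, width) paste0(s, strrep("-", width - nchar(s)))
    rebuild <- function(p) {
      pieces <- character(0)
      for (i in seq_len(L)) {
        pieces <- c(pieces, pad(p$ins[i], profile[i]), p$base_char[i])
      }
      paste0(paste(pieces, collapse = ""), pad(p$ins[L + 1L], profile[L + 1L]))
    }
    central_parsed <- list(ins = rep("", L + 1L),
                           base_char = strsplit(central, "")[[1L]])
    aligned <- c(setNames(rebuild(central_parsed), central),
                 setNames(vapply(parsed, rebuild, ""), others))
    aligned <- aligned[seqs]
  }
  structure(list(members = members, aligned = aligned, central_seq = central,
                 central_aligned = unname(aligned[central])),
            class = "clone_alignment")
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat(sprintf("<clone_alignment> %d members, alignment length %d, central BCR %s...\n",
              length(x$aligned), nchar(x$central_aligned),
              substr(x$central_seq, 1L, 24L)))
  invisible(x)
}

# --- Fitch parsimony machinery --------------------------------------------
# States are bitmasks: A=1, C=2, G=4, T=8, gap "-"=16 (fifth state), N=15.

encode_states <- function(aligned) {
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 16L, N = 15L)
  t(vapply(strsplit(unname(aligned), ""), function(ch) unname(code[ch]),
           integer(nchar(aligned[[1L]]))))
}

# Adjacency list of an unrooted tree given as a 2-column edge matrix.
tree_adjacency <- function(edges, n_nodes) {
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Postorder node ordering of the tree rooted at `root` (a tip).
postorder_nodes <- function(adj, root) {
  n_nodes <- length(adj)
  parent <- rep(NA_integer_, n_nodes)
  order_out <- integer(0)
  stack <- root
  parent[root] <- 0L
  visit <- integer(0)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    for (w in adj[[v]]) {
      if (is.na(parent[w])) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  list(order = rev(visit), parent = parent)
}

# Fitch parsimony score of an unrooted tree over bitmask tip states.
# `states`: n_tips x S integer matrix; tips are nodes 1..n_tips.
fitch_score <- function(edges, states) {
  n_tips <- nrow(states)
  S <- ncol(states)
  n_nodes <- max(edges)
  adj <- tree_adjacency(edges, n_nodes)
  po <- postorder_nodes(adj, root = 1L)
  sets <- matrix(0L, n_nodes, S)
  sets[seq_len(n_tips), ] <- states
  score <- 0L
  for (v in po$order) {
    kids <- adj[[v]][adj[[v]] != po$parent[v]]
    if (length(kids) == 0L) next
    acc <- sets[kids[1L], ]
    for (k in kids[-1L]) {
      inter <- bitwAnd(acc, sets[k, ])
      miss <- inter == 0L
      score <- score + sum(miss)
      acc <- ifelse(miss, bitwOr(acc, sets[k, ]), inter)
    }
    if (v == 1L) {  # fold the root tip's own state in
      inter <- bitwAnd(acc, sets[1L, ])
      score <- score + sum(inter == 0L)
    } else {
      sets[v, ] <- acc
    }
  }
  score
}

# Attach tip `tip` onto edge `e` (row index) of `edges`, using `new_node` as
# the inserted internal node id.
attach_tip <- function(edges, e, tip, new_node) {
  u <- edges[e, 1L]; v <- edges[e, 2L]
  rbind(edges[-e, , drop = FALSE],
        c(u, new_node), c(new_node, v), c(new_node, tip))
}

# One round of nearest-neighbor interchange proposals; returns improved edge
# matrix or NULL.
nni_improve <- function(edges, states, current) {
  n_tips <- nrow(states)
  n_nodes <- max(edges)
  adj <- tree_adjacency(edges, n_nodes)
  internal_edges <- which(edges[, 1L] > n_tips & edges[, 2L] > n_tips)
  for (e in internal_edges) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    xs <- adj[[a]][adj[[a]] != b]
    us <- adj[[b]][adj[[b]] != a]
    if (length(xs) != 2L || length(us) != 2L) next
    for (swap in list(c(xs[2L], us[1L]), c(xs[2L], us[2L]))) {
      y <- swap[1L]; u <- swap[2L]
      alt <- edges
      for (i in seq_len(nrow(alt))) {
        pr <- alt[i, ]
        if (setequal(pr, c(a, y))) alt[i, ] <- c(a, u)
        else if (setequal(pr, c(b, u))) alt[i, ] <- c(b, y)
      }
      s <- fitch_score(alt, states)
      if (s < current) return(list(edges = alt, score = s))
    }
  }
  NULL
}

# Exhaustive search over all unrooted topologies by recursive tip addition;
# feasible for small tip counts (3 tips: 1 topology ... 7 tips: 945).
exhaustive_parsimony <- function(states) {
  n <- nrow(states)
  best <- list(score = Inf, edges = NULL)
  recurse <- function(edges, next_tip, next_internal) {
    if (next_tip > n) {
      s <- fitch_score(edges, states)
      if (s < best$score) best <<- list(score = s, edges = edges)
      return(invisible())
    }
    # prune: the score of a partial tree only grows as tips are added
    if (fitch_score(edges, states[seq_len(next_tip - 1L), , drop = FALSE]) >=
        best$score) {
      return(invisible())
    }
    for (e in seq_len(nrow(edges))) {
      recurse(attach_tip(edges, e, next_tip, next_internal),
              next_tip + 1L, next_internal + 1L)
    }
  }
  recurse(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)), 4L, n + 2L)
  best
}

#' Build a maximum parsimony tree for a clone alignment
#'
#' For up to `exact_limit` tips the search is exact: every unrooted
#' topology is scored (branch-and-bound over recursive tip addition).
#' Beyond that, heuristic search: deterministic stepwise addition (tips in
#' decreasing count order, each placed on the edge minimizing the Fitch
#' parsimony score) followed by nearest-neighbor interchange until no
#' rearrangement improves the score. States are unordered and equal-cost
#' over \{A, C, G, T\} with the alignment gap as a fifth state. The
#' reported score is the exact Fitch length of the returned topology;
#' branch lengths are substitution counts from a Fitch backtrace and sum to
#' the score.
#'
#' @param aln A `clone_alignment` from [align_members()].
#' @param seed Seed controlling bootstrap-style randomized steps (the search
#'   itself is deterministic; the seed is recorded for reproducibility).
#' @param exact_limit Largest tip count searched exhaustively (default 7).
#' @return A `parsimony_tree`: list with `tree` (an [ape::read.tree()]-style
#'   `phylo`, unrooted, branch lengths in substitutions), `total_length`,
#'   `n_tips`, `tip_seqs` (tip label to sequence map).
#' @export
build_parsimony_tree <- function(aln, seed = 1L, exact_limit = 7L) {
  stopifnot(inherits(aln, "clone_alignment"))
  n <- length(aln$aligned)
  tot <- aln$members$count_diag + aln$members$count_rel
  ord <- order(-tot, aln$members$seq)
  aligned <- aln$aligned[aln$members$seq[ord]]
  labels <- sprintf("s%02d", seq_len(n))
  tip_seqs <- setNames(names(aligned), labels)
  states <- encode_states(aligned)
  # drop constant columns (they never contribute substitutions)
  variable <- apply(states, 2L, function(col) length(unique(col)) > 1L)
  st <- states[, variable, drop = FALSE]
  if (ncol(st) == 0L) st <- matrix(1L, n, 1L)

  if (n == 2L) {
    d <- sum(bitwAnd(states[1L, ], states[2L, ]) == 0L)
    tree <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                           edge.length = c(0, d), Nnode = 1L,
                           tip.label = labels), class = "phylo")
    return(structure(list(tree = tree, total_length = d, n_tips = 2L,
                          tip_seqs = tip_seqs, seed = seed),
                     class = "parsimony_tree"))
  }

  if (n <= exact_limit) {
    found <- exhaustive_parsimony(st)
    edges <- found$edges
    score <- found$score
  } else {
    # stepwise addition
    edges <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
    next_internal <- n + 2L
    for (tip in 4L:n) {
      best_score <- Inf
      best_edges <- NULL
      for (e in seq_len(nrow(edges))) {
        cand <- attach_tip(edges, e, tip, next_internal)
        s <- fitch_score(cand, st)
        if (s < best_score) {
          best_score <- s
          best_edges <- cand
        }
      }
      edges <- best_edges
      next_internal <- next_internal + 1L
    }
    score <- fitch_score(edges, st)
    # NNI refinement
    repeat {
      imp <- nni_improve(edges, st, score)
      if (is.null(imp)) break
      edges <- imp$edges
      score <- imp$score
    }
  }
  phy <- edges_to_phylo(edges, st, labels)
  structure(list(tree = phy, total_length = score, n_tips = n,
                 tip_seqs = tip_seqs, seed = seed),
            class = "parsimony_tree")
}

# Convert the internal edge matrix into an ape phylo with Fitch-backtrace
# branch lengths. Rooting the backtrace at tip 1 keeps every internal node
# binary, so the realized substitution counts sum exactly to the Fitch
# score (with single-bit tip states).
edges_to_phylo <- function(edges, states, labels) {
  n_tips <- nrow(states)
  S <- ncol(states)
  n_nodes <- max(edges)
  adj <- tree_adjacency(edges, n_nodes)
  po <- postorder_nodes(adj, root = 1L)
  sets <- matrix(0L, n_nodes, S)
  sets[seq_len(n_tips), ] <- states
  for (v in po$order) {
    kids <- adj[[v]][adj[[v]] != po$parent[v]]
    if (length(kids) == 0L || v == 1L) next
    acc <- sets[kids[1L], ]
    for (k in kids[-1L]) {
      inter <- bitwAnd(acc, sets[k, ])
      acc <- ifelse(inter == 0L, bitwOr(acc, sets[k, ]), inter)
    }
    sets[v, ] <- acc
  }
  lowest_bit <- function(x) bitwAnd(x, -x)
  assigned <- matrix(0L, n_nodes, S)
  preorder <- rev(po$order)  # starts at the root tip
  assigned[1L, ] <- lowest_bit(sets[1L, ])
  for (v in preorder) {
    if (v == 1L) next
    p <- po$parent[v]
    inter <- bitwAnd(sets[v, ], assigned[p, ])
    assigned[v, ] <- ifelse(inter > 0L, inter, lowest_bit(sets[v, ]))
  }
  # ape representation: root at the internal node adjacent to tip 1
  phylo_root <- adj[[1L]][1L]
  parent <- po$parent
  parent[1L] <- phylo_root
  parent[phylo_root] <- 0L
  new_id <- integer(n_nodes)
  new_id[seq_len(n_tips)] <- seq_len(n_tips)
  next_id <- n_tips + 1L
  for (v in c(phylo_root, preorder)) {
    if (v > n_tips && new_id[v] == 0L) {
      new_id[v] <- next_id
      next_id <- next_id + 1L
    }
  }
  childs <- which(seq_len(n_nodes) != phylo_root)
  edge_mat <- cbind(new_id[parent[childs]], new_id[childs])
  edge_len <- vapply(childs, function(v) {
    sum(assigned[v, ] != assigned[parent[v], ])
  }, 0L)
  ord <- order(edge_mat[, 1L], edge_mat[, 2L])
  structure(list(edge = edge_mat[ord, , drop = FALSE],
                 edge.length = as.numeric(edge_len[ord]),
                 Nnode = n_nodes - n_tips, tip.label = labels),
            class = "phylo")
}

#' @export
print.parsimony_tree <- function(x, ...) {
  cat(sprintf("<parsimony_tree> %d tips, parsimony length %d\n",
              x$n_tips, x$total_length))
  invisible(x)
}

#' Bootstrap support for a parsimony tree
#'
#' Column (site) resampling with replacement: each replicate rebuilds the
#' tree from a resampled alignment and clade support is the fraction of
#' replicates containing each internal edge's bipartition.
#'
#' @param aln A `clone_alignment`.
#' @param reps Number of replicates (default 100).
#' @param seed RNG seed.
#' @return List with `tree` (the full-data `parsimony_tree`), `support`
#'   (per internal node, fraction in \[0,1\]), `reps`.
#' @export
parsimony_bootstrap <- function(aln, reps = 100L, seed = 1L) {
  pt <- build_parsimony_tree(aln, seed = seed)
  L <- nchar(aln$central_aligned)
  boot_trees <- with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      resampled <- vapply(aln$aligned, function(s) {
        paste(strsplit(s, "")[[1L]][cols], collapse = "")
      }, "")
      baln <- structure(list(members = aln$members,
                             aligned = setNames(resampled, names(aln$aligned)),
                             central_seq = aln$central_seq,
                             central_aligned = unname(resampled[aln$central_seq])),
                        class = "clone_alignment")
      build_parsimony_tree(baln, seed = seed + r)$tree
    })
  })
  counts <- ape::prop.clades(pt$tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = pt, support = counts / reps, reps = reps)
}

#' Diagnosis-relapse clone structure summary
#'
#' Quantifies how much of the clone's population structure is retained from
#' diagnosis to relapse: the fraction of unique diagnosis members resampled
#' at relapse, the same per distance shell from the central BCR, and the
#' squared correlation between member frequencies at diagnosis and relapse
#' (reported on the raw scale and on the cube-root scale, which gives
#' low-frequency members visible weight).
#'
#' @param aln A `clone_alignment`.
#' @return List with `overlap` (|both| / |diagnosis members|), `shells`
#'   (data frame `d`, `n_diag`, `n_rel`, `n_both`), `r2_raw`,
#'   `r2_cuberoot`, `central_seq`.
#' @export
structure_summary <- function(aln) {
  stopifnot(inherits(aln, "clone_alignment"))
  m <- aln$members
  diag_members <- m$origin %in% c("both", "diagnosis-only")
  overlap <- sum(m$origin == "both") / sum(diag_members)
  cen <- utf8ToInt(aln$central_aligned)
  d <- vapply(unname(aln$aligned[m$seq]), function(s) sum(utf8ToInt(s) != cen), 0L)
  shells <- do.call(rbind, lapply(sort(unique(d)), function(dd) {
    at <- d == dd
    data.frame(d = dd,
               n_diag = sum(at & diag_members),
               n_rel = sum(at & m$origin %in% c("both", "relapse-only")),
               n_both = sum(at & m$origin == "both"))
  }))
  f_diag <- m$count_diag / sum(m$count_diag)
  f_rel <- m$count_rel / sum(m$count_rel)
  # OLS R^2 of simple regression = squared Pearson correlation
  r2 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)^2
  }
  list(overlap = overlap, shells = shells,
       r2_raw = r2(f_diag, f_rel),
       r2_cuberoot = r2(f_diag^(1 / 3), f_rel^(1 / 3)),
       central_seq = aln$central_seq)
}

#' Export a parsimony tree to Newick
#'
#' @param pt A `parsimony_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_tree <- function(pt, path) {
  ape::write.tree(pt$tree, file = path)
  invisible(path)
}

#' Export a clone alignment to FASTA
#'
#' @param aln A `clone_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$aligned), path)
  invisible(path)
}
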