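# Independent brute-force oracles used across the test files.

# Enumerate every local alignment path of `seq` (residue string) through a
# profile HMM and return the total probability-odds weights of all paths.
# Semantics mirror the scoring contract: uniform entry into any match state
# (weight 1/L), free exit after any match state, insert states emit the
# background (odds 1).  Independent of the C++ dynamic programs: pure
# recursive enumeration.
enumerate_path_odds <- function(hmm, seq) {
  codes <- rabrep:::encode_residues(seq) + 1L  # 1..20, 21 = X
  n <- length(codes)
  L <- hmm$L
  q <- hmm$background
  em_odds <- function(j, a) {
    if (a == 21L) return(1)
    hmm$match_emissions[j, a] / q[a]
  }
  tr <- hmm$transitions
  weights <- numeric(0)
  # extend from a match state at (model j, query i) with accumulated odds w
  extend <- function(j, i, w) {
    weights[length(weights) + 1] <<- w  # exit here (free)
    if (j >= L) return(invisible(NULL))
    # M -> M
    if (i < n) {
      extend(j + 1, i + 1, w * tr[j, "MM"] * em_odds(j + 1, codes[i + 1]))
    }
    # M -> I (k >= 1 insertions, odds 1 each) -> M
    k <- 1
    while (i + k + 1 <= n) {
      wk <- w * tr[j, "MI"] * (tr[j, "II"]^(k - 1)) * tr[j, "IM"]
      extend(j + 1, i + k + 1, wk * em_odds(j + 1, codes[i + k + 1]))
      k <- k + 1
    }
    # M -> D (d >= 1 deletions) -> M
    d <- 1
    repeat {
      jn <- j + d + 1  # next match position after d deletions
      if (jn > L) break
      if (i < n) {
        wD <- w * tr[j, "MD"]
        if (d > 1) for (s in seq_len(d - 1)) wD <- wD * tr[j + s, "DD"]
        wD <- wD * tr[j + d, "DM"]
        extend(jn, i + 1, wD * em_odds(jn, codes[i + 1]))
      }
      d <- d + 1
    }
    invisible(NULL)
  }
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(L)) {
      extend(j0, i0, (1 / L) * em_odds(j0, codes[i0]))
    }
  }
  weights
}

brute_viterbi_bits <- function(hmm, seq) log2(max(enumerate_path_odds(hmm, seq)))
brute_forward_bits <- function(hmm, seq) log2(sum(enumerate_path_odds(hmm, seq)))

# random small alignment for profile building
random_alignment <- function(n_seq, n_col, seed, gap_frac = 0) {
  set.seed(seed)
  rows <- vapply(seq_len(n_seq), function(i) {
    r <- sample(rabrep:::AA_ALPHABET, n_col, replace = TRUE)
    if (gap_frac > 0) {
      g <- which(stats::runif(n_col) < gap_frac)
      r[g] <- "-"
    }
    paste(r, collapse = "")
  }, character(1))
  # avoid all-gap rows
  rows[!nzchar(gsub("-", "", rows))] <- paste(rep("A", n_col), collapse = "")
  as_alignment(seq_records(sprintf("s%02d", seq_len(n_seq)), rows,
                           allow_gap = TRUE))
}

random_background_records <- function(n, len, seed, prefix = "bg") {
  set.seed(seed)
  seq_records(sprintf("%s%04d", prefix, seq_len(n)),
              vapply(seq_len(n), function(i)
                paste(sample(rabrep:::AA_ALPHABET, len, replace = TRUE),
                      collapse = ""), character(1)))
}

# brute-force Dollo oracle: enumerate single-gain scenarios on a two-sided
# root and call a family ancestral iff the minimal-event scenario places
# the gain at the root
brute_dollo <- function(m, rooting) {
  sp <- supergroup_presence(m)
  side_a <- setdiff(rooting$side_a, rooting$excluded)
  side_b <- setdiff(rooting$side_b, rooting$excluded)
  anc <- character(0)
  for (fam in rownames(sp)) {
    in_a <- any(sp[fam, intersect(side_a, colnames(sp))])
    in_b <- any(sp[fam, intersect(side_b, colnames(sp))])
    if (!in_a && !in_b) next
    # scenarios: gain at root (cost 1 + losses on empty sides), or gain on
    # one side (only allowed if the family is absent from the other side)
    cost_root <- 1 + (!in_a) + (!in_b)
    cost_a <- if (!in_b && in_a) 1 else Inf
    cost_b <- if (!in_a && in_b) 1 else Inf
    if (cost_root < min(cost_a, cost_b)) anc <- c(anc, fam)
  }
  anc
}

# random presence matrix over 2-4 supergroups
random_presence <- function(n_fam, n_tax, seed) {
  set.seed(seed)
  groups <- c("Unikonta", "Excavata", "Archaeplastida", "SAR+CCTH")
  taxa <- sprintf("tax%02d", seq_len(n_tax))
  sg <- stats::setNames(sample(groups, n_tax, replace = TRUE), taxa)
  m <- matrix(stats::runif(n_fam * n_tax) < 0.5, n_fam, n_tax,
              dimnames = list(sprintf("fam%02d", seq_len(n_fam)), taxa))
  # ensure at least one presence so the matrix is non-degenerate
  if (!any(m)) m[1, 1] <- TRUE
  presence_matrix(m, sg)
}

# least-squares tree-fitting oracle for NJ consistency: enumerate all
# unrooted topologies (via ape), fit branch lengths by ordinary least
# squares on the path-indicator design, return the topology with minimal
# residual sum of squares
ls_best_topology <- function(dm) {
  taxa <- rownames(dm)
  n <- length(taxa)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  pairs <- t(utils::combn(n, 2))
  d <- dm[pairs]
  best <- NULL
  best_rss <- Inf
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]  # [[ decompresses the multiPhylo, restoring tip labels
    X <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (r in seq_len(nrow(pairs))) {
      path_nodes <- ape::nodepath(tr, pairs[r, 1], pairs[r, 2])
      for (s in seq_len(length(path_nodes) - 1)) {
        e <- which((tr$edge[, 1] == path_nodes[s] & tr$edge[, 2] == path_nodes[s + 1]) |
                     (tr$edge[, 2] == path_nodes[s] & tr$edge[, 1] == path_nodes[s + 1]))
        X[r, e] <- 1
      }
    }
    fit <- stats::lm.fit(X, d)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-10) {
      best_rss <- rss
      best <- tr
      best$edge.length <- fit$coefficients
    }
  }
  list(tree = best, rss = best_rss)
}

# unrooted bipartition keys of a phylo tree (canonical form)
split_keys <- function(tree) {
  names(rabrep:::tree_bipartitions(tree))
}

canonical_split_key_for <- function(tips, tree) {
  rabrep:::canonical_split_key(tips, sort(tree$tip.label))
}

# random additive distance matrix from a random binary tree with positive
# branch lengths; returns list(dm, tree)
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   tip.label = sprintf("t%02d", seq_len(n_taxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 2)
  list(dm = ape::cophenetic.phylo(tr), tree = tr)
}

# adjusted Rand index between two labelled partitions (named vectors)
adjusted_rand <- function(a, b) {
  ids <- intersect(names(a), names(b))
  a <- a[ids]; b <- b[ids]
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(ids)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
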