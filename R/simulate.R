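#' Configuration for the sequence-family simulator
#'
#' @param tree A `phylo` tree or Newick string with branch lengths in
#'   expected substitutions per site.
#' @param root_length Root sequence length in residues (>= 1).
#' @param gamma_shape Shape of the gamma distribution of per-site rates
#'   (mean 1); large values approach rate homogeneity.
#' @param indel_rate Indel events per site per unit branch length
#'   (default 0: substitutions only).
#' @param indel_mean_len Mean indel length (geometric).
#' @param background 20-entry residue frequency table.
#' @param seed Integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(tree, root_length = 150, gamma_shape = 1,
                              indel_rate = 0, indel_mean_len = 3,
                              background = aa_background(), seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), root_length >= 1, gamma_shape > 0,
            indel_rate >= 0, indel_mean_len >= 1)
  structure(list(tree = tree, root_length = as.integer(root_length),
                 gamma_shape = gamma_shape, indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len,
                 background = background, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Evolve protein sequences along a tree
#'
#' The root sequence is drawn i.i.d. from the background.  Along each
#' branch of length `t`, site `i` receives `Poisson(t * r_i)`
#' substitutions, with site rate `r_i ~ Gamma(shape, mean 1)` drawn once
#' per site; each substitution replaces the residue by a uniform draw from
#' the other 19.  Indel events arrive as a Poisson process (rate
#' `indel_rate * t` per site); lengths are geometric with mean
#' `indel_mean_len`; insertions draw new residues (and new site rates)
#' from the background.  The true alignment (gap history) is returned
#' alongside the leaf sequences.
#'
#' @param cfg A [simulation_config()].
#' @return List: `records` (leaf sequences, ungapped), `alignment`
#'   (`aa_alignment` of all leaves with the true gap structure).
#' @export
evolve_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  tree <- ape::reorder.phylo(cfg$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L

  env <- new.env()
  env$col_order <- sprintf("c%07d", seq_len(cfg$root_length))
  env$counter <- cfg$root_length

  root_res <- sample.int(20L, cfg$root_length, replace = TRUE,
                         prob = cfg$background)
  root_rate <- stats::rgamma(cfg$root_length, shape = cfg$gamma_shape,
                             rate = cfg$gamma_shape)
  root_state <- list(cols = env$col_order, res = root_res, rate = root_rate)

  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- root_state

  evolve_branch <- function(state, t) {
    L <- length(state$res)
    if (t > 0 && L > 0) {
      nsub <- stats::rpois(L, t * state$rate)
      for (i in which(nsub > 0)) {
        r <- state$res[i]
        for (k in seq_len(nsub[i])) {
          r <- sample(setdiff(1:20, r), 1)
        }
        state$res[i] <- r
      }
      if (cfg$indel_rate > 0) {
        n_events <- stats::rpois(1, cfg$indel_rate * t * L)
        for (e in seq_len(n_events)) {
          len <- stats::rgeom(1, 1 / cfg$indel_mean_len) + 1L
          if (stats::runif(1) < 0.5 || length(state$res) <= len) {
            # insertion after a uniformly chosen position (0 = before start)
            pos <- sample.int(length(state$res) + 1L, 1) - 1L
            new_cols <- sprintf("c%07d", env$counter + seq_len(len))
            env$counter <- env$counter + len
            anchor <- if (pos == 0) 0L else
              match(state$cols[pos], env$col_order)
            env$col_order <- append(env$col_order, new_cols, after = anchor)
            new_res <- sample.int(20L, len, replace = TRUE,
                                  prob = cfg$background)
            new_rate <- stats::rgamma(len, shape = cfg$gamma_shape,
                                      rate = cfg$gamma_shape)
            state$cols <- append(state$cols, new_cols, after = pos)
            state$res <- append(state$res, new_res, after = pos)
            state$rate <- append(state$rate, new_rate, after = pos)
          } else {
            pos <- sample.int(length(state$res) - len + 1L, 1)
            drop <- pos:(pos + len - 1L)
            state$cols <- state$cols[-drop]
            state$res <- state$res[-drop]
            state$rate <- state$rate[-drop]
          }
        }
      }
    }
    state
  }

  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    t <- tree$edge.length[k]
    states[[child]] <- evolve_branch(states[[parent]], t)
  }

  ids <- tree$tip.label
  seqs <- vapply(seq_len(n_tip), function(i) {
    paste(AA_ALPHABET[states[[i]]$res], collapse = "")
  }, character(1))
  records <- seq_records(ids, seqs, species = ids)

  aligned <- vapply(seq_len(n_tip), function(i) {
    row <- stats::setNames(rep("-", length(env$col_order)), env$col_order)
    row[states[[i]]$cols] <- AA_ALPHABET[states[[i]]$res]
    paste(row, collapse = "")
  }, character(1))
  alignment <- as_alignment(seq_records(ids, aligned, species = ids,
                                        allow_gap = TRUE))
  list(records = records, alignment = alignment)
}

#' Generate a labelled multi-family classification benchmark
#'
#' Families are simulated on a two-level star tree: `n_families` ancestors
#' sit at depth `between_depth` below the root and each subtends a star of
#' `members_per_family` leaves at depth `within_depth`.  The ratio
#' `between_depth / within_depth` controls family separability.  Seed
#' alignments are the true alignments restricted to each family.
#'
#' @param n_families,members_per_family Benchmark shape.
#' @param within_depth,between_depth Branch lengths (substitutions/site).
#' @param root_length,gamma_shape,indel_rate,indel_mean_len,background
#'   Passed to [simulation_config()].
#' @param seed Integer RNG seed.
#' @return List: `records` (all leaf sequences; `species` carries the leaf
#'   id), `labels` (data frame `id`, `family`), `seeds` (named list of
#'   per-family `aa_alignment`s).
#' @export
make_family_benchmark <- function(n_families = 5, members_per_family = 20,
                                  within_depth = 0.2,
                                  between_depth = 0.6,
                                  root_length = 150, gamma_shape = 1,
                                  indel_rate = 0, indel_mean_len = 3,
                                  background = aa_background(), seed = 1) {
  stopifnot(between_depth > 0, within_depth >= 0)
  fam_sub <- vapply(seq_len(n_families), function(f) {
    leaves <- sprintf("fam%02d_m%03d:%s", f, seq_len(members_per_family),
                      format(within_depth, scientific = FALSE))
    sprintf("(%s):%s", paste(leaves, collapse = ","),
            format(between_depth, scientific = FALSE))
  }, character(1))
  nwk <- sprintf("(%s);", paste(fam_sub, collapse = ","))
  cfg <- simulation_config(nwk, root_length = root_length,
                           gamma_shape = gamma_shape,
                           indel_rate = indel_rate,
                           indel_mean_len = indel_mean_len,
                           background = background, seed = seed)
  sim <- evolve_sequences(cfg)
  fam <- sub("_m[0-9]+$", "", sim$records$id)
  labels <- data.frame(id = sim$records$id, family = fam,
                       stringsAsFactors = FALSE)
  seeds <- lapply(split(seq_len(nrow(sim$records)), fam), function(idx) {
    sub <- sim$alignment
    sub$seq <- sub$seq[idx, , drop = FALSE]
    sub$meta <- sub$meta[idx, , drop = FALSE]
    keep <- colSums(sub$seq != "-") > 0
    sub$seq <- sub$seq[, keep, drop = FALSE]
    sub
  })
  list(records = sim$records, labels = labels, seeds = seeds)
}
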