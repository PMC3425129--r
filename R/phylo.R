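#' Corrected pairwise distances from a protein alignment
#'
#' Distances use pairwise deletion: only columns where both sequences
#' carry a canonical residue are compared.  Models: `p` = raw mismatch
#' fraction; `poisson` = `-ln(1 - p)`; `gamma` =
#' `a * ((1 - p)^(-1/a) - 1)` with shape `a` (rate heterogeneity across
#' sites; the continuous closed form, no discretisation).  Saturated pairs
#' (`p = 1`) under `poisson`/`gamma` are set to `cap` with a warning and
#' recorded in the `saturated` attribute.
#'
#' @param aln An `aa_alignment` (>= 2 sequences).
#' @param model `"p"`, `"poisson"` or `"gamma"`.
#' @param gamma_shape Gamma shape parameter `a` (default 1).
#' @param cap Distance assigned to saturated pairs (default 10).
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames;
#'   class `dist_matrix`.
#' @export
pairwise_distance <- function(aln, model = c("p", "poisson", "gamma"),
                              gamma_shape = 1, cap = 10) {
  model <- match.arg(model)
  mat <- aln$seq
  n <- nrow(mat)
  if (n < 2) stop("need at least two sequences")
  ids <- rownames(mat)
  ok <- matrix(mat %in% AA_ALPHABET, n, ncol(mat))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  saturated <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) stop("no comparable columns for pair ", ids[i], ", ", ids[j])
      p <- mean(mat[i, comp] != mat[j, comp])
      v <- switch(model,
                  p = p,
                  poisson = if (p >= 1) NA_real_ else -log(1 - p),
                  gamma = if (p >= 1) NA_real_ else
                    gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1))
      if (is.na(v)) {
        v <- cap
        saturated <- c(saturated, paste(ids[i], ids[j], sep = ":"))
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  if (length(saturated) > 0) {
    warning("saturated pairs capped at ", cap, ": ",
            paste(saturated, collapse = ", "))
  }
  structure(d, saturated = saturated, model = model, class = c("dist_matrix",
                                                               "matrix"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Q criterion with Studier-Keppler updates).
#' Exact ties in Q are broken by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest tip).  Negative
#' branch lengths are clamped to zero with the deficit moved to the
#' sibling edge.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dm) {
  dm <- unclass(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # active clusters: newick fragment + representative label
  frag <- labels
  rep_lab <- labels
  D <- dm
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.10g", max(0, x))

  while (length(active) > 3) {
    r <- length(active)
    Dsub <- D[active, active, drop = FALSE]
    R <- rowSums(Dsub)
    best <- NULL
    best_q <- Inf
    for (a in seq_len(r - 1)) {
      for (b in (a + 1):r) {
        q <- (r - 2) * Dsub[a, b] - R[a] - R[b]
        if (q < best_q - 1e-12) {
          best_q <- q; best <- c(a, b)
        } else if (abs(q - best_q) <= 1e-12) {
          # lexicographic tie-break on sorted representative label pair
          cand <- sort(c(rep_lab[active[a]], rep_lab[active[b]]))
          cur <- sort(c(rep_lab[active[best[1]]], rep_lab[active[best[2]]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(a, b)
          }
        }
      }
    }
    ia <- active[best[1]]; ib <- active[best[2]]
    dij <- D[ia, ib]
    va <- dij / 2 + (R[best[1]] - R[best[2]]) / (2 * (r - 2))
    vb <- dij - va
    if (va < 0) { vb <- vb + va; va <- 0 }
    if (vb < 0) { va <- va + vb; vb <- 0; va <- max(0, va) }
    # new cluster
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[ia], fmt(va), frag[ib], fmt(vb))
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    for (k in active) {
      if (k == ia || k == ib) next
      D[u, k] <- D[k, u] <- (D[ia, k] + D[ib, k] - dij) / 2
    }
    frag <- c(frag, newfrag)
    rep_lab <- c(rep_lab, min(rep_lab[ia], rep_lab[ib]))
    active <- c(setdiff(active, c(ia, ib)), u)
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  vb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  vc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], fmt(va), frag[b], fmt(vb),
                 frag[c3], fmt(vc))
  ape::read.tree(text = nwk)
}

# canonical key of one side of a split: the side NOT containing the
# alphabetically first tip, sorted and joined
canonical_split_key <- function(side, all_tips) {
  side <- sort(side)
  if (all_tips[1] %in% side) side <- sort(setdiff(all_tips, side))
  paste(side, collapse = "|")
}

# non-trivial bipartitions of an unrooted phylo; named list key -> tip set,
# with attribute `node` giving the internal node whose parent edge is cut
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- list()
  nodes <- integer(0)
  for (i in seq_along(pp)) {
    node <- n + i
    tips <- tree$tip.label[pp[[i]]]
    if (length(tips) <= 1 || length(tips) >= n - 1) next
    if (i == 1) next  # root clade = all tips, trivial
    key <- canonical_split_key(tips, all_tips)
    out[[key]] <- sort(tips)
    nodes <- c(nodes, node)
  }
  attr(out, "node") <- nodes
  out
}

#' Column-bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes the distance
#' matrix and NJ tree per replicate, and labels each internal edge of the
#' original tree with the fraction of replicates whose tree contains the
#' same bipartition.
#'
#' @param aln An `aa_alignment`.
#' @param model,gamma_shape Passed to [pairwise_distance()].
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return The original NJ `phylo` tree with `node.label` carrying support
#'   in `[0, 1]` (empty for the basal node); the support table is attached
#'   as attribute `support`.
#' @export
bootstrap_support <- function(aln, model = "gamma", gamma_shape = 1,
                              reps = 1000, seed = 1) {
  if (reps < 1) stop("reps must be >= 1")
  if (ncol(aln$seq) < 2) stop("alignment has a single column")
  base_dm <- pairwise_distance(aln, model = model, gamma_shape = gamma_shape)
  tree <- neighbor_joining(base_dm)
  bp <- tree_bipartitions(tree)
  counts <- stats::setNames(numeric(length(bp)), names(bp))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(aln$seq), replace = TRUE)
    baln <- aln
    baln$seq <- aln$seq[, cols, drop = FALSE]
    bdm <- suppressWarnings(pairwise_distance(baln, model = model,
                                              gamma_shape = gamma_shape))
    btree <- neighbor_joining(bdm)
    bkeys <- names(tree_bipartitions(btree))
    hit <- names(counts) %in% bkeys
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / reps
  n <- length(tree$tip.label)
  nlab <- rep("", tree$Nnode)
  nodes <- attr(bp, "node")
  for (i in seq_along(nodes)) {
    nlab[nodes[i] - n] <- sprintf("%.3f", support[i])
  }
  tree$node.label <- nlab
  attr(tree, "support") <- support
  tree
}

#' Read / write a square distance matrix as TSV
#' @param dm Distance matrix.
#' @param path File path.
#' @return `read_dist_matrix` returns the matrix.
#' @export
write_dist_matrix <- function(dm, path) {
  df <- data.frame(taxon = rownames(dm), unclass(dm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
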