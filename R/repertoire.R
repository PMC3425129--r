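#' Construct a family-by-taxon presence matrix
#'
#' @param present Logical (or 0/1) matrix, rows = families, columns =
#'   taxa, with dimnames.
#' @param supergroup_of Named character vector mapping every taxon to its
#'   eukaryotic supergroup (default supergroup set: Unikonta, Excavata,
#'   Archaeplastida, SAR+CCTH).
#' @return Object of class `presence_matrix`.
#' @export
presence_matrix <- function(present, supergroup_of) {
  if (is.null(rownames(present)) || is.null(colnames(present)))
    stop("presence matrix needs family and taxon dimnames")
  if (nrow(present) < 1 || ncol(present) < 1)
    stop("need at least one family and one taxon")
  storage.mode(present) <- "logical"
  taxa <- colnames(present)
  missing <- setdiff(taxa, names(supergroup_of))
  if (length(missing) > 0)
    stop("taxa without supergroup mapping: ", paste(missing, collapse = ", "))
  structure(list(present = present,
                 supergroup_of = supergroup_of[taxa]),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d families x %d taxa (%d supergroups)\n",
              nrow(x$present), ncol(x$present),
              length(unique(x$supergroup_of))))
  invisible(x)
}

#' Read / write a presence matrix (TSV pair)
#'
#' The matrix file has a first column `family` and one 0/1 column per
#' taxon; the mapping file has columns `taxon` and `supergroup`.
#'
#' @param path Matrix TSV path.
#' @param mapping_path Taxon-to-supergroup TSV path.
#' @return A `presence_matrix`.
#' @export
read_presence_matrix <- function(path, mapping_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "family") stop("first column must be 'family'")
  fam <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(matrix(!(vals %in% c("0", "1")), nrow(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-0/1 cell '%s' at family '%s', taxon '%s'",
                 vals[bad[1, , drop = FALSE]], fam[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  }
  m <- matrix(vals == "1", nrow(vals), ncol(vals),
              dimnames = list(fam, colnames(vals)))
  map <- utils::read.delim(mapping_path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "supergroup") %in% names(map)))
    stop("mapping file needs columns 'taxon' and 'supergroup'")
  presence_matrix(m, stats::setNames(map$supergroup, map$taxon))
}

#' @rdname read_presence_matrix
#' @param m A `presence_matrix`.
#' @export
write_presence_matrix <- function(m, path, mapping_path) {
  df <- data.frame(family = rownames(m$present),
                   ifelse(m$present, "1", "0"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(taxon = names(m$supergroup_of),
                    supergroup = unname(m$supergroup_of),
                    stringsAsFactors = FALSE)
  utils::write.table(map, mapping_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse taxon presence to supergroup presence
#'
#' A family is present in a supergroup iff it is present in at least one
#' of the supergroup's taxa (OR collapse).
#'
#' @param m A `presence_matrix`.
#' @return Logical matrix families x supergroups.
#' @export
supergroup_presence <- function(m) {
  groups <- unique(unname(m$supergroup_of))
  out <- sapply(groups, function(g) {
    cols <- names(m$supergroup_of)[m$supergroup_of == g]
    rowSums(m$present[, cols, drop = FALSE]) > 0
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(m$present),
                                                       groups))
  out
}

#' Families present in at least k supergroups
#'
#' @param m A `presence_matrix`.
#' @param k Minimum number of supergroups (1 .. number of supergroups).
#' @return List with `count` and `families`.
#' @export
families_in_at_least <- function(m, k) {
  sp <- supergroup_presence(m)
  if (k < 1 || k > ncol(sp)) stop("k out of range")
  hit <- rowSums(sp) >= k
  list(count = sum(hit), families = rownames(sp)[hit])
}

#' Define a rooting hypothesis for the eukaryotic tree
#'
#' The root splits the supergroups into two disjoint sides; supergroups
#' with uncertain placement can be excluded (they then contribute to
#' neither side).
#'
#' @param name Hypothesis name.
#' @param side_a,side_b Disjoint non-empty character vectors of
#'   supergroups.
#' @param excluded Supergroups ignored by the hypothesis.
#' @return Object of class `rooting_hypothesis`.
#' @export
rooting_hypothesis <- function(name, side_a, side_b, excluded = character(0)) {
  if (length(side_a) == 0 || length(side_b) == 0)
    stop("both sides of the root must be non-empty")
  if (length(intersect(side_a, side_b)) > 0)
    stop("sides must be disjoint")
  structure(list(name = name, side_a = side_a, side_b = side_b,
                 excluded = excluded),
            class = "rooting_hypothesis")
}

#' Dollo-parsimony ancestral repertoire at the root
#'
#' Under single-origin (Dollo) parsimony a family was present in the last
#' common ancestor iff it occurs on both sides of the root; families seen
#' on one side only are explained by a single post-root gain.  Excluded
#' supergroups contribute to neither side.
#'
#' @param m A `presence_matrix`.
#' @param rooting A `rooting_hypothesis`.
#' @return Character vector of ancestral families (matrix row order).
#' @export
leca_dollo <- function(m, rooting) {
  sp <- supergroup_presence(m)
  side_a <- setdiff(rooting$side_a, rooting$excluded)
  side_b <- setdiff(rooting$side_b, rooting$excluded)
  side_a <- intersect(side_a, colnames(sp))
  side_b <- intersect(side_b, colnames(sp))
  if (length(side_a) == 0 || length(side_b) == 0)
    stop("a side of the root is empty after exclusions")
  in_a <- rowSums(sp[, side_a, drop = FALSE]) > 0
  in_b <- rowSums(sp[, side_b, drop = FALSE]) > 0
  rownames(sp)[in_a & in_b]
}

#' Construct a gain/loss event ledger along a lineage path
#'
#' @param path Ordered character vector of lineage node names, ancestor
#'   first.
#' @param events Data frame with columns `node`, `kind` (`gain`/`loss`),
#'   `family`, and optionally `uncertain` (logical).
#' @return Object of class `event_ledger`.
#' @export
event_ledger <- function(path, events) {
  if (length(path) < 1) stop("empty lineage path")
  if (anyDuplicated(path)) stop("duplicated node on path")
  if (nrow(events) > 0) {
    stopifnot(all(c("node", "kind", "family") %in% names(events)))
    bad <- setdiff(events$node, path)
    if (length(bad) > 0)
      stop("event node(s) not on path: ", paste(unique(bad), collapse = ", "))
    if (!all(events$kind %in% c("gain", "loss")))
      stop("event kind must be 'gain' or 'loss'")
  }
  if (is.null(events$uncertain)) events$uncertain <- rep(FALSE, nrow(events))
  structure(list(path = path, events = events), class = "event_ledger")
}

#' @export
print.event_ledger <- function(x, ...) {
  cat(sprintf("event_ledger: %s -> %s (%d nodes, %d gains, %d losses)\n",
              x$path[1], x$path[length(x$path)], length(x$path),
              sum(x$events$kind == "gain"), sum(x$events$kind == "loss")))
  invisible(x)
}

#' Propagate a repertoire along an event ledger
#'
#' Applies the ledger's gains and losses in path order, starting from the
#' ancestral family set, and returns the repertoire at every node.
#' Inconsistent events (loss of an absent family, gain of a present one)
#' raise an error naming the node and family.
#'
#' @param start Character vector: ancestral family set.
#' @param ledger An `event_ledger`.
#' @return Named list, one sorted character vector of families per path
#'   node.
#' @export
propagate_ledger <- function(start, ledger) {
  cur <- sort(unique(start))
  out <- vector("list", length(ledger$path))
  names(out) <- ledger$path
  for (node in ledger$path) {
    ev <- ledger$events[ledger$events$node == node, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      fam <- ev$family[i]
      if (ev$kind[i] == "loss") {
        if (!(fam %in% cur))
          stop(sprintf("loss of absent family '%s' at node '%s'", fam, node))
        cur <- setdiff(cur, fam)
      } else {
        if (fam %in% cur)
          stop(sprintf("gain of already-present family '%s' at node '%s'",
                       fam, node))
        cur <- sort(c(cur, fam))
      }
    }
    out[[node]] <- cur
  }
  out
}

#' Count ancestral families lost by a given path node
#'
#' @param start Ancestral family set.
#' @param ledger An `event_ledger`.
#' @param node A node on the ledger path.
#' @return Integer: `|start| - |repertoire(node) intersect start|`.
#' @export
losses_on_path <- function(start, ledger, node) {
  if (!(node %in% ledger$path)) stop("node '", node, "' not on path")
  rep_at <- propagate_ledger(start, ledger)[[node]]
  length(start) - length(intersect(rep_at, start))
}

#' Read / write an event ledger as TSV
#'
#' Columns `node`, `kind`, `family`, `uncertain`; the path is stored as a
#' commented first line `# path: n1 > n2 > ...`.
#'
#' @param ledger An `event_ledger`.
#' @param path File path.
#' @return `read_ledger` returns the `event_ledger`.
#' @export
write_ledger <- function(ledger, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# path: ", paste(ledger$path, collapse = " > ")), con)
  utils::write.table(ledger$events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# path: ", lines[1])) stop("missing '# path:' header")
  nodes <- strsplit(sub("^# path: ", "", lines[1]), " > ", fixed = TRUE)[[1]]
  events <- utils::read.delim(text = paste(lines[-1], collapse = "\n"),
                              stringsAsFactors = FALSE)
  event_ledger(nodes, events)
}
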