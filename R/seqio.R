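#' Construct a table of sequence records
#'
#' Sequence records are plain data frames with one row per sequence and
#' columns `id`, `species`, `source_rank`, `version` and `residues`.
#' `source_rank` encodes database reliability (1 = RefSeq, 2 = Nr, 3 = EST,
#' 4 = other); it drives duplicate resolution in [dedupe_records()].
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param residues Character vector of uppercase amino-acid strings
#'   (letters of the 20-residue alphabet plus `X`; `-` only if
#'   `allow_gap = TRUE`).
#' @param species Species tags; recycled.
#' @param source_rank Integer reliability ranks in 1..4; recycled.
#' @param version Non-negative integer sequence versions; recycled.
#' @param allow_gap Permit `-` in `residues` (for alignment rows).
#' @return A `data.frame` with one row per record.
#' @export
#' @examples
#' seq_records(c("a", "b"), c("MKV", "MKL"))
seq_records <- function(id, residues, species = "unknown", source_rank = 4L,
                        version = 0L, allow_gap = FALSE) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues)) stop("id and residues lengths differ")
  if (any(!nzchar(id))) stop("empty record id")
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(gsub("-", "", residues, fixed = TRUE)))) {
    stop("empty sequence body for id(s): ",
         paste(id[!nzchar(gsub("-", "", residues, fixed = TRUE))], collapse = ", "))
  }
  check_residues(residues, allow_gap = allow_gap)
  df <- data.frame(
    id = id,
    species = rep_len(as.character(species), length(id)),
    source_rank = rep_len(as.integer(source_rank), length(id)),
    version = rep_len(as.integer(version), length(id)),
    residues = residues,
    stringsAsFactors = FALSE
  )
  if (any(df$source_rank < 1L | df$source_rank > 4L)) {
    stop("source_rank must be in 1..4")
  }
  if (any(df$version < 0L)) stop("version must be >= 0")
  df
}

#' Read sequences from a FASTA file
#'
#' Headers follow the dialect `>id species=... db=... version=...`; absent
#' tags default to species `"unknown"`, source rank 4 and version 0.  The
#' `db` tag maps to `source_rank`: refseq = 1, nr = 2, est = 3, anything
#' else = 4.
#'
#' @param path FASTA file path.
#' @param allow_gap Permit `-` in sequence bodies (aligned FASTA).
#' @return A record data frame (see [seq_records()]); rows in file order.
#' @export
read_fasta <- function(path, allow_gap = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(seq_records(character(), character(), allow_gap = allow_gap))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("malformed FASTA: first non-blank line is not a header")
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  bodies <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) paste(x, collapse = ""), character(1))
  n <- length(headers)
  seqs <- character(n)
  present <- names(bodies)
  seqs[as.integer(present)] <- bodies
  if (any(!nzchar(seqs))) {
    stop("empty sequence body for header(s): ",
         paste(headers[!nzchar(seqs)], collapse = ", "))
  }
  parse_header <- function(h) {
    parts <- strsplit(trimws(h), "\\s+")[[1]]
    id <- parts[1]
    tags <- parts[-1]
    kv <- regmatches(tags, regexec("^([a-zA-Z_]+)=(.*)$", tags))
    out <- list(species = "unknown", db = "", version = "0")
    for (m in kv) {
      if (length(m) == 3) out[[m[2]]] <- m[3]
    }
    rank <- switch(tolower(out$db), refseq = 1L, nr = 2L, est = 3L, 4L)
    list(id = id, species = out$species, source_rank = rank,
         version = suppressWarnings(as.integer(out$version)))
  }
  meta <- lapply(headers, parse_header)
  versions <- vapply(meta, `[[`, integer(1), "version")
  versions[is.na(versions)] <- 0L
  seq_records(
    id = vapply(meta, `[[`, character(1), "id"),
    residues = toupper(gsub(".", "-", seqs, fixed = TRUE)),
    species = vapply(meta, `[[`, character(1), "species"),
    source_rank = vapply(meta, `[[`, integer(1), "source_rank"),
    version = versions,
    allow_gap = allow_gap
  )
}

#' Write sequence records to FASTA
#'
#' Headers carry the `species=`, `db=` and `version=` tags understood by
#' [read_fasta()]; bodies are wrapped at 60 columns.
#'
#' @param records A record data frame.
#' @param path Output file path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  db <- c("refseq", "nr", "est", "other")[records$source_rank]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(sprintf(">%s species=%s db=%s version=%d",
                       records$id[i], records$species[i], db[i],
                       records$version[i]), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct an alignment from gapped records
#'
#' An alignment is a list of class `aa_alignment` holding a character matrix
#' `seq` (rows = sequences, columns = alignment positions, single-character
#' entries) and the record metadata `meta`.  All rows must have equal length
#' and degap to valid sequences.
#'
#' @param records Record data frame with gapped residues (gap `-`).
#' @return An `aa_alignment` object.
#' @export
as_alignment <- function(records) {
  lens <- nchar(records$residues)
  if (nrow(records) == 0) stop("alignment needs at least one sequence")
  if (length(unique(lens)) != 1) stop("gapped rows differ in length")
  if (lens[1] < 1) stop("alignment needs at least one column")
  check_residues(records$residues, allow_gap = TRUE, what = "alignment")
  mat <- do.call(rbind, strsplit(records$residues, "", fixed = TRUE))
  rownames(mat) <- records$id
  structure(list(seq = mat, meta = records[, c("id", "species", "source_rank",
                                               "version")]),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d columns\n",
              nrow(x$seq), ncol(x$seq)))
  invisible(x)
}

#' Number of columns / sequences of an alignment
#' @param aln An `aa_alignment`.
#' @return Integer.
#' @export
n_columns <- function(aln) ncol(aln$seq)

#' @rdname n_columns
#' @export
n_sequences <- function(aln) nrow(aln$seq)

#' Degap alignment rows back to sequence records
#' @param aln An `aa_alignment`.
#' @return Record data frame of ungapped sequences.
#' @export
alignment_records <- function(aln) {
  res <- apply(aln$seq, 1, function(r) paste(r[r != "-"], collapse = ""))
  out <- aln$meta
  out$residues <- unname(res)
  out
}

#' Trim gappy columns, then gappy sequences, from an alignment
#'
#' Removes every column whose gap fraction strictly exceeds `max_col_gap`,
#' then every sequence whose gap fraction over the remaining columns
#' strictly exceeds `max_seq_gap`.  One pass, in that order; the operation
#' is idempotent.
#'
#' @param aln An `aa_alignment`.
#' @param max_col_gap Maximum tolerated per-column gap fraction (default 0.25).
#' @param max_seq_gap Maximum tolerated per-sequence gap fraction (default 0.25).
#' @return The trimmed `aa_alignment`.
#' @export
trim_alignment <- function(aln, max_col_gap = 0.25, max_seq_gap = 0.25) {
  gap <- aln$seq == "-"
  keep_col <- colMeans(gap) <= max_col_gap
  if (!any(keep_col)) stop("alignment emptied by trimming")
  sub <- aln$seq[, keep_col, drop = FALSE]
  keep_row <- rowMeans(sub == "-") <= max_seq_gap
  if (!any(keep_row)) stop("alignment emptied by trimming")
  structure(list(seq = sub[keep_row, , drop = FALSE],
                 meta = aln$meta[keep_row, , drop = FALSE]),
            class = "aa_alignment")
}

#' Resolve duplicate sequence records
#'
#' Within each duplicate set the survivor is the record with the lowest
#' `source_rank` (most reliable database); among equal ranks the highest
#' `version`; among equal versions the first seen.  Input order of
#' survivors is preserved.
#'
#' @param records Record data frame.
#' @param key `"residues"` (identical sequence strings are duplicates) or
#'   `"id"` (shared ids are duplicates).
#' @return Deduplicated record data frame.
#' @export
dedupe_records <- function(records, key = c("residues", "id")) {
  key <- match.arg(key)
  if (nrow(records) == 0) return(records)
  k <- records[[key]]
  keep <- logical(nrow(records))
  for (v in unique(k)) {
    idx <- which(k == v)
    ord <- idx[order(records$source_rank[idx], -records$version[idx],
                     seq_along(idx))]
    keep[ord[1]] <- TRUE
  }
  records[keep, , drop = FALSE]
}

#' Write an alignment to aligned FASTA
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  recs <- aln$meta
  recs$residues <- apply(aln$seq, 1, paste, collapse = "")
  write_fasta(recs, path)
}

#' Read an alignment from aligned FASTA
#' @param path Input path.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path) {
  as_alignment(read_fasta(path, allow_gap = TRUE))
}
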