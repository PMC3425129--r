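#' Strict and soft confidence cut-offs from score distributions
#'
#' Both cut-offs live in `-log10(E)` space (larger = better).  The strict
#' cut-off is the 5th percentile of the member score distribution; the soft
#' cut-off is the 95th percentile of the decoy (non-member) score
#' distribution, floored at 0, or 0 when no decoy ever hits the model.
#' Percentiles use linear interpolation between order statistics
#' (zero-based index `h = p * (n - 1)`, i.e. R's quantile type 7).
#'
#' @param member_scores Numeric vector of member `-log10(E)` scores
#'   (at least 5).
#' @param decoy_scores Numeric vector of decoy `-log10(E)` scores; may be
#'   empty.
#' @return Named numeric vector `c(strict = , soft = )`, with attribute
#'   `reliable` set to `FALSE` when `soft > strict`.
#' @export
#' @examples
#' calibrate_cutoffs(3:12, numeric(0))  # strict 3.45, soft 0
calibrate_cutoffs <- function(member_scores, decoy_scores = numeric(0)) {
  if (length(member_scores) < 5) stop("insufficient members for calibration")
  strict <- unname(stats::quantile(member_scores, 0.05, type = 7))
  soft <- if (length(decoy_scores) == 0) 0 else
    max(0, unname(stats::quantile(decoy_scores, 0.95, type = 7)))
  out <- c(strict = strict, soft = soft)
  attr(out, "reliable") <- soft <= strict
  out
}

#' Bundle a calibrated profile HMM into a subfamily model
#'
#' @param hmm A calibrated `profile_hmm`.
#' @param strict_cutoff,soft_cutoff Cut-offs in `-log10(E)` units.
#' @param members Character vector of member sequence ids (non-empty).
#' @param kingdoms Character vector of kingdom tags covered by the members.
#' @return An object of class `subfamily_model`.  Models with
#'   `soft_cutoff > strict_cutoff` are flagged `reliable = FALSE` but remain
#'   usable.
#' @export
subfamily_model <- function(hmm, strict_cutoff, soft_cutoff, members,
                            kingdoms = character(0)) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (length(members) == 0) stop("subfamily model needs members")
  structure(list(name = hmm$name, hmm = hmm,
                 strict_cutoff = strict_cutoff, soft_cutoff = soft_cutoff,
                 members = members, kingdoms = unique(kingdoms),
                 reliable = soft_cutoff <= strict_cutoff),
            class = "subfamily_model")
}

#' @export
print.subfamily_model <- function(x, ...) {
  cat(sprintf("subfamily_model '%s': %d members, strict %.2f / soft %.2f [-log10 E]%s\n",
              x$name, length(x$members), x$strict_cutoff, x$soft_cutoff,
              if (x$reliable) "" else " (flagged unreliable)"))
  invisible(x)
}

#' Fit a library of subfamily models from seed alignments
#'
#' For each seed alignment this builds a profile HMM, calibrates its
#' E-value tail against random background sequences, scores the seed
#' members (their ungapped sequences) to obtain the strict cut-off and the
#' decoys to obtain the soft cut-off.
#'
#' @param seeds Named list of `aa_alignment` seed alignments (>= 5
#'   sequences each).
#' @param decoys Optional record data frame of decoy (non-family)
#'   sequences.
#' @param alpha,background Passed to [profile_hmm()].
#' @param n_calib Calibration sequences per model.
#' @param db_size Effective database size for E-values.
#' @param seed Integer RNG seed.
#' @param kingdom_of Optional function mapping a species tag to a kingdom
#'   tag (defaults to using the species tag itself).
#' @return An object of class `subfamily_library`: a list of
#'   `subfamily_model` objects plus fitting metadata.
#' @export
fit_subfamily_library <- function(seeds, decoys = NULL, alpha = 1,
                                  background = aa_background(),
                                  n_calib = 200, db_size = 1e5, seed = 1,
                                  kingdom_of = identity) {
  if (length(seeds) == 0) stop("no seed alignments")
  if (is.null(names(seeds)) || any(!nzchar(names(seeds))))
    stop("seed alignments must be named")
  decoy_codes <- if (!is.null(decoys) && nrow(decoys) > 0)
    lapply(decoys$residues, encode_residues) else list()

  models <- vector("list", length(seeds))
  names(models) <- names(seeds)
  for (nm in names(seeds)) {
    aln <- seeds[[nm]]
    if (nrow(aln$seq) < 5) stop("seed '", nm, "' has fewer than 5 sequences")
    hmm <- profile_hmm(aln, alpha = alpha, background = background, name = nm)
    hmm <- calibrate_evalue(hmm, n_random = n_calib,
                            seed = derive_seed(seed, match(nm, names(seeds)), 0L),
                            db_size = db_size)
    member_recs <- alignment_records(aln)
    member_scores <- viterbi_scores(hmm, lapply(member_recs$residues, encode_residues))
    member_nl10 <- -log10(evalue(hmm, member_scores))
    decoy_nl10 <- if (length(decoy_codes) > 0)
      -log10(evalue(hmm, viterbi_scores(hmm, decoy_codes))) else numeric(0)
    cut <- calibrate_cutoffs(member_nl10, decoy_nl10)
    models[[nm]] <- subfamily_model(hmm, cut[["strict"]], cut[["soft"]],
                                    members = member_recs$id,
                                    kingdoms = unique(kingdom_of(member_recs$species)))
  }
  structure(list(models = models, db_size = db_size, alpha = alpha,
                 n_calib = n_calib, seed = seed),
            class = "subfamily_library")
}

#' @export
print.subfamily_library <- function(x, ...) {
  cat(sprintf("subfamily_library: %d models (db_size = %g)\n",
              length(x$models), x$db_size))
  for (m in x$models) print(m)
  invisible(x)
}

#' Classify one sequence against a model library
#'
#' The winning model minimises the E-value; exact ties are broken by higher
#' bit score, then lexicographic model name (the tie-break actually used is
#' recorded).  The confidence label compares `-log10(E)` with the winning
#' model's cut-offs: `confident` at or above strict, `possible` at or above
#' soft, otherwise `none`.
#'
#' @param seq A single-row record data frame or residue string.
#' @param library A `subfamily_library` (or plain list of
#'   `subfamily_model`).
#' @return One-row data frame: `query_id`, `model`, `score_bits`, `evalue`,
#'   `neglog10e`, `label`, `span_start`, `span_end`, `tie_break_used`.
#' @export
classify_sequence <- function(seq, library) {
  hits <- classify_batch(if (is.data.frame(seq)) seq else
    seq_records("query", seq), library)
  hits$hits
}

library_models <- function(library) {
  if (inherits(library, "subfamily_library")) library$models
  else if (is.list(library) && length(library) > 0 &&
           all(vapply(library, inherits, logical(1), "subfamily_model"))) library
  else stop("empty or invalid model library")
}

#' Classify a batch of sequences
#'
#' Vectorised [classify_sequence()]; output row order equals input order.
#'
#' @param seqs Record data frame of queries.
#' @param library A `subfamily_library`.
#' @return List with `hits` (one row per query) and `top4` (per-query
#'   best-four models by ascending E-value).
#' @export
classify_batch <- function(seqs, library) {
  models <- library_models(library)
  if (length(models) == 0) stop("empty model library")
  n <- nrow(seqs)
  codes <- lapply(seqs$residues, encode_residues)
  k <- length(models)
  bits <- matrix(NA_real_, n, k, dimnames = list(seqs$id, names(models)))
  ev <- bits
  for (j in seq_len(k)) {
    b <- viterbi_scores(models[[j]]$hmm, codes)
    bits[, j] <- b
    ev[, j] <- evalue(models[[j]]$hmm, b)
  }
  spans <- matrix(NA_integer_, n, 2)
  rows <- vector("list", n)
  top4 <- vector("list", n)
  for (i in seq_len(n)) {
    e <- ev[i, ]
    best <- which(e == min(e))
    tie <- "none"
    if (length(best) > 1) {
      b2 <- best[bits[i, best] == max(bits[i, best])]
      tie <- "bits"
      if (length(b2) > 1) {
        b2 <- b2[order(names(models)[b2])][1]
        tie <- "name"
      }
      best <- b2[1]
    }
    mod <- models[[best]]
    sv <- score_viterbi(mod$hmm, seqs$residues[i])
    nl10 <- -log10(e[best])
    label <- if (nl10 >= mod$strict_cutoff) "confident"
      else if (nl10 >= mod$soft_cutoff && nl10 >= 0) "possible"
      else "none"
    rows[[i]] <- data.frame(
      query_id = seqs$id[i], model = mod$name,
      score_bits = bits[i, best], evalue = unname(e[best]),
      neglog10e = unname(nl10), label = label,
      span_start = sv$span[1], span_end = sv$span[2],
      tie_break_used = tie, stringsAsFactors = FALSE)
    ord <- order(e, -bits[i, ], names(models))[seq_len(min(4, k))]
    top4[[i]] <- data.frame(query_id = seqs$id[i], rank = seq_along(ord),
                            model = names(models)[ord],
                            evalue = unname(e[ord]),
                            score_bits = unname(bits[i, ord]),
                            stringsAsFactors = FALSE)
  }
  list(hits = do.call(rbind, rows), top4 = do.call(rbind, top4))
}

#' Classify sequences with a fitted subfamily library
#'
#' @param object A `subfamily_library`.
#' @param newdata Record data frame of query sequences.
#' @param ... Unused.
#' @return As [classify_batch()].
#' @export
predict.subfamily_library <- function(object, newdata, ...) {
  classify_batch(newdata, object)
}

#' Flag classification hits needing human review
#'
#' Automated stand-in for manual inspection: flags `fragment` when the
#' matched span covers less than `min_span_fraction` of the winning model's
#' length, `no fit` for label `none`, and `ambiguous` when a second model
#' scores within 2 `-log10(E)` units of the winner.
#'
#' @param batch Result of [classify_batch()] / `predict()`.
#' @param library The library used to produce `batch`.
#' @param min_span_fraction Minimum span fraction (default 0.6).
#' @return Data frame `query_id`, `flag`, `detail`; zero rows if nothing is
#'   flagged.
#' @export
verify_hits <- function(batch, library, min_span_fraction = 0.6) {
  models <- library_models(library)
  hits <- batch$hits
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    mod <- models[[h$model]]
    span_len <- h$span_end - h$span_start
    if (span_len < min_span_fraction * mod$hmm$L) {
      out[[length(out) + 1]] <- data.frame(
        query_id = h$query_id, flag = "fragment",
        detail = sprintf("span %d of model length %d", span_len, mod$hmm$L),
        stringsAsFactors = FALSE)
    }
    if (h$label == "none") {
      out[[length(out) + 1]] <- data.frame(
        query_id = h$query_id, flag = "no fit",
        detail = sprintf("-log10(E) = %.2f below soft cut-off", h$neglog10e),
        stringsAsFactors = FALSE)
    }
    t4 <- batch$top4[batch$top4$query_id == h$query_id, ]
    if (nrow(t4) >= 2) {
      d <- -log10(t4$evalue[1]) - (-log10(t4$evalue[2]))
      if (is.finite(d) && d < 2) {
        out[[length(out) + 1]] <- data.frame(
          query_id = h$query_id, flag = "ambiguous",
          detail = sprintf("models %s and %s within %.2f -log10E units",
                           t4$model[1], t4$model[2], d),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    data.frame(query_id = character(0), flag = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Assign a parent group to an ambiguous subfamily by best-hit voting
#'
#' Each group member is aligned (affine-gap local alignment, BLOSUM62,
#' gap open 11 / extend 1) against all candidate sequences from the same
#' species; the label of its best-scoring hit is one vote.  The parent is
#' the label with strictly the most votes; an exact tie returns
#' `"unresolved"`.  Members whose species has no pool sequences abstain.
#'
#' @param group Record data frame of the subfamily to place.
#' @param per_species_pool Named list: species tag -> data frame with
#'   columns `residues` (sequence) and `group` (candidate label).
#' @param gap_open,gap_ext Affine gap penalties.
#' @return Character scalar: winning label or `"unresolved"`, with a
#'   `votes` attribute (named vote counts).
#' @export
assign_parent <- function(group, per_species_pool, gap_open = 11, gap_ext = 1) {
  if (nrow(group) == 0) stop("empty group")
  votes <- character(0)
  for (i in seq_len(nrow(group))) {
    pool <- per_species_pool[[group$species[i]]]
    if (is.null(pool) || nrow(pool) == 0) next  # abstain
    sc <- vapply(pool$residues, function(s)
      local_align_score(group$residues[i], s, gap_open, gap_ext), numeric(1))
    votes <- c(votes, pool$group[which.max(sc)])
  }
  if (length(votes) == 0) return(structure("unresolved", votes = table(character(0))))
  tab <- sort(table(votes), decreasing = TRUE)
  winner <- if (length(tab) > 1 && tab[1] == tab[2]) "unresolved" else names(tab)[1]
  structure(winner, votes = tab)
}

#' Affine-gap local alignment score (BLOSUM62)
#'
#' Smith-Waterman with affine gap penalties over the BLOSUM62 table
#' (`X` scores -1 against everything).
#'
#' @param a,b Residue strings.
#' @param gap_open,gap_ext Positive penalties (default 11 / 1).
#' @return Alignment score (>= 0).
#' @export
local_align_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  sub <- blosum62_matrix()
  cpp_sw_score(encode_residues(toupper(a)), encode_residues(toupper(b)),
               sub, gap_open, gap_ext)
}

#' Write a classification hit table as TSV
#' @param batch Result of [classify_batch()].
#' @param path Output path.
#' @export
write_hits <- function(batch, path) {
  utils::write.table(batch$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a subfamily library as JSON
#' @param library A `subfamily_library`.
#' @param path File path.
#' @return `read_library` returns the restored library.
#' @export
write_library <- function(library, path) {
  doc <- list(schema = "rabrep-library-1", db_size = library$db_size,
              alpha = library$alpha, n_calib = library$n_calib,
              seed = library$seed,
              models = lapply(library$models, function(m) {
                list(name = m$name, strict_cutoff = m$strict_cutoff,
                     soft_cutoff = m$soft_cutoff, members = m$members,
                     kingdoms = m$kingdoms,
                     hmm = list(name = m$hmm$name, L = m$hmm$L,
                                match_emissions = m$hmm$match_emissions,
                                insert_emissions = as.numeric(m$hmm$insert_emissions),
                                transitions = m$hmm$transitions,
                                background = as.numeric(m$hmm$background),
                                n_seed = m$hmm$n_seed,
                                calibration = m$hmm$calibration))
              }))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "rabrep-library-1")) stop("unrecognized library schema")
  models <- lapply(doc$models, function(m) {
    h <- m$hmm
    calib <- h$calibration
    if (!is.null(calib) && !is.null(calib$mu)) {
      calib <- list(mu = calib$mu, lam = calib$lam,
                    n_calibration = as.integer(calib$n_calibration),
                    db_size = calib$db_size)
    } else calib <- NULL
    hmm <- structure(list(
      name = h$name, L = as.integer(h$L),
      match_emissions = matrix(unlist(h$match_emissions), nrow = h$L,
                               dimnames = list(NULL, AA_ALPHABET)),
      insert_emissions = stats::setNames(h$insert_emissions, AA_ALPHABET),
      transitions = matrix(unlist(h$transitions), nrow = h$L,
                           dimnames = list(NULL, c("MM", "MI", "MD", "IM",
                                                   "II", "DM", "DD"))),
      background = stats::setNames(h$background, AA_ALPHABET),
      calibration = calib, n_seed = h$n_seed), class = "profile_hmm")
    subfamily_model(hmm, m$strict_cutoff, m$soft_cutoff, unlist(m$members),
                    unlist(m$kingdoms))
  })
  names(models) <- vapply(models, function(m) m$name, character(1))
  structure(list(models = models, db_size = doc$db_size, alpha = doc$alpha,
                 n_calib = doc$n_calib, seed = doc$seed),
            class = "subfamily_library")
}

# deterministic seed derivation: one stream per (context, index) pair,
# kept below 2^31
derive_seed <- function(seed, i, j) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i) +
                104729 * as.numeric(j)) %% 2147483647)
}
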