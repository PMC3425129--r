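#' Fit a profile hidden Markov model to a seed alignment
#'
#' Every column of the (pre-trimmed) seed alignment becomes a match state.
#' Match emissions are background-smoothed observed frequencies,
#' `e_j(a) = (c_j(a) + alpha * q(a)) / (n_j + alpha)`, where `c_j` are the
#' observed residue counts in column `j`, `n_j` the number of non-gap
#' residues and `q` the background.  Transition probabilities come from the
#' observed match/delete paths through the seed with a +1 pseudocount on
#' every allowed transition; insert states share the background emission.
#' Scoring is local: uniform entry into any match state, free exit.
#'
#' @param seed An [`aa_alignment`][as_alignment] (trim first with
#'   [trim_alignment()] so columns carry at most 25% gaps).
#' @param alpha Pseudocount mass (>= 0, default 1).  `alpha = 0` keeps raw
#'   frequencies and warns if any column has unobserved residues.
#' @param background 20-entry background probability vector
#'   (default [aa_background()]).
#' @param name Model name.
#' @param weights Optional per-sequence weights; `"uniform"` (default) or
#'   `"henikoff"` for Henikoff position-based weights.
#' @return An object of class `profile_hmm` with components `name`, `L`,
#'   `match_emissions` (L x 20), `insert_emissions`, `transitions` (L x 7,
#'   columns MM MI MD IM II DM DD), `background` and `calibration`
#'   (`NULL` until [calibrate_evalue()] is run).
#' @seealso [score_viterbi()], [score_forward()], [calibrate_evalue()]
#' @export
#' @examples
#' aln <- as_alignment(seq_records(c("s1", "s2"), c("MKV", "MKV")))
#' hmm <- profile_hmm(aln, alpha = 1)
#' hmm$L
profile_hmm <- function(seed, alpha = 1, background = aa_background(),
                        name = "model", weights = c("uniform", "henikoff")) {
  stopifnot(inherits(seed, "aa_alignment"))
  weights <- match.arg(weights)
  if (alpha < 0) stop("alpha must be >= 0")
  L <- ncol(seed$seq)
  if (L < 1) stop("seed alignment has zero columns")
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-6)
  background <- stats::setNames(as.numeric(background), AA_ALPHABET)

  n_seq <- nrow(seed$seq)
  w <- if (weights == "henikoff") henikoff_weights(seed$seq) else
    rep(1 / n_seq, n_seq)
  w <- w * n_seq  # keep total count mass comparable to sequence count

  emis <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  unobserved <- FALSE
  for (j in seq_len(L)) {
    col <- seed$seq[, j]
    ok <- col %in% AA_ALPHABET
    cnt <- vapply(AA_ALPHABET, function(a) sum(w[ok][col[ok] == a]), numeric(1))
    nj <- sum(cnt)
    if (nj + alpha <= 0) stop("column ", j, " has no observed residues and alpha = 0")
    emis[j, ] <- (cnt + alpha * background) / (nj + alpha)
    if (alpha == 0 && any(emis[j, ] == 0)) unobserved <- TRUE
  }
  if (unobserved) {
    warning("alpha = 0 with unobserved residues: some match emissions are zero")
  }

  # transition counts over the match/delete path implied by the gap pattern
  tr <- matrix(NA_real_, L, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  if (L > 1) {
    isgap <- seed$seq == "-"
    for (j in seq_len(L - 1)) {
      a <- isgap[, j]; b <- isgap[, j + 1]
      nMM <- sum(w[!a & !b]); nMD <- sum(w[!a & b])
      nDM <- sum(w[a & !b]);  nDD <- sum(w[a & b])
      tr[j, "MM"] <- (nMM + 1) / (nMM + nMD + 0 + 3)
      tr[j, "MI"] <- 1 / (nMM + nMD + 0 + 3)
      tr[j, "MD"] <- (nMD + 1) / (nMM + nMD + 0 + 3)
      tr[j, "IM"] <- 0.5
      tr[j, "II"] <- 0.5
      tr[j, "DM"] <- (nDM + 1) / (nDM + nDD + 2)
      tr[j, "DD"] <- (nDD + 1) / (nDM + nDD + 2)
    }
  }

  structure(list(name = name, L = L, match_emissions = emis,
                 insert_emissions = background, transitions = tr,
                 background = background, calibration = NULL,
                 n_seed = n_seq),
            class = "profile_hmm")
}

henikoff_weights <- function(mat) {
  # Henikoff & Henikoff position-based weights over non-gap residues
  w <- rep(0, nrow(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    ok <- col != "-"
    if (!any(ok)) next
    tab <- table(col[ok])
    r <- length(tab)
    w[ok] <- w[ok] + 1 / (r * as.numeric(tab[col[ok]]))
  }
  if (sum(w) == 0) return(rep(1 / nrow(mat), nrow(mat)))
  w / sum(w)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': %d match states, %d seed sequences\n",
              x$name, x$L, x$n_seed))
  if (!is.null(x$calibration)) {
    cat(sprintf("  Gumbel calibration: mu = %.3f bits, lambda = %.3f (n = %d, db = %g)\n",
                x$calibration$mu, x$calibration$lam,
                x$calibration$n_calibration, x$calibration$db_size))
  }
  invisible(x)
}

#' @export
summary.profile_hmm <- function(object, ...) {
  ic <- apply(object$match_emissions, 1, function(e) {
    q <- object$background
    sum(ifelse(e > 0, e * log2(e / q), 0))
  })
  out <- list(name = object$name, L = object$L,
              information_bits = sum(ic), mean_column_bits = mean(ic),
              calibrated = !is.null(object$calibration))
  class(out) <- "summary.profile_hmm"
  out
}

#' @export
print.summary.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': L = %d, total relative entropy %.1f bits (%.2f bits/column), %s\n",
              x$name, x$L, x$information_bits, x$mean_column_bits,
              if (x$calibrated) "calibrated" else "uncalibrated"))
  invisible(x)
}

#' @export
coef.profile_hmm <- function(object, ...) {
  list(match_emissions = object$match_emissions,
       insert_emissions = object$insert_emissions,
       transitions = object$transitions)
}

validate_phmm <- function(hmm, tol = 1e-9) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (any(abs(rowSums(hmm$match_emissions) - 1) > tol))
    stop("match emission rows do not sum to 1")
  if (abs(sum(hmm$insert_emissions) - 1) > tol)
    stop("insert emissions do not sum to 1")
  if (any(hmm$match_emissions < 0) || any(hmm$insert_emissions < 0))
    stop("negative emission probability")
  if (hmm$L > 1) {
    tr <- hmm$transitions[-hmm$L, , drop = FALSE]
    if (any(abs(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]) - 1) > tol) ||
        any(abs(rowSums(tr[, c("IM", "II"), drop = FALSE]) - 1) > tol) ||
        any(abs(rowSums(tr[, c("DM", "DD"), drop = FALSE]) - 1) > tol))
      stop("transition triplets do not sum to 1")
    if (any(tr < 0)) stop("negative transition probability")
  }
  invisible(TRUE)
}

# log2-odds tables for the C++ kernels
phmm_tables <- function(hmm) {
  lodds <- log2(hmm$match_emissions) -
    matrix(log2(hmm$background), hmm$L, 20, byrow = TRUE)
  lodds[!is.finite(lodds)] <- -1e30
  mlodds <- cbind(lodds, X = 0)
  tr <- hmm$transitions
  trl <- log2(tr)
  trl[!is.finite(trl)] <- -1e30
  if (hmm$L == 1) trl <- matrix(-1e30, 1, 7)
  list(mlodds = mlodds, tr = trl)
}

residue_codes <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$residues
  if (length(seq) != 1) stop("expected a single sequence")
  if (nchar(seq) == 0) stop("empty sequence")
  encode_residues(gsub("-", "", toupper(seq), fixed = TRUE))
}

#' Score a sequence against a profile HMM (Viterbi)
#'
#' Best local alignment log2-odds score against the i.i.d. background null.
#'
#' @param hmm A `profile_hmm`.
#' @param seq A single-row record data frame, or a plain residue string.
#' @return A list with `bits` (score), `span` (0-based half-open query
#'   interval aligned to the model), `model_span` (1-based inclusive match
#'   positions) and `path` (state string over `M`, `I`, `D`).
#' @export
score_viterbi <- function(hmm, seq) {
  tab <- phmm_tables(hmm)
  res <- cpp_viterbi(tab$mlodds, tab$tr, residue_codes(seq))
  list(bits = res$score, span = res$span, model_span = res$model_span,
       path = res$path)
}

#' Score a sequence against a profile HMM (Forward)
#'
#' log2 of the summed likelihood ratio over all local alignments; always at
#' least the Viterbi score.
#'
#' @inheritParams score_viterbi
#' @return Score in bits.
#' @export
score_forward <- function(hmm, seq) {
  tab <- phmm_tables(hmm)
  cpp_forward(tab$mlodds, tab$tr, residue_codes(seq))
}

# fast path used by classify/validate: scores for many encoded sequences
viterbi_scores <- function(hmm, codes_list) {
  tab <- phmm_tables(hmm)
  cpp_viterbi_batch(tab$mlodds, tab$tr, codes_list)
}

#' Calibrate the E-value tail of a profile HMM
#'
#' Scores `n_random` i.i.d. background sequences with Viterbi and fits a
#' Gumbel distribution to the scores by the method of moments
#' (`lambda = pi / (sd * sqrt(6))`, `mu = mean - 0.5772157 / lambda`).
#' E-values are then reported for a database of `db_size` sequences.
#'
#' @param hmm A `profile_hmm`.
#' @param n_random Number of calibration sequences (>= 50).
#' @param seed Integer RNG seed.
#' @param db_size Effective database size for E-values (default 100000).
#' @param length_model Function `n -> integer vector` of sequence lengths;
#'   defaults to lengths uniform between `L` and `2 L`.
#' @return The `profile_hmm` with a `calibration` list (`mu`, `lam`,
#'   `n_calibration`, `db_size`) attached.
#' @export
calibrate_evalue <- function(hmm, n_random = 200, seed = 1, db_size = 1e5,
                             length_model = NULL) {
  if (n_random < 50) stop("n_random must be >= 50")
  if (is.null(length_model)) {
    length_model <- function(n) sample(hmm$L:(2L * hmm$L), n, replace = TRUE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lens <- length_model(n_random)
  codes <- lapply(lens, function(l) {
    sample.int(20L, l, replace = TRUE, prob = hmm$background) - 1L
  })
  scores <- viterbi_scores(hmm, codes)
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) stop("degenerate calibration: zero score variance")
  lam <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649015329 / lam
  hmm$calibration <- list(mu = mu, lam = lam,
                          n_calibration = as.integer(n_random),
                          db_size = db_size)
  hmm
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' E-value of a bit score under a Gumbel calibration
#'
#' `E = db_size * min(1, exp(-lambda * (score - mu)))`; monotonically
#' decreasing in the score.
#'
#' @param fit A calibration list (`mu`, `lam`, `db_size`) as attached by
#'   [calibrate_evalue()], or a calibrated `profile_hmm`.
#' @param score Bit score(s).
#' @return E-value(s): expected number of random hits scoring at least
#'   this well in a database of `db_size` sequences.
#' @export
evalue <- function(fit, score) {
  if (inherits(fit, "profile_hmm")) fit <- fit$calibration
  if (is.null(fit)) stop("model is not calibrated")
  fit$db_size * pmin(1, exp(-fit$lam * (score - fit$mu)))
}

#' Simulate sequences from a profile HMM
#'
#' Draws `nsim` sequences by walking the model from a uniformly chosen
#' entry match state, sampling emissions and transitions.  Useful for
#' generating positive controls for classifier tests.
#'
#' @param object A `profile_hmm`.
#' @param nsim Number of sequences.
#' @param seed Integer RNG seed (required for reproducibility).
#' @param ... Unused.
#' @return Record data frame of simulated sequences.
#' @export
simulate.profile_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- character(nsim)
  for (k in seq_len(nsim)) {
    j <- 1L
    res <- character(0)
    while (j <= object$L) {
      res <- c(res, sample(AA_ALPHABET, 1, prob = object$match_emissions[j, ]))
      if (j == object$L) break
      p <- object$transitions[j, c("MM", "MI", "MD")]
      nxt <- sample(c("M", "I", "D"), 1, prob = p)
      if (nxt == "I") {
        repeat {
          res <- c(res, sample(AA_ALPHABET, 1, prob = object$insert_emissions))
          if (stats::runif(1) < object$transitions[j, "IM"]) break
        }
      }
      j <- j + 1L
    }
    out[k] <- paste(res, collapse = "")
  }
  seq_records(sprintf("%s_sim%03d", object$name, seq_len(nsim)), out,
              species = "simulated")
}

#' Serialize / restore a profile HMM as JSON
#'
#' Lossless round-trip of all tables and the calibration.
#'
#' @param hmm A `profile_hmm`.
#' @param path File path.
#' @return `read_phmm` returns the restored `profile_hmm`.
#' @export
write_phmm <- function(hmm, path) {
  doc <- list(schema = "rabrep-phmm-1", name = hmm$name, L = hmm$L,
              match_emissions = hmm$match_emissions,
              insert_emissions = as.numeric(hmm$insert_emissions),
              transitions = hmm$transitions,
              background = as.numeric(hmm$background),
              n_seed = hmm$n_seed,
              calibration = hmm$calibration)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_phmm
#' @export
read_phmm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "rabrep-phmm-1")) stop("unrecognized model schema")
  emis <- matrix(unlist(doc$match_emissions), nrow = doc$L,
                 dimnames = list(NULL, AA_ALPHABET))
  tr <- matrix(unlist(doc$transitions), nrow = doc$L,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  calib <- doc$calibration
  if (!is.null(calib)) {
    calib <- list(mu = calib$mu, lam = calib$lam,
                  n_calibration = as.integer(calib$n_calibration),
                  db_size = calib$db_size)
  }
  structure(list(name = doc$name, L = as.integer(doc$L),
                 match_emissions = emis,
                 insert_emissions = stats::setNames(doc$insert_emissions, AA_ALPHABET),
                 transitions = tr,
                 background = stats::setNames(doc$background, AA_ALPHABET),
                 calibration = calib, n_seed = doc$n_seed),
            class = "profile_hmm")
}
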