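#' Resampling estimate of per-model sensitivity and positive predictive rate
#'
#' Mirrors the classical resampling protocol for profile-HMM classifiers:
#' per replicate, `ceiling(frac * n)` members of each family are sampled
#' without replacement (minimum 4), a model is rebuilt from the resampled
#' seed, and every evaluation sequence is assigned to the model with the
#' best E-value (E-values normalised to a database of `db_size` sequences;
#' no physical decoys are generated).  Sensitivity of a family is the
#' fraction of its held-out members assigned back to it; the positive
#' predictive rate (PPR) is the fraction of sequences assigned to a model
#' that truly belong to it.
#'
#' With the default `eval_scope = "heldout_plus_others"` the held-out
#' members of every family are always evaluated, and a training sequence
#' only enters the counts when it is misassigned to a foreign model (so
#' trivially-correct training self-hits never inflate the estimates).
#' `eval_scope = "all"` counts every sequence.
#'
#' Gumbel calibrations are fitted once per family from the full-member
#' model and reused for the rebuilt models (`calibrate_each_rep = TRUE`
#' refits per replicate).  Sampling uses one derived RNG substream per
#' (replicate, family), so results do not depend on family iteration
#' order.
#'
#' @param families Named list of `aa_alignment` seed alignments, one per
#'   family; families with fewer than `min_members` sequences are excluded
#'   with a warning and listed in the report.
#' @param frac Training fraction per replicate (default 0.9).
#' @param reps Number of replicates (default 1000; scale down for quick
#'   checks).
#' @param db_size Effective database size for E-values (default 100000).
#' @param seed Integer RNG seed.
#' @param alpha,background,n_calib Passed to model building/calibration.
#' @param eval_scope `"heldout_plus_others"` or `"all"`.
#' @param calibrate_each_rep Refit the Gumbel tail for every rebuilt model.
#' @param min_members Minimum family size (default 5).
#' @return An object of class `validation_report`: data frame `per_model`
#'   (`model`, `sensitivity`, `ppr`, `n_members`), pooled `confusion`
#'   matrix (true family x assigned family, counts summed over
#'   replicates), `reps`, `seed`, `db_size`, `excluded`.
#' @export
resample_validate <- function(families, frac = 0.9, reps = 1000,
                              db_size = 1e5, seed = 1, alpha = 1,
                              background = aa_background(), n_calib = 150,
                              eval_scope = c("heldout_plus_others", "all"),
                              calibrate_each_rep = FALSE, min_members = 5) {
  eval_scope <- match.arg(eval_scope)
  if (reps < 1) stop("reps must be >= 1")
  sizes <- vapply(families, function(a) nrow(a$seq), integer(1))
  excluded <- names(families)[sizes < min_members]
  if (length(excluded) > 0) {
    warning("excluding families below minimum size: ",
            paste(excluded, collapse = ", "))
  }
  families <- families[sizes >= min_members]
  if (length(families) < 2) stop("need at least two families to validate")
  fam_names <- sort(names(families))
  families <- families[fam_names]
  k <- length(fam_names)

  # pre-encode every member's ungapped sequence
  codes <- lapply(families, function(a) {
    recs <- alignment_records(a)
    lapply(recs$residues, encode_residues)
  })
  n_mem <- vapply(codes, length, integer(1))

  # one calibration per family, from the full-member model
  full_calib <- vector("list", k)
  names(full_calib) <- fam_names
  for (f in seq_len(k)) {
    hmm <- profile_hmm(families[[f]], alpha = alpha, background = background,
                       name = fam_names[f])
    hmm <- calibrate_evalue(hmm, n_random = n_calib,
                            seed = derive_seed(seed, 0L, f), db_size = db_size)
    full_calib[[f]] <- hmm$calibration
  }

  confusion <- matrix(0, k, k, dimnames = list(true = fam_names,
                                               assigned = fam_names))
  sens_num <- sens_den <- stats::setNames(numeric(k), fam_names)
  ppr_num <- ppr_den <- stats::setNames(numeric(k), fam_names)

  for (rep_i in seq_len(reps)) {
    train <- vector("list", k)
    hmms <- vector("list", k)
    for (f in seq_len(k)) {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, rep_i, f))
      n_train <- max(4L, min(n_mem[f], as.integer(ceiling(frac * n_mem[f]))))
      train[[f]] <- sort(sample.int(n_mem[f], n_train))
      .Random.seed_restore(old)
      sub <- families[[f]]
      sub$seq <- sub$seq[train[[f]], , drop = FALSE]
      sub$meta <- sub$meta[train[[f]], , drop = FALSE]
      hmm <- profile_hmm(sub, alpha = alpha, background = background,
                         name = fam_names[f])
      if (calibrate_each_rep) {
        hmm <- calibrate_evalue(hmm, n_random = n_calib,
                                seed = derive_seed(seed, rep_i, f + k),
                                db_size = db_size)
      } else {
        hmm$calibration <- full_calib[[f]]
      }
      hmms[[f]] <- hmm
    }
    # score all members of all families against all rebuilt models
    all_codes <- unlist(codes, recursive = FALSE, use.names = FALSE)
    fam_of <- rep(seq_len(k), n_mem)
    idx_in_fam <- unlist(lapply(n_mem, seq_len), use.names = FALSE)
    ev <- matrix(NA_real_, length(all_codes), k)
    for (f in seq_len(k)) {
      ev[, f] <- evalue(hmms[[f]]$calibration,
                        viterbi_scores(hmms[[f]], all_codes))
    }
    assigned <- max.col(-ev, ties.method = "first")
    heldout <- !mapply(function(fam, i) i %in% train[[fam]], fam_of, idx_in_fam)
    for (s in seq_along(all_codes)) {
      f <- fam_of[s]; g <- assigned[s]
      count_it <- switch(eval_scope,
                         all = TRUE,
                         heldout_plus_others = heldout[s] || g != f)
      if (!count_it) next
      confusion[f, g] <- confusion[f, g] + 1
      if (heldout[s]) {
        sens_den[f] <- sens_den[f] + 1
        if (g == f) sens_num[f] <- sens_num[f] + 1
      }
      ppr_den[g] <- ppr_den[g] + 1
      if (g == f) ppr_num[g] <- ppr_num[g] + 1
    }
  }

  per_model <- data.frame(
    model = fam_names,
    sensitivity = ifelse(sens_den > 0, sens_num / sens_den, NA_real_),
    ppr = ifelse(ppr_den > 0, ppr_num / ppr_den, NA_real_),
    n_members = as.integer(n_mem),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(per_model = per_model, confusion = confusion,
                 reps = as.integer(reps), seed = as.integer(seed),
                 db_size = db_size, frac = frac, eval_scope = eval_scope,
                 excluded = excluded),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d models, %d replicates (seed %d, db %g)\n",
              nrow(x$per_model), x$reps, x$seed, x$db_size))
  df <- x$per_model
  df$sensitivity <- sprintf("%.3f", df$sensitivity)
  df$ppr <- sprintf("%.3f", df$ppr)
  print(df, row.names = FALSE)
  if (length(x$excluded) > 0)
    cat("excluded (too small):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.validation_report <- function(object, ...) {
  acc <- sum(diag(object$confusion)) / sum(object$confusion)
  safe_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  out <- list(micro_accuracy = acc,
              min_sensitivity = safe_min(object$per_model$sensitivity),
              min_ppr = safe_min(object$per_model$ppr),
              reps = object$reps)
  class(out) <- "summary.validation_report"
  out
}

#' @export
print.summary.validation_report <- function(x, ...) {
  cat(sprintf("micro-accuracy %.4f; min sensitivity %.4f; min PPR %.4f (%d reps)\n",
              x$micro_accuracy, x$min_sensitivity, x$min_ppr, x$reps))
  invisible(x)
}

#' Write a validation report (per-model TSV + confusion JSON)
#' @param report A `validation_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @export
write_validation_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$per_model, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(confusion = report$confusion, reps = report$reps,
           seed = report$seed, db_size = report$db_size,
           eval_scope = report$eval_scope, excluded = report$excluded),
      json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(report)
}
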