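test_that("cut-off calibration interpolates percentiles as specified", {
  # zero-based order-statistic index h = p * (n - 1): for 3..12 at p = 0.05,
  # h = 0.45 so strict = 3 + 0.45 * (4 - 3) = 3.45
  cut <- calibrate_cutoffs(3:12, numeric(0))
  expect_equal(unname(cut["strict"]), 3.45)
  expect_equal(unname(cut["soft"]), 0)

  cut <- calibrate_cutoffs(rep(7, 10), c(1, 2, 3))
  expect_equal(unname(cut["strict"]), 7)
  expect_equal(unname(cut["soft"]), unname(quantile(c(1, 2, 3), 0.95)))

  expect_error(calibrate_cutoffs(c(1, 2, 3, 4)), "insufficient members")

  # soft above strict flags the model unreliable but still constructs
  bad <- calibrate_cutoffs(rep(2, 6), rep(9, 6))
  expect_false(attr(bad, "reliable"))
})

make_two_family_library <- function(seed = 7) {
  bm <- make_family_benchmark(n_families = 2, members_per_family = 10,
                              within_depth = 0.2, between_depth = 0.6,
                              root_length = 120, seed = seed)
  list(bm = bm,
       lib = fit_subfamily_library(bm$seeds, n_calib = 150, seed = 2))
}

test_that("sequences simulated from a family classify confidently to it", {
  tf <- make_two_family_library()
  # low-divergence draws from family A's profile: its consensus with a few
  # substitutions (~2.5% divergence, well inside the family's own spread)
  hA <- tf$lib$models[[1]]$hmm
  consensus <- paste(rabrep:::AA_ALPHABET[apply(hA$match_emissions, 1,
                                                which.max)],
                     collapse = "")
  set.seed(31)
  sims <- seq_records(sprintf("sim%03d", 1:50),
                      vapply(1:50, function(i) {
                        ch <- strsplit(consensus, "")[[1]]
                        idx <- sample(length(ch), 3)
                        ch[idx] <- sample(rabrep:::AA_ALPHABET, 3, TRUE)
                        paste(ch, collapse = "")
                      }, character(1)))
  pr <- predict(tf$lib, sims)
  expect_true(all(pr$hits$model == names(tf$lib$models)[1]))
  expect_gte(mean(pr$hits$label == "confident"), 0.95)
})

test_that("background sequences are labelled none almost always", {
  tf <- make_two_family_library()
  bg <- random_background_records(200, 150, seed = 17)
  pr <- predict(tf$lib, bg)
  expect_gte(mean(pr$hits$label == "none"), 0.95)
})

test_that("a member of a one-model library classifies confidently to it", {
  tf <- make_two_family_library()
  one <- tf$lib
  one$models <- one$models[1]
  member <- alignment_records(tf$bm$seeds[[1]])[3, ]
  hit <- classify_sequence(member, one)
  expect_equal(hit$model, names(one$models))
  expect_equal(hit$label, "confident")
})

test_that("batch classification is order-stable and equals the per-sequence map", {
  tf <- make_two_family_library()
  qs <- tf$bm$records[1:8, ]
  batch <- classify_batch(qs, tf$lib)
  expect_equal(nrow(batch$hits), 8)
  expect_equal(batch$hits$query_id, qs$id)
  # equivalence oracle: batch equals mapping the scalar operation
  for (i in seq_len(nrow(qs))) {
    single <- classify_sequence(qs[i, ], tf$lib)
    expect_equal(batch$hits[i, ], single, ignore_attr = TRUE)
  }
  # permuting the input permutes the output rows identically
  perm <- c(5, 3, 8, 1, 2, 7, 6, 4)
  batch_p <- classify_batch(qs[perm, ], tf$lib)
  expect_equal(batch_p$hits, batch$hits[perm, ], ignore_attr = TRUE)
  # best-4 ranking is ascending in E
  for (qid in unique(batch$top4$query_id)) {
    e <- batch$top4$evalue[batch$top4$query_id == qid]
    expect_true(all(diff(e) >= 0))
  }
})

test_that("raising the strict cut-off never enlarges the confident set", {
  tf <- make_two_family_library()
  qs <- rbind(tf$bm$records, random_background_records(20, 120, seed = 3))
  count_confident <- function(lib) {
    sum(classify_batch(qs, lib)$hits$label == "confident")
  }
  base <- count_confident(tf$lib)
  raised <- tf$lib
  for (nm in names(raised$models)) {
    raised$models[[nm]]$strict_cutoff <- raised$models[[nm]]$strict_cutoff + 2
  }
  expect_lte(count_confident(raised), base)
})

test_that("verification flags fragments, non-fits and ambiguous hits", {
  tf <- make_two_family_library()
  memberA <- alignment_records(tf$bm$seeds[[1]])[1, ]
  full <- classify_batch(memberA, tf$lib)
  expect_equal(nrow(verify_hits(full, tf$lib)[
    verify_hits(full, tf$lib)$flag == "fragment", ]), 0)

  # constructed truncation: 40% of the motif -> fragment flag
  frag <- memberA
  frag$residues <- substr(frag$residues, 1, round(0.4 * nchar(frag$residues)))
  frag$id <- "frag1"
  vb <- verify_hits(classify_batch(frag, tf$lib), tf$lib)
  expect_true("fragment" %in% vb$flag)

  # background sequence -> "no fit" flag
  bg <- random_background_records(1, 120, seed = 23)
  vb <- verify_hits(classify_batch(bg, tf$lib), tf$lib)
  expect_true("no fit" %in% vb$flag)

  # two models that score a query within 2 -log10(E) units -> ambiguous;
  # constructed as an identically-calibrated twin of model A
  twins <- tf$lib
  twin <- twins$models[[1]]
  twin$name <- "twin"
  twin$hmm$name <- "twin"
  twins$models <- c(twins$models, list(twin = twin))
  vb <- verify_hits(classify_batch(memberA, twins), twins)
  expect_true("ambiguous" %in% vb$flag)
})

test_that("parent assignment follows the best-hit vote with a tie rule", {
  set.seed(5)
  seqX <- paste(sample(rabrep:::AA_ALPHABET, 60, TRUE), collapse = "")
  seqY <- paste(sample(rabrep:::AA_ALPHABET, 60, TRUE), collapse = "")
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- sample(rabrep:::AA_ALPHABET, k, TRUE)
    paste(ch, collapse = "")
  }
  # five members, each most similar to X exemplars in 4 species, Y in 1
  pool <- lapply(1:5, function(i) {
    data.frame(residues = c(if (i == 1) mutate(seqY, 2) else mutate(seqX, 2),
                            if (i == 1) mutate(seqX, 30) else mutate(seqY, 30)),
               group = c(if (i == 1) "Y" else "X",
                         if (i == 1) "X" else "Y"),
               stringsAsFactors = FALSE)
  })
  names(pool) <- sprintf("sp%d", 1:5)
  group <- seq_records(sprintf("g%d", 1:5),
                       vapply(1:5, function(i)
                         if (i == 1) mutate(seqY, 1) else mutate(seqX, 1),
                         character(1)),
                       species = sprintf("sp%d", 1:5))
  out <- assign_parent(group, pool)
  expect_equal(unclass(out)[1], "X")
  expect_equal(unname(attr(out, "votes")["X"]), 4)

  # exact tie -> unresolved
  pool2 <- pool[1:4]
  group2 <- group[1:4, ]
  group2$residues <- c(mutate(seqY, 1), mutate(seqY, 1),
                       mutate(seqX, 1), mutate(seqX, 1))
  out2 <- assign_parent(group2, pool2)
  expect_equal(unclass(out2)[1], "unresolved")

  expect_error(assign_parent(group[0, ], pool), "empty group")

  # members without a species pool abstain
  out3 <- assign_parent(group, pool[2:5])
  expect_equal(unclass(out3)[1], "X")
})

test_that("synthetic-family parent assignment recovers the generator", {
  bm <- make_family_benchmark(n_families = 2, members_per_family = 6,
                              within_depth = 0.15, between_depth = 0.6,
                              root_length = 80, seed = 41)
  labels <- bm$labels
  famX <- labels$family == "fam01"
  hX <- profile_hmm(bm$seeds[["fam01"]], name = "X")
  wins <- 0
  n_runs <- 20
  for (s in seq_len(n_runs)) {
    grp <- simulate(hX, nsim = 3, seed = 100 + s)
    grp$species <- c("spA", "spB", "spC")
    pool <- lapply(1:3, function(i) {
      data.frame(residues = c(bm$records$residues[famX][i],
                              bm$records$residues[!famX][i]),
                 group = c("X", "Y"), stringsAsFactors = FALSE)
    })
    names(pool) <- c("spA", "spB", "spC")
    if (unclass(assign_parent(grp, pool))[1] == "X") wins <- wins + 1
  }
  expect_gte(wins / n_runs, 0.95)
})

test_that("library JSON serialization preserves classification behaviour", {
  tf <- make_two_family_library()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_library(tf$lib, tmp)
  lib2 <- read_library(tmp)
  qs <- tf$bm$records[c(1, 11), ]
  expect_equal(classify_batch(qs, lib2)$hits, classify_batch(qs, tf$lib)$hits)
})
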