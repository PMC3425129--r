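test_that("profile construction yields stochastic tables and the documented limits", {
  # degenerate counts: point mass on the observed residue at alpha = 0
  aln <- as_alignment(seq_records(sprintf("s%d", 1:4), rep("MKVA", 4)))
  h <- suppressWarnings(profile_hmm(aln, alpha = 0))
  expect_equal(unname(h$match_emissions[1, "M"]), 1)
  expect_equal(unname(h$match_emissions[3, "V"]), 1)
  rabrep:::validate_phmm(h)

  # alpha -> infinity: emissions converge to the background
  h_inf <- profile_hmm(aln, alpha = 1e9)
  expect_lt(max(abs(sweep(h_inf$match_emissions, 2, h_inf$background))), 1e-6)

  # row stochasticity after building from gappy seeds
  for (s in 1:5) {
    aln <- random_alignment(8, 10, seed = s, gap_frac = 0.15)
    aln <- trim_alignment(aln, 0.25, 0.9)
    rabrep:::validate_phmm(profile_hmm(aln, alpha = 1))
  }

  expect_error(profile_hmm(aln, alpha = -1), "alpha")
})

test_that("single-state log-odds has its closed form", {
  aln <- as_alignment(seq_records(sprintf("s%d", 1:4), rep("A", 4)))
  h <- suppressWarnings(profile_hmm(aln, alpha = 0))
  sv <- score_viterbi(h, "A")
  expect_equal(sv$bits, log2(1 / 0.05), tolerance = 1e-12)
  expect_equal(sv$span, c(0L, 1L))
  expect_equal(sv$path, "M")
})

test_that("Viterbi and Forward agree with brute-force path enumeration", {
  # oracle-checked scores on small random models and queries
  for (s in 1:8) {
    aln <- random_alignment(5, 3, seed = s, gap_frac = 0.15)
    aln <- tryCatch(trim_alignment(aln, 0.4, 0.9), error = function(e) aln)
    h <- profile_hmm(aln, alpha = 0.7)
    set.seed(1000 + s)
    q <- paste(sample(rabrep:::AA_ALPHABET, sample(2:4, 1), TRUE),
               collapse = "")
    expect_equal(score_viterbi(h, q)$bits, brute_viterbi_bits(h, q),
                 tolerance = 1e-9)
    expect_equal(score_forward(h, q), brute_forward_bits(h, q),
                 tolerance = 1e-7)
  }
})

test_that("Forward dominates Viterbi and both ignore sequence metadata", {
  aln <- random_alignment(6, 8, seed = 21)
  h <- profile_hmm(aln)
  for (s in 1:20) {
    set.seed(s)
    q <- paste(sample(rabrep:::AA_ALPHABET, sample(4:20, 1), TRUE),
               collapse = "")
    expect_gte(score_forward(h, q), score_viterbi(h, q)$bits)
  }
  r1 <- seq_records("idA", "MKVLAMKV", species = "Hs", source_rank = 1L)
  r2 <- seq_records("idB", "MKVLAMKV", species = "Sc", source_rank = 3L)
  expect_equal(score_viterbi(h, r1)$bits, score_viterbi(h, r2)$bits)

  # for a sharply peaked profile and its consensus, Forward exceeds Viterbi
  # only by the small mass of partial sub-alignments admitted by uniform
  # local entry/exit (about 0.2 bits here, confirmed by the enumeration
  # oracle above)
  alnc <- as_alignment(seq_records(sprintf("s%d", 1:6), rep("MKWA", 6)))
  hc <- profile_hmm(alnc, alpha = 1e-3)
  gap <- score_forward(hc, "MKWA") - score_viterbi(hc, "MKWA")$bits
  expect_gte(gap, 0)
  expect_lt(gap, 0.3)
  expect_equal(score_forward(hc, "MKWA"), brute_forward_bits(hc, "MKWA"),
               tolerance = 1e-7)
})

test_that("local scoring is robust to flanking residues and handles X", {
  aln <- as_alignment(seq_records(sprintf("s%d", 1:6), rep("MKWAHY", 6)))
  h <- profile_hmm(aln, alpha = 0.1)
  core <- score_viterbi(h, "MKWAHY")
  set.seed(9)
  flank1 <- paste(sample(rabrep:::AA_ALPHABET, 100, TRUE), collapse = "")
  flank2 <- paste(sample(rabrep:::AA_ALPHABET, 100, TRUE), collapse = "")
  padded <- score_viterbi(h, paste0(flank1, "MKWAHY", flank2))
  expect_equal(padded$bits, core$bits, tolerance = 1e-9)
  expect_lte(padded$span[1], 100L)
  expect_gte(padded$span[2], 106L)

  # all-X query scores without error, emitting the background
  sx <- score_viterbi(h, "XXXXXX")
  expect_true(is.finite(sx$bits))
  expect_error(score_viterbi(h, ""), "empty")
})

test_that("Gumbel calibration is deterministic and matches its own tail", {
  aln <- random_alignment(8, 40, seed = 5)
  h <- profile_hmm(aln)
  h1 <- calibrate_evalue(h, n_random = 200, seed = 7)
  h2 <- calibrate_evalue(h, n_random = 200, seed = 7)
  expect_identical(h1$calibration, h2$calibration)
  expect_error(calibrate_evalue(h, n_random = 10, seed = 1), "n_random")

  # Monte-Carlo tail check: fraction of fresh background sequences with
  # fitted upper-tail probability <= 0.05 is 0.05 +/- 0.02 at n = 2000
  fit <- h1$calibration
  set.seed(1234)
  codes <- lapply(1:2000, function(i)
    sample.int(20L, sample(h$L:(2L * h$L), 1), TRUE) - 1L)
  sc <- rabrep:::viterbi_scores(h1, codes)
  # the moment fit is approximate (scores are not exactly Gumbel); the
  # nominal 5% tail must land within a factor of about two
  pval <- 1 - exp(-exp(-fit$lam * (sc - fit$mu)))
  expect_gte(mean(pval <= 0.05), 0.02)
  expect_lte(mean(pval <= 0.05), 0.10)

  # degenerate calibration: a model that scores every sequence identically
  flat <- as_alignment(seq_records(sprintf("s%d", 1:5), rep("A", 5)))
  hflat <- profile_hmm(flat, alpha = 1)
  hflat$match_emissions[1, ] <- hflat$background  # scores collapse to 0
  expect_error(calibrate_evalue(hflat, n_random = 50, seed = 1),
               "degenerate calibration")
})

test_that("E-values follow the calibrated exponential tail", {
  fit <- list(mu = 10, lam = 1.2, db_size = 1e5)
  expect_equal(evalue(fit, 10), 1e5)
  expect_equal(evalue(fit, 10 + log(1e5) / 1.2), 1, tolerance = 1e-12)
  s <- seq(5, 40, by = 0.5)
  expect_true(all(diff(evalue(fit, s)) <= 0))
})

test_that("random-query hit counts scale linearly with the E-value threshold", {
  aln <- random_alignment(10, 30, seed = 11)
  h <- calibrate_evalue(profile_hmm(aln), n_random = 300, seed = 3)
  set.seed(99)
  codes <- lapply(1:5000, function(i)
    sample.int(20L, sample(h$L:(2L * h$L), 1), TRUE) - 1L)
  ev <- evalue(h, rabrep:::viterbi_scores(h, codes))
  # expected hits at threshold x among N draws: x * N / db_size
  for (x in c(0.1, 1, 10)) {
    observed <- sum(ev <= x)
    expected <- x * 5000 / h$calibration$db_size
    # linear scaling within a factor of two (Poisson noise allowed for)
    expect_lte(observed, 2 * expected + 3 * sqrt(expected) + 2)
  }
})

test_that("model JSON serialization round-trips losslessly", {
  aln <- random_alignment(7, 15, seed = 8, gap_frac = 0.1)
  aln <- trim_alignment(aln, 0.25, 0.9)
  h <- calibrate_evalue(profile_hmm(aln, name = "rt"), n_random = 100,
                        seed = 2)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_phmm(h, tmp)
  h2 <- read_phmm(tmp)
  expect_equal(h2$match_emissions, h$match_emissions)
  expect_equal(h2$transitions, h$transitions)
  expect_equal(h2$calibration, h$calibration)
  q <- "MKVLAWQH"
  expect_equal(score_viterbi(h2, q)$bits, score_viterbi(h, q)$bits)
})

test_that("simulated model members outscore background sequences", {
  # separation property behind the classifier benchmarks
  aln <- random_alignment(8, 60, seed = 13)
  h <- profile_hmm(aln, alpha = 0.5, name = "sep")
  members <- simulate(h, nsim = 20, seed = 4)
  bg <- random_background_records(20, 60, seed = 5)
  ms <- vapply(members$residues, function(s) score_viterbi(h, s)$bits,
               numeric(1))
  bs <- vapply(bg$residues, function(s) score_viterbi(h, s)$bits, numeric(1))
  expect_gte(min(ms) - max(bs), 10)

  # determinism of simulate under a fixed seed
  expect_identical(simulate(h, nsim = 5, seed = 11),
                   simulate(h, nsim = 5, seed = 11))
})
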