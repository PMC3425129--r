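toy_matrix <- function() {
  m <- matrix(FALSE, 3, 4,
              dimnames = list(c("famA", "famB", "famC"),
                              c("meta", "naeg", "chlo", "hete")))
  m["famA", ] <- TRUE
  m["famB", c("meta", "naeg")] <- TRUE
  m["famC", "hete"] <- TRUE
  presence_matrix(m, c(meta = "Unikonta", naeg = "Excavata",
                       chlo = "Archaeplastida", hete = "SAR+CCTH"))
}

test_that("supergroup presence is an OR collapse over member taxa", {
  m <- toy_matrix()
  sp <- supergroup_presence(m)
  expect_true(sp["famC", "SAR+CCTH"])
  expect_false(any(sp["famC", c("Unikonta", "Excavata", "Archaeplastida")]))
  expect_true(all(sp["famA", ]))

  # all-zero family row is absent everywhere
  m2 <- toy_matrix()
  m2$present["famC", ] <- FALSE
  expect_false(any(supergroup_presence(m2)["famC", ]))

  # curated compendium: Rab29 is confined to Unikonta and Excavata
  sp <- supergroup_presence(rab_presence())
  expect_true(all(sp["Rab29", c("Unikonta", "Excavata")]))
  expect_false(any(sp["Rab29", c("Archaeplastida", "SAR+CCTH")]))
})

test_that("families_in_at_least counts are monotone in k", {
  m <- rab_presence()
  counts <- vapply(1:4, function(k) families_in_at_least(m, k)$count,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(families_in_at_least(m, 4)$families %in%
                    families_in_at_least(m, 3)$families))
  expect_equal(families_in_at_least(m, 1)$count, 20)
  expect_error(families_in_at_least(m, 0), "out of range")
})

test_that("Dollo reconstruction requires presence on both root sides", {
  m <- toy_matrix()
  root <- rooting_hypothesis("ub", "Unikonta",
                             c("Excavata", "Archaeplastida", "SAR+CCTH"))
  anc <- leca_dollo(m, root)
  expect_true("famA" %in% anc)
  expect_true("famB" %in% anc)   # unikont + excavate presence suffices
  expect_false("famC" %in% anc)  # one-sided

  # excluded supergroups contribute to neither side
  rootx <- rooting_hypothesis("ax", "Archaeplastida",
                              c("Unikonta", "SAR+CCTH"),
                              excluded = "Excavata")
  expect_equal(leca_dollo(m, rootx), "famA")

  m_only_exc <- toy_matrix()
  m_only_exc$supergroup_of[] <- "Excavata"
  expect_error(leca_dollo(m_only_exc, rootx), "empty")

  expect_error(rooting_hypothesis("bad", character(0), "Unikonta"))
  expect_error(rooting_hypothesis("bad", "Unikonta", "Unikonta"),
               "disjoint")
})

test_that("Dollo reconstruction matches brute-force scenario enumeration", {
  roots <- list(
    rooting_hypothesis("ub", "Unikonta",
                       c("Excavata", "Archaeplastida", "SAR+CCTH")),
    rooting_hypothesis("ex", "Excavata",
                       c("Unikonta", "Archaeplastida", "SAR+CCTH")),
    rooting_hypothesis("ax", "Archaeplastida", c("Unikonta", "SAR+CCTH"),
                       excluded = "Excavata"))
  checked <- 0
  for (s in 1:250) {
    m <- random_presence(sample(2:8, 1), sample(2:8, 1), seed = s)
    for (root in roots) {
      got <- tryCatch(leca_dollo(m, root), error = function(e) NULL)
      if (is.null(got)) next  # a side emptied by the random supergroups
      expect_identical(got, brute_dollo(m, root))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 200)
})

test_that("Dollo reconstruction is monotone in the matrix", {
  root <- rooting_hypothesis("ub", "Unikonta",
                             c("Excavata", "Archaeplastida", "SAR+CCTH"))
  for (s in 1:20) {
    m <- random_presence(5, 6, seed = 400 + s)
    base <- tryCatch(leca_dollo(m, root), error = function(e) NULL)
    if (is.null(base)) next
    m2 <- m
    off <- which(!m2$present)
    if (length(off) == 0) next
    m2$present[sample(off, 1)] <- TRUE
    expect_true(all(base %in% leca_dollo(m2, root)))
  }
})

test_that("ledger propagation applies events in order and validates them", {
  led <- event_ledger(c("n1", "n2", "n3"),
                      data.frame(node = c("n2", "n3"), kind = c("loss", "gain"),
                                 family = c("famA", "famZ"),
                                 stringsAsFactors = FALSE))
  out <- propagate_ledger(c("famA", "famB"), led)
  expect_equal(out$n1, c("famA", "famB"))
  expect_equal(out$n2, "famB")
  expect_equal(out$n3, c("famB", "famZ"))

  # empty ledger: every node keeps the start
  led0 <- event_ledger(c("a", "b"), data.frame(node = character(0),
                                               kind = character(0),
                                               family = character(0)))
  out0 <- propagate_ledger(c("f1"), led0)
  expect_true(all(vapply(out0, identical, logical(1), "f1")))

  bad_loss <- event_ledger("n1", data.frame(node = "n1", kind = "loss",
                                            family = "nope",
                                            stringsAsFactors = FALSE))
  expect_error(propagate_ledger("famA", bad_loss),
               "loss of absent family 'nope' at node 'n1'")
  bad_gain <- event_ledger("n1", data.frame(node = "n1", kind = "gain",
                                            family = "famA",
                                            stringsAsFactors = FALSE))
  expect_error(propagate_ledger("famA", bad_gain), "gain of already-present")
  expect_error(event_ledger(c("n1"), data.frame(node = "zz", kind = "loss",
                                                family = "f",
                                                stringsAsFactors = FALSE)),
               "not on path")
})

test_that("loss counts are non-decreasing along loss-only paths", {
  led <- rab_ledgers()$fungal
  start <- rownames(rab_presence()$present)
  losses <- vapply(led$path, function(nd) losses_on_path(start, led, nd),
                   numeric(1))
  expect_true(all(diff(losses) >= 0))
  expect_equal(unname(losses[1]), 0)
  expect_error(losses_on_path(start, led, "not_a_node"), "not on path")
})

test_that("every curated ledger is internally consistent with the 20-family start", {
  start <- rownames(rab_presence()$present)
  for (led in rab_ledgers()) {
    expect_silent(propagate_ledger(start, led))
  }
  # provenance covers every presence call in the compendium
  prov <- rab_provenance()
  m <- rab_presence()
  expect_equal(nrow(prov), sum(m$present))
  expect_true(all(prov$confidence %in%
                    c("reported", "inferred", "low-confidence")))
})

test_that("shipped fixture files equal the in-code compendium", {
  base <- system.file("extdata", package = "rabrep")
  m <- read_presence_matrix(file.path(base, "rab_presence.tsv"),
                            file.path(base, "rab_supergroups.tsv"))
  expect_identical(m$present, rab_presence()$present)
  led <- read_ledger(file.path(base, "ledger_fungal.tsv"))
  expect_identical(led$events, rab_ledgers()$fungal$events)
})
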