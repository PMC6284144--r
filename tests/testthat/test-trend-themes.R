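# Topic frequencies, two-timepoint trend classification, and the theme
# codebook machinery.

uniprep <- function() prep_options(ngram_min = 1, ngram_max = 1,
                                   min_term_docfreq = 1, weighting = "tf",
                                   normalize_docs = FALSE)

test_that("topic_frequency counts tweets, not token occurrences", {
  cp <- make_corpus(c("stigma here", "no mention", "stigma stigma stigma",
                      "stigma again", "last one"))
  expect_equal(topic_frequency(cp, "stigma", uniprep()), 3)
  expect_equal(topic_frequency(cp, "absentterm", uniprep()), 0)
  cp2 <- make_corpus(c("cure cure cure", "cure"))
  expect_equal(topic_frequency(cp2, "cure", uniprep()), 2)
})

test_that("frequency_table matches the hand-counted 12-tweet fixture", {
  tab <- frequency_table(fixture12(), uniprep(), min_count = 3)
  expect_equal(tab$term, c("fight", "stigma", "cure", "fact"))
  expect_equal(tab$frequency, c(4L, 4L, 3L, 3L))
})

test_that("frequency_table default threshold is 35 and filters correctly", {
  expect_equal(formals(frequency_table)$min_count, 35L)
  texts <- c(sprintf("common filler %d", 1:40), sprintf("rare gem %d", 1:10))
  cp <- make_corpus(texts)
  tab <- frequency_table(cp, uniprep())  # default min_count
  expect_equal(tab$term, c("common", "filler"))
  expect_true(all(tab$frequency >= 35))
})

test_that("raising min_count yields a subset (filtration property)", {
  cp <- fixture12()
  lo <- frequency_table(cp, uniprep(), min_count = 1)
  hi <- frequency_table(cp, uniprep(), min_count = 3)
  expect_true(all(hi$term %in% lo$term))
  expect_equal(hi$frequency,
               lo$frequency[match(hi$term, lo$term)])
})

test_that("compare_periods classifies directions per mode", {
  ta <- tibble::tibble(term = c("fight", "gone"), frequency = c(40L, 50L))
  tb <- tibble::tibble(term = c("fight", "fresh"), frequency = c(80L, 60L))
  # corpus doubled: 40/1000 vs 80/2000 is flat in rates
  norm <- compare_periods(ta, tb, 1000, 2000, mode = "normalized",
                          stable_band = 0.1)
  expect_equal(norm$direction[norm$term == "fight"], "stable")
  raw <- compare_periods(ta, tb, 1000, 2000, mode = "raw", stable_band = 0.1)
  expect_equal(raw$direction[raw$term == "fight"], "increase")
  expect_equal(norm$direction[norm$term == "fresh"], "new")
  expect_equal(norm$direction[norm$term == "gone"], "absent")
  expect_equal(norm$rate_a[norm$term == "fight"], 400)
  expect_equal(norm$rate_b[norm$term == "fight"], 400)
  expect_error(compare_periods(ta, tb, 0, 10), "positive")
})

test_that("normalized mode is invariant to duplicating both corpora", {
  ta <- tibble::tibble(term = c("a", "b"), frequency = c(40L, 100L))
  tb <- tibble::tibble(term = c("a", "b"), frequency = c(90L, 60L))
  one <- compare_periods(ta, tb, 500, 800)
  ta2 <- ta; tb2 <- tb
  ta2$frequency <- ta$frequency * 2L
  tb2$frequency <- tb$frequency * 2L
  two <- compare_periods(ta2, tb2, 1000, 1600)
  expect_equal(two$direction, one$direction)
  expect_equal(two$rate_a, one$rate_a)
})

test_that("codebook construction validates and stems keywords", {
  cb <- codebook(tibble::tibble(
    theme = "Reduce Stigma",
    keywords = "ending stigma;lgbt",
    core_action = "Eliminate Stigma and Discrimination",
    commitment = "Support"
  ))
  expect_equal(cb$keywords[[1]], c("end stigma", "lgbt"))
  expect_error(codebook(tibble::tibble(
    theme = c("A", "A"), keywords = "x",
    core_action = "Access to Services", commitment = "Support"
  )), "unique")
  expect_error(codebook(tibble::tibble(
    theme = "A", keywords = "x", core_action = "Nonsense",
    commitment = "Support"
  )), "core_action")
})

test_that("default codebook covers the published themes and round-trips", {
  cb <- default_codebook()
  expect_equal(nrow(cb), 19)
  expect_true(all(cb$core_action %in% c(
    "Decrease Vulnerability of Acquiring HIV/AIDS", "Access to Services",
    "Expand Programs", "Safeguard Human Rights",
    "Partnerships and Alliances", "Eliminate Stigma and Discrimination"
  )))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_equal(back$theme, cb$theme)
  expect_equal(back$keywords, cb$keywords)
})

test_that("apply_codebook maps the published example cluster words", {
  cb <- default_codebook()
  hit <- apply_codebook(porter_stem(c("fight", "today", "support", "cure",
                                      "love")), cb)
  expect_equal(hit$theme, "Combat HIV/AIDS")
  expect_equal(hit$core_action, "Safeguard Human Rights")
  expect_equal(hit$commitment, "Support")
})

test_that("apply_codebook handles no-overlap, ties and thresholds", {
  cb <- codebook(tibble::tibble(
    theme = c("T1", "T2"),
    keywords = c("alpha;beta", "gamma;delta"),
    core_action = "Access to Services",
    commitment = "Treatment or Care"
  ))
  expect_null(apply_codebook(c("nothing", "matches"), cb))
  tie <- apply_codebook(c("alpha", "gamma"), cb)
  expect_true(tie$review)
  expect_true(is.na(tie$theme))
  expect_equal(sort(attr(tie, "tied_themes")), c("T1", "T2"))
  expect_null(apply_codebook(c("alpha", "x", "y"), cb, min_overlap = 2))
  expect_error(apply_codebook("x", cb[0, ]), "empty")
})

test_that("apply_codebook is independent of codebook entry order", {
  cb <- default_codebook()
  terms <- porter_stem(c("discrimination", "living", "people", "plwh"))
  a <- apply_codebook(terms, cb)
  b <- apply_codebook(terms, cb[rev(seq_len(nrow(cb))), ])
  expect_equal(a$theme, b$theme)
})

test_that("theme_depth_table reports level shifts and one-sided themes", {
  cb <- default_codebook()
  kw <- function(theme) cb$keywords[[match(theme, cb$theme)]]
  tree_a <- tibble::tibble(
    node_id = 1:3,
    depth = c(2L, 4L, 2L),
    top_terms = list(kw("Combat HIV/AIDS"), kw("Prevent HIV/AIDS"),
                     kw("Reduce Stigma"))
  )
  tree_b <- tibble::tibble(
    node_id = 1:4,
    depth = c(5L, 3L, 3L, 2L),
    top_terms = list(kw("Combat HIV/AIDS"), kw("Discrimination of PLWH"),
                     kw("Impact of the HIV/AIDS Pandemic"),
                     kw("Reduce Stigma"))
  )
  tab <- theme_depth_table(tree_a, tree_b, cb)
  combat <- tab[tab$theme == "Combat HIV/AIDS", ]
  expect_equal(combat$depth_a, 2L)
  expect_equal(combat$depth_b, 5L)
  expect_equal(combat$delta, 3L)
  prevent <- tab[tab$theme == "Prevent HIV/AIDS", ]
  expect_equal(prevent$depth_a, 4L)
  expect_true(is.na(prevent$depth_b))
  expect_true(is.na(tab$depth_a[tab$theme == "Discrimination of PLWH"]))
  expect_true(is.na(tab$depth_a[
    tab$theme == "Impact of the HIV/AIDS Pandemic"]))
  stigma <- tab[tab$theme == "Reduce Stigma", ]
  expect_equal(stigma$delta, 0L)
})

test_that("identical trees give all-zero deltas and conflicts error", {
  cb <- default_codebook()
  kw <- function(theme) cb$keywords[[match(theme, cb$theme)]]
  tr <- tibble::tibble(node_id = 1:2, depth = c(1L, 2L),
                       top_terms = list(kw("Combat HIV/AIDS"),
                                        kw("Reduce Stigma")))
  tab <- theme_depth_table(tr, tr, cb)
  expect_equal(tab$delta, c(0L, 0L))
  conflicted <- tibble::tibble(
    node_id = 1:2, depth = c(1L, 2L),
    top_terms = list(kw("Combat HIV/AIDS"), kw("Combat HIV/AIDS"))
  )
  expect_error(theme_depth_table(conflicted, tr, cb), "multiple nodes")
})
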