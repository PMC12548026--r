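# Independent oracle: scan every colon position, choose the earliest split
# yielding non-empty trimmed tag and value; colon+space splits are
# preferred by scanning them first.
brute_force_split <- function(s) {
  scan <- function(pat, off) {
    pos <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (pos[1] < 0) return(NULL)
    for (p in pos) {
      tag <- trimws(substr(s, 1, p - 1))
      val <- trimws(substr(s, p + off, nchar(s)))
      if (nzchar(tag) && nzchar(val)) return(c(tag, val))
    }
    NULL
  }
  scan(": ", 2) %||% scan(":", 1)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("parse_characteristics follows the first-colon split rule", {
  p <- parse_characteristics("strain: MG1655")
  expect_equal(p$tag, "strain")
  expect_equal(p$value, "MG1655")
  expect_equal(p$tag_words, 1L)
  expect_equal(p$value_words, 1L)
  expect_true(p$parsed)

  expect_false(parse_characteristics("grown overnight in LB")$parsed)
  expect_false(parse_characteristics(": value only")$parsed)
  expect_false(parse_characteristics("tag only :")$parsed)
  expect_false(parse_characteristics("")$parsed)

  # colon+space preference keeps URLs intact (frozen from the brute-force
  # earliest-valid-split oracle below)
  p <- parse_characteristics("source: http://x.org/a")
  expect_equal(p$tag, "source")
  expect_equal(p$value, "http://x.org/a")
})

test_that("split rule agrees with the brute-force earliest-valid oracle", {
  cases <- c("strain: MG1655", "source: http://x.org/a",
             "time: 12:30:00", "a:b", "x : y", "od600: 0.4: approx",
             "genotype: delta-lacZ x = y", "temp:37C")
  for (s in cases) {
    oracle <- brute_force_split(s)
    got <- parse_characteristics(s)
    expect_equal(c(got$tag, got$value), oracle, info = s)
  }
})

test_that("classify_gsm partitions into empty/structured/not_structured", {
  expect_equal(classify_gsm(gsm_with("G1"), 1)$label, "empty")
  expect_equal(classify_gsm(gsm_with("G2", c("  ", "")), 1)$label, "empty")
  expect_equal(
    classify_gsm(gsm_with("G3", c("strain: MG1655", "medium: LB")), 1)$label,
    "putative_structured")
  # one non-conforming pair taints the whole GSM at any stringency
  expect_equal(
    classify_gsm(gsm_with("G4", c("strain: MG1655", "no colon here")), Inf)$label,
    "not_structured")
  # word limits enforced on both sides
  expect_equal(
    classify_gsm(gsm_with("G5", "strain: MG1655 K12"), k_tag = 1,
                 k_value = 1)$label,
    "not_structured")
  expect_equal(
    classify_gsm(gsm_with("G5", "strain: MG1655 K12"), k_tag = 1,
                 k_value = 2)$label,
    "putative_structured")
})

test_that("stringency sweep is monotone and partitions the corpus", {
  corp <- generate_corpus(small_config(n = 250L, seed = 5L))
  gsms <- gsm_records(corp$document)
  sw <- stringency_sweep(gsms, k_max = 8, unbounded = TRUE)
  expect_equal(sw$n_empty + sw$n_structured + sw$n_not_structured,
               rep(length(gsms), nrow(sw)))
  expect_true(all(diff(sw$n_structured) >= 0))
  expect_true(all(diff(sw$n_not_structured) <= 0))
  expect_equal(length(unique(sw$n_empty)), 1L)
  # generator manifest is the oracle for every k
  expect_equal(sw, manifest_sweep(corp$manifest, 8, unbounded = TRUE))
})

test_that("all-1:1-word corpora are structured at every k", {
  gsms <- lapply(1:5, function(i) gsm_with(paste0("G", i),
                                           c("strain: MG1655", "medium: LB")))
  sw <- stringency_sweep(gsms, k_max = 4)
  expect_equal(sw$n_structured, rep(5L, 4))
})

test_that("build_table union semantics, collisions, and conservation", {
  g1 <- gsm_with("G1", c("strain: MG1655", "medium: LB"))
  g2 <- gsm_with("G2", "Strain:  168")
  tb <- build_table(list(g1, g2))
  expect_setequal(colnames(tb$matrix), c("strain", "medium"))
  expect_equal(unname(tb$column_missing_fraction["medium"]), 0.5)
  expect_equal(unname(tb$column_missing_fraction["strain"]), 0)
  # cell conservation: non-missing cells == retained pairs
  expect_equal(sum(!is.na(tb$matrix)), 3L)

  # duplicate tag keeps first value and warns
  g3 <- gsm_with("G3", c("strain: A", "strain: B"))
  expect_warning(tb3 <- build_table(list(g3)), "duplicate tag")
  expect_equal(unname(tb3$matrix["G3", "strain"]), "A")
  expect_equal(sum(!is.na(tb3$matrix)), 1L)
  expect_equal(tb3$n_collisions, 1L)

  # identical tag sets -> zero missingness
  tb0 <- build_table(list(g1, gsm_with("G9", c("strain: x", "medium: y"))))
  expect_true(all(tb0$column_missing_fraction == 0))

  # precondition: not-structured input rejected
  expect_error(build_table(list(gsm_with("G4", "no colon"))),
               "putative_structured")
})

test_that("mean missingness tracks the configured inclusion probability", {
  # single-word vocabulary, all tags p = 0.6, fully structured corpus
  vocab <- data.frame(tag = c("strain", "medium", "genotype", "phase"),
                      p_include = 0.6)
  cfg <- corpus_config(
    n_gsm = 400L, seed = 9L,
    characteristics = list(
      microarray = list(p_empty = 0, p_structured = 1, p_structured_k1 = 1,
                        max_words = 1, p_adversarial = 0),
      rnaseq = list(p_empty = 0, p_structured = 1, p_structured_k1 = 1,
                    max_words = 1, p_adversarial = 0)),
    tag_vocabulary = vocab)
  corp <- generate_corpus(cfg)
  gsms <- gsm_records(corp$document)
  tb <- build_table(gsms, 1)
  # forcing >= 1 tag per GSM shifts missingness by P(no tag) = 0.4^4 ~ .026;
  # allow that plus 4 binomial standard errors
  se <- sqrt(0.6 * 0.4 / 400)
  expect_lt(abs(mean(1 - tb$column_missing_fraction) - 0.6), 0.026 + 4 * se)
})

test_that("tag_frequency matches a brute-force recount of raw pairs", {
  corp <- generate_corpus(small_config(n = 150L, seed = 13L))
  gsms <- gsm_records(corp$document)
  keep <- vapply(gsms, function(g) classify_gsm(g, Inf)$label, character(1)) ==
    "putative_structured"
  tb <- suppressWarnings(build_table(gsms[keep]))
  tf <- tag_frequency(tb)

  # independent recount straight from the raw characteristics strings
  recount <- new.env()
  for (g in gsms[keep]) {
    raw <- unlist(g$characteristics)
    raw <- raw[nzchar(trimws(raw))]
    tags <- unique(vapply(raw, function(s) {
      sp <- brute_force_split(s)
      tolower(gsub("[[:space:]]+", " ", trimws(sp[1])))
    }, character(1)))
    for (t in tags) assign(t, (recount[[t]] %||% 0) + 1, envir = recount)
  }
  for (i in seq_len(nrow(tf))) {
    expect_equal(tf$pct_gsms[i], 100 * recount[[tf$tag[i]]] / sum(keep),
                 info = tf$tag[i])
  }
  # top-ranked percentage equals the definitional identity
  expect_equal(tf$pct_gsms[1],
               max(100 * (1 - tb$column_missing_fraction)))
  # descending order with lexicographic ties
  expect_true(all(diff(tf$pct_gsms) <= 0))
  # empty table -> empty list
  empty <- list(matrix = matrix(character(), 0, 0),
                column_missing_fraction = numeric())
  expect_equal(nrow(tag_frequency(empty)), 0L)
})

test_that("strain-like tags use word-boundary token matching", {
  res <- strain_like_tags(c("strain", "Strain name", "medium"))
  expect_setequal(res$tags, c("strain", "Strain name"))
  expect_equal(res$proportion, 2 / 3)
  expect_length(strain_like_tags("constraint")$tags, 0)
  expect_length(strain_like_tags("strains")$tags, 0)
  expect_setequal(strain_like_tags(c("strain/background", "strain-id"))$tags,
                  c("strain/background", "strain-id"))
})

test_that("generator strain aliases are recovered exactly", {
  vocab <- data.frame(
    tag = c("strain", "strain background", "medium", "genotype"),
    p_include = c(0.9, 0.5, 0.7, 0.6))
  cfg <- corpus_config(n_gsm = 150L, seed = 21L, tag_vocabulary = vocab)
  corp <- generate_corpus(cfg)
  gsms <- gsm_records(corp$document)
  keep <- vapply(gsms, function(g) classify_gsm(g, Inf)$label,
                 character(1)) == "putative_structured"
  tb <- suppressWarnings(build_table(gsms[keep]))
  found <- strain_like_tags(colnames(tb$matrix))$tags
  # every vocabulary strain alias that was emitted must be found, and every
  # found tag must contain the strain token
  emitted <- unique(unlist(strsplit(corp$manifest$tags, "|", fixed = TRUE)))
  emitted_strain <- emitted[grepl("(^| )strain( |$)", tolower(emitted))]
  expect_setequal(tolower(found),
                  tolower(gsub("[[:space:]]+", " ", emitted_strain)))
})
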