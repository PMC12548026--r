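test_that("file_category strips compression and classifies extensions", {
  fc <- file_category(c("a.CEL.gz", "scan.jpg", "", "x.pair.bz2", "img.TIFF",
                        "table.xlsx", "noext"))
  expect_equal(fc$extension[1], "cel")
  expect_equal(fc$category[1], "processable_candidate")
  expect_equal(fc$category[2], "nonprocessable")
  expect_equal(fc$category[3], "none")
  expect_equal(fc$extension[4], "pair")
  expect_equal(fc$category[5], "nonprocessable")  # .tif/.tiff folded
  expect_equal(fc$category[6], "nonprocessable")
  expect_equal(fc$extension[7], "")
  expect_equal(fc$category[7], "processable_candidate")
})

test_that("normalize_manufacturer resolves aliases case-insensitively", {
  m <- normalize_manufacturer(c("agilent technologies", "AFFX",
                                "Roche NimbleGen", "", "Febit"))
  expect_equal(m$canonical,
               c("Agilent", "Affymetrix", "NimbleGen", "none", "other:Febit"))
})

test_that("every bundled alias maps to exactly one canonical name", {
  al <- load_manufacturer_aliases()
  expect_false(anyDuplicated(al$raw_name) > 0)
  expect_true(all(al$canonical %in% c("Affymetrix", "Agilent", "NimbleGen")))
  # round trip through the normalizer
  m <- normalize_manufacturer(al$raw_name, "commercial", al)
  expect_equal(m$canonical, al$canonical)
})

test_that("triage rules fire in order", {
  mk <- function(files) gsm_record("G", supplementary_files = files,
                                   technology_hint = "microarray")
  affy <- data.frame(canonical = "Affymetrix", distribution = "commercial")

  r <- triage_gsm(mk(character()), affy)
  expect_equal(r$label, "unrecoverable")
  expect_equal(r$rule_fired, "no_supplementary_files")

  r <- triage_gsm(mk("x.cel"),
                  data.frame(canonical = "none", distribution = "unknown"))
  expect_equal(r$rule_fired, "no_manufacturer")

  r <- triage_gsm(mk(c("a.jpg", "b.xls")), affy)
  expect_equal(r$rule_fired, "all_files_nonprocessable")

  r <- triage_gsm(mk("x.cel"),
                  data.frame(canonical = "Affymetrix",
                             distribution = "noncommercial"))
  expect_equal(r$rule_fired, "noncommercial_distribution")

  # manufacturer/extension pairings
  expect_equal(triage_gsm(mk("x.cel"), affy)$label, "reusable")
  expect_equal(triage_gsm(
    mk("x.txt"),
    data.frame(canonical = "Agilent", distribution = "custom_commercial"))$label,
    "reusable")
  expect_equal(triage_gsm(
    mk("x.pair.gz"),
    data.frame(canonical = "NimbleGen", distribution = "commercial"))$label,
    "reusable")

  # mixed file sets are not unrecoverable; mismatched extension falls through
  expect_equal(triage_gsm(mk(c("a.jpg", "x.cel")), affy)$label, "reusable")
  expect_equal(triage_gsm(mk("x.txt"), affy)$label, "potentially_reusable")
  expect_equal(triage_gsm(
    mk("x.txt"),
    data.frame(canonical = "other:Febit", distribution = "commercial"))$label,
    "potentially_reusable")
  # unknown distribution is not noncommercial
  expect_equal(triage_gsm(
    mk("x.cel"),
    data.frame(canonical = "Affymetrix", distribution = "unknown"))$label,
    "potentially_reusable")

  # RNA-seq records are rejected
  expect_error(
    triage_gsm(gsm_record("R1", technology_hint = "rnaseq"), affy),
    "microarray")
})

test_that("labels partition and adding a file never worsens reusable to unrecoverable", {
  affy <- data.frame(canonical = "Affymetrix", distribution = "commercial")
  file_pool <- c("a.cel", "b.txt", "c.jpg", "d.xys", "e.pair", "f.xlsx")
  set.seed(404)
  for (rep in 1:50) {
    files <- sample(file_pool, sample(0:3, 1))
    g <- gsm_record("G", supplementary_files = files,
                    technology_hint = "microarray")
    r <- triage_gsm(g, affy)
    expect_true(r$label %in% c("reusable", "potentially_reusable",
                               "unrecoverable"))
    g2 <- gsm_record("G", supplementary_files = c(files, "extra.cel"),
                     technology_hint = "microarray")
    r2 <- triage_gsm(g2, affy)
    if (r$label == "reusable") expect_false(r2$label == "unrecoverable")
  }
})

test_that("triage_summary fractions sum to one per group", {
  mk <- function(label, manu) {
    structure(list(gsm = "G", label = label, rule_fired = "r",
                   manufacturer = manu, distribution = "commercial"),
              class = "triage_result")
  }
  res <- c(lapply(1:3, function(i) mk("unrecoverable", "Affymetrix")),
           list(mk("reusable", "Agilent")))
  tab <- triage_summary(res, "overall")
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)
  expect_equal(tab$fraction[tab$label == "unrecoverable"], 0.75)
  by_m <- triage_summary(res, "manufacturer")
  sums <- tapply(by_m$fraction, by_m$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # all-unrecoverable input
  tab2 <- triage_summary(res[1:3], "overall")
  expect_equal(tab2$fraction[tab2$label == "unrecoverable"], 1)
})

test_that("triage of a generated corpus matches the manifest exactly", {
  corp <- generate_corpus(small_config(n = 300L, seed = 17L))
  rep <- suppressWarnings(run_audit(corp$document, k_max = 3))
  m <- corp$manifest[corp$manifest$technology == "microarray", ]
  expected <- table(factor(m$triage_label,
                           c("reusable", "potentially_reusable",
                             "unrecoverable")))
  got <- rep$triage
  expect_equal(got$n, as.integer(expected))
  # rule-level audit: no-file rule fraction equals the manifest's
  expect_equal(sum(m$triage_rule == "no_supplementary_files"),
               sum(m$n_files == 0))
})
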