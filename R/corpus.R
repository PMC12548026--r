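# Synthetic SOFT corpus generator with a ground-truth manifest.
#
# The generator emits a corpus whose statistical structure matches the
# audited repository's stated world: a 48/52 microarray/RNA-seq technology
# split; ~10% of samples putative-structured at the strictest single-word
# stringency rising to ~70% (microarray) and ~95% (RNA-seq) when any word
# count is allowed; ~17% of microarray samples with no supplementary file
# and ~44% reusable; Affymetrix/Agilent/NimbleGen manufacturer shares of
# ~23/21/11%; submission dates following a logistic (microarray, records
# since 2000) or cubic (RNA-seq, records since 2009) cumulative curve.
# Every intended label is recorded in a manifest at generation time, so
# the manifest — not the audit code — is the oracle in tests.
#
# Randomness is drawn from per-GSM per-aspect substreams: changing, say,
# the supplementary-file mix cannot perturb characteristics sampling.

DEFAULT_TAG_VOCABULARY <- data.frame(
  tag = c("strain", "genotype", "medium", "treatment", "temperature",
          "growth phase", "strain background"),
  p_include = c(0.85, 0.55, 0.60, 0.45, 0.35, 0.30, 0.10),
  stringsAsFactors = FALSE
)

WORD_POOL <- c("aerobic", "anaerobic", "exponential", "stationary", "culture",
               "minimal", "rich", "glucose", "phosphate", "limited", "heat",
               "shock", "control", "mutant", "wild", "type", "biofilm",
               "planktonic", "replicate", "induced", "depleted", "log",
               "phase", "sample", "cells")

#' Construct a synthetic-corpus configuration
#'
#' Defaults encode the audited repository's reported proportions (see the
#' methods vignette); probabilities within each mix must sum to 1.
#'
#' @param n_gsm number of samples to generate.
#' @param seed integer master seed; all randomness derives from it.
#' @param technology_mix named probabilities for `microarray`, `rnaseq`.
#' @param characteristics per-technology list with `p_empty`,
#'   `p_structured` (share putative-structured when any word count is
#'   allowed), `p_structured_k1` (share putative-structured at the
#'   single-word stringency; must not exceed `p_structured`), `max_words`
#'   (largest per-sample tag/value word count), and `p_adversarial`
#'   (share of not-structured samples given an "almost structured" line,
#'   e.g. a colon with an empty tag).
#' @param tag_vocabulary data.frame with columns `tag`, `p_include`: the
#'   per-tag inclusion probability for structured samples.
#' @param triage_mix named probabilities over microarray triage scenarios:
#'   `reusable`, `potentially_reusable`, `no_files`, `no_manufacturer`,
#'   `all_nonprocessable`, `noncommercial`.
#' @param manufacturer_mix named probabilities over `Affymetrix`,
#'   `Agilent`, `NimbleGen` for reusable-scenario platforms.
#' @param organism_mix named probabilities; names are lineage organisms or
#'   the specials `multiple`, `synthetic`, `environmental`, `unknown`.
#' @param years per-technology `c(from, to)` calendar-year spans.
#' @param growth per-technology growth-curve shape (`list(type =
#'   "logistic", k=, x0=)` or `list(type = "cubic", a3=, a2=, a1=, a0=,
#'   center=)`); cumulative yearly submissions follow the normalized,
#'   rounded curve.
#' @return list of class `corpus_config`.
#' @export
corpus_config <- function(
    n_gsm = 1000L,
    seed = 20260910L,
    technology_mix = c(microarray = 0.48, rnaseq = 0.52),
    characteristics = list(
      microarray = list(p_empty = 0.12, p_structured = 0.70,
                        p_structured_k1 = 0.10, max_words = 86,
                        p_adversarial = 0.25),
      rnaseq = list(p_empty = 0.01, p_structured = 0.95,
                    p_structured_k1 = 0.10, max_words = 12,
                    p_adversarial = 0.25)
    ),
    tag_vocabulary = DEFAULT_TAG_VOCABULARY,
    triage_mix = c(reusable = 0.44, potentially_reusable = 0.34,
                   no_files = 0.17, no_manufacturer = 0.02,
                   all_nonprocessable = 0.015, noncommercial = 0.015),
    manufacturer_mix = c(Affymetrix = 0.23, Agilent = 0.21,
                         NimbleGen = 0.11) / 0.55,
    organism_mix = c("escherichia coli" = 0.30,
                     "bacillus subtilis" = 0.12,
                     "mycobacterium tuberculosis" = 0.10,
                     "pseudomonas aeruginosa" = 0.08,
                     "staphylococcus aureus" = 0.06,
                     "salmonella enterica" = 0.05,
                     "streptomyces coelicolor" = 0.05,
                     "synechocystis sp. pcc 6803" = 0.04,
                     "helicobacter pylori" = 0.04,
                     "corynebacterium glutamicum" = 0.04,
                     "vibrio cholerae" = 0.04,
                     "listeria monocytogenes" = 0.02,
                     multiple = 0.02, synthetic = 0.015,
                     environmental = 0.015, unknown = 0.01),
    years = list(microarray = c(2000, 2025), rnaseq = c(2009, 2025)),
    growth = list(
      microarray = list(type = "logistic", k = 0.3968, x0 = 2011.245),
      rnaseq = list(type = "cubic", a3 = 1, a2 = 2, a1 = 12, a0 = 0,
                    center = 2009)
    )) {
  cfg <- list(n_gsm = as.integer(n_gsm), seed = as.integer(seed),
              technology_mix = technology_mix,
              characteristics = characteristics,
              tag_vocabulary = tag_vocabulary, triage_mix = triage_mix,
              manufacturer_mix = manufacturer_mix,
              organism_mix = organism_mix, years = years, growth = growth)
  validate_corpus_config(cfg)
  structure(cfg, class = "corpus_config")
}

validate_corpus_config <- function(cfg) {
  check_mix <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("invalid config: ", what, " probabilities must be in [0,1] and sum to 1")
    }
  }
  if (cfg$n_gsm < 1L) stop("invalid config: n_gsm must be positive")
  check_mix(cfg$technology_mix, "technology_mix")
  check_mix(cfg$triage_mix, "triage_mix")
  check_mix(cfg$manufacturer_mix, "manufacturer_mix")
  check_mix(cfg$organism_mix, "organism_mix")
  for (tech in names(cfg$characteristics)) {
    ch <- cfg$characteristics[[tech]]
    probs <- c(ch$p_empty, ch$p_structured, ch$p_structured_k1, ch$p_adversarial)
    if (any(probs < 0 | probs > 1)) {
      stop("invalid config: characteristics probabilities out of [0,1]")
    }
    if (ch$p_structured_k1 > ch$p_structured) {
      stop("invalid config: p_structured_k1 exceeds p_structured for ", tech)
    }
    if (ch$p_empty + ch$p_structured > 1) {
      stop("invalid config: p_empty + p_structured > 1 for ", tech)
    }
  }
  if (any(cfg$tag_vocabulary$p_include < 0 | cfg$tag_vocabulary$p_include > 1)) {
    stop("invalid config: tag inclusion probabilities out of [0,1]")
  }
  invisible(cfg)
}

# Distribution of the per-GSM maximum tag/value word count s (>= 1), given
# the configured structured shares: P(s = 1) reproduces the single-word
# share; the remainder decays geometrically up to max_words.
word_limit_distribution <- function(ch) {
  p1 <- if (ch$p_structured > 0) ch$p_structured_k1 / ch$p_structured else 1
  if (ch$max_words == 1L) return(c(`1` = 1))
  rest <- 0.5^(seq(2L, ch$max_words) - 2L)
  rest <- rest / sum(rest) * (1 - p1)
  stats::setNames(c(p1, rest), seq_len(ch$max_words))
}

sample_words <- function(n) {
  paste(sample(WORD_POOL, n, replace = TRUE), collapse = " ")
}

# Yearly submission counts per technology: the configured curve is
# evaluated at year ends, normalized to n_tech, rounded cumulatively.
yearly_counts <- function(growth, years, n_tech) {
  yr <- seq(years[1], years[2])
  f <- switch(growth$type,
    logistic = {
      fit <- logistic_fit(L = 1, k = growth$k, x0 = growth$x0)
      logistic_value(fit, yr)
    },
    cubic = {
      fit <- cubic_fit(growth$a3, growth$a2, growth$a1, growth$a0,
                       center = growth$center)
      cubic_value(fit, yr)
    },
    stop("invalid config: unknown growth type ", growth$type)
  )
  f <- f - min(f)
  if (max(f) <= 0) stop("invalid config: flat growth curve over year span")
  f[length(f)] <- max(f) # guard against non-monotone tails
  cum <- round(n_tech * cummax(f) / max(f))
  cum[length(cum)] <- n_tech
  counts <- diff(c(0, cum))
  counts[counts < 0] <- 0
  # rounding slack goes to the final year
  counts[length(counts)] <- counts[length(counts)] + (n_tech - sum(counts))
  stats::setNames(counts, yr)
}

# --- per-aspect samplers (each runs inside its own RNG substream) --------

sample_characteristics <- function(ch, vocab, i, seed) {
  with_substream(seed, i, "characteristics", {
    u <- stats::runif(1)
    if (u < ch$p_empty) {
      return(list(class = "empty", lines = character(), s = NA_integer_,
                  tags = character()))
    }
    if (u < ch$p_empty + ch$p_structured) {
      wl <- word_limit_distribution(ch)
      s <- as.integer(sample(names(wl), 1, prob = wl))
      # only vocabulary tags within the word limit are eligible
      ok <- word_count(vocab$tag) <= s
      inc <- stats::runif(nrow(vocab)) < vocab$p_include & ok
      if (!any(inc)) inc[which(ok)[1]] <- TRUE
      tags <- vocab$tag[inc]
      vals <- vapply(tags, function(t) {
        sample_words(if (s == 1L) 1L else sample.int(s, 1))
      }, character(1))
      # realize the configured word limit on one pair (value side, or with
      # probability 0.3 by extending the tag into a longer variant)
      j <- length(tags)
      if (s > 1L && stats::runif(1) < 0.3 && word_count(tags[j]) < s) {
        tags[j] <- paste(tags[j], sample_words(s - word_count(tags[j])))
      } else {
        vals[j] <- sample_words(s)
      }
      return(list(class = "structured",
                  lines = paste0(tags, ": ", vals), s = s, tags = tags))
    }
    n_lines <- sample.int(3L, 1)
    lines <- vapply(seq_len(n_lines), function(...) {
      sample_words(sample.int(6L, 1) + 1L)
    }, character(1))
    if (stats::runif(1) < ch$p_adversarial) {
      lines[1] <- paste0(": ", sample_words(2)) # colon with empty tag
    }
    list(class = "not_structured", lines = lines, s = NA_integer_,
         tags = character())
  })
}

sample_triage_scenario <- function(cfg, i, aliases) {
  with_substream(cfg$seed, i, "files", {
    scen <- sample(names(cfg$triage_mix), 1, prob = cfg$triage_mix)
    pick_alias <- function(canon) {
      opts <- aliases$raw_name[aliases$canonical == canon]
      sample(opts, 1)
    }
    major <- sample(names(cfg$manufacturer_mix), 1,
                    prob = cfg$manufacturer_mix)
    std_ext <- c(Affymetrix = "cel", Agilent = "txt", NimbleGen = "xys")
    switch(scen,
      reusable = list(
        label = "reusable", rule = "manufacturer_extension_match",
        manufacturer_raw = pick_alias(major), manufacturer = major,
        distribution = sample(c("commercial", "custom_commercial"), 1,
                              prob = c(0.8, 0.2)),
        files = paste0("raw_", i, ".", std_ext[[major]],
                       if (stats::runif(1) < 0.3) ".gz" else "")),
      potentially_reusable = {
        sub <- sample(c("other_manufacturer", "unknown_distribution",
                        "extension_mismatch"), 1)
        if (sub == "other_manufacturer") {
          list(label = "potentially_reusable", rule = "fallthrough",
               manufacturer_raw = sample(c("Febit", "Oxford Gene Technology",
                                           "MWG Biotech", "CombiMatrix"), 1),
               manufacturer = "other", distribution = "commercial",
               files = paste0("raw_", i, ".txt"))
        } else if (sub == "unknown_distribution") {
          list(label = "potentially_reusable", rule = "fallthrough",
               manufacturer_raw = pick_alias(major), manufacturer = major,
               distribution = "unknown",
               files = paste0("raw_", i, ".", std_ext[[major]]))
        } else {
          list(label = "potentially_reusable", rule = "fallthrough",
               manufacturer_raw = pick_alias(major), manufacturer = major,
               distribution = "commercial",
               files = paste0("raw_", i, ".gpr"))
        }
      },
      no_files = list(label = "unrecoverable", rule = "no_supplementary_files",
                      manufacturer_raw = pick_alias(major),
                      manufacturer = major, distribution = "commercial",
                      files = character()),
      no_manufacturer = list(label = "unrecoverable", rule = "no_manufacturer",
                             manufacturer_raw = "", manufacturer = "none",
                             distribution = "unknown",
                             files = paste0("raw_", i, ".txt")),
      all_nonprocessable = list(
        label = "unrecoverable", rule = "all_files_nonprocessable",
        manufacturer_raw = pick_alias(major), manufacturer = major,
        distribution = "commercial",
        files = paste0("scan_", i, ".",
                       sample(c("tiff", "jpg", "xls", "xlsx"), 1))),
      noncommercial = list(
        label = "unrecoverable", rule = "noncommercial_distribution",
        manufacturer_raw = sample(c("In-house spotted", "University core"), 1),
        manufacturer = "other", distribution = "noncommercial",
        files = paste0("raw_", i, ".txt"))
    )
  })
}

sample_organism <- function(cfg, i, lineage) {
  with_substream(cfg$seed, i, "organism", {
    pick <- sample(names(cfg$organism_mix), 1, prob = cfg$organism_mix)
    switch(pick,
      multiple = {
        orgs <- sample(lineage$organism[lineage$superkingdom == "Bacteria"], 2)
        list(organisms = tools::toTitleCase(orgs), label = "multiple_organism")
      },
      synthetic = list(organisms = "synthetic construct",
                       label = "synthetic_chimeric"),
      environmental = list(organisms = "environmental samples",
                           label = "environmental_samples"),
      unknown = list(organisms = "Candidatus unknownii",
                     label = "unclassified"),
      {
        i2 <- match(pick, lineage$organism)
        list(organisms = tools::toTitleCase(pick),
             label = lineage$superkingdom[i2])
      })
  })
}

#' Generate a synthetic SOFT corpus with ground-truth manifest
#'
#' Deterministic given `config$seed`: the same configuration yields a
#' byte-identical corpus. The manifest records every intended label
#' (structuredness class and word limit, triage label and rule, taxon
#' label, submission year) at generation time, independently of the audit
#' code, so it can serve as the oracle for every pipeline stage.
#'
#' @param config a [corpus_config()].
#' @param dir optional directory; when given, `corpus.soft`,
#'   `manifest.tsv` and `config.json` are written there.
#' @return list of class `synthetic_corpus`: `document` (a
#'   [soft_document()] with PLATFORM then SAMPLE entities), `manifest`
#'   (data.frame, one row per GSM), `config`.
#' @export
generate_corpus <- function(config, dir = NULL) {
  validate_corpus_config(config)
  n <- config$n_gsm
  aliases <- load_manufacturer_aliases()
  lineage <- load_lineage()

  # -- technology assignment ---------------------------------------------
  tech <- with_substream(config$seed, 0, "technology", {
    sample(names(config$technology_mix), n, replace = TRUE,
           prob = config$technology_mix)
  })

  # -- submission years: fill the configured growth curves ----------------
  year <- integer(n)
  for (tk in unique(tech)) {
    idx <- which(tech == tk)
    counts <- yearly_counts(config$growth[[tk]], config$years[[tk]],
                            length(idx))
    year[idx] <- rep(as.integer(names(counts)), counts)
  }

  # -- per-GSM aspects ----------------------------------------------------
  entities <- vector("list", n)
  gpl_key <- character(n)
  man <- list(char_class = character(n), word_limit = rep(NA_integer_, n),
              n_pairs = integer(n), tags = character(n),
              triage_label = rep(NA_character_, n),
              triage_rule = rep(NA_character_, n),
              manufacturer = rep(NA_character_, n),
              distribution = rep(NA_character_, n),
              n_files = integer(n), organism_label = character(n))
  for (i in seq_len(n)) {
    ch_cfg <- config$characteristics[[tech[i]]]
    chars <- sample_characteristics(ch_cfg, config$tag_vocabulary, i,
                                    config$seed)
    org <- sample_organism(config, i, lineage)
    tri <- if (tech[i] == "microarray") {
      sample_triage_scenario(config, i, aliases)
    } else {
      list(label = NA_character_, rule = NA_character_,
           manufacturer_raw = "", manufacturer = NA_character_,
           distribution = NA_character_, files = character())
    }
    gpl_key[i] <- paste(tech[i], tri$manufacturer_raw, tri$distribution,
                        sep = "\r")
    man$char_class[i] <- chars$class
    man$word_limit[i] <- chars$s
    man$n_pairs[i] <- length(chars$lines) * (chars$class == "structured")
    man$tags[i] <- paste(chars$tags, collapse = "|")
    man$triage_label[i] <- tri$label
    man$triage_rule[i] <- tri$rule
    man$manufacturer[i] <- tri$manufacturer
    man$distribution[i] <- tri$distribution
    man$n_files[i] <- length(tri$files)
    man$organism_label[i] <- org$label
    entities[[i]] <- list(chars = chars, org = org, tri = tri)
  }
  manifest <- data.frame(accession = sprintf("GSM%06d", seq_len(n)),
                         technology = tech, year = year, man,
                         stringsAsFactors = FALSE)

  # -- platforms: one GPL per (technology, manufacturer, distribution) ----
  ukey <- unique(gpl_key)
  gpl_acc <- stats::setNames(sprintf("GPL%04d", seq_along(ukey)), ukey)
  gpl_entities <- lapply(seq_along(ukey), function(j) {
    parts <- strsplit(ukey[j], "\r", fixed = TRUE)[[1]]
    attrs <- data.frame(
      name = c("technology",
               if (nzchar(parts[2])) "manufacturer",
               if (parts[3] != "NA") "distribution"),
      value = c(if (parts[1] == "microarray") "in situ oligonucleotide"
                else "high-throughput sequencing",
                if (nzchar(parts[2])) parts[2],
                if (parts[3] != "NA") parts[3]),
      stringsAsFactors = FALSE
    )
    attrs$raw_name <- paste0("Platform_", attrs$name)
    soft_entity("PLATFORM", gpl_acc[[j]],
                attrs[, c("name", "raw_name", "value")])
  })

  # -- sample entities ----------------------------------------------------
  month_names <- month.abb
  gsm_entities <- lapply(seq_len(n), function(i) {
    e <- entities[[i]]
    mon <- with_substream(config$seed, i, "date_jitter",
                          sample(month_names, 1))
    files <- e$tri$files
    nm <- c("title", "geo_accession", "status", "submission_date",
            "channel_count",
            rep("organism_ch1", length(e$org$organisms)),
            rep("characteristics_ch1", length(e$chars$lines)),
            if (tech[i] == "rnaseq") c("library_strategy", "library_source")
            else "label",
            "platform_id", "series_id",
            if (length(files) == 1L) "supplementary_file"
            else if (length(files) > 1L)
              paste0("supplementary_file_", seq_along(files)))
    val <- c(paste("synthetic sample", i), sprintf("GSM%06d", i),
             paste("Public on", mon, "15", year[i]),
             paste(mon, "15", year[i]), "1",
             e$org$organisms, e$chars$lines,
             if (tech[i] == "rnaseq") c("RNA-Seq", "transcriptomic")
             else "biotin",
             gpl_acc[[gpl_key[i]]],
             sprintf("GSE%04d", (i - 1L) %/% 20L + 1L),
             files)
    a <- data.frame(name = nm, raw_name = paste0("Sample_", nm), value = val,
                    stringsAsFactors = FALSE)
    soft_entity("SAMPLE", sprintf("GSM%06d", i), a)
  })

  doc <- soft_document(c(gpl_entities, gsm_entities))
  out <- structure(list(document = doc, manifest = manifest, config = config),
                   class = "synthetic_corpus")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_soft(doc, file.path(dir, "corpus.soft"))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(config_for_json(config),
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}

config_for_json <- function(cfg) {
  lapply(unclass(cfg), function(x) if (is.data.frame(x)) as.list(x) else x)
}

#' Expected stringency-sweep table implied by a manifest
#'
#' @param manifest the manifest of a [generate_corpus()] result.
#' @param k_max,unbounded as in [stringency_sweep()].
#' @return data.frame matching the [stringency_sweep()] layout.
#' @export
manifest_sweep <- function(manifest, k_max, unbounded = FALSE) {
  ks <- c(seq_len(k_max), if (unbounded) Inf)
  n <- nrow(manifest)
  do.call(rbind, lapply(ks, function(k) {
    ns <- sum(manifest$char_class == "structured" &
                manifest$word_limit <= k, na.rm = TRUE)
    ne <- sum(manifest$char_class == "empty")
    data.frame(k = k, n_empty = ne, n_structured = ns,
               n_not_structured = n - ne - ns)
  }))
}

#' Write the bundled reference fixtures to a directory
#'
#' Copies the versioned reference files (field catalog, manufacturer
#' aliases, lineage) shipped with the package, and self-checks the catalog
#' accounting before writing.
#'
#' @param dir target directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
generate_reference_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat <- load_field_catalog()
  s <- summarize_catalog(cat)
  stopifnot(s$n_total == 45, nrow(cat) == 45 + 7)
  cls <- classify_fields(cat$name[!cat$duplicate], cat)
  stopifnot(all(cls$known))
  files <- c("field_catalog.tsv", "manufacturer_aliases.tsv", "lineage.tsv")
  src <- vapply(files, function(f) {
    system.file("extdata", f, package = "softaudit")
  }, character(1))
  dest <- file.path(dir, files)
  file.copy(src, dest, overwrite = TRUE)
  invisible(dest)
}
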