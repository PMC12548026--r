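# Orchestration: run every audit stage on a parsed corpus and emit a
# single reconstructible report (JSON plus per-stage TSV exports).

#' Run the full metadata audit
#'
#' Parses SOFT input (or accepts an already parsed document), then runs
#' field inventory/classification, the characteristics structuredness
#' audit, microarray reusability triage, taxonomic profiling and growth
#' fitting, and assembles a deterministic report. Growth models are fitted
#' only when a technology has enough dated records (>= 4 yearly points
#' logistic, >= 5 cubic); otherwise that fit is `NULL` and a note is
#' recorded.
#'
#' @param input a [soft_document()], a path to a `.soft`(.gz) file, or a
#'   directory of such files.
#' @param k_max stringency sweep upper limit.
#' @param k_tag,k_value stringency used for the characteristics table
#'   (default unbounded).
#' @param catalog,aliases,lineage reference fixtures (bundled defaults).
#' @param out optional output directory for TSV/JSON exports.
#' @param lenient when `FALSE` (default) structural parse errors abort the
#'   audit; when `TRUE` unreadable files are skipped with a warning.
#' @return list of class `audit_report`.
#' @export
run_audit <- function(input, k_max = 10L, k_tag = Inf, k_value = k_tag,
                      catalog = load_field_catalog(),
                      aliases = load_manufacturer_aliases(),
                      lineage = load_lineage(),
                      out = NULL, lenient = FALSE) {
  doc <- if (inherits(input, "soft_document")) {
    input
  } else if (length(input) == 1L && dir.exists(input)) {
    paths <- list.files(input, pattern = "\\.soft(\\.gz)?$", full.names = TRUE)
    if (!length(paths)) stop("no .soft files found under ", input)
    docs <- lapply(paths, function(p) {
      if (lenient) {
        tryCatch(read_soft(p), error = function(e) {
          warning("skipping ", p, ": ", conditionMessage(e), call. = FALSE)
          NULL
        })
      } else read_soft(p)
    })
    soft_document(do.call(c, lapply(Filter(Negate(is.null), docs),
                                    `[[`, "entities")))
  } else {
    read_soft(input)
  }

  gsm_entities <- Filter(function(e) e$entity_kind == "SAMPLE", doc$entities)
  if (!length(gsm_entities)) stop("audit error: input contains no SAMPLE entities")
  gsms <- lapply(gsm_entities, as_gsm_record)

  # --- field inventory and catalog classification ------------------------
  inv <- inventory_fields(gsm_entities)
  canon <- reduce_redundant(inv$name)
  classified <- classify_fields(unique(unname(canon)), catalog)
  catalog_summary <- summarize_catalog(catalog)

  # --- characteristics audit ---------------------------------------------
  sweep <- stringency_sweep(gsms, k_max = k_max, unbounded = TRUE)
  labels <- classify_all(gsms, k_tag, k_value)
  structured <- gsms[labels == "putative_structured"]
  char_table <- if (length(structured)) {
    suppressWarnings(build_table(structured, k_tag, k_value))
  } else NULL
  tag_freq <- if (!is.null(char_table)) tag_frequency(char_table, top = 10)
  strain <- if (!is.null(char_table)) {
    strain_like_tags(colnames(char_table$matrix))
  }

  # --- triage (microarray only) ------------------------------------------
  gpl_info <- platform_manufacturers(doc, aliases)
  micro <- gsms[vapply(gsms, `[[`, character(1), "technology_hint") ==
                  "microarray"]
  triage <- lapply(micro, function(g) {
    m <- gpl_info[match(g$platform_id, gpl_info$platform_id), , drop = FALSE]
    if (!nrow(m) || is.na(g$platform_id) || is.na(m$canonical[1])) {
      m <- data.frame(canonical = "none", distribution = "unknown")
    }
    triage_gsm(g, m)
  })
  triage_tab <- if (length(triage)) triage_summary(triage, "overall")

  # --- taxonomy -----------------------------------------------------------
  taxa <- count_by_rank(gsms, "superkingdom", lineage)

  # --- growth -------------------------------------------------------------
  notes <- character()
  fit_one <- function(tk, fitter, min_pts) {
    series <- tryCatch(cumulative_by_year(gsms, tk), error = function(e) NULL)
    if (is.null(series) || length(series$x) < min_pts) {
      notes <<- c(notes, paste0("growth fit skipped for ", tk,
                                ": insufficient dated records"))
      return(NULL)
    }
    tryCatch(fitter(series), error = function(e) {
      notes <<- c(notes, paste0("growth fit failed for ", tk, ": ",
                                conditionMessage(e)))
      NULL
    })
  }
  fit_ma <- fit_one("microarray", fit_logistic, 4L)
  fit_rs <- fit_one("rnaseq", fit_cubic, 5L)
  fold <- if (!is.null(fit_ma) && !is.null(fit_rs)) {
    last_yr <- max(vapply(gsms, function(g) {
      if (is.na(g$submission_date)) -Inf
      else as.numeric(format(g$submission_date, "%Y"))
    }, numeric(1)))
    project_fold_change(fit_ma, fit_rs, last_yr, 2030)
  }

  report <- structure(list(
    n_gsm = length(gsms),
    catalog_summary = catalog_summary,
    field_inventory = inv,
    field_classification = classified,
    sweep = sweep,
    structure_labels = table(labels),
    characteristics_table = char_table,
    tag_frequency = tag_freq,
    strain_like = strain,
    triage = triage_tab,
    taxonomy = taxa,
    growth = list(microarray = fit_ma, rnaseq = fit_rs,
                  fold_change_2030 = fold),
    notes = notes,
    run = list(package_version = as.character(utils::packageVersion("softaudit")),
               k_max = k_max, k_tag = k_tag, k_value = k_value)
  ), class = "audit_report")

  if (!is.null(out)) export_report(report, out)
  report
}

# Manufacturer/distribution per PLATFORM entity in a document.
platform_manufacturers <- function(doc, aliases = load_manufacturer_aliases()) {
  gpls <- Filter(function(e) e$entity_kind == "PLATFORM", doc$entities)
  if (!length(gpls)) {
    return(data.frame(platform_id = character(), canonical = character(),
                      distribution = character(), stringsAsFactors = FALSE))
  }
  raw <- vapply(gpls, function(e) {
    attr_values(e, "manufacturer")[1] %||% NA_character_
  }, character(1))
  dist <- vapply(gpls, function(e) {
    attr_values(e, "distribution")[1] %||% NA_character_
  }, character(1))
  norm <- normalize_manufacturer(raw, dist, aliases)
  data.frame(platform_id = vapply(gpls, `[[`, character(1), "accession"),
             canonical = norm$canonical, distribution = norm$distribution,
             stringsAsFactors = FALSE)
}

#' Export an audit report to a directory
#'
#' Writes `report.json` plus per-stage TSVs (`field_inventory.tsv`,
#' `sweep.tsv`, `characteristics_table.tsv`, `column_profile.tsv`,
#' `tag_frequency.tsv`, `triage.tsv`, `taxonomy.tsv`). Output is
#' deterministic: no timestamps.
#'
#' @param report an [run_audit()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  wt(report$field_inventory, "field_inventory.tsv")
  wt(report$sweep, "sweep.tsv")
  wt(report$tag_frequency, "tag_frequency.tsv")
  wt(report$triage, "triage.tsv")
  wt(report$taxonomy, "taxonomy.tsv")
  ct <- report$characteristics_table
  if (!is.null(ct)) {
    m <- ct$matrix
    m[is.na(m)] <- ""
    out <- data.frame(gsm = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    wt(out, "characteristics_table.tsv")
    wt(data.frame(tag = colnames(ct$matrix),
                  n_gsms = colSums(!is.na(ct$matrix)),
                  missing_fraction = ct$column_missing_fraction,
                  row.names = NULL),
       "column_profile.tsv")
  }
  json <- list(
    n_gsm = report$n_gsm,
    catalog_summary = unclass(report$catalog_summary),
    structure_labels = as.list(report$structure_labels),
    sweep = report$sweep,
    tag_frequency = report$tag_frequency,
    strain_like = report$strain_like,
    triage = report$triage,
    taxonomy = report$taxonomy,
    growth = lapply(report$growth, function(g) {
      if (is.null(g)) NULL else unclass(g)
    }),
    notes = report$notes,
    run = report$run
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report> ", x$n_gsm, " GSMs\n", sep = "")
  cat("  structure labels:",
      paste(names(x$structure_labels), as.integer(x$structure_labels),
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$triage)) {
    cat("  triage:",
        paste(x$triage$label, sprintf("%.1f%%", 100 * x$triage$fraction),
              sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$growth$microarray)) {
    cat("  logistic fit: L=", round(x$growth$microarray$L, 2),
        " k=", round(x$growth$microarray$k, 4),
        " x0=", round(x$growth$microarray$x0, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `gen-corpus`, `report` (runs all audit stages). Invoked
#' from the installed script, e.g.
#' `Rscript -e 'softaudit::softaudit_cli()' report --input corpus.soft --out audit/`.
#'
#' @param args character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
softaudit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: softaudit <command> [options]",
    "commands:",
    "  gen-corpus --out DIR [--n N] [--seed S]",
    "  report     --input PATH [--out DIR] [--k-max K] [--lenient]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  has <- function(flag) flag %in% args
  status <- tryCatch({
    if (cmd == "gen-corpus") {
      outdir <- opt("--out")
      if (is.null(outdir)) stop("gen-corpus requires --out")
      cfg <- corpus_config(n_gsm = as.integer(opt("--n", "1000")),
                           seed = as.integer(opt("--seed", "20260910")))
      generate_corpus(cfg, dir = outdir)
      message("corpus written to ", outdir)
      0L
    } else if (cmd == "report") {
      input <- opt("--input")
      if (is.null(input)) stop("report requires --input")
      rep <- run_audit(input,
                       k_max = as.integer(opt("--k-max", "10")),
                       out = opt("--out"), lenient = has("--lenient"))
      print(rep)
      0L
    } else {
      message(usage)
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
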