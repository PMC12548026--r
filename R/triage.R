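# Raw-data reusability triage for microarray samples.
#
# Microarray raw data lives in per-sample supplementary files whose
# processability depends on the file type and on the platform's
# manufacturer and distribution class. The rules, applied in order:
#   1. unrecoverable  — no supplementary files, OR no manufacturer, OR all
#      files of a nonprocessable type (image/spreadsheet), OR the platform
#      is of noncommercial distribution;
#   2. reusable       — commercial or custom-commercial platform from one
#      of the three major manufacturers with at least one file carrying
#      that manufacturer's standard raw extension
#      (Affymetrix: .cel; Agilent: .txt; NimbleGen: .xys or .pair);
#   3. potentially_reusable — everything else.

NONPROCESSABLE_EXT <- c("tiff", "tif", "jpg", "jpeg", "xls", "xlsx")

MANUFACTURER_EXTENSIONS <- list(
  Affymetrix = "cel",
  Agilent = "txt",
  NimbleGen = c("xys", "pair")
)

#' Categorize a supplementary file by extension
#'
#' Compression suffixes (`.gz`, `.bz2`) are stripped before the terminal
#' extension is extracted and lower-cased. Image and spreadsheet types
#' (.tiff/.tif, .jpg/.jpeg, .xls, .xlsx) are nonprocessable; an absent or
#' empty filename has category `none`; anything else is a candidate for
#' processing.
#'
#' @param filename character vector of file names (may be empty strings).
#' @return data.frame with columns `filename`, `extension`, `category`
#'   (`processable_candidate` / `nonprocessable` / `none`).
#' @export
#' @examples
#' file_category(c("a.CEL.gz", "scan.jpg", ""))
file_category <- function(filename) {
  filename <- as.character(filename)
  base <- sub("\\.(gz|bz2)$", "", filename, ignore.case = TRUE)
  has_ext <- grepl(".", base, fixed = TRUE) & nzchar(trim_ws(base))
  ext <- ifelse(has_ext, tolower(sub(".*\\.", "", base)), "")
  category <- ifelse(!nzchar(trim_ws(filename)), "none",
                     ifelse(ext %in% NONPROCESSABLE_EXT, "nonprocessable",
                            "processable_candidate"))
  data.frame(filename = filename, extension = ext, category = category,
             stringsAsFactors = FALSE)
}

#' Load the bundled manufacturer alias table
#'
#' @param path optional path to a TSV with columns `raw_name`, `canonical`;
#'   defaults to the bundled fixture.
#' @return data.frame with lower-cased `raw_name` keys.
#' @export
load_manufacturer_aliases <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "manufacturer_aliases.tsv",
                        package = "softaudit")
  }
  al <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  al$raw_name <- tolower(trim_ws(al$raw_name))
  if (anyDuplicated(al$raw_name)) {
    stop("alias table validation error: duplicated raw names")
  }
  al
}

#' Normalize a manufacturer name
#'
#' Case-insensitive lookup in the alias table (manufacturer names appear in
#' many variants, e.g. "Affymetrix, Inc.", "Roche NimbleGen"). An unmatched
#' non-empty name maps to `other:<cleaned>`; an empty or absent name to
#' `none`.
#'
#' @param raw character vector of raw manufacturer strings.
#' @param distribution character vector (recycled) of GPL distribution
#'   classes: `commercial`, `custom_commercial`, `noncommercial`, `unknown`.
#' @param aliases alias table from [load_manufacturer_aliases()].
#' @return data.frame with columns `raw_name`, `canonical`, `distribution`.
#' @export
normalize_manufacturer <- function(raw, distribution = "unknown",
                                   aliases = load_manufacturer_aliases()) {
  raw <- as.character(raw)
  raw[is.na(raw)] <- ""
  distribution <- rep_len(as.character(distribution), length(raw))
  distribution[is.na(distribution) |
                 !distribution %in% c("commercial", "custom_commercial",
                                      "noncommercial")] <- "unknown"
  key <- tolower(squish_ws(raw))
  i <- match(key, aliases$raw_name)
  canonical <- ifelse(!nzchar(key), "none",
                      ifelse(!is.na(i), aliases$canonical[i],
                             paste0("other:", squish_ws(raw))))
  distribution[canonical == "none" & distribution == "unknown"] <- "unknown"
  data.frame(raw_name = raw, canonical = canonical,
             distribution = distribution, stringsAsFactors = FALSE)
}

#' Triage one microarray GSM for raw-data reusability
#'
#' Applies the ordered rules described above. Mixed file sets (some
#' nonprocessable, some candidates) are NOT unrecoverable: the
#' all-nonprocessable condition is read literally. An unknown distribution
#' class is not treated as noncommercial; it falls through to rules 2-3.
#'
#' @param gsm a [gsm_record()]; must not be an RNA-seq record.
#' @param manufacturer one row of [normalize_manufacturer()] output (or a
#'   list with `canonical` and `distribution`).
#' @return list of class `triage_result`: `gsm`, `label`, `rule_fired`.
#' @export
triage_gsm <- function(gsm, manufacturer) {
  if (gsm$technology_hint == "rnaseq") {
    stop("triage_gsm() applies to microarray records; ", gsm$accession,
         " is RNA-seq")
  }
  canonical <- manufacturer$canonical[1]
  distribution <- manufacturer$distribution[1]
  files <- file_category(gsm$supplementary_files)
  files <- files[files$category != "none", , drop = FALSE]

  res <- if (!nrow(files)) {
    list(label = "unrecoverable", rule_fired = "no_supplementary_files")
  } else if (canonical == "none") {
    list(label = "unrecoverable", rule_fired = "no_manufacturer")
  } else if (all(files$category == "nonprocessable")) {
    list(label = "unrecoverable", rule_fired = "all_files_nonprocessable")
  } else if (distribution == "noncommercial") {
    list(label = "unrecoverable", rule_fired = "noncommercial_distribution")
  } else if (distribution %in% c("commercial", "custom_commercial") &&
             canonical %in% names(MANUFACTURER_EXTENSIONS) &&
             any(files$extension %in% MANUFACTURER_EXTENSIONS[[canonical]])) {
    list(label = "reusable", rule_fired = "manufacturer_extension_match")
  } else {
    list(label = "potentially_reusable", rule_fired = "fallthrough")
  }
  structure(c(list(gsm = gsm$accession), res,
              list(manufacturer = canonical, distribution = distribution)),
            class = "triage_result")
}

#' Summarize triage results
#'
#' @param results list of [triage_gsm()] results.
#' @param by `"overall"` or `"manufacturer"`.
#' @return data.frame of per-group counts and fractions (fractions sum to 1
#'   within each group).
#' @export
triage_summary <- function(results, by = c("overall", "manufacturer")) {
  by <- match.arg(by)
  lab <- vapply(results, `[[`, character(1), "label")
  grp <- if (by == "overall") rep("overall", length(lab)) else {
    vapply(results, `[[`, character(1), "manufacturer")
  }
  levels <- c("reusable", "potentially_reusable", "unrecoverable")
  tab <- table(factor(grp), factor(lab, levels = levels))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "label", "n")
  tot <- stats::ave(out$n, out$group, FUN = sum)
  out$fraction <- ifelse(tot > 0, out$n / tot, 0)
  out[order(out$group, match(out$label, levels)), , drop = FALSE]
}
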