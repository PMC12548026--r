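# Typed view of a SAMPLE entity: the fields the audit pipeline consumes.

#' Construct a GSM record
#'
#' A light, typed view of one SAMPLE entity. `characteristics` is a list
#' indexed `1..channel_count` holding the raw characteristics strings of
#' each channel (empty character vectors allowed).
#'
#' @param accession GSM accession.
#' @param channel_count integer >= 0.
#' @param characteristics list of character vectors, one per channel.
#' @param organisms,taxids character vectors.
#' @param supplementary_files character vector of file names.
#' @param platform_id,series_ids linkage accessions.
#' @param submission_date a `Date` or `NA`.
#' @param technology_hint one of `"microarray"`, `"rnaseq"`, `"unknown"`.
#' @return object of class `gsm_record`.
#' @export
gsm_record <- function(accession, channel_count = 1L,
                       characteristics = rep(list(character()), channel_count),
                       organisms = character(), taxids = character(),
                       supplementary_files = character(),
                       platform_id = NA_character_, series_ids = character(),
                       submission_date = as.Date(NA),
                       technology_hint = c("unknown", "microarray", "rnaseq")) {
  technology_hint <- match.arg(technology_hint)
  channel_count <- as.integer(channel_count)
  stopifnot(channel_count >= 0L, is.list(characteristics))
  if (length(characteristics) < channel_count) {
    characteristics <- c(characteristics,
                         rep(list(character()),
                             channel_count - length(characteristics)))
  }
  structure(
    list(accession = accession, channel_count = channel_count,
         characteristics = characteristics, organisms = organisms,
         taxids = taxids, supplementary_files = supplementary_files,
         platform_id = platform_id, series_ids = series_ids,
         submission_date = submission_date, technology_hint = technology_hint),
    class = "gsm_record"
  )
}

#' @export
print.gsm_record <- function(x, ...) {
  cat("<gsm_record> ", x$accession, " (", x$technology_hint, "), ",
      x$channel_count, " channel(s), ",
      sum(lengths(x$characteristics)), " characteristics line(s)\n", sep = "")
  invisible(x)
}

# Parse the SOFT date convention "Mon DD YYYY"; NA (with a warning) on failure.
parse_soft_date <- function(x) {
  if (is.null(x) || !length(x) || !nzchar(trim_ws(x[1]))) return(as.Date(NA))
  d <- as.Date(trim_ws(x[1]), format = "%b %d %Y")
  if (is.na(d)) {
    warning("unparseable submission date '", x[1],
            "'; record excluded from growth series", call. = FALSE)
  }
  d
}

attr_values <- function(entity, field) {
  entity$attributes$value[entity$attributes$name == field]
}

#' Convert a SAMPLE entity to a GSM record
#'
#' Channel-suffixed attributes (`characteristics_ch1`, `organism_ch2`, ...)
#' are gathered per channel; enumerated `supplementary_file_<n>` attributes
#' are collected in order. The technology hint derives only from attribute
#' values: presence of `library_strategy`/`library_source` marks RNA-seq,
#' presence of array-specific protocol fields (`label`, `label_protocol`,
#' `hyb_protocol`, `scan_protocol`) marks microarray, otherwise unknown.
#'
#' @param entity a [soft_entity()] of kind SAMPLE.
#' @return a [gsm_record()].
#' @export
as_gsm_record <- function(entity) {
  stopifnot(inherits(entity, "soft_entity"))
  if (entity$entity_kind != "SAMPLE") {
    stop("as_gsm_record() expects a SAMPLE entity, got ", entity$entity_kind)
  }
  att <- entity$attributes
  cc <- suppressWarnings(as.integer(attr_values(entity, "channel_count")[1]))
  ch_fields <- grep("^characteristics_ch[0-9]+$", att$name, value = TRUE)
  ch_idx <- as.integer(sub("^characteristics_ch", "", unique(ch_fields)))
  if (is.na(cc) || !length(cc)) cc <- if (length(ch_idx)) max(ch_idx) else 1L
  chars <- lapply(seq_len(max(cc, 0L)), function(i) {
    att$value[att$name == paste0("characteristics_ch", i)]
  })
  sup <- att$value[grepl("^supplementary_file(_[0-9]+)?$", att$name)]
  sup <- sup[nzchar(trim_ws(sup)) & tolower(trim_ws(sup)) != "none"]
  organisms <- unique(att$value[grepl("^organism(_ch[0-9]+)?$", att$name)])
  taxids <- unique(att$value[grepl("^taxid(_ch[0-9]+)?$", att$name)])
  hint <- if (any(att$name %in% c("library_strategy", "library_source"))) {
    "rnaseq"
  } else if (any(att$name %in% c("label", "label_protocol", "hyb_protocol",
                                 "scan_protocol"))) {
    "microarray"
  } else {
    "unknown"
  }
  gsm_record(
    accession = entity$accession,
    channel_count = max(cc, 0L),
    characteristics = chars,
    organisms = organisms[nzchar(organisms)],
    taxids = taxids[nzchar(taxids)],
    supplementary_files = sup,
    platform_id = attr_values(entity, "platform_id")[1] %||% NA_character_,
    series_ids = attr_values(entity, "series_id"),
    submission_date = parse_soft_date(attr_values(entity, "submission_date")),
    technology_hint = hint
  )
}

#' Extract all GSM records from a document
#'
#' @param doc a [soft_document()].
#' @return list of [gsm_record()] objects.
#' @export
gsm_records <- function(doc) {
  stopifnot(inherits(doc, "soft_document"))
  samples <- Filter(function(e) e$entity_kind == "SAMPLE", doc$entities)
  lapply(samples, as_gsm_record)
}
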