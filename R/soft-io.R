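# Lossless reading and writing of the SOFT plain-text dialect.
#
# SOFT ("Simple Omnibus Format in Text") is a line-oriented format: lines
# beginning "^" open an entity (SAMPLE / SERIES / PLATFORM), lines beginning
# "!" carry attribute = value pairs, "#" lines describe table columns, and
# rows between the *_table_begin / *_table_end markers hold a data table.

SOFT_ENTITY_KINDS <- c("SAMPLE", "SERIES", "PLATFORM")

entity_prefix <- function(kind) {
  switch(kind,
    SAMPLE   = "Sample_",
    SERIES   = "Series_",
    PLATFORM = "Platform_",
    ""
  )
}

#' Construct a SOFT entity
#'
#' @param entity_kind one of `"SAMPLE"`, `"SERIES"`, `"PLATFORM"`.
#' @param accession non-empty accession string (e.g. `"GSM1"`).
#' @param attributes data.frame with character columns `name` (canonical,
#'   lower-case field name), `raw_name` (the attribute name as written in the
#'   file, entity prefix included), and `value`. Row order is the file order;
#'   names may repeat (the attribute set is an ordered multimap).
#' @param table optional list with character vectors `comments` (the `#`
#'   header lines, without the leading `#`) and `rows` (verbatim data rows),
#'   present iff the source had table_begin/table_end delimiters.
#' @return object of class `soft_entity`.
#' @export
soft_entity <- function(entity_kind, accession, attributes = NULL, table = NULL) {
  entity_kind <- toupper(entity_kind)
  if (!entity_kind %in% SOFT_ENTITY_KINDS) {
    stop("unknown entity kind: ", entity_kind)
  }
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession)) {
    stop("accession must be a non-empty string")
  }
  if (is.null(attributes)) {
    attributes <- data.frame(name = character(), raw_name = character(),
                             value = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "raw_name", "value") %in% names(attributes)))
  structure(
    list(entity_kind = entity_kind, accession = accession,
         attributes = attributes, table = table),
    class = "soft_entity"
  )
}

#' Construct a SOFT document
#'
#' @param entities list of [soft_entity()] objects, in file order.
#' @return object of class `soft_document`.
#' @export
soft_document <- function(entities = list()) {
  stopifnot(all(vapply(entities, inherits, logical(1), "soft_entity")))
  structure(list(entities = entities), class = "soft_document")
}

#' @export
print.soft_document <- function(x, ...) {
  kinds <- vapply(x$entities, `[[`, character(1), "entity_kind")
  cat("<soft_document> ", length(x$entities), " entities (",
      paste(sprintf("%s: %d", names(table(kinds)), as.integer(table(kinds))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
print.soft_entity <- function(x, ...) {
  cat("<soft_entity> ", x$entity_kind, " ", x$accession, ", ",
      nrow(x$attributes), " attributes",
      if (!is.null(x$table)) paste0(", table of ", length(x$table$rows), " rows"),
      "\n", sep = "")
  invisible(x)
}

#' Canonicalize a SOFT attribute name
#'
#' Strips the entity prefix (`Sample_`, `Series_`, `Platform_`,
#' case-insensitively) and lower-cases the remainder. Idempotent.
#'
#' @param raw_name attribute name as written after the `!`.
#' @return canonical field name.
#' @export
#' @examples
#' canonical_field_name("Sample_channel_count")
canonical_field_name <- function(raw_name) {
  tolower(sub("^(sample_|series_|platform_)", "", raw_name, ignore.case = TRUE))
}

#' Parse SOFT text into a document
#'
#' Every line starting with `^` opens a new entity (`^KIND = ACCESSION`).
#' Lines starting with `!` are attribute lines split at the FIRST `=` with
#' surrounding whitespace trimmed; values may themselves contain `=`.
#' `#` lines and the rows between the `*_table_begin` / `*_table_end`
#' attribute markers become the entity's table. Unknown or undocumented
#' attribute names are preserved verbatim, never rejected. Blank lines are
#' ignored.
#'
#' @param text a single string, or a character vector of lines.
#' @return a [soft_document()].
#' @export
#' @examples
#' doc <- parse_soft("^SAMPLE = GSM1\n!Sample_channel_count = 1")
#' doc$entities[[1]]$attributes
parse_soft <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }

  entities <- list()
  cur <- NULL
  in_table <- FALSE
  table_comments <- character()
  table_rows <- character()

  flush_entity <- function(cur) {
    if (is.null(cur)) return(NULL)
    attrs <- data.frame(
      name = as.character(cur$name), raw_name = as.character(cur$raw_name),
      value = as.character(cur$value), stringsAsFactors = FALSE
    )
    soft_entity(cur$kind, cur$accession, attrs, cur$table)
  }

  for (ln in lines) {
    if (!nzchar(trim_ws(ln))) next
    first <- substr(ln, 1L, 1L)
    if (first == "^") {
      if (in_table) stop("structural error: table_begin without table_end")
      if (!is.null(cur)) entities[[length(entities) + 1L]] <- flush_entity(cur)
      body <- substr(ln, 2L, nchar(ln))
      eq <- regexpr("=", body, fixed = TRUE)
      if (eq < 0L) stop("structural error: malformed entity line: ", ln)
      kind <- toupper(trim_ws(substr(body, 1L, eq - 1L)))
      acc <- trim_ws(substr(body, eq + 1L, nchar(body)))
      if (!nzchar(acc)) stop("structural error: empty accession in: ", ln)
      cur <- list(kind = kind, accession = acc, name = character(),
                  raw_name = character(), value = character(), table = NULL)
      table_comments <- character()
    } else if (first == "!") {
      if (is.null(cur)) {
        stop("structural error: attribute line before any entity line: ", ln)
      }
      body <- substr(ln, 2L, nchar(ln))
      eq <- regexpr("=", body, fixed = TRUE)
      raw_name <- trim_ws(if (eq > 0L) substr(body, 1L, eq - 1L) else body)
      value <- if (eq > 0L) trim_ws(substr(body, eq + 1L, nchar(body))) else ""
      canon <- canonical_field_name(raw_name)
      if (canon == "table_begin") {
        if (in_table) stop("structural error: nested table_begin")
        in_table <- TRUE
        table_rows <- character()
      } else if (canon == "table_end") {
        if (!in_table) stop("structural error: table_end without table_begin")
        in_table <- FALSE
        cur$table <- list(comments = table_comments, rows = table_rows)
      } else {
        if (in_table) stop("structural error: attribute line inside table")
        cur$name <- c(cur$name, canon)
        cur$raw_name <- c(cur$raw_name, raw_name)
        cur$value <- c(cur$value, value)
      }
    } else if (first == "#") {
      if (is.null(cur)) {
        stop("structural error: column-description line before any entity line")
      }
      table_comments <- c(table_comments, substr(ln, 2L, nchar(ln)))
    } else {
      if (is.null(cur)) {
        stop("structural error: data row before any entity line")
      }
      if (!in_table) {
        stop("structural error: data row outside table_begin/table_end: ", ln)
      }
      table_rows <- c(table_rows, ln)
    }
  }
  if (in_table) stop("structural error: table_begin without table_end")
  if (!is.null(cur)) entities[[length(entities) + 1L]] <- flush_entity(cur)
  soft_document(entities)
}

#' Read a SOFT file
#'
#' Plain text or gzip-compressed (`.gz`) files are both accepted; input is
#' read line-wise.
#'
#' @param path file path.
#' @return a [soft_document()].
#' @export
read_soft <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  parse_soft(readLines(con, warn = FALSE))
}

#' Serialize a SOFT document
#'
#' Emits the same dialect accepted by [parse_soft()]. For documents produced
#' by [parse_soft()] on normalized input (single spaces around `=`) the
#' output is bit-exact; in general, `parse_soft(write_soft(parse_soft(t)))`
#' equals `parse_soft(t)`.
#'
#' @param doc a [soft_document()].
#' @param path optional file path; when given, the text is written there
#'   (gzip if the path ends in `.gz`) and returned invisibly.
#' @return the serialized text as a single string.
#' @export
write_soft <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "soft_document"))
  out <- character()
  for (e in doc$entities) {
    out <- c(out, paste0("^", e$entity_kind, " = ", e$accession))
    if (nrow(e$attributes)) {
      out <- c(out, paste0("!", e$attributes$raw_name, " = ", e$attributes$value))
    }
    if (!is.null(e$table)) {
      pre <- entity_prefix(e$entity_kind)
      out <- c(out,
               if (length(e$table$comments)) paste0("#", e$table$comments),
               paste0("!", pre, "table_begin"),
               e$table$rows,
               paste0("!", pre, "table_end"))
    }
  }
  text <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(out, con)
    return(invisible(text))
  }
  text
}

#' Export one entity as a hierarchical key-value (YAML) document
#'
#' Attributes that repeat (e.g. `supplementary_file`) become lists; when a
#' field catalog is supplied, attributes are grouped under their field class
#' (`biological` / `database` / `technical` / `unknown`) to make the export
#' self-describing.
#'
#' @param entity a [soft_entity()].
#' @param catalog optional field catalog data.frame (see
#'   [load_field_catalog()]); used only for grouping.
#' @return YAML text (single string).
#' @export
soft_to_yaml <- function(entity, catalog = NULL) {
  stopifnot(inherits(entity, "soft_entity"))
  attrs <- entity$attributes
  fold <- function(df) {
    if (!nrow(df)) return(structure(list(), names = character()))
    sp <- split(df$value, factor(df$name, levels = unique(df$name)))
    lapply(sp, function(v) if (length(v) == 1L) v else as.list(v))
  }
  doc <- list(entity = entity$entity_kind, accession = entity$accession)
  if (is.null(catalog) || !nrow(attrs)) {
    doc$attributes <- fold(attrs)
  } else {
    cls <- classify_fields(attrs$name, catalog)
    grp <- ifelse(cls$field_class == "unknown" | is.na(cls$field_class),
                  "unknown", cls$field_class)[match(attrs$name, cls$name)]
    doc$attributes <- lapply(split(attrs, factor(grp, levels = unique(grp))), fold)
  }
  yaml::as.yaml(doc)
}
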