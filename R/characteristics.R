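# Structuredness audit of the "characteristics" sample annotation field.
#
# The field is intended to carry <tag>:<value> pairs describing the
# biological source. A sample is "putative structured" at stringency k when
# every one of its pairs parses as <tag>:<value> with at most k words on
# each side; samples with no characteristics content at all are "empty",
# the rest "not structured". Unbounded stringency is expressed as k = Inf.

#' Parse one characteristics string into a tag:value pair
#'
#' The string is split at the first `": "` (colon + space) when present,
#' otherwise at the first `:`; both sides are trimmed. The pair parses only
#' when both sides are non-empty after trimming. Unparseable input returns
#' `parsed = FALSE`, never an error. The colon+space preference avoids
#' false splits inside URLs and clock times appearing in values.
#'
#' @param raw character vector of characteristics strings.
#' @return data.frame with columns `raw`, `tag`, `value`, `tag_words`,
#'   `value_words`, `parsed` (one row per input).
#' @export
#' @examples
#' parse_characteristics(c("strain: MG1655", "grown overnight in LB",
#'                         "source: http://x.org/a"))
parse_characteristics <- function(raw) {
  raw <- as.character(raw)
  split_one <- function(s) {
    pos <- regexpr(": ", s, fixed = TRUE)
    if (pos < 0L) pos <- regexpr(":", s, fixed = TRUE)
    if (pos < 0L) return(c(NA_character_, NA_character_))
    c(substr(s, 1L, pos - 1L), substr(s, pos + attr(pos, "match.length"), nchar(s)))
  }
  parts <- vapply(raw, split_one, character(2), USE.NAMES = FALSE)
  tag <- trim_ws(parts[1L, ])
  value <- trim_ws(parts[2L, ])
  parsed <- !is.na(tag) & nzchar(tag) & !is.na(value) & nzchar(value)
  tag[!parsed] <- NA_character_
  value[!parsed] <- NA_character_
  data.frame(
    raw = raw, tag = tag, value = value,
    tag_words = ifelse(parsed, word_count(ifelse(parsed, tag, "")), 0L),
    value_words = ifelse(parsed, word_count(ifelse(parsed, value, "")), 0L),
    parsed = parsed, stringsAsFactors = FALSE
  )
}

all_characteristics <- function(gsm) {
  x <- unlist(gsm$characteristics, use.names = FALSE)
  x[!is.na(x) & nzchar(trim_ws(x))]
}

#' Classify one GSM's characteristics structuredness
#'
#' @param gsm a [gsm_record()].
#' @param k_tag,k_value maximum words allowed in tag and value
#'   (`Inf` = unbounded); joint stringency uses `k_tag == k_value`.
#' @return list with `gsm`, `label` (one of `"empty"`,
#'   `"putative_structured"`, `"not_structured"`), `k_tag`, `k_value`.
#' @export
classify_gsm <- function(gsm, k_tag = Inf, k_value = k_tag) {
  stopifnot(k_tag >= 1, k_value >= 1)
  strings <- all_characteristics(gsm)
  label <- if (!length(strings)) {
    "empty"
  } else {
    p <- parse_characteristics(strings)
    if (all(p$parsed) && all(p$tag_words <= k_tag) &&
        all(p$value_words <= k_value)) "putative_structured" else "not_structured"
  }
  list(gsm = gsm$accession, label = label, k_tag = k_tag, k_value = k_value)
}

classify_all <- function(gsms, k_tag = Inf, k_value = k_tag) {
  vapply(gsms, function(g) classify_gsm(g, k_tag, k_value)$label, character(1))
}

#' Sweep the word-count stringency
#'
#' Classifies every GSM at joint stringencies k = 1..k_max (tag and value
#' limits equal). The empty count is constant in k; the putative-structured
#' count is non-decreasing (relaxing the limit only admits samples).
#'
#' @param gsms list of [gsm_record()] objects.
#' @param k_max largest stringency to evaluate.
#' @param unbounded also append a row for k = Inf.
#' @return data.frame with columns `k`, `n_empty`, `n_structured`,
#'   `n_not_structured`.
#' @export
stringency_sweep <- function(gsms, k_max, unbounded = FALSE) {
  stopifnot(k_max >= 1)
  # one parse per GSM; per-k classification reuses the word counts
  per_gsm <- lapply(gsms, function(g) {
    s <- all_characteristics(g)
    if (!length(s)) return(NULL)
    p <- parse_characteristics(s)
    list(all_parsed = all(p$parsed),
         max_words = if (all(p$parsed)) max(p$tag_words, p$value_words) else Inf)
  })
  ks <- c(seq_len(k_max), if (unbounded) Inf)
  rows <- lapply(ks, function(k) {
    lab <- vapply(per_gsm, function(x) {
      if (is.null(x)) return("empty")
      if (x$all_parsed && x$max_words <= k) "putative_structured" else "not_structured"
    }, character(1))
    data.frame(k = k, n_empty = sum(lab == "empty"),
               n_structured = sum(lab == "putative_structured"),
               n_not_structured = sum(lab == "not_structured"))
  })
  do.call(rbind, rows)
}

canonical_tag <- function(tag) squish_ws(tolower(tag))

#' Build the GSM-by-tag characteristics table
#'
#' Rows are the supplied putative-structured GSMs, columns the union of
#' canonical tags (case-folded, internal whitespace collapsed). A duplicate
#' tag within one GSM keeps the first value (a collision warning is
#' issued); an absent tag is a missing (`NA`) cell. Values are not
#' canonicalized.
#'
#' @param gsms list of [gsm_record()] objects, all classifying
#'   `putative_structured` at the chosen stringency.
#' @param k_tag,k_value the stringency the inputs were classified at
#'   (checked as a precondition).
#' @return list of class `characteristics_table`: `matrix` (character,
#'   rows = GSMs, cols = tags), `column_missing_fraction`, `n_collisions`.
#' @export
build_table <- function(gsms, k_tag = Inf, k_value = k_tag) {
  labels <- classify_all(gsms, k_tag, k_value)
  if (any(labels != "putative_structured")) {
    stop("build_table() requires putative_structured inputs; offending GSMs: ",
         paste(vapply(gsms[labels != "putative_structured"], `[[`,
                      character(1), "accession"), collapse = ", "))
  }
  pairs <- lapply(gsms, function(g) {
    p <- parse_characteristics(all_characteristics(g))
    p$tag <- canonical_tag(p$tag)
    p
  })
  acc <- vapply(gsms, `[[`, character(1), "accession")
  tags <- unique(unlist(lapply(pairs, `[[`, "tag"), use.names = FALSE))
  m <- matrix(NA_character_, nrow = length(gsms), ncol = length(tags),
              dimnames = list(acc, tags))
  n_coll <- 0L
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    dup <- duplicated(p$tag)
    if (any(dup)) {
      n_coll <- n_coll + sum(dup)
      warning("duplicate tag(s) within ", acc[i], ": ",
              paste(unique(p$tag[dup]), collapse = ", "),
              " (keeping first value)", call. = FALSE)
      p <- p[!dup, , drop = FALSE]
    }
    m[i, p$tag] <- p$value
  }
  structure(
    list(matrix = m,
         column_missing_fraction = colMeans(is.na(m)),
         n_collisions = n_coll),
    class = "characteristics_table"
  )
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat("<characteristics_table> ", nrow(x$matrix), " GSMs x ",
      ncol(x$matrix), " tags; median column missingness ",
      round(100 * stats::median(x$column_missing_fraction), 1), "%\n", sep = "")
  invisible(x)
}

#' Rank tags by the percentage of GSMs carrying them
#'
#' @param table a [build_table()] result.
#' @param top return at most this many rows (default all).
#' @return data.frame with columns `tag`, `pct_gsms`, sorted by decreasing
#'   percentage, ties broken lexicographically.
#' @export
tag_frequency <- function(table, top = Inf) {
  m <- table$matrix
  if (!nrow(m) || !ncol(m)) {
    return(data.frame(tag = character(), pct_gsms = numeric()))
  }
  pct <- 100 * colSums(!is.na(m)) / nrow(m)
  out <- data.frame(tag = colnames(m), pct_gsms = unname(pct),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct_gsms, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top)
}

#' Find strain-like tags
#'
#' A tag is strain-like when its case-folded form contains the token
#' "strain" at word boundaries after punctuation is stripped, so
#' `"Strain name"` matches but `"constraint"` does not. The matching rule
#' is a declared policy of this package.
#'
#' @param tags character vector of (canonical) tag names.
#' @return list with `tags` (the strain-like subset) and `proportion`
#'   (share of all supplied tags).
#' @export
strain_like_tags <- function(tags) {
  tags <- unique(tags)
  tokenized <- gsub("[[:punct:]]", " ", tolower(tags))
  hit <- grepl("(^| )strain( |$)", squish_ws(tokenized))
  list(tags = tags[hit],
       proportion = if (length(tags)) sum(hit) / length(tags) else NaN)
}
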