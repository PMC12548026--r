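# Internal helpers shared across modules.

trim_ws <- function(x) {
  gsub("^[[:space:]]+|[[:space:]]+$", "", x)
}

#' Count words in a string
#'
#' A word is a maximal run of non-whitespace characters. The empty string
#' (and whitespace-only strings) contain zero words.
#'
#' @param x character vector.
#' @return integer vector of word counts.
#' @export
#' @examples
#' word_count(c("strain", "LB medium  broth", "", "  "))
word_count <- function(x) {
  x <- trim_ws(x)
  out <- lengths(strsplit(x, "[[:space:]]+"))
  out[!nzchar(x)] <- 0L
  as.integer(out)
}

# Collapse internal whitespace runs to single spaces and trim.
squish_ws <- function(x) {
  trim_ws(gsub("[[:space:]]+", " ", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible 31-bit sub-seed for an independent random substream.
# A small multiplicative hash over (seed, unit, aspect): changing the draws
# made under one aspect never perturbs another aspect's stream.
substream_seed <- function(seed, unit, aspect) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  aspect_id <- if (is.character(aspect)) {
    sum(utf8ToInt(aspect) * seq_along(utf8ToInt(aspect))) %% 100003L
  } else {
    as.integer(aspect)
  }
  h <- (as.double(seed) %% 2147483647) + 1
  h <- (h * 48271 + as.double(unit) * 16807 + aspect_id * 69621) %% 2147483647
  h <- (h * 48271 + 12345) %% 2147483647
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded from a substream; the
# caller's RNG state is untouched.
with_substream <- function(seed, unit, aspect, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, unit, aspect))
  expr
}
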