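#' @keywords internal
"_PACKAGE"

## Canonical topic inventory used throughout the package. Extensible lexicons
## may declare other topics, but the canonical profile validates against these 8.
CANONICAL_TOPICS <- c(
  "symptoms", "medication", "nutrition", "procedures",
  "marijuana", "stigma", "ostomy", "intimacy"
)

#' Canonical IBD topic names
#'
#' The eight non-mutually-exclusive IBD discussion topics the package
#' classifies: symptoms, medication, nutrition, procedures, marijuana,
#' stigma, ostomy, intimacy.
#'
#' @return Character vector of length 8.
#' @export
canonical_topics <- function() CANONICAL_TOPICS

## URL pattern shared by the tokenizer and the hyperlink counter.
.url_regex <- "(?:https?://|www\\.)[^[:space:]]+"

## Sentinel emitted for URL spans; cannot collide with alphanumeric tokens.
.url_sentinel <- "<url>"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half up
#'
#' Rounds to the nearest integer with halves going up (0.5 -> 1, 1.5 -> 2),
#' the convention used for all reported integer percentages. Base R's
#' `round()` uses banker's rounding, which does not reproduce printed
#' percentage tables.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
round_half_up <- function(x) floor(x + 0.5)

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so package functions never perturb global randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## sample() mis-handles length-1 x; this always treats x as the urn.
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

stop_data <- function(...) stop(..., call. = FALSE)
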