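#' Experimental-condition vocabulary
#'
#' Evidence pairs are tagged with the experimental condition under which the
#' supporting experiments were performed. The default vocabulary holds the
#' nine condition classes used for curated yeast TF-gene evidence, for
#' example `"nitrogen source quality/availability"` for nitrogen catabolite
#' regulation. Two labels are reserved and always appended: `"any"` (a query
#' label meaning "no condition filter", never a tag on data) and
#' `"unclassified"` (the bucket for tags that match no vocabulary entry).
#'
#' @param labels Character vector of condition names. Must be non-empty and
#'   unique after case-folding.
#' @return A character vector of canonical labels with the reserved labels
#'   `"any"` and `"unclassified"` appended (class `"trp_vocabulary"`).
#' @examples
#' condition_vocabulary()
#' condition_vocabulary(c("heat shock", "cold shock"))
#' @export
condition_vocabulary <- function(labels = default_condition_labels()) {
  labels <- trimws(as.character(labels))
  labels <- labels[!labels %in% reserved_condition_labels()]
  if (length(labels) == 0) {
    abort("condition vocabulary needs at least one non-reserved label",
          class = "trp_format_error")
  }
  if (anyDuplicated(tolower(labels))) {
    abort("condition vocabulary labels must be unique (case-insensitively)",
          class = "trp_format_error")
  }
  structure(c(labels, reserved_condition_labels()), class = "trp_vocabulary")
}

#' @rdname condition_vocabulary
#' @export
default_condition_labels <- function() {
  c(
    "cycle/morphology",
    "stress",
    "oxygen availability",
    "unstressed log-phase growth (control)",
    "nitrogen source quality/availability",
    "carbon source quality/availability",
    "ion/metal/phosphate/sulfur/vitamin availability",
    "lipid supplementation",
    "complex industrial media"
  )
}

reserved_condition_labels <- function() c("any", "unclassified")

#' Map free-text condition tags onto a vocabulary
#'
#' Matching is case-insensitive on the trimmed label. Tags that match no
#' vocabulary entry are mapped to `"unclassified"` with a warning rather than
#' an error: real exports carry idiosyncratic spellings and strictness would
#' reject them.
#'
#' @param tags Character vector of free-text condition tags.
#' @param vocabulary A [condition_vocabulary()].
#' @param warn_unmatched Emit one warning listing unmatched tags?
#' @return Character vector of canonical labels, same length as `tags`.
#' @export
match_conditions <- function(tags, vocabulary = condition_vocabulary(),
                             warn_unmatched = TRUE) {
  if (length(tags) == 0) return(character())
  tags <- trimws(as.character(tags))
  idx <- match(tolower(tags), tolower(vocabulary))
  if (warn_unmatched && anyNA(idx)) {
    warn(paste0("condition tag(s) not in vocabulary, mapped to 'unclassified': ",
                paste(unique(tags[is.na(idx)]), collapse = ", ")),
         class = "trp_condition_warning")
  }
  out <- vocabulary[idx]
  out[is.na(idx)] <- "unclassified"
  unclass(out)
}

# Canonicalize a single queried condition label against the vocabulary.
# "any" passes through; an unknown query label is an error (a query typo
# should not silently return an empty result).
canonical_condition <- function(condition, vocabulary = condition_vocabulary()) {
  stopifnot(length(condition) == 1)
  condition <- trimws(as.character(condition))
  i <- match(tolower(condition), tolower(vocabulary))
  if (is.na(i)) {
    abort(paste0("unknown condition label: '", condition, "'"),
          class = "trp_query_error")
  }
  unclass(vocabulary[i])
}
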