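#' Evidence-pair tables
#'
#' The package's central input is a tidy table of TF-gene evidence pairs,
#' one row per (TF, target, evidence kind) with set-valued condition tags and
#' publication identifiers held in list-columns. Two evidence kinds exist:
#'
#' * `"TFB"` — TF-gene *binding* evidence: the TF binds the target gene's
#'   promoter (ChIP-chip, band-shift, footprinting).
#' * `"TFR"` — TF-gene *regulation* evidence: perturbing (deleting or
#'   overexpressing) the TF significantly changes the target's expression
#'   (TF perturbation experiments, gene-by-gene analysis).
#'
#' `as_evidence_pairs()` validates and normalizes a data frame into this
#' shape: symbols are upper-cased (`Gln3` and `GLN3` unify to `GLN3` — yeast
#' protein names are capitalization variants of gene names, so one canonical
#' key prevents silent query misses), rows with the same (tf, target,
#' evidence_kind) are merged with their condition and publication sets
#' unioned, and set elements are sorted for deterministic output.
#'
#' @param x A data frame with columns `tf`, `target` (character), optionally
#'   `evidence_kind` (`"TFB"`/`"TFR"`), `conditions` and `publications`
#'   (character list-columns, or `";"`-separated character columns).
#' @param default_kind Evidence kind assigned to rows lacking an
#'   `evidence_kind` column.
#' @param vocabulary A [condition_vocabulary()] used to canonicalize
#'   condition tags.
#' @return A tibble with columns `tf`, `target`, `evidence_kind`,
#'   `conditions` (list of character), `publications` (list of character),
#'   sorted by (tf, target, evidence_kind).
#' @examples
#' as_evidence_pairs(data.frame(
#'   tf = c("Gln3", "GLN3"), target = c("gat1", "GAT1"),
#'   evidence_kind = "TFR", publications = c("P1", "P2")
#' ))
#' @export
as_evidence_pairs <- function(x, default_kind = NULL,
                              vocabulary = condition_vocabulary()) {
  x <- as_tibble(x)
  for (col in c("tf", "target")) {
    if (!col %in% names(x)) {
      abort(paste0("evidence table is missing mandatory column '", col, "'"),
            class = "trp_format_error")
    }
  }
  if (!"evidence_kind" %in% names(x)) {
    if (is.null(default_kind)) {
      abort("evidence table has no 'evidence_kind' column and no default_kind was given",
            class = "trp_format_error")
    }
    x$evidence_kind <- default_kind
  }
  x$evidence_kind[is.na(x$evidence_kind) | x$evidence_kind == ""] <-
    default_kind %||% NA_character_
  bad <- !x$evidence_kind %in% c("TFB", "TFR")
  if (any(bad)) {
    abort(paste0("unknown evidence_kind value(s) in row(s) ",
                 paste(utils::head(which(bad), 5), collapse = ", "),
                 ": ", paste(unique(x$evidence_kind[bad]), collapse = ", "),
                 " (expected TFB or TFR)"),
          class = "trp_format_error")
  }

  x$tf <- normalize_symbol(x$tf)
  x$target <- normalize_symbol(x$target)
  if (any(x$tf == "" | x$target == "")) {
    abort("tf and target symbols must be non-empty", class = "trp_format_error")
  }

  x$conditions <- as_set_column(x[["conditions"]], nrow(x))
  x$conditions <- lapply(x$conditions, function(tags) {
    sort(unique(match_conditions(tags, vocabulary)))
  })

  pubs <- as_set_column(x[["publications"]], nrow(x))
  missing_pubs <- lengths(pubs) == 0
  if (any(missing_pubs)) {
    warn(paste0(sum(missing_pubs), " row(s) lacked publication identifiers; ",
                "assigned synthetic ids UNSPEC:<row#>"),
         class = "trp_publication_warning")
    pubs[missing_pubs] <- lapply(which(missing_pubs),
                                 function(i) paste0("UNSPEC:", i))
  }
  x$publications <- pubs

  x %>%
    dplyr::select("tf", "target", "evidence_kind", "conditions", "publications") %>%
    dplyr::group_by(.data$tf, .data$target, .data$evidence_kind) %>%
    dplyr::summarise(
      conditions = list(sort(unique(unlist(.data$conditions)))),
      publications = list(sort(unique(unlist(.data$publications)))),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$tf, .data$target, .data$evidence_kind)
}

#' Normalize TF/gene symbols to their canonical upper-case form
#'
#' @param x Character vector of symbols.
#' @return Upper-cased, whitespace-trimmed character vector.
#' @export
normalize_symbol <- function(x) toupper(trimws(as.character(x)))

# Coerce a column that may be absent, a ';'-separated character column, or a
# list-column into a list of character sets.
as_set_column <- function(col, n) {
  if (is.null(col)) return(rep(list(character()), n))
  if (is.list(col)) {
    return(lapply(col, function(v) {
      v <- trimws(as.character(v))
      v[!is.na(v) & v != ""]
    }))
  }
  col <- as.character(col)
  lapply(col, function(cell) {
    if (is.na(cell) || cell == "") return(character())
    v <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
    v[v != ""]
  })
}

# Keep rows of an evidence-pair table whose condition tags satisfy the
# queried condition under the given policy. condition must already be
# canonical. Policy "any": the label is among the pair's tags; "all": the
# pair is tagged and every tag is the label.
filter_condition <- function(pairs, condition, policy = c("any", "all")) {
  policy <- match.arg(policy)
  if (condition == "any") return(pairs)
  keep <- vapply(pairs$conditions, function(tags) {
    if (policy == "any") condition %in% tags
    else length(tags) > 0 && all(tags == condition)
  }, logical(1))
  pairs[keep, , drop = FALSE]
}

check_kind <- function(pairs, kind) {
  if (nrow(pairs) > 0 && !all(pairs$evidence_kind == kind)) {
    abort(paste0("evidence kind mismatch: expected all rows to be ", kind),
          class = "trp_kind_error")
  }
  invisible(pairs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
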