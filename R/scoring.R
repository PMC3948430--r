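#' Evidence indices for scoring
#'
#' An evidence index is the set of (tf, target) keys carrying a given
#' evidence kind under a condition, with distinct-publication counts. The
#' index used to score a pathway is condition-filtered identically to the
#' network the pathway was mined from; pass `condition = "any"` for a
#' global, unfiltered index.
#'
#' @param pairs Evidence-pair tibble of the matching kind.
#' @param kind `"TFR"` or `"TFB"`.
#' @inheritParams trp_network
#' @return A tibble with columns `tf`, `target`, `n_pubs`, `publications`.
#' @export
evidence_index <- function(pairs, kind = c("TFR", "TFB"), condition = "any",
                           vocabulary = condition_vocabulary(),
                           policy = c("any", "all")) {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  check_kind(pairs, kind)
  condition <- canonical_condition(condition, vocabulary)
  p <- filter_condition(pairs, condition, policy)
  tibble(tf = p$tf, target = p$target,
         n_pubs = lengths(p$publications),
         publications = p$publications) %>%
    dplyr::arrange(.data$tf, .data$target)
}

#' Confidence score of a pathway
#'
#' The confidence score is the proportion of ordered TF-gene pairs along the
#' direction of the pathway (see [pairs_along()]) that possess TFR evidence.
#' A score of 1 (reported as 100% in user-facing output) means the
#' perturbation of every upstream TF in the pathway is documented to
#' influence every downstream member — the pathway is fully experimentally
#' supported.
#'
#' @param nodes Pathway nodes (character vector or one-row pathway tibble).
#' @param tfr_index A TFR [evidence_index()].
#' @return A fraction in `[0, 1]`.
#' @export
confidence_score <- function(nodes, tfr_index) {
  pe <- pairs_along(nodes)
  mean(pair_key(pe$upstream, pe$downstream) %in%
         pair_key(tfr_index$tf, tfr_index$target))
}

pair_key <- function(tf, target) paste(tf, target, sep = "\r")

#' Annotate a pathway with per-pair experimental evidence
#'
#' For every ordered pair along the pathway, records whether TFR and TFB
#' evidence exists, the distinct-publication counts, and the field's label
#' for the pair: a pair with both evidence kinds is a *direct regulatory
#' pair*, one with TFR evidence only is an *indirect regulatory target
#' pair*; pairs with TFB only or neither are labeled accordingly.
#'
#' @inheritParams confidence_score
#' @param tfb_index A TFB [evidence_index()] (condition-consistent with
#'   `tfr_index`).
#' @return An object of class `trp_annotation`: list with `nodes`,
#'   `confidence`, and `pair_evidence` (tibble: `upstream`, `downstream`,
#'   `has_tfr`, `has_tfb`, `tfr_count`, `tfb_count`, `label`). Status is
#'   filled in by [classify_trp()].
#' @export
annotate_path <- function(nodes, tfr_index, tfb_index) {
  nodes <- path_nodes(nodes)
  pe <- pairs_along(nodes)
  key <- pair_key(pe$upstream, pe$downstream)
  ri <- match(key, pair_key(tfr_index$tf, tfr_index$target))
  bi <- match(key, pair_key(tfb_index$tf, tfb_index$target))
  pe$has_tfr <- !is.na(ri)
  pe$has_tfb <- !is.na(bi)
  pe$tfr_count <- ifelse(pe$has_tfr, tfr_index$n_pubs[ri], 0L)
  pe$tfb_count <- ifelse(pe$has_tfb, tfb_index$n_pubs[bi], 0L)
  pe$label <- dplyr::case_when(
    pe$has_tfr & pe$has_tfb ~ "direct regulatory pair",
    pe$has_tfr ~ "indirect regulatory target pair",
    pe$has_tfb ~ "binding-only pair",
    TRUE ~ "unsupported pair"
  )
  structure(
    list(nodes = nodes, confidence = mean(pe$has_tfr), pair_evidence = pe,
         status = NA_character_, supporting = character()),
    class = "trp_annotation"
  )
}

#' @export
print.trp_annotation <- function(x, ...) {
  cat(sprintf("<trp_annotation: %s>\n", paste(x$nodes, collapse = " -> ")))
  cat(sprintf("  confidence %.1f%%; status: %s\n", 100 * x$confidence,
              ifelse(is.na(x$status), "(unclassified)", x$status)))
  print(x$pair_evidence)
  invisible(x)
}

#' @export
tidy.trp_annotation <- function(x, ...) x$pair_evidence

#' Classify a pathway as known or putative against an abstract corpus
#'
#' A pathway is *known* when at least one literature abstract mentions every
#' one of its member TFs/genes, matched case-insensitively as whole words
#' (word boundaries at non-alphanumerics, so `GAT1` never matches `GAT12`;
#' both the gene form `GZF3` and the protein form `Gzf3` match). Otherwise
#' it is *putative*. All matching abstracts are returned as supporting
#' literature.
#'
#' @inheritParams confidence_score
#' @param corpus A tibble with columns `publication_id` and `text` (see
#'   [read_abstract_corpus()]); may be empty.
#' @return A list with `status` (`"known"`/`"putative"`) and `supporting`
#'   (character vector of publication ids, empty iff putative).
#' @export
classify_trp <- function(nodes, corpus) {
  nodes <- path_nodes(nodes)
  if (is.null(corpus) || nrow(corpus) == 0) {
    return(list(status = "putative", supporting = character()))
  }
  hits <- rep(TRUE, nrow(corpus))
  for (sym in unique(nodes)) {
    pat <- paste0("(?<![A-Za-z0-9])", escape_regex(sym), "(?![A-Za-z0-9])")
    hits <- hits & grepl(pat, corpus$text, perl = TRUE, ignore.case = TRUE)
  }
  supporting <- sort(corpus$publication_id[hits])
  list(status = if (length(supporting) > 0) "known" else "putative",
       supporting = supporting)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

#' Annotate, score and curate a set of mined pathways
#'
#' Tidy wrapper applying [annotate_path()], [confidence_score()] and
#' [classify_trp()] across a pathway tibble.
#'
#' @param paths A pathway tibble from [enumerate_all_trps()] or
#'   [enumerate_shortest_trps()].
#' @inheritParams annotate_path
#' @inheritParams classify_trp
#' @return `paths` with added columns `confidence` (fraction), `status`,
#'   `supporting` (list of publication ids) and `pair_evidence` (list of
#'   per-pair evidence tibbles).
#' @export
annotate_trps <- function(paths, tfr_index, tfb_index, corpus = NULL) {
  ann <- lapply(paths$nodes, annotate_path, tfr_index = tfr_index,
                tfb_index = tfb_index)
  cls <- lapply(paths$nodes, classify_trp, corpus = corpus)
  paths$confidence <- vapply(ann, `[[`, numeric(1), "confidence")
  paths$status <- vapply(cls, `[[`, character(1), "status")
  paths$supporting <- lapply(cls, `[[`, "supporting")
  paths$pair_evidence <- lapply(ann, `[[`, "pair_evidence")
  paths
}
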