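#' Read a TF-gene evidence-pair table
#'
#' The table dialect is UTF-8 tab-separated text with a header row,
#' `#`-prefixed comment lines ignored, and `;` as the in-cell list separator.
#' Mandatory columns are `tf` and `target`; optional columns are
#' `evidence_kind` (`TFB`/`TFR`), `conditions` and `publications`
#' (`;`-separated). Rows are normalized and merged via [as_evidence_pairs()]:
#' duplicate (tf, target, kind) rows have their condition and publication
#' sets unioned, and rows without publications receive a synthetic
#' `UNSPEC:<row#>` identifier with a warning.
#'
#' @param path Path to a TSV file.
#' @param default_kind Evidence kind for files lacking an `evidence_kind`
#'   column (e.g. a pure binding-pair export).
#' @param vocabulary A [condition_vocabulary()].
#' @return An evidence-pair tibble (see [as_evidence_pairs()]).
#' @export
read_pair_table <- function(path, default_kind = NULL,
                            vocabulary = condition_vocabulary()) {
  x <- read_tsv_dialect(path)
  if (nrow(x) == 0) {
    abort(paste0("evidence table is empty: ", path), class = "trp_format_error")
  }
  as_evidence_pairs(x, default_kind = default_kind, vocabulary = vocabulary)
}

#' Write an evidence-pair table
#'
#' Inverse of [read_pair_table()]: `read_pair_table(write_pair_table(x, p))`
#' reproduces `x` field-for-field. Output is deterministic (rows sorted,
#' in-cell sets sorted and `;`-joined).
#'
#' @param pairs An evidence-pair tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  out <- tibble(
    tf = pairs$tf,
    target = pairs$target,
    evidence_kind = pairs$evidence_kind,
    conditions = vapply(pairs$conditions, paste, "", collapse = ";"),
    publications = vapply(pairs$publications, paste, "", collapse = ";")
  ) %>%
    dplyr::arrange(.data$tf, .data$target, .data$evidence_kind)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an abstract corpus
#'
#' A corpus is a two-column TSV (`publication_id`, `text`) holding literature
#' abstracts used for known/putative pathway classification. Duplicate ids
#' keep the last occurrence with a warning; rows with empty text are skipped
#' with a warning. An empty file yields an empty corpus without error.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `publication_id` and `text`.
#' @export
read_abstract_corpus <- function(path) {
  x <- read_tsv_dialect(path)
  if (nrow(x) == 0) {
    return(tibble(publication_id = character(), text = character()))
  }
  for (col in c("publication_id", "text")) {
    if (!col %in% names(x)) {
      abort(paste0("abstract corpus is missing mandatory column '", col, "'"),
            class = "trp_format_error")
    }
  }
  empty <- is.na(x$text) | trimws(x$text) == ""
  if (any(empty)) {
    warn(paste0(sum(empty), " abstract row(s) with empty text skipped"),
         class = "trp_corpus_warning")
    x <- x[!empty, , drop = FALSE]
  }
  dup <- duplicated(x$publication_id, fromLast = TRUE)
  if (any(dup)) {
    warn(paste0("duplicate publication_id(s) in corpus; keeping last occurrence: ",
                paste(unique(x$publication_id[dup]), collapse = ", ")),
         class = "trp_corpus_warning")
    x <- x[!dup, , drop = FALSE]
  }
  tibble(publication_id = as.character(x$publication_id), text = x$text)
}

# Shared TSV dialect: tab-separated, UTF-8, '#' comments. readr handles
# quoting-free cells verbatim.
read_tsv_dialect <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "trp_format_error")
  }
  readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                  progress = FALSE, show_col_types = FALSE)
}

#' Export a network or pathway set as a Graphviz DOT figure
#'
#' Emits a deterministic DOT digraph: nodes sorted lexicographically, edges
#' sorted by (tf, target) and labeled `"(tfr_count, tfb_count)"` — the
#' (x, y) = (number of TFR evidence, number of TFB evidence) convention used
#' in pathway figures. Identical input produces byte-identical output.
#'
#' @param x A [trp_network] object, or a pathway tibble (as returned by
#'   [enumerate_all_trps()]) together with `network` to look up edge
#'   evidence; in the latter case the union subnetwork induced by the
#'   pathways' edges is drawn.
#' @param path Output `.dot` file path.
#' @param network Evidence source when `x` is a pathway tibble.
#' @param name Graph name in the DOT header.
#' @return `path`, invisibly.
#' @examples
#' fx <- gln3_fixture()
#' net <- build_direct_regulatory_network(fx$tfb, fx$tfr,
#'   condition = "nitrogen source quality/availability")
#' write_dot(net, tempfile(fileext = ".dot"))
#' @export
write_dot <- function(x, path, network = NULL, name = "TRP") {
  if (inherits(x, "trp_network")) {
    edges <- x$edges
  } else {
    if (is.null(network)) {
      abort("a pathway table needs `network` to look up edge evidence",
            class = "trp_query_error")
    }
    edges <- paths_edge_union(x, network)
  }
  if (nrow(edges) == 0) {
    abort("cannot write a DOT figure for an empty node set",
          class = "trp_query_error")
  }
  nodes <- sort(unique(c(edges$tf, edges$target)))
  edges <- dplyr::arrange(edges, .data$tf, .data$target)
  lines <- c(
    paste0("digraph ", name, " {"),
    paste0("  ", dot_id(nodes), ";"),
    sprintf("  %s -> %s [label=\"(%d, %d)\"];",
            dot_id(edges$tf), dot_id(edges$target),
            edges$tfr_count, edges$tfb_count),
    "}"
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

dot_id <- function(x) {
  ok <- grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
  x[!ok] <- paste0("\"", gsub("\"", "\\\\\"", x[!ok]), "\"")
  x
}

# Induced edge union over a set of pathways, with evidence counts taken from
# the network the pathways were mined from.
paths_edge_union <- function(paths, network) {
  if (nrow(paths) == 0) {
    return(network$edges[0, , drop = FALSE])
  }
  steps <- purrr::map_dfr(paths$nodes, function(nd) {
    tibble(tf = nd[-length(nd)], target = nd[-1])
  }) %>% dplyr::distinct()
  dplyr::inner_join(network$edges, steps, by = c("tf", "target"))
}
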