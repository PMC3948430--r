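#' Condition-specific transcriptional regulatory networks
#'
#' Two directed networks underlie pathway mining, both built from
#' literature-curated evidence restricted to one experimental condition:
#'
#' * the **binding network** (`kind = "binding"`): an edge TF -> gene for
#'   every TF-gene *binding* (TFB) pair under the condition. Dense, weaker
#'   biological support per edge.
#' * the **direct-regulatory network** (`kind = "direct_regulatory"`): an
#'   edge only where the pair has *both* binding (TFB) and regulation (TFR)
#'   evidence under the condition — the TF binds the promoter and its
#'   perturbation changes the target's expression. Much sparser, with much
#'   stronger support per edge.
#'
#' By construction the direct-regulatory edge set is a subset of the binding
#' edge set built from the same TFB table. Each edge carries per-kind
#' distinct-publication counts and identifier sets. Self-loop edges (TF
#' autoregulation) are retained; the simple-path rule keeps them out of
#' mined pathways.
#'
#' @param tfb_pairs Evidence-pair tibble of kind `"TFB"`.
#' @param tfr_pairs Evidence-pair tibble of kind `"TFR"`.
#' @param condition Condition label, or `"any"` for no filter.
#' @param vocabulary A [condition_vocabulary()].
#' @param policy Condition-match policy: `"any"` (default) keeps a pair when
#'   the label is among its tags; `"all"` requires every tag to be the label.
#' @return A `trp_network` object: a list with `kind`, `condition`, `edges`
#'   (tibble: `tf`, `target`, `tfr_count`, `tfb_count`, `tfr_pubs`,
#'   `tfb_pubs`) and `nodes` (sorted character vector).
#' @examples
#' fx <- gln3_fixture()
#' build_direct_regulatory_network(fx$tfb, fx$tfr,
#'   condition = "nitrogen source quality/availability")
#' @name trp_network
NULL

#' @rdname trp_network
#' @export
build_binding_network <- function(tfb_pairs, condition = "any",
                                  vocabulary = condition_vocabulary(),
                                  policy = c("any", "all")) {
  policy <- match.arg(policy)
  check_kind(tfb_pairs, "TFB")
  condition <- canonical_condition(condition, vocabulary)
  b <- filter_condition(tfb_pairs, condition, policy)
  edges <- tibble(
    tf = b$tf, target = b$target,
    tfr_count = 0L,
    tfb_count = lengths(b$publications),
    tfr_pubs = rep(list(character()), nrow(b)),
    tfb_pubs = b$publications
  ) %>% dplyr::arrange(.data$tf, .data$target)
  new_trp_network("binding", condition, edges)
}

#' @rdname trp_network
#' @export
build_direct_regulatory_network <- function(tfb_pairs, tfr_pairs,
                                            condition = "any",
                                            vocabulary = condition_vocabulary(),
                                            policy = c("any", "all")) {
  policy <- match.arg(policy)
  check_kind(tfb_pairs, "TFB")
  check_kind(tfr_pairs, "TFR")
  condition <- canonical_condition(condition, vocabulary)
  b <- filter_condition(tfb_pairs, condition, policy)
  r <- filter_condition(tfr_pairs, condition, policy)
  # intersection keyed on (tf, target) only: a pair is "direct" even when
  # its TFB and TFR evidence come from different publications
  edges <- dplyr::inner_join(
    tibble(tf = r$tf, target = r$target,
           tfr_count = lengths(r$publications), tfr_pubs = r$publications),
    tibble(tf = b$tf, target = b$target,
           tfb_count = lengths(b$publications), tfb_pubs = b$publications),
    by = c("tf", "target")
  ) %>%
    dplyr::select("tf", "target", "tfr_count", "tfb_count",
                  "tfr_pubs", "tfb_pubs") %>%
    dplyr::arrange(.data$tf, .data$target)
  new_trp_network("direct_regulatory", condition, edges)
}

new_trp_network <- function(kind, condition, edges) {
  structure(
    list(kind = kind, condition = condition, edges = edges,
         nodes = sort(unique(c(edges$tf, edges$target)))),
    class = "trp_network"
  )
}

#' Count direct-regulatory pairs per condition
#'
#' Tallies, for every label in the vocabulary (the reserved query label
#' `"any"` reported last as the unfiltered total), the number of TF-gene
#' pairs supported by both TFB and TFR evidence — the edge count of the
#' direct-regulatory network at that condition.
#'
#' @inheritParams trp_network
#' @return A tibble with columns `condition` and `n_direct_pairs`.
#' @export
direct_pair_count <- function(tfb_pairs, tfr_pairs,
                              vocabulary = condition_vocabulary(),
                              policy = c("any", "all")) {
  policy <- match.arg(policy)
  labels <- c(setdiff(unclass(vocabulary), "any"), "any")
  purrr::map_dfr(labels, function(cond) {
    net <- build_direct_regulatory_network(tfb_pairs, tfr_pairs, cond,
                                           vocabulary, policy)
    tibble(condition = cond, n_direct_pairs = nrow(net$edges))
  })
}

#' Write a network as an edge-list TSV
#'
#' One row per edge with evidence counts and `;`-joined publication sets;
#' deterministic row order.
#'
#' @param network A [trp_network].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  out <- network$edges %>%
    dplyr::mutate(
      tfr_pubs = vapply(.data$tfr_pubs, paste, "", collapse = ";"),
      tfb_pubs = vapply(.data$tfb_pubs, paste, "", collapse = ";")
    ) %>%
    dplyr::arrange(.data$tf, .data$target)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
print.trp_network <- function(x, ...) {
  cat(sprintf("<trp_network: %s | condition: %s>\n", x$kind, x$condition))
  cat(sprintf("  %d nodes, %d edges, %d TFs (nodes with out-edges)\n",
              length(x$nodes), nrow(x$edges), length(unique(x$edges$tf))))
  if (nrow(x$edges) > 0) {
    print(dplyr::select(x$edges, "tf", "target", "tfr_count", "tfb_count"),
          n = 6)
  }
  invisible(x)
}

#' Tidy and summary methods for networks
#'
#' `tidy()` returns the edge table (one row per directed edge with evidence
#' counts); `glance()` returns a one-row summary.
#'
#' @param x A [trp_network].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trp_network <- function(x, ...) {
  dplyr::mutate(x$edges, kind = x$kind, condition = x$condition,
                .before = "tf")
}

#' @rdname tidy.trp_network
#' @export
glance.trp_network <- function(x, ...) {
  tibble(
    kind = x$kind,
    condition = x$condition,
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_tfs = length(unique(x$edges$tf)),
    n_tfr_publications = length(unique(unlist(x$edges$tfr_pubs))),
    n_tfb_publications = length(unique(unlist(x$edges$tfb_pubs)))
  )
}
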