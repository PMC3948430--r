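#' Search pathway information for TF-gene regulatory pairs
#'
#' The search surface answers "which of my TF-gene pairs have pathway
#' information?". Three query shapes are supported: a TF list against all
#' genes (`gene_list = "ALL"`), all TFs against a gene list
#' (`tf_list = "ALL"`), or list against list. Only pairs with TFR
#' (perturbation) evidence under the condition are reported — pairs without
#' perturbation support are not deposited, because the engine exists to
#' explain perturbation-identified regulation. For each reported pair the
#' kind-appropriate miner is run: all pathways on the direct-regulatory
#' network, all shortest pathways on the binding network.
#'
#' @inheritParams trp_network
#' @param tf_list,gene_list Character vectors of symbols, or `"ALL"`.
#' @param network_kind `"direct_regulatory"` or `"binding"`.
#' @param budget A [mining_budget()].
#' @param force Allow an `ALL` x `ALL` query whose candidate-pair count
#'   exceeds `budget$max_paths`.
#' @return A tibble with one row per reported pair: `tf`, `gene`,
#'   `condition`, `network_kind`, `n_trps`, `trp_lengths` (list of integer),
#'   `n_tfr_evidence`, `n_tfb_evidence`.
#' @examples
#' fx <- gln3_fixture()
#' search_trps(fx$tfb, fx$tfr, tf_list = "GLN3", gene_list = "GZF3",
#'             condition = fx$condition)
#' @export
search_trps <- function(tfb_pairs, tfr_pairs, tf_list = "ALL",
                        gene_list = "ALL", condition = "any",
                        network_kind = c("direct_regulatory", "binding"),
                        budget = mining_budget(),
                        vocabulary = condition_vocabulary(),
                        policy = c("any", "all"), force = FALSE) {
  network_kind <- match.arg(network_kind)
  policy <- match.arg(policy)
  if (length(tf_list) == 0 || length(gene_list) == 0) {
    abort("tf_list and gene_list must be non-empty (use \"ALL\" as wildcard)",
          class = "trp_query_error")
  }
  condition <- canonical_condition(condition, vocabulary)
  tfr_idx <- evidence_index(tfr_pairs, "TFR", condition, vocabulary, policy)
  tfb_idx <- evidence_index(tfb_pairs, "TFB", condition, vocabulary, policy)

  cand <- tfr_idx
  if (!identical(tf_list, "ALL")) {
    cand <- cand[cand$tf %in% normalize_symbol(tf_list), , drop = FALSE]
  }
  if (!identical(gene_list, "ALL")) {
    cand <- cand[cand$target %in% normalize_symbol(gene_list), , drop = FALSE]
  }
  if (identical(tf_list, "ALL") && identical(gene_list, "ALL") &&
      nrow(cand) > budget$max_paths && !force) {
    abort(sprintf(
      "wildcard x wildcard query over %d candidate pairs exceeds max_paths = %d; pass force = TRUE to proceed",
      nrow(cand), budget$max_paths),
      class = "trp_budget_error")
  }

  net <- switch(network_kind,
    direct_regulatory = build_direct_regulatory_network(
      tfb_pairs, tfr_pairs, condition, vocabulary, policy),
    binding = build_binding_network(tfb_pairs, condition, vocabulary, policy))
  miner <- switch(network_kind,
    direct_regulatory = enumerate_all_trps,
    binding = enumerate_shortest_trps)

  tfb_key <- pair_key(tfb_idx$tf, tfb_idx$target)
  purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    tf <- cand$tf[i]; gene <- cand$target[i]
    paths <- miner(net, tf, gene, budget)
    bi <- match(pair_key(tf, gene), tfb_key)
    tibble(
      tf = tf, gene = gene, condition = condition,
      network_kind = network_kind,
      n_trps = nrow(paths),
      trp_lengths = list(paths$length),
      n_tfr_evidence = cand$n_pubs[i],
      n_tfb_evidence = if (is.na(bi)) 0L else tfb_idx$n_pubs[bi]
    )
  }) %>%
    dplyr::arrange(.data$tf, .data$gene)
}

#' Browse regulatory targets of TFs, or regulators of genes
#'
#' `axis = "by_tf"` lists all direct and indirect regulatory targets
#' (TFR-evidenced pairs) of the queried TFs; `axis = "by_gene"` lists all
#' regulators of the queried genes. Rows carry the same pathway summary as
#' [search_trps()]. An optional functional-annotation table (columns
#' `symbol`, `category`) filters rows to those whose counterpart symbol
#' (the target when browsing by TF, the regulator when browsing by gene)
#' belongs to one of the requested categories.
#'
#' @inheritParams search_trps
#' @param symbols Symbols to browse from.
#' @param axis `"by_tf"` or `"by_gene"`.
#' @param categories Optional two-column annotation table (`symbol`,
#'   `category`).
#' @param category Optional character vector of category names to keep;
#'   names absent from `categories` produce an empty result with a warning.
#' @return A tibble like [search_trps()]'s, plus a `counterpart_category`
#'   column when `categories` is supplied.
#' @export
browse_trps <- function(tfb_pairs, tfr_pairs, symbols,
                        axis = c("by_tf", "by_gene"), condition = "any",
                        network_kind = c("direct_regulatory", "binding"),
                        categories = NULL, category = NULL,
                        budget = mining_budget(),
                        vocabulary = condition_vocabulary(),
                        policy = c("any", "all")) {
  axis <- match.arg(axis)
  res <- switch(axis,
    by_tf = search_trps(tfb_pairs, tfr_pairs, tf_list = symbols,
                        gene_list = "ALL", condition = condition,
                        network_kind = network_kind, budget = budget,
                        vocabulary = vocabulary, policy = policy),
    by_gene = search_trps(tfb_pairs, tfr_pairs, tf_list = "ALL",
                          gene_list = symbols, condition = condition,
                          network_kind = network_kind, budget = budget,
                          vocabulary = vocabulary, policy = policy))
  if (is.null(categories)) return(res)

  categories$symbol <- normalize_symbol(categories$symbol)
  counterpart <- if (axis == "by_tf") res$gene else res$tf
  cat_of <- function(sym) {
    sort(unique(categories$category[categories$symbol == sym]))
  }
  res$counterpart_category <-
    vapply(counterpart, function(s) paste(cat_of(s), collapse = ";"), "")
  if (!is.null(category)) {
    unknown <- setdiff(category, unique(categories$category))
    if (length(unknown) > 0) {
      warn(paste0("unknown functional categor(y/ies): ",
                  paste(unknown, collapse = ", ")),
           class = "trp_category_warning")
    }
    keep <- vapply(counterpart,
                   function(s) length(intersect(cat_of(s), category)) > 0,
                   logical(1))
    res <- res[keep, , drop = FALSE]
  }
  res
}

#' Assemble the four-part detail report for a TF-gene pair
#'
#' The detail report answers "how might this TF regulate this gene?" in
#' four parts: (1) the queried pair and the TFR evidence that makes it
#' interesting; (2) every enumerated pathway with its confidence score and
#' known/putative status; (3) the experimental evidence (TFR/TFB) for every
#' ordered pair along every pathway, labeled direct / indirect; (4) the
#' plain-text serialization (filled in by [write_detail_report()]).
#'
#' @inheritParams search_trps
#' @param tf,gene The queried pair; the pair must carry TFR evidence under
#'   `condition` (pairs without perturbation evidence are not deposited).
#' @param corpus Optional abstract corpus for known/putative classification.
#' @return An object of class `trp_detail_report`.
#' @examples
#' fx <- gln3_fixture()
#' build_detail_report(fx$tfb, fx$tfr, "GLN3", "GZF3",
#'                     condition = fx$condition, corpus = fx$corpus)
#' @export
build_detail_report <- function(tfb_pairs, tfr_pairs, tf, gene,
                                condition = "any",
                                network_kind = c("direct_regulatory", "binding"),
                                corpus = NULL, budget = mining_budget(),
                                vocabulary = condition_vocabulary(),
                                policy = c("any", "all")) {
  network_kind <- match.arg(network_kind)
  policy <- match.arg(policy)
  tf <- normalize_symbol(tf)
  gene <- normalize_symbol(gene)
  condition <- canonical_condition(condition, vocabulary)
  tfr_idx <- evidence_index(tfr_pairs, "TFR", condition, vocabulary, policy)
  tfb_idx <- evidence_index(tfb_pairs, "TFB", condition, vocabulary, policy)

  ri <- match(pair_key(tf, gene), pair_key(tfr_idx$tf, tfr_idx$target))
  if (is.na(ri)) {
    abort(paste0(
      "pair ", tf, " -> ", gene, " has no TFR evidence under condition '",
      condition, "': only perturbation-identified (TFR-evidenced) pairs ",
      "are deposited, because pathways explain perturbation responses"),
      class = "trp_query_error")
  }
  bi <- match(pair_key(tf, gene), pair_key(tfb_idx$tf, tfb_idx$target))

  net <- switch(network_kind,
    direct_regulatory = build_direct_regulatory_network(
      tfb_pairs, tfr_pairs, condition, vocabulary, policy),
    binding = build_binding_network(tfb_pairs, condition, vocabulary, policy))
  miner <- switch(network_kind,
    direct_regulatory = enumerate_all_trps,
    binding = enumerate_shortest_trps)
  paths <- miner(net, tf, gene, budget)
  part2 <- annotate_trps(paths, tfr_idx, tfb_idx, corpus)

  part1 <- tibble(
    tf = tf, gene = gene, condition = condition,
    network_kind = network_kind,
    n_tfr_evidence = tfr_idx$n_pubs[ri],
    tfr_publications = tfr_idx$publications[ri],
    n_tfb_evidence = if (is.na(bi)) 0L else tfb_idx$n_pubs[bi]
  )
  part3 <- if (nrow(part2) > 0) {
    tidyr::unnest(
      dplyr::select(part2, "path_id", "path", "pair_evidence"),
      "pair_evidence")
  } else {
    tibble(path_id = integer(), path = character(),
           upstream = character(), downstream = character(),
           has_tfr = logical(), has_tfb = logical(),
           tfr_count = integer(), tfb_count = integer(), label = character())
  }
  structure(
    list(part1 = part1, part2 = part2, part3 = part3, part4 = NULL,
         network = net),
    class = "trp_detail_report"
  )
}

#' @export
print.trp_detail_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.trp_detail_report <- function(x, ...) {
  p1 <- x$part1
  out <- c(
    "==== Part 1: queried TF-gene regulatory pair ====",
    sprintf("TF: %s", p1$tf),
    sprintf("Gene: %s", p1$gene),
    sprintf("Condition: %s", p1$condition),
    sprintf("Network: %s", p1$network_kind),
    sprintf("TFR evidence: %d publication(s): %s", p1$n_tfr_evidence,
            paste(p1$tfr_publications[[1]], collapse = "; ")),
    sprintf("TFB evidence: %d publication(s)%s", p1$n_tfb_evidence,
            if (p1$n_tfb_evidence == 0)
              " -- the pair is not a direct edge; regulation must be indirect"
            else ""),
    "",
    "==== Part 2: enumerated TRPs and confidence scores ===="
  )
  if (nrow(x$part2) == 0) {
    out <- c(out, "no TRPs found")
  } else {
    for (i in seq_len(nrow(x$part2))) {
      r <- x$part2[i, ]
      out <- c(out,
        sprintf("TRP %d (length %d): %s", r$path_id, r$length, r$path),
        sprintf("  confidence: %.1f%%  status: %s%s",
                100 * r$confidence, r$status,
                if (length(r$supporting[[1]]) > 0)
                  paste0("  support: ",
                         paste(r$supporting[[1]], collapse = "; "))
                else ""))
    }
  }
  out <- c(out, "", "==== Part 3: experimental evidence along each TRP ====")
  if (nrow(x$part3) == 0) {
    out <- c(out, "no TRPs found")
  } else {
    for (pid in unique(x$part3$path_id)) {
      rows <- x$part3[x$part3$path_id == pid, ]
      out <- c(out, sprintf("TRP %d: %s", pid, rows$path[1]))
      out <- c(out, sprintf("  %s -> %s: TFR=%d TFB=%d  %s",
                            rows$upstream, rows$downstream,
                            rows$tfr_count, rows$tfb_count, rows$label))
    }
  }
  c(out, "", "==== Part 4: download ====",
    sprintf("Saved copy: %s", x$part4 %||% "(unsaved)"))
}

#' Write a detail report as text plus a machine-readable sidecar
#'
#' The text file carries the four-part report for humans; a JSON sidecar
#' with the same stem carries the structured content so reports round-trip
#' ([read_detail_sidecar()]). Output is deterministic: identical reports
#' produce byte-identical files.
#'
#' @param report A `trp_detail_report`.
#' @param path Output text-file path; the sidecar replaces its extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_detail_report <- function(report, path) {
  report$part4 <- basename(path)
  writeLines(format(report), path, useBytes = TRUE)
  sidecar <- paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".json")
  payload <- list(
    part1 = list(
      tf = report$part1$tf, gene = report$part1$gene,
      condition = report$part1$condition,
      network_kind = report$part1$network_kind,
      n_tfr_evidence = report$part1$n_tfr_evidence,
      tfr_publications = report$part1$tfr_publications[[1]],
      n_tfb_evidence = report$part1$n_tfb_evidence
    ),
    part2 = lapply(seq_len(nrow(report$part2)), function(i) {
      r <- report$part2[i, ]
      list(nodes = r$nodes[[1]], length = r$length,
           confidence = r$confidence, status = r$status,
           supporting = r$supporting[[1]])
    }),
    part3 = lapply(seq_len(nrow(report$part3)), function(i) {
      as.list(report$part3[i, setdiff(names(report$part3), "path")])
    }),
    part4 = report$part4
  )
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_detail_report
#' @export
read_detail_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' @export
tidy.trp_detail_report <- function(x, ...) {
  dplyr::select(x$part2, -"nodes", -"pair_evidence")
}

#' @export
glance.trp_detail_report <- function(x, ...) {
  tibble(
    tf = x$part1$tf, gene = x$part1$gene, condition = x$part1$condition,
    network_kind = x$part1$network_kind,
    n_trps = nrow(x$part2),
    min_length = if (nrow(x$part2)) min(x$part2$length) else NA_integer_,
    max_length = if (nrow(x$part2)) max(x$part2$length) else NA_integer_,
    n_known = sum(x$part2$status == "known"),
    mean_confidence = if (nrow(x$part2)) mean(x$part2$confidence) else NA_real_
  )
}

#' Per-condition summary statistics of an evidence corpus
#'
#' For every condition label: the number of TFR pairs (perturbation-
#' identified regulation), TFB pairs, direct-regulatory pairs (both
#' evidence kinds), and — when `explainable = TRUE` — the number of TFR
#' pairs connected by at least one pathway in the direct-regulatory
#' network, i.e. the pairs whose regulation the network can explain
#' mechanistically.
#'
#' @inheritParams trp_network
#' @param explainable Also mine each TFR pair for pathway existence
#'   (quadratic in pairs; keep for desk-scale tables).
#' @param budget A [mining_budget()].
#' @return A tibble with one row per condition.
#' @export
condition_stats <- function(tfb_pairs, tfr_pairs,
                            vocabulary = condition_vocabulary(),
                            policy = c("any", "all"), explainable = FALSE,
                            budget = mining_budget()) {
  policy <- match.arg(policy)
  labels <- c(setdiff(unclass(vocabulary), "any"), "any")
  purrr::map_dfr(labels, function(cond) {
    r <- filter_condition(tfr_pairs, cond, policy)
    b <- filter_condition(tfb_pairs, cond, policy)
    net <- build_direct_regulatory_network(tfb_pairs, tfr_pairs, cond,
                                           vocabulary, policy)
    row <- tibble(condition = cond, n_tfr_pairs = nrow(r),
                  n_tfb_pairs = nrow(b), n_direct_pairs = nrow(net$edges))
    if (explainable) {
      ok <- vapply(seq_len(nrow(r)), function(i) {
        if (!(r$tf[i] %in% net$nodes) || !(r$target[i] %in% net$nodes) ||
            r$tf[i] == r$target[i]) return(FALSE)
        is.finite(shortest_trp_length(net, r$tf[i], r$target[i]))
      }, logical(1))
      row$n_explainable <- sum(ok)
      row$pct_explainable <-
        if (nrow(r) > 0) 100 * sum(ok) / nrow(r) else NA_real_
    }
    row
  })
}
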