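#' Specification for a synthetic evidence-table pair
#'
#' The generator emulates the regime the mining engine targets: a sparse
#' directed regulatory layer in which only TFs have out-edges, every edge
#' carries TFR (perturbation-response) evidence, and a fraction of edges
#' additionally carries TFB (promoter-binding) evidence — mirroring the
#' empirical scarcity of binding support among perturbation-identified
#' pairs. "Planted" pathways are guaranteed recoverable: their edges get
#' both evidence kinds and every ordered pair along them gets TFR evidence,
#' so each planted pathway appears in the direct-regulatory network and
#' scores a confidence of exactly 1.
#'
#' @param n_tfs Number of TF nodes (potential regulators), default 15.
#' @param n_genes Number of non-TF gene nodes, default 30.
#' @param edge_probability Probability of each admissible TF -> node edge,
#'   default 0.08 (sparse regime).
#' @param tfb_given_edge Probability that an edge also has TFB evidence,
#'   default 0.5.
#' @param conditions Condition label(s) tagged onto every generated row.
#' @param n_planted_paths Number of planted pathways, default 3.
#' @param planted_length_range Inclusive (min, max) planted pathway length
#'   in edges, default c(2, 4).
#' @param seed Integer seed; identical specs generate identical tables.
#' @return A list of class `trp_synth_spec`.
#' @export
synth_spec <- function(n_tfs = 15L, n_genes = 30L, edge_probability = 0.08,
                       tfb_given_edge = 0.5, conditions = "stress",
                       n_planted_paths = 3L, planted_length_range = c(2L, 4L),
                       seed = 1L) {
  stopifnot(n_tfs >= 1, n_genes >= 0,
            edge_probability >= 0, edge_probability <= 1,
            tfb_given_edge >= 0, tfb_given_edge <= 1,
            n_planted_paths >= 0, all(planted_length_range >= 1),
            planted_length_range[1] <= planted_length_range[2])
  if (n_planted_paths > 0 && planted_length_range[2] > n_tfs) {
    abort(sprintf(
      "cannot plant a pathway of length %d with only %d TFs (a length-L pathway needs L TF nodes)",
      planted_length_range[2], n_tfs),
      class = "trp_spec_error")
  }
  structure(list(n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
                 edge_probability = edge_probability,
                 tfb_given_edge = tfb_given_edge, conditions = conditions,
                 n_planted_paths = as.integer(n_planted_paths),
                 planted_length_range = as.integer(planted_length_range),
                 seed = as.integer(seed)),
            class = "trp_synth_spec")
}

#' Generate synthetic TFB/TFR evidence tables with planted pathways
#'
#' @param spec A [synth_spec()].
#' @param vocabulary A [condition_vocabulary()] extended with the spec's
#'   condition labels if they are not already present.
#' @return A list with `tfb` and `tfr` evidence-pair tibbles and `truth`,
#'   a pathway tibble of the planted pathways.
#' @examples
#' tabs <- generate_tables(synth_spec(seed = 7))
#' nrow(tabs$tfr)
#' @export
generate_tables <- function(spec, vocabulary = NULL) {
  stopifnot(inherits(spec, "trp_synth_spec"))
  if (is.null(vocabulary)) {
    vocabulary <- condition_vocabulary(
      unique(c(default_condition_labels(), spec$conditions)))
  }
  tfs <- sprintf("TF%02d", seq_len(spec$n_tfs))
  genes <- if (spec$n_genes > 0) sprintf("G%03d", seq_len(spec$n_genes)) else character()
  nodes <- c(tfs, genes)

  withr::with_seed(spec$seed, {
    # admissible edges: TF source, no self-loop
    grid <- expand.grid(tf = tfs, target = nodes, stringsAsFactors = FALSE)
    grid <- grid[grid$tf != grid$target, , drop = FALSE]
    grid <- grid[order(grid$tf, grid$target), , drop = FALSE]
    keep <- stats::runif(nrow(grid)) < spec$edge_probability
    edges <- grid[keep, , drop = FALSE]
    has_tfb <- stats::runif(nrow(edges)) < spec$tfb_given_edge

    tfr_rows <- edges
    tfb_rows <- edges[has_tfb, , drop = FALSE]

    planted <- list()
    if (spec$n_planted_paths > 0) {
      for (k in seq_len(spec$n_planted_paths)) {
        lmin <- spec$planted_length_range[1]
        lmax <- spec$planted_length_range[2]
        L <- if (lmin == lmax) lmin else sample(lmin:lmax, 1)
        chain_tfs <- sample(tfs, L)
        terminal <- sample(setdiff(nodes, chain_tfs), 1)
        planted[[k]] <- c(chain_tfs, terminal)
      }
    }
    plant_edges <- purrr::map_dfr(planted, function(nd) {
      data.frame(tf = nd[-length(nd)], target = nd[-1])
    })
    plant_pairs <- purrr::map_dfr(planted, function(nd) {
      as.data.frame(pairs_along(nd)) |>
        stats::setNames(c("tf", "target"))
    })

    tfb_rows <- unique(rbind(tfb_rows, plant_edges))
    # every along-direction ordered pair of a planted pathway gets TFR
    # evidence so the pathway scores 100%
    tfr_rows <- unique(rbind(tfr_rows, plant_edges, plant_pairs))
  })

  cond <- paste(spec$conditions, collapse = ";")
  mk <- function(rows, kind) {
    if (nrow(rows) == 0) {
      return(as_evidence_pairs(
        tibble(tf = character(), target = character(),
               evidence_kind = character(), conditions = character(),
               publications = character()),
        vocabulary = vocabulary))
    }
    as_evidence_pairs(
      tibble(tf = rows$tf, target = rows$target, evidence_kind = kind,
             conditions = cond,
             publications = paste0("SYN:", kind, ":", rows$tf, ":", rows$target)),
      vocabulary = vocabulary)
  }

  truth <- as_trp_paths(planted,
                        source = NA_character_, target = NA_character_)
  if (nrow(truth) > 0) {
    truth$source <- vapply(planted, `[`, "", 1)
    truth$target <- vapply(planted, utils::tail, "", 1)
  }
  list(tfb = mk(tfb_rows, "TFB"), tfr = mk(tfr_rows, "TFR"), truth = truth)
}

#' The nitrogen-catabolite GATA-factor fixture
#'
#' A six-edge evidence fixture reproducing the published worked example of
#' nitrogen catabolite repression in *Saccharomyces cerevisiae*, where the
#' four GATA-family factors Gln3, Gat1, Dal80 and Gzf3 control nitrogen
#' catabolic gene expression. Gln3 perturbation changes *GZF3* expression
#' but Gln3 does not bind the *GZF3* promoter, making *GZF3* an indirect
#' Gln3 target whose mechanism runs through intermediate factors:
#'
#' * both TFB and TFR evidence: GLN3->GAT1, GLN3->DAL80, DAL80->GAT1,
#'   GAT1->GZF3 (the direct-regulatory edges);
#' * TFR-only evidence: GLN3->GZF3 (the queried indirect pair) and
#'   DAL80->GZF3 (Dal80 indirectly regulates *GZF3*).
#'
#' All rows are tagged `"nitrogen source quality/availability"`. Mining
#' (GLN3, GZF3) in the direct-regulatory network yields exactly two
#' pathways — GLN3->GAT1->GZF3 and GLN3->DAL80->GAT1->GZF3 — both with
#' confidence 100%. Publication identifiers and the one-abstract corpus are
#' synthetic stand-ins (`SYN:*`), not literature citations.
#'
#' @return A list with `tfb`, `tfr` (evidence-pair tibbles), `corpus`
#'   (one-abstract tibble) and `condition` (the fixture's condition label).
#' @examples
#' fx <- gln3_fixture()
#' direct_pair_count(fx$tfb, fx$tfr)
#' @export
gln3_fixture <- function() {
  cond <- "nitrogen source quality/availability"
  both <- data.frame(
    tf = c("GLN3", "GLN3", "DAL80", "GAT1"),
    target = c("GAT1", "DAL80", "GAT1", "GZF3")
  )
  tfr_only <- data.frame(
    tf = c("GLN3", "DAL80"),
    target = c("GZF3", "GZF3")
  )
  mk <- function(rows, kind) {
    as_evidence_pairs(tibble(
      tf = rows$tf, target = rows$target, evidence_kind = kind,
      conditions = cond,
      publications = paste0("SYN:", kind, ":", rows$tf, ":", rows$target)
    ))
  }
  corpus <- tibble(
    publication_id = "SYN:ABSTRACT:1",
    text = paste("Under poor nitrogen sources, Gln3 activates GAT1",
                 "transcription, and Gat1 in turn controls GZF3 expression",
                 "as part of the GATA-factor circuit.")
  )
  list(tfb = mk(both, "TFB"),
       tfr = mk(rbind(both, tfr_only), "TFR"),
       corpus = corpus,
       condition = cond)
}
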