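# Compact constructors for inline evidence tables and TSV files.

mk_pairs <- function(tf, target, kind, conditions = "", publications = NULL) {
  n <- max(length(tf), length(target))
  tf <- rep_len(tf, n); target <- rep_len(target, n)
  if (is.null(publications)) {
    publications <- paste0("P", seq_len(n), ":", rep_len(kind, n))
  }
  as_evidence_pairs(tibble::tibble(
    tf = tf, target = target, evidence_kind = rep_len(kind, n),
    conditions = rep_len(conditions, n),
    publications = rep_len(publications, n)))
}

# a simple chain/DAG as a direct-regulatory network (both evidence kinds)
mk_net <- function(tf, target) {
  build_direct_regulatory_network(mk_pairs(tf, target, "TFB"),
                                  mk_pairs(tf, target, "TFR"))
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
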