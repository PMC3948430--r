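test_that("read_pair_table merges duplicates and normalizes symbols", {
  path <- write_tsv_fixture(c(
    "# comment line",
    "tf\ttarget\tevidence_kind\tconditions\tpublications",
    "GLN3\tGAT1\tTFR\tnitrogen source quality/availability\tP1",
    "GLN3\tGAT1\tTFR\tnitrogen source quality/availability\tP2",
    "Gln3\tgat1\tTFB\t\tP3"
  ))
  x <- read_pair_table(path)
  expect_equal(nrow(x), 2)
  tfr <- x[x$evidence_kind == "TFR", ]
  expect_equal(tfr$publications[[1]], c("P1", "P2"))
  expect_equal(unique(x$tf), "GLN3")
  expect_equal(unique(x$target), "GAT1")
})

test_that("read_pair_table raises format errors for bad files", {
  expect_error(read_pair_table(write_tsv_fixture("tf\ttarget")),
               class = "trp_format_error")           # header only
  expect_error(
    read_pair_table(write_tsv_fixture(c("tf\tpublications", "A\tP1"))),
    regexp = "target", class = "trp_format_error")   # names missing column
  expect_error(
    read_pair_table(write_tsv_fixture(
      c("tf\ttarget\tevidence_kind", "A\tB\tCHIPCHIP"))),
    class = "trp_format_error")                      # unknown kind
  expect_error(read_pair_table(tempfile()), class = "trp_format_error")
})

test_that("parsing is insensitive to input row order", {
  rows <- c("GLN3\tGAT1\tTFR\t\tP1", "GLN3\tDAL80\tTFR\t\tP2",
            "GLN3\tGAT1\tTFR\t\tP3", "DAL80\tGAT1\tTFR\t\tP4")
  hdr <- "tf\ttarget\tevidence_kind\tconditions\tpublications"
  a <- read_pair_table(write_tsv_fixture(c(hdr, rows)))
  b <- read_pair_table(write_tsv_fixture(c(hdr, rev(rows))))
  expect_equal(a, b)
})

test_that("abstract corpora read with last-wins duplicates and skipped empties", {
  path <- write_tsv_fixture(c(
    "publication_id\ttext",
    "P9\tGln3 activates GAT1 which represses GZF3"
  ))
  x <- read_abstract_corpus(path)
  expect_equal(nrow(x), 1)
  expect_match(x$text, "GAT1")

  path2 <- write_tsv_fixture(c(
    "publication_id\ttext",
    "P1\told text", "P2\t", "P1\tnew text"
  ))
  expect_warning(expect_warning(y <- read_abstract_corpus(path2),
                                class = "trp_corpus_warning"),
                 class = "trp_corpus_warning")
  expect_equal(y$publication_id, "P1")
  expect_equal(y$text, "new text")

  empty <- read_abstract_corpus(write_tsv_fixture("publication_id\ttext"))
  expect_equal(nrow(empty), 0)
})

test_that("DOT export matches the (tfr, tfb) edge-label convention", {
  net <- build_direct_regulatory_network(
    mk_pairs("GLN3", "DAL80", "TFB", publications = list(c("B1", "B2"))),
    mk_pairs("GLN3", "DAL80", "TFR", publications = list(c("R1", "R2", "R3"))))
  path <- withr::local_tempfile(fileext = ".dot")
  write_dot(net, path)
  txt <- readLines(path)
  expect_true(any(grepl("GLN3 -> DAL80 [label=\"(3, 2)\"]", txt,
                        fixed = TRUE)))
})

test_that("DOT of the nitrogen-fixture pathway union has 4 nodes and 4 edges", {
  fx <- gln3_fixture()
  net <- build_direct_regulatory_network(fx$tfb, fx$tfr, fx$condition)
  paths <- enumerate_all_trps(net, "GLN3", "GZF3")
  path <- withr::local_tempfile(fileext = ".dot")
  write_dot(paths, path, network = net)
  txt <- readLines(path)
  expect_length(grep(" -> ", txt, fixed = TRUE), 4)
  node_lines <- grep("^  [A-Z0-9]+;$", txt, value = TRUE)
  expect_length(node_lines, 4)
  # deterministic bytes
  path2 <- withr::local_tempfile(fileext = ".dot")
  write_dot(paths, path2, network = net)
  expect_identical(readLines(path), readLines(path2))

  expect_error(write_dot(paths[0, ], path, network = net),
               class = "trp_query_error")
})

test_that("detail reports serialize deterministically with a JSON sidecar", {
  fx <- gln3_fixture()
  rep <- build_detail_report(fx$tfb, fx$tfr, "GLN3", "GZF3",
                             condition = fx$condition, corpus = fx$corpus)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "report.txt")
  write_detail_report(rep, p1)
  txt <- readLines(p1)
  expect_length(grep("^TRP [0-9]+ \\(length", txt), 2)
  # identical report written twice to the same path -> identical bytes
  first <- readLines(p1)
  first_side <- readLines(file.path(dir, "report.json"))
  write_detail_report(rep, p1)
  expect_identical(readLines(p1), first)
  expect_identical(readLines(file.path(dir, "report.json")), first_side)

  side <- read_detail_sidecar(file.path(dir, "report.json"))
  expect_equal(side$part1$tf, "GLN3")
  expect_length(side$part2, 2)
  expect_equal(side$part2[[1]]$nodes, c("GLN3", "GAT1", "GZF3"))
  expect_equal(side$part2[[1]]$confidence, 1)
})

test_that("a report for a pathway-free pair states the absence explicitly", {
  tfb <- mk_pairs("A", "B", "TFB")
  tfr <- mk_pairs(c("A", "X"), c("B", "Y"), "TFR")
  rep <- build_detail_report(tfb, tfr, "X", "Y")
  expect_equal(nrow(rep$part2), 0)
  path <- withr::local_tempfile(fileext = ".txt")
  write_detail_report(rep, path)
  expect_true(any(grepl("no TRPs found", readLines(path), fixed = TRUE)))
})
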