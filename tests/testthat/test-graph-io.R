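test_that("similarity matrices round-trip through TSV and validate structure", {
  net <- toy_similarity()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(net, path)
  back <- read_similarity_matrix(path)
  expect_equal(back$ids, net$ids)
  expect_lt(max(abs(back$weights - net$weights)), 1e-12)

  # gzip round-trip
  gzpath <- withr::local_tempfile(fileext = ".tsv.gz")
  write_similarity_matrix(net, gzpath)
  expect_equal(read_similarity_matrix(gzpath)$weights, net$weights)
})

test_that("identity-like similarity has nodes but no walkable edges", {
  w <- diag(3)
  net <- similarity_network(w, ids = c("a", "b", "c"))
  g <- as_walk_graph(net)
  expect_length(g$ids, 3)
  expect_length(g$nbr, 0)
})

test_that("a single positive off-diagonal weight becomes one undirected edge", {
  net <- toy_similarity()
  g <- as_walk_graph(net)
  expect_equal(length(g$nbr), 2) # both directions of one edge
  expect_equal(unique(g$wts), 0.7)
})

test_that("a MISIM-scale fixture keeps all 495 nodes", {
  n <- 495
  set.seed(11)
  w <- matrix(runif(n * n, 0, 0.3), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(
    similarity_network(w, ids = sprintf("hsa-miR-%03d", 1:n)), path
  )
  expect_length(read_similarity_matrix(path)$ids, 495)
})

test_that("similarity reader rejects malformed input and symmetrizes with a warning", {
  w <- matrix(c(1, .5, .1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(net <- similarity_network(w), "symmetrized")
  expect_equal(net$weights[1, 2], 0.3)

  expect_error(
    similarity_network(matrix(0, 2, 3)), class = "mirdap_format_error"
  )
  expect_error(
    similarity_network(matrix(-0.1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
    class = "mirdap_value_error"
  )
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,a,b", "a,1,x", "b,x,1"), bad)
  expect_error(read_similarity_matrix(bad), class = "mirdap_value_error")
})

test_that("edge lists collapse duplicates and report degrees", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "m1\tg1", "m1\tg2", "m2\tg1", "m1\tg1"), path)
  net <- read_interaction_edges(path, quiet = TRUE)
  expect_equal(nrow(net$edges), 3)
  g <- as_walk_graph(net)
  deg <- diff(g$offsets)
  names(deg) <- g$ids
  expect_equal(deg[["m1"]], 2L)
  expect_equal(deg[["m2"]], 1L)
})

test_that("edge reader errors carry the offending line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("m1\tg1", "m2\tg1\textra"), path)
  expect_error(read_interaction_edges(path, quiet = TRUE),
    "line 2",
    class = "mirdap_format_error"
  )
})

test_that("distinct miRNA/gene counts match an independent set-based recount", {
  set.seed(5)
  edges <- data.frame(
    mirna = sprintf("m%02d", sample(30, 400, replace = TRUE)),
    gene = sprintf("g%03d", sample(150, 400, replace = TRUE))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(edges, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  msg <- capture.output(net <- read_interaction_edges(path), type = "message")
  expect_match(
    paste(msg, collapse = ""),
    sprintf(
      "%d edges, %d distinct miRNAs, %d distinct genes",
      nrow(unique(edges)), length(unique(edges$mirna)),
      length(unique(edges$gene))
    ),
    fixed = TRUE
  )
  expect_setequal(net$mirna_ids, unique(edges$mirna))
})

test_that("labels intersect with the universe, warn on drops, and deduplicate", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("m1", "m2", "M2", "m3", "m4", "zzz"), path)
  universe <- c("m1", "m2", "m3", "m4", "m5")
  expect_warning(ls1 <- read_labels(path, universe), "1 label")
  expect_setequal(ls1$positives, c("m1", "m2", "m3", "m4"))
  expect_setequal(ls1$unlabeled, "m5")

  all_present <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("m1", "m5"), all_present)
  expect_length(read_labels(all_present, universe)$positives, 2)

  none <- withr::local_tempfile(fileext = ".txt")
  writeLines("absent", none)
  expect_error(
    suppressWarnings(read_labels(none, universe)),
    class = "mirdap_config_error"
  )
})
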