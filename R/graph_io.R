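# Readers, writers and containers for the three input formats: a weighted
# miRNA functional-similarity matrix, a bipartite miRNA-mRNA interaction edge
# list, and a positive-label list of disease-associated miRNAs.

#' Construct a miRNA functional-similarity network
#'
#' Wraps a symmetric matrix of pairwise functional-similarity scores in
#' `[0, 1]` (MISIM-style). Off-diagonal positive entries are the weighted
#' edges a biased random walk can traverse; the diagonal is ignored for
#' walks (no self-loops).
#'
#' @param weights Square numeric matrix of similarity scores. Row and column
#'   names, when present, must agree; otherwise `ids` must be supplied.
#' @param ids Character vector of miRNA identifiers in matrix order.
#' @param tol Symmetry tolerance. Asymmetries beyond `tol` are resolved by
#'   averaging `(W + t(W))/2` with a warning.
#' @return An object of class `similarity_network` with elements `ids` and
#'   `weights`.
#' @export
similarity_network <- function(weights, ids = rownames(weights), tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    abort_format("similarity weights must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    abort_format(sprintf(
      "similarity matrix must be square (got %d x %d)",
      nrow(weights), ncol(weights)
    ))
  }
  if (is.null(ids)) abort_format("miRNA identifiers are required")
  ids <- trimws(as.character(ids))
  if (length(ids) != nrow(weights)) {
    abort_format("length of `ids` must equal the matrix dimension")
  }
  if (anyDuplicated(id_key(ids))) {
    abort_format("duplicate miRNA identifiers in similarity matrix")
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    abort_value("similarity matrix contains non-finite entries")
  }
  if (any(weights < 0)) {
    abort_value("similarity scores must be non-negative")
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    warn(sprintf(
      "similarity matrix asymmetric (max |W - t(W)| = %.3g); symmetrized by averaging",
      asym
    ))
    weights <- (weights + t(weights)) / 2
  } else if (asym > 0) {
    weights <- (weights + t(weights)) / 2
  }
  dimnames(weights) <- list(ids, ids)
  structure(list(ids = ids, weights = weights), class = "similarity_network")
}

#' Read a miRNA functional-similarity matrix
#'
#' Expects a delimited file with a header row and a first label column
#' holding the same ordered miRNA identifiers. Gzipped files are handled
#' transparently.
#'
#' @param path Path to a TSV/CSV file (optionally gzipped).
#' @param delimiter Field separator; `NULL` auto-detects tab vs comma.
#' @inheritParams similarity_network
#' @return A [similarity_network].
#' @export
read_similarity_matrix <- function(path, delimiter = NULL, tol = 1e-9) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path,
    header = TRUE, sep = delimiter, row.names = 1,
    check.names = FALSE, comment.char = "", quote = "\"",
    stringsAsFactors = FALSE
  )
  m <- as.matrix(df)
  if (!is.numeric(m)) abort_value("similarity matrix contains non-numeric entries")
  row_ids <- trimws(rownames(m))
  col_ids <- trimws(colnames(m))
  if (length(row_ids) != length(col_ids) ||
    !all(id_key(row_ids) == id_key(col_ids))) {
    abort_format("row and column identifiers must be identical and ordered")
  }
  similarity_network(m, ids = row_ids, tol = tol)
}

#' Write a similarity network to a TSV file
#'
#' @param net A [similarity_network].
#' @param path Output path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(net, path) {
  stopifnot(inherits(net, "similarity_network"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  df <- as.data.frame(net$weights, check.names = FALSE)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = TRUE, col.names = NA
  )
  invisible(path)
}

#' Construct a bipartite miRNA-mRNA interaction network
#'
#' Interactions are stored as unique (miRNA, gene) pairs. For walking and
#' embedding the graph is treated as a single homogeneous unweighted
#' undirected graph over miRNA and gene nodes.
#'
#' @param edges Data frame with two columns: miRNA id then gene id.
#' @return An object of class `bipartite_network` with `mirna_ids`,
#'   `gene_ids` (first-appearance order) and an `edges` tibble.
#' @export
bipartite_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) != 2) abort_format("edge table must have exactly 2 columns")
  names(edges) <- c("mirna", "gene")
  edges$mirna <- trimws(as.character(edges$mirna))
  edges$gene <- trimws(as.character(edges$gene))
  if (any(edges$mirna == "" | edges$gene == "")) {
    abort_format("edge list contains empty identifiers")
  }
  key <- paste(id_key(edges$mirna), id_key(edges$gene), sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  mirna_ids <- edges$mirna[!duplicated(id_key(edges$mirna))]
  gene_ids <- edges$gene[!duplicated(id_key(edges$gene))]
  structure(
    list(
      mirna_ids = mirna_ids, gene_ids = gene_ids,
      edges = tibble::as_tibble(edges)
    ),
    class = "bipartite_network"
  )
}

#' Read a miRNA-mRNA interaction edge list
#'
#' Two tab-separated columns (miRNA id, gene id), one interaction per line;
#' lines starting with `#` are comments. Duplicate interactions are
#' collapsed and the distinct miRNA/gene counts are reported.
#'
#' @param path Path to the edge list (optionally gzipped).
#' @param quiet Suppress the distinct-count message.
#' @return A [bipartite_network].
#' @export
read_interaction_edges <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    bad <- which(keep)[which(nf != 2)[1]]
    abort_format(sprintf(
      "line %d: expected 2 tab-separated fields, found %d", bad,
      nf[which(nf != 2)[1]]
    ))
  }
  edges <- data.frame(
    mirna = vapply(fields, `[[`, "", 1L),
    gene = vapply(fields, `[[`, "", 2L)
  )
  net <- bipartite_network(edges)
  if (!quiet) {
    inform(sprintf(
      "interaction network: %d edges, %d distinct miRNAs, %d distinct genes",
      nrow(net$edges), length(net$mirna_ids), length(net$gene_ids)
    ))
  }
  net
}

#' Write an interaction edge list to a TSV file
#'
#' @param net A [bipartite_network].
#' @param path Output path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_interaction_edges <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(net$edges), con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Construct a positive-label set
#'
#' In the positive-unlabeled setting only disease-associated miRNAs are
#' annotated; every other miRNA of the universe is unlabeled.
#'
#' @param positives Character vector of disease-associated miRNA ids.
#' @param universe Character vector of all miRNA ids present in at least one
#'   network.
#' @return An object of class `label_set` with `positives`, `universe` and
#'   `unlabeled`.
#' @export
label_set <- function(positives, universe) {
  positives <- trimws(as.character(positives))
  universe <- trimws(as.character(universe))
  universe <- universe[!duplicated(id_key(universe))]
  positives <- positives[!duplicated(id_key(positives))]
  miss <- !(id_key(positives) %in% id_key(universe))
  if (any(miss)) {
    abort_config(sprintf(
      "%d positive id(s) not in the universe; use read_labels() to drop them",
      sum(miss)
    ))
  }
  # report positives in the universe's spelling
  positives <- universe[match(id_key(positives), id_key(universe))]
  structure(
    list(
      positives = positives, universe = universe,
      unlabeled = setdiff(universe, positives)
    ),
    class = "label_set"
  )
}

#' Read a positive-label list
#'
#' One miRNA id per line; duplicates are collapsed and ids absent from the
#' universe are dropped with a warning.
#'
#' @param path Path to the label file (optionally gzipped).
#' @param universe Character vector of all known miRNA ids.
#' @return A [label_set].
#' @export
read_labels <- function(path, universe) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  ids <- trimws(readLines(con, warn = FALSE))
  ids <- ids[ids != "" & !grepl("^#", ids)]
  ids <- ids[!duplicated(id_key(ids))]
  present <- id_key(ids) %in% id_key(universe)
  if (any(!present)) {
    warn(sprintf("%d label id(s) absent from the universe were dropped", sum(!present)))
  }
  ids <- ids[present]
  if (length(ids) == 0) {
    abort_config("no positive labels remain after intersecting with the universe")
  }
  label_set(ids, universe)
}

#' Write a positive-label list
#'
#' @param labels A [label_set].
#' @param path Output path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_set"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(labels$positives, con)
  invisible(path)
}

#' @export
print.similarity_network <- function(x, ...) {
  pos <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf(
    "<similarity_network> %d miRNAs, %d positive-weight pairs\n",
    length(x$ids), pos
  ))
  invisible(x)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network> %d miRNAs, %d genes, %d interactions\n",
    length(x$mirna_ids), length(x$gene_ids), nrow(x$edges)
  ))
  invisible(x)
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf(
    "<label_set> %d positives / %d universe (%d unlabeled)\n",
    length(x$positives), length(x$universe), length(x$unlabeled)
  ))
  invisible(x)
}
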