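# Skip-gram embedding of walk corpora. Production training uses negative
# sampling (SGNS); the exact-softmax co-occurrence likelihood is implemented
# separately as a diagnostic/oracle and is never part of the training path.

#' Skip-gram training configuration
#'
#' @param dim Embedding dimension per network (default 512).
#' @param window Context radius within a walk.
#' @param negatives Negative samples per positive (center, context) pair.
#' @param epochs Passes over the walk corpus (default 1, the reference
#'   node2vec setting; the corpus already visits every node `num_walks`
#'   times).
#' @param learning_rate Initial SGD rate; decays linearly to 1e-4 of itself.
#' @param seed Integer seed (initialization, window jitter, negatives).
#' @return A `skipgram_config` list.
#' @export
skipgram_config <- function(dim = 512L, window = 10L, negatives = 5L,
                            epochs = 1L, learning_rate = 0.025, seed = 1L) {
  check_scalar_number(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  structure(
    list(
      dim = check_count(dim, "dim", 1L),
      window = check_count(window, "window", 1L),
      negatives = check_count(negatives, "negatives", 0L),
      epochs = check_count(epochs, "epochs", 1L),
      learning_rate = learning_rate,
      seed = check_count(seed, "seed", 0L)
    ),
    class = "skipgram_config"
  )
}

#' Train skip-gram with negative sampling on a walk corpus
#'
#' Learns one `dim`-dimensional vector per node by maximizing the
#' probability of observing each node's walk-window neighborhood, with the
#' softmax normalizer approximated by negative sampling from the
#' unigram^(3/4) distribution. Stochastic gradient descent with a linearly
#' decaying rate; deterministic given the seed (single-threaded).
#'
#' @param corpus A `walk_corpus` from [generate_walks()].
#' @param cfg A [skipgram_config].
#' @param snapshots Keep a copy of the embedding after every epoch (for
#'   convergence diagnostics on small graphs) in attribute `"snapshots"`.
#' @return An `embedding_matrix`: `ids` plus a `|ids| x dim` matrix
#'   `vectors` (rownames = ids).
#' @export
train_skipgram <- function(corpus, cfg = skipgram_config(), snapshots = FALSE) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (nrow(corpus$walks) == 0) abort_config("walk corpus is empty")
  res <- cpp_train_skipgram(
    corpus$walks, length(corpus$ids), cfg$dim, cfg$window,
    cfg$negatives, cfg$epochs, cfg$learning_rate, cfg$seed, snapshots
  )
  emb <- embedding_matrix(res$embedding, corpus$ids)
  if (snapshots) {
    attr(emb, "snapshots") <- lapply(res$snapshots, function(m) {
      rownames(m) <- corpus$ids
      m
    })
  }
  emb
}

#' Construct an embedding matrix
#'
#' @param vectors Numeric `n x d` matrix of node vectors.
#' @param ids Character node ids, one per row.
#' @return An `embedding_matrix`.
#' @export
embedding_matrix <- function(vectors, ids) {
  vectors <- as.matrix(vectors)
  if (length(ids) != nrow(vectors)) {
    abort_shape("one id per embedding row is required")
  }
  if (any(!is.finite(vectors))) abort_value("embedding has non-finite entries")
  rownames(vectors) <- ids
  structure(list(ids = as.character(ids), vectors = vectors),
    class = "embedding_matrix"
  )
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf(
    "<embedding_matrix> %d nodes x %d dims\n",
    nrow(x$vectors), ncol(x$vectors)
  ))
  invisible(x)
}

#' @describeIn embedding_matrix Long tibble (id, dimension, value).
#' @param x An `embedding_matrix`.
#' @param ... Unused.
#' @export
tidy.embedding_matrix <- function(x, ...) {
  tibble::tibble(
    id = rep(x$ids, ncol(x$vectors)),
    dimension = rep(seq_len(ncol(x$vectors)), each = length(x$ids)),
    value = as.vector(x$vectors)
  )
}

#' Write / read embeddings in word2vec text format
#'
#' Header line `"N d"`, then one `"id v1 ... vd"` line per node.
#'
#' @param emb An `embedding_matrix`.
#' @param path Output path (gzipped when it ends in `.gz`).
#' @return `path` invisibly; `read_embedding()` returns the
#'   `embedding_matrix`.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb$vectors), ncol(emb$vectors)), con)
  rows <- apply(emb$vectors, 1, function(v) {
    paste(format(v, digits = 17, scientific = TRUE, trim = TRUE), collapse = " ")
  })
  writeLines(paste(emb$ids, rows), con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) abort_format("missing word2vec header line")
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  if (length(parts) != hdr[1]) abort_format("row count does not match header")
  ids <- vapply(parts, `[[`, "", 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  embedding_matrix(vec, ids)
}

#' Exact softmax co-occurrence probability
#'
#' The exact (unapproximated) softmax probability of observing node `v` in
#' the neighborhood of `u`: `exp(f(u).f(v)) / sum_n exp(f(u).f(n))` over the
#' whole vocabulary. Used as the oracle the negative-sampling objective
#' approximates; quadratic in vocabulary size, so intended for small graphs.
#'
#' @param emb An `embedding_matrix`.
#' @param u,v Node ids.
#' @return Probability in (0, 1).
#' @export
skipgram_softmax_prob <- function(emb, u, v) {
  ui <- match(u, emb$ids)
  vi <- match(v, emb$ids)
  if (is.na(ui) || is.na(vi)) abort_value("unknown node id")
  s <- drop(emb$vectors %*% emb$vectors[ui, ])
  s <- s - max(s)
  unname(exp(s[vi]) / sum(exp(s)))
}

#' Exact softmax corpus loss
#'
#' Sum over every (center, context) pair within `window` in the corpus of
#' `-log P(context | f(center))` with the exact softmax — the negative
#' co-occurrence log-likelihood the embedding is meant to reduce.
#'
#' @param emb An `embedding_matrix`.
#' @param corpus A `walk_corpus` over the same node set.
#' @param window Context radius.
#' @return Scalar loss (mean per pair).
#' @export
skipgram_softmax_loss <- function(emb, corpus, window = 10L) {
  V <- emb$vectors
  S <- V %*% t(V)
  S <- sweep(S, 1, apply(S, 1, max))
  logZ <- log(rowSums(exp(S)))
  logP <- S - logZ # logP[u, v] = log P(v | f(u))
  walks <- corpus$walks
  tot <- 0
  np <- 0L
  wl <- ncol(walks)
  for (off in seq_len(min(window, wl - 1L))) {
    a <- walks[, seq_len(wl - off), drop = FALSE]
    b <- walks[, seq_len(wl - off) + off, drop = FALSE]
    # both directions: b in NS(a) and a in NS(b)
    tot <- tot - sum(logP[cbind(as.vector(a), as.vector(b))]) -
      sum(logP[cbind(as.vector(b), as.vector(a))])
    np <- np + 2L * length(a)
  }
  tot / np
}

#' Negative-sampling pair loss and gradient
#'
#' Loss for one (center, context) pair with sampled negatives:
#' `-log sigmoid(u . v) - sum_i log sigmoid(-u . n_i)`, where `u` is the
#' input vector of the context word and `v`, `n_i` are output vectors.
#' `sgns_pair_grad()` returns the analytic gradients checked against finite
#' differences in the test suite.
#'
#' @param u Input vector.
#' @param v Positive output vector.
#' @param negs Matrix of negative output vectors (one per row), or `NULL`.
#' @return Scalar loss; for the gradient, a list with `du`, `dv`, `dnegs`.
#' @export
sgns_pair_loss <- function(u, v, negs = NULL) {
  loss <- -log(stats::plogis(sum(u * v)))
  if (!is.null(negs) && nrow(negs) > 0) {
    loss <- loss - sum(log(stats::plogis(-drop(negs %*% u))))
  }
  loss
}

#' @rdname sgns_pair_loss
#' @export
sgns_pair_grad <- function(u, v, negs = NULL) {
  sp <- stats::plogis(sum(u * v))
  du <- -(1 - sp) * v
  dv <- -(1 - sp) * u
  dnegs <- NULL
  if (!is.null(negs) && nrow(negs) > 0) {
    sn <- stats::plogis(drop(negs %*% u)) # sigmoid(u . n_i)
    du <- du + drop(t(negs) %*% sn)
    dnegs <- outer(sn, u)
  }
  list(du = du, dv = dv, dnegs = dnegs)
}
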