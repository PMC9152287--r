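# Second-order biased random walks (node2vec-style). The return parameter p
# penalizes stepping back to the previous node; the in-out parameter q trades
# breadth-first (q > 1) against depth-first (q < 1) exploration. Transition
# scores are w(curr, x) * alpha with alpha = 1/p when x is the previous node,
# 1 when x is adjacent to it, and 1/q otherwise; p = q = 1 recovers the
# plain weight-proportional walk (DeepWalk).

#' Random-walk configuration
#'
#' @param p Return parameter (> 0). Default 10: walks rarely step back.
#' @param q In-out parameter (> 0). Default 0.5: depth-first leaning walks.
#' @param num_walks Walks started from every non-isolated node.
#' @param walk_length Nodes per walk.
#' @param seed Integer seed; identical seeds reproduce corpora exactly.
#' @return A `walk_config` list.
#' @export
walk_config <- function(p = 10, q = 0.5, num_walks = 10L, walk_length = 80L,
                        seed = 1L) {
  check_scalar_number(p, "p", lower = 0, strict_lower = TRUE)
  check_scalar_number(q, "q", lower = 0, strict_lower = TRUE)
  structure(
    list(
      p = p, q = q,
      num_walks = check_count(num_walks, "num_walks", 1L),
      walk_length = check_count(walk_length, "walk_length", 2L),
      seed = check_count(seed, "seed", 0L)
    ),
    class = "walk_config"
  )
}

#' Convert a network to a walkable graph
#'
#' Builds the compressed sparse adjacency used by the walker. For similarity
#' networks, off-diagonal entries above `threshold` become weighted edges
#' (zero-weight pairs are omitted: their transition probability is zero
#' either way). Bipartite networks become a single homogeneous unweighted
#' graph over miRNA followed by gene nodes.
#'
#' @param x A [similarity_network] or [bipartite_network].
#' @param threshold Minimum similarity for an edge (similarity networks
#'   only); the default 0 keeps every positive weight.
#' @return A `walk_graph` list with `ids`, CSR `offsets`/`nbr`/`wts`, and
#'   `n_mirna` (bipartite only).
#' @export
as_walk_graph <- function(x, threshold = 0) {
  UseMethod("as_walk_graph")
}

#' @export
as_walk_graph.walk_graph <- function(x, threshold = 0) x

#' @export
as_walk_graph.similarity_network <- function(x, threshold = 0) {
  w <- x$weights
  diag(w) <- 0
  w[w <= threshold] <- 0
  idx <- which(w > 0, arr.ind = TRUE)
  # order by source node then neighbor for a deterministic CSR layout
  o <- order(idx[, 1], idx[, 2])
  src <- idx[o, 1]
  dst <- idx[o, 2]
  deg <- tabulate(src, nbins = nrow(w))
  structure(
    list(
      ids = x$ids,
      offsets = c(0L, cumsum(deg)),
      nbr = as.integer(dst - 1L),
      wts = w[cbind(src, dst)],
      n_mirna = length(x$ids)
    ),
    class = "walk_graph"
  )
}

#' @export
as_walk_graph.bipartite_network <- function(x, threshold = 0) {
  nm <- length(x$mirna_ids)
  ids <- c(x$mirna_ids, x$gene_ids)
  mi <- match(id_key(x$edges$mirna), id_key(x$mirna_ids))
  gi <- match(id_key(x$edges$gene), id_key(x$gene_ids)) + nm
  src <- c(mi, gi)
  dst <- c(gi, mi)
  o <- order(src, dst)
  src <- src[o]
  dst <- dst[o]
  deg <- tabulate(src, nbins = length(ids))
  structure(
    list(
      ids = ids,
      offsets = c(0L, cumsum(deg)),
      nbr = as.integer(dst - 1L),
      wts = rep(1, length(src)),
      n_mirna = nm
    ),
    class = "walk_graph"
  )
}

#' Second-order transition distribution
#'
#' Probability of stepping from `curr` to each of its neighbors given the
#' previously visited node. With `prev = NULL` (the first step of a walk)
#' probabilities are purely weight-proportional.
#'
#' @param graph A network or `walk_graph`.
#' @param curr Current node id.
#' @param prev Previous node id, or `NULL` for the first step.
#' @param cfg A [walk_config] supplying `p` and `q`.
#' @return Named numeric vector of probabilities over the neighbors of
#'   `curr` (sums to 1), or an empty vector when `curr` is isolated.
#' @export
transition_distribution <- function(graph, curr, prev = NULL,
                                    cfg = walk_config()) {
  g <- as_walk_graph(graph)
  ci <- match(id_key(curr), id_key(g$ids))
  if (is.na(ci)) abort_value(sprintf("unknown node `%s`", curr))
  pi <- -1L
  if (!is.null(prev)) {
    pi <- match(id_key(prev), id_key(g$ids)) - 1L
    if (is.na(pi)) abort_value(sprintf("unknown node `%s`", prev))
  }
  pr <- cpp_transition_probs(
    g$offsets, g$nbr, g$wts, as.integer(pi),
    as.integer(ci - 1L), cfg$p, cfg$q
  )
  lo <- g$offsets[ci] + 1L
  hi <- g$offsets[ci + 1L]
  names(pr) <- if (hi >= lo) g$ids[g$nbr[lo:hi] + 1L] else character(0)
  pr
}

#' Generate a biased random-walk corpus
#'
#' Starts `num_walks` walks of `walk_length` nodes from every non-isolated
#' node; the first step is weight-proportional, later steps use the
#' second-order bias. Isolated nodes produce no walks and are reported.
#'
#' @inheritParams transition_distribution
#' @param quiet Suppress the isolated-node message.
#' @return A `walk_corpus`: node `ids` plus an integer matrix `walks` (one
#'   walk per row, values index `ids`).
#' @export
generate_walks <- function(graph, cfg = walk_config(), quiet = FALSE) {
  g <- as_walk_graph(graph)
  n <- length(g$ids)
  if (n == 0) abort_config("graph has no nodes")
  iso <- sum(diff(g$offsets) == 0)
  if (iso > 0 && !quiet) {
    inform(sprintf("%d isolated node(s) produce no walks", iso))
  }
  walks <- cpp_generate_walks(
    g$offsets, g$nbr, g$wts, cfg$num_walks,
    cfg$walk_length, cfg$p, cfg$q, cfg$seed
  )
  structure(
    list(ids = g$ids, walks = walks, n_mirna = g$n_mirna),
    class = "walk_corpus"
  )
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf(
    "<walk_corpus> %d walks x %d steps over %d nodes\n",
    nrow(x$walks), ncol(x$walks), length(x$ids)
  ))
  invisible(x)
}
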