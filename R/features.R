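# Per-miRNA feature construction: embed each network separately, keep only
# miRNA vectors, and concatenate [similarity-block | interaction-block]. A
# miRNA present in only one network gets exact zeros in the other block.

#' Embed one network
#'
#' Generates the biased-walk corpus and trains skip-gram on it. For
#' bipartite networks gene nodes participate in the walks and the
#' vocabulary, but only miRNA vectors are used downstream.
#'
#' @param net A [similarity_network] or [bipartite_network].
#' @param walk A [walk_config].
#' @param skipgram A [skipgram_config].
#' @param quiet Suppress progress messages.
#' @return An `embedding_matrix` over all nodes of the network.
#' @export
embed_network <- function(net, walk = walk_config(),
                          skipgram = skipgram_config(), quiet = TRUE) {
  corpus <- generate_walks(net, walk, quiet = quiet)
  train_skipgram(corpus, skipgram)
}

#' Fuse per-network embeddings into miRNA features
#'
#' Builds the `|miRNAs| x (d_sim + d_int)` feature table whose rows are
#' `[similarity-block | interaction-block]`. Blocks of miRNAs absent from a
#' network are zero-padded; miRNAs absent from both networks are dropped
#' with a warning.
#'
#' @param emb_sim Embedding of the similarity network.
#' @param emb_int Embedding of the interaction network (may contain gene
#'   vectors, which are ignored).
#' @param mirna_ids Character vector: the miRNA universe to assemble rows
#'   for (ids are matched case-insensitively).
#' @return A `feature_table` with `ids`, a `features` matrix, and a
#'   `presence` tibble of per-network membership flags.
#' @export
fuse_features <- function(emb_sim, emb_int, mirna_ids) {
  stopifnot(inherits(emb_sim, "embedding_matrix"), inherits(emb_int, "embedding_matrix"))
  mirna_ids <- trimws(as.character(mirna_ids))
  mirna_ids <- mirna_ids[!duplicated(id_key(mirna_ids))]
  d1 <- ncol(emb_sim$vectors)
  d2 <- ncol(emb_int$vectors)
  i1 <- match(id_key(mirna_ids), id_key(emb_sim$ids))
  i2 <- match(id_key(mirna_ids), id_key(emb_int$ids))
  orphan <- is.na(i1) & is.na(i2)
  if (any(orphan)) {
    warn(sprintf("%d miRNA(s) absent from both networks were dropped", sum(orphan)))
    mirna_ids <- mirna_ids[!orphan]
    i1 <- i1[!orphan]
    i2 <- i2[!orphan]
  }
  if (length(mirna_ids) == 0) abort_config("no miRNAs left to fuse")
  feats <- matrix(0, nrow = length(mirna_ids), ncol = d1 + d2)
  feats[!is.na(i1), seq_len(d1)] <- emb_sim$vectors[i1[!is.na(i1)], , drop = FALSE]
  feats[!is.na(i2), d1 + seq_len(d2)] <- emb_int$vectors[i2[!is.na(i2)], , drop = FALSE]
  rownames(feats) <- mirna_ids
  structure(
    list(
      ids = mirna_ids, features = feats, d_sim = d1, d_int = d2,
      presence = tibble::tibble(
        id = mirna_ids,
        in_similarity = !is.na(i1),
        in_interaction = !is.na(i2)
      )
    ),
    class = "feature_table"
  )
}

#' Restrict a feature table to one network's block
#'
#' Zeroes the complementary 512-column block, as in the single-network
#' comparison experiments.
#'
#' @param ft A `feature_table`.
#' @param source `"both"`, `"similarity_only"`, or `"interaction_only"`.
#' @return The modified `feature_table`.
#' @export
apply_feature_source <- function(ft, source = c("both", "similarity_only", "interaction_only")) {
  source <- match.arg(source)
  stopifnot(inherits(ft, "feature_table"))
  if (source == "similarity_only") {
    ft$features[, ft$d_sim + seq_len(ft$d_int)] <- 0
  } else if (source == "interaction_only") {
    ft$features[, seq_len(ft$d_sim)] <- 0
  }
  ft
}

#' Full feature pipeline: embed both networks and fuse
#'
#' @param similarity A [similarity_network].
#' @param interaction A [bipartite_network].
#' @param walk A [walk_config]; `embedder = "deepwalk"` overrides p = q = 1.
#' @param skipgram A [skipgram_config] (applied to both networks; the
#'   interaction network uses `seed + 1` so the two trainings are
#'   independent streams).
#' @param embedder `"node2vec"` (biased walks) or `"deepwalk"` (p = q = 1).
#' @param quiet Suppress progress messages.
#' @return A `feature_table` over the union of the two networks' miRNAs.
#' @export
mirdap_features <- function(similarity, interaction, walk = walk_config(),
                            skipgram = skipgram_config(),
                            embedder = c("node2vec", "deepwalk"),
                            quiet = TRUE) {
  embedder <- match.arg(embedder)
  if (embedder == "deepwalk") {
    walk$p <- 1
    walk$q <- 1
  }
  walk_int <- walk
  walk_int$seed <- walk$seed + 1L
  sg_int <- skipgram
  sg_int$seed <- skipgram$seed + 1L
  emb_sim <- embed_network(similarity, walk, skipgram, quiet = quiet)
  emb_int <- embed_network(interaction, walk_int, sg_int, quiet = quiet)
  universe <- c(similarity$ids, interaction$mirna_ids)
  fuse_features(emb_sim, emb_int, universe)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d miRNAs x %d features (%d + %d)\n",
    length(x$ids), ncol(x$features), x$d_sim, x$d_int
  ))
  invisible(x)
}

#' @describeIn fuse_features Presence flags as a tibble.
#' @param x A `feature_table`.
#' @param ... Unused.
#' @export
tidy.feature_table <- function(x, ...) x$presence
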