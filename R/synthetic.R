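# Synthetic benchmark generator. Emulates the statistical structure the
# method assumes: disease-associated miRNAs form a functional-similarity
# community (elevated pairwise similarity) and preferentially share mRNA
# targets drawn from a common gene pool. Writes the same three formats the
# readers consume, so synthetic runs exercise the real parsers.

#' Synthetic dataset configuration
#'
#' @param n_mirna,n_gene,n_pos Numbers of miRNAs, genes, and planted
#'   positives.
#' @param sim_within Mean similarity among positive miRNAs.
#' @param sim_background Mean similarity otherwise.
#' @param sim_noise SD of the additive Gaussian noise (mirrored across the
#'   diagonal, then clipped to `[0, 1]`).
#' @param targets_per_mirna Distinct gene targets per miRNA.
#' @param shared_target_pool Size of the gene pool positives preferentially
#'   target.
#' @param share_prob Probability a positive's target comes from the shared
#'   pool.
#' @param missing_frac Fraction of miRNAs removed from exactly one network
#'   (exercises zero-padding).
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_mirna = 500L, n_gene = 2000L, n_pos = 100L,
                             sim_within = 0.6, sim_background = 0.15,
                             sim_noise = 0.05, targets_per_mirna = 40L,
                             shared_target_pool = 200L, share_prob = 0.7,
                             missing_frac = 0.1, seed = 42L) {
  cfg <- list(
    n_mirna = check_count(n_mirna, "n_mirna", 2L),
    n_gene = check_count(n_gene, "n_gene", 1L),
    n_pos = check_count(n_pos, "n_pos", 1L),
    sim_within = check_scalar_number(sim_within, "sim_within", 0, 1),
    sim_background = check_scalar_number(sim_background, "sim_background", 0, 1),
    sim_noise = check_scalar_number(sim_noise, "sim_noise", 0),
    targets_per_mirna = check_count(targets_per_mirna, "targets_per_mirna", 1L),
    shared_target_pool = check_count(shared_target_pool, "shared_target_pool", 1L),
    share_prob = check_scalar_number(share_prob, "share_prob", 0, 1),
    missing_frac = check_scalar_number(missing_frac, "missing_frac", 0, 1),
    seed = check_count(seed, "seed", 0L)
  )
  if (cfg$n_pos >= cfg$n_mirna) abort_config("`n_pos` must be < `n_mirna`")
  if (cfg$sim_background > cfg$sim_within) {
    abort_config("`sim_background` must be <= `sim_within`")
  }
  if (cfg$targets_per_mirna > cfg$n_gene) {
    abort_config("`targets_per_mirna` cannot exceed `n_gene`")
  }
  if (cfg$shared_target_pool > cfg$n_gene) {
    abort_config("`shared_target_pool` cannot exceed `n_gene`")
  }
  structure(cfg, class = "synthetic_config")
}

#' The standard synthetic benchmark configuration
#'
#' Scales mimic the real resources: ~500 miRNAs with ~100 disease
#' positives, 2000 genes, 40 targets per miRNA, a 200-gene shared pool
#' targeted with probability 0.7, and 10% of miRNAs present in only one
#' network.
#'
#' @return A [synthetic_config()].
#' @export
default_benchmark <- function() synthetic_config()

#' Generate a synthetic dataset
#'
#' Similarity = block means (within-positive vs background) + symmetric
#' truncated Gaussian noise, clipped to `[0, 1]`, unit diagonal. Each miRNA
#' targets `targets_per_mirna` distinct genes; positives draw each target
#' from the shared pool with probability `share_prob`. `missing_frac` of
#' the miRNAs are then removed from exactly one (randomly chosen) network.
#'
#' @param cfg A [synthetic_config()].
#' @return A `mirdap_dataset` list: `similarity` ([similarity_network]),
#'   `interaction` ([bipartite_network]), `labels` ([label_set]), `config`.
#' @export
generate_dataset <- function(cfg = default_benchmark()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_mirna
    ids <- sprintf("hsa-miR-synth-%d", seq_len(n))
    genes <- sprintf("G%06d", seq_len(cfg$n_gene))
    pos <- sort(sample(n, cfg$n_pos))

    w <- matrix(cfg$sim_background, n, n)
    w[pos, pos] <- cfg$sim_within
    noise <- matrix(0, n, n)
    up <- upper.tri(noise)
    noise[up] <- rnorm(sum(up), 0, cfg$sim_noise)
    noise <- noise + t(noise)
    w <- pmin(pmax(w + noise, 0), 1)
    diag(w) <- 1
    dimnames(w) <- list(ids, ids)

    pool <- genes[seq_len(cfg$shared_target_pool)]
    k <- cfg$targets_per_mirna
    target_list <- lapply(seq_len(n), function(i) {
      if (i %in% pos) {
        k_shared <- stats::rbinom(1, k, cfg$share_prob)
        sh <- sample(pool, min(k_shared, length(pool)))
        c(sh, sample(setdiff(genes, sh), k - length(sh)))
      } else {
        sample(genes, k)
      }
    })
    edges <- data.frame(
      mirna = rep(ids, each = k),
      gene = unlist(target_list)
    )

    n_miss <- round(cfg$missing_frac * n)
    sim_keep <- rep(TRUE, n)
    if (n_miss > 0) {
      miss <- sample(n, n_miss)
      from_sim <- as.logical(stats::rbinom(n_miss, 1, 0.5))
      sim_keep[miss[from_sim]] <- FALSE
      drop_int <- ids[miss[!from_sim]]
      edges <- edges[!(edges$mirna %in% drop_int), , drop = FALSE]
    }

    structure(
      list(
        similarity = similarity_network(
          w[sim_keep, sim_keep, drop = FALSE],
          ids = ids[sim_keep]
        ),
        interaction = bipartite_network(edges),
        labels = label_set(ids[pos], ids),
        config = cfg
      ),
      class = "mirdap_dataset"
    )
  })
}

#' Write a synthetic dataset in the three input formats
#'
#' Creates `similarity.tsv`, `interactions.tsv` and `positives.txt` under
#' `dir`.
#'
#' @param ds A `mirdap_dataset`.
#' @param dir Output directory (created if needed).
#' @param gzip Compress the similarity matrix and edge list.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, dir, gzip = FALSE) {
  stopifnot(inherits(ds, "mirdap_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  paths <- c(
    similarity = file.path(dir, paste0("similarity.tsv", ext)),
    interactions = file.path(dir, paste0("interactions.tsv", ext)),
    labels = file.path(dir, "positives.txt")
  )
  write_similarity_matrix(ds$similarity, paths[["similarity"]])
  write_interaction_edges(ds$interaction, paths[["interactions"]])
  write_labels(ds$labels, paths[["labels"]])
  invisible(paths)
}

#' @export
print.mirdap_dataset <- function(x, ...) {
  cat(sprintf(
    "<mirdap_dataset> %d miRNAs (%d positive), %d in similarity net, %d genes\n",
    length(x$labels$universe), length(x$labels$positives),
    length(x$similarity$ids), length(x$interaction$gene_ids)
  ))
  invisible(x)
}
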