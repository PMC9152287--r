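# A reduced-scale generator configuration used for the cheap structural
# checks (the full default benchmark is exercised in the acceptance suite).
small_syn <- function(...) {
  args <- list(...)
  defaults <- list(
    n_mirna = 100L, n_gene = 200L, n_pos = 30L, sim_within = 0.8,
    sim_background = 0.2, sim_noise = 0.05, targets_per_mirna = 10L,
    shared_target_pool = 30L, share_prob = 0.7, missing_frac = 0.1,
    seed = 12L
  )
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

test_that("the default benchmark echoes its stated scale", {
  cfg <- default_benchmark()
  expect_equal(cfg$n_mirna, 500L)
  expect_equal(cfg$n_pos, 100L)
  ds <- cache_get("bench_ds_small_checks", generate_dataset(cfg))
  expect_length(ds$labels$universe, 500)
  expect_length(ds$labels$positives, 100)
  expect_true(all(ds$labels$positives %in% ds$labels$universe))
  # every miRNA appears in at least one network
  in_sim <- ds$labels$universe %in% ds$similarity$ids
  in_int <- ds$labels$universe %in% ds$interaction$mirna_ids
  expect_true(all(in_sim | in_int))
  # about missing_frac are single-network
  expect_equal(sum(!(in_sim & in_int)), 50)
})

test_that("emitted similarity matrices satisfy the network invariants", {
  ds <- generate_dataset(small_syn())
  w <- ds$similarity$weights
  expect_equal(w, t(w))
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diag(w) == 1))
})

test_that("the planted similarity block is detectable (t-statistic > 5)", {
  ds <- generate_dataset(small_syn())
  w <- ds$similarity$weights
  pos <- intersect(ds$labels$positives, ds$similarity$ids)
  pp <- w[pos, pos][upper.tri(diag(length(pos)))]
  bg_ids <- setdiff(ds$similarity$ids, pos)
  bb <- w[bg_ids, bg_ids][upper.tri(diag(length(bg_ids)))]
  tt <- t.test(pp, bb)
  expect_gt(unname(tt$statistic), 5)
})

test_that("positives share targets from the common pool", {
  ds <- generate_dataset(small_syn(missing_frac = 0))
  pool <- sprintf("G%06d", seq_len(30))
  edges <- ds$interaction$edges
  pos_frac <- mean(edges$gene[edges$mirna %in% ds$labels$positives] %in% pool)
  neg_frac <- mean(edges$gene[!edges$mirna %in% ds$labels$positives] %in% pool)
  expect_gt(pos_frac, 0.6) # share_prob 0.7
  expect_lt(neg_frac, 0.3) # background rate 30/200
})

test_that("identical seeds produce byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(small_syn()), d1)
  write_dataset(generate_dataset(small_syn()), d2)
  for (f in c("similarity.tsv", "interactions.tsv", "positives.txt")) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f))
    )
  }
  d3 <- withr::local_tempdir()
  write_dataset(generate_dataset(small_syn(seed = 13)), d3)
  expect_false(identical(
    readLines(file.path(d1, "positives.txt")),
    readLines(file.path(d3, "positives.txt"))
  ))
})

test_that("a null configuration plants no similarity signal", {
  ds <- generate_dataset(small_syn(
    sim_within = 0.2, sim_background = 0.2,
    share_prob = 30 / 200 # the background pool rate
  ))
  w <- ds$similarity$weights
  pos <- intersect(ds$labels$positives, ds$similarity$ids)
  pp <- w[pos, pos][upper.tri(diag(length(pos)))]
  bg_ids <- setdiff(ds$similarity$ids, pos)
  bb <- w[bg_ids, bg_ids][upper.tri(diag(length(bg_ids)))]
  expect_gt(t.test(pp, bb)$p.value, 0.01)
})

test_that("written datasets re-read into equivalent objects through the parsers", {
  ds <- generate_dataset(small_syn())
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  sim <- read_similarity_matrix(paths[["similarity"]])
  int <- read_interaction_edges(paths[["interactions"]], quiet = TRUE)
  labs <- read_labels(paths[["labels"]], c(sim$ids, int$mirna_ids))
  expect_equal(sim$weights, ds$similarity$weights, tolerance = 1e-12)
  expect_equal(nrow(int$edges), nrow(ds$interaction$edges))
  expect_setequal(labs$positives, ds$labels$positives)
})

test_that("infeasible configurations are rejected", {
  expect_error(small_syn(targets_per_mirna = 300), class = "mirdap_config_error")
  expect_error(small_syn(n_pos = 100), class = "mirdap_config_error")
  expect_error(small_syn(sim_background = 0.9), class = "mirdap_config_error")
})

test_that("a stronger planted effect yields higher pipeline ROC-AUC (reduced scale)", {
  auc_for_gap <- function(gap, seed) {
    ds <- generate_dataset(small_syn(
      sim_within = 0.2 + gap, sim_background = 0.2, seed = seed
    ))
    ft <- mirdap_features(ds$similarity, ds$interaction,
      walk = walk_config(num_walks = 4, walk_length = 20, seed = seed),
      skipgram = skipgram_config(dim = 24, seed = seed)
    )
    rep <- run_experiment(
      ft, ds$labels, experiment_config(seed = seed),
      encoder_config(code_dim = 32, epochs = 30, seed = seed)
    )
    glance(rep)$mean_roc_auc
  }
  lo <- stats::median(vapply(1:3, function(s) auc_for_gap(0.1, s), numeric(1)))
  hi <- stats::median(vapply(1:3, function(s) auc_for_gap(0.5, s), numeric(1)))
  expect_gt(hi, lo)
})
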