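test_that("exact softmax gives 0.5 for a two-node vocabulary with equal vectors", {
  emb <- embedding_matrix(rbind(c(1, 2, 3), c(1, 2, 3)), c("u", "v"))
  expect_equal(skipgram_softmax_prob(emb, "u", "v"), 0.5, tolerance = 1e-15)
  expect_equal(skipgram_softmax_prob(emb, "u", "u"), 0.5, tolerance = 1e-15)
})

test_that("negative-sampling pair gradients match central finite differences", {
  set.seed(21)
  d <- 12
  u <- rnorm(d, sd = 0.5)
  v <- rnorm(d, sd = 0.5)
  negs <- matrix(rnorm(3 * d, sd = 0.5), 3, d)
  an <- sgns_pair_grad(u, v, negs)

  rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))
  expect_lt(rel_err(
    numeric_gradient(function(x) sgns_pair_loss(x, v, negs), u), an$du
  ), 1e-5)
  expect_lt(rel_err(
    numeric_gradient(function(x) sgns_pair_loss(u, x, negs), v), an$dv
  ), 1e-5)
  num_dn <- numeric_gradient(
    function(x) sgns_pair_loss(u, v, matrix(x, 3, d)), as.vector(negs)
  )
  expect_lt(rel_err(matrix(num_dn, 3, d), an$dnegs), 1e-5)
})

test_that("training is deterministic given the seed", {
  net <- two_clique_similarity(6)
  cor <- generate_walks(net, walk_config(num_walks = 3, walk_length = 10, seed = 2),
    quiet = TRUE
  )
  cfg <- skipgram_config(dim = 8, epochs = 2, seed = 5)
  e1 <- train_skipgram(cor, cfg)
  e2 <- train_skipgram(cor, cfg)
  expect_identical(e1$vectors, e2$vectors)
  cfg2 <- cfg
  cfg2$seed <- 6
  expect_false(identical(e1$vectors, train_skipgram(cor, cfg2)$vectors))
})

test_that("nodes in the same community get more similar vectors than across", {
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  ok <- vapply(1:5, function(seed) {
    net <- two_clique_similarity(10)
    cor <- generate_walks(net,
      walk_config(num_walks = 8, walk_length = 20, seed = seed),
      quiet = TRUE
    )
    emb <- train_skipgram(cor, skipgram_config(dim = 8, epochs = 3, seed = seed))
    v <- emb$vectors
    grp <- rep(1:2, each = 10)
    intra <- c()
    inter <- c()
    for (i in 1:19) {
      for (j in (i + 1):20) {
        cs <- cos(v[i, ], v[j, ])
        if (grp[i] == grp[j]) intra <- c(intra, cs) else inter <- c(inter, cs)
      }
    }
    mean(intra) > mean(inter)
  }, logical(1))
  expect_gte(sum(ok), 4) # homophily holds in nearly every seed
})

test_that("training reduces the exact-softmax loss and holds it down across epochs", {
  # The sampled objective is not the exact softmax, so later epochs may
  # jitter by a few thousandths of a nat; what must hold is the large drop
  # from the untrained baseline and no systematic increase beyond that
  # stochastic tolerance (median over 5 seeds).
  trajectories <- sapply(1:5, function(seed) {
    net <- two_clique_similarity(10) # 20 nodes
    cor <- generate_walks(net,
      walk_config(num_walks = 5, walk_length = 15, seed = seed),
      quiet = TRUE
    )
    emb <- train_skipgram(cor, skipgram_config(dim = 8, epochs = 5, seed = seed),
      snapshots = TRUE
    )
    vapply(attr(emb, "snapshots"), function(m) {
      skipgram_softmax_loss(embedding_matrix(m, cor$ids), cor, window = 10)
    }, numeric(1))
  })
  baseline <- log(20) # uniform softmax over the 20-node vocabulary
  expect_true(all(trajectories < baseline - 0.3))
  deltas <- apply(trajectories, 2, diff)
  expect_true(all(apply(deltas, 1, stats::median) <= 0.01))
})

test_that("embeddings round-trip through word2vec text format", {
  set.seed(3)
  emb <- embedding_matrix(matrix(rnorm(12), 3, 4), c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_embedding(emb, path)
  expect_equal(readLines(path, n = 1), "3 4")
  back <- read_embedding(path)
  expect_equal(back$ids, emb$ids)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-15)
})
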