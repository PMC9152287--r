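test_that("transition distributions follow the p/q bias rule", {
  g <- second_order_graph()

  # p = q = 1: uniform over neighbors (unweighted)
  cfg1 <- walk_config(p = 1, q = 1)
  pr <- transition_distribution(g, "curr", prev = "prev", cfg = cfg1)
  expect_equal(unname(pr), rep(1 / 3, 3))

  # p = 10, q = 0.5: unnormalized (1/p, 1, 1/q) = (0.1, 1, 2)
  cfg <- walk_config(p = 10, q = 0.5)
  pr <- transition_distribution(g, "curr", prev = "prev", cfg = cfg)
  expect_equal(pr[["prev"]], 0.1 / 3.1, tolerance = 1e-12)
  expect_equal(pr[["a"]], 1 / 3.1, tolerance = 1e-12)
  expect_equal(pr[["b"]], 2 / 3.1, tolerance = 1e-12)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("edge weights scale transition probabilities proportionally", {
  g <- second_order_graph(weighted = TRUE) # w(curr,a)=0.5, w(curr,b)=0.25
  pr <- transition_distribution(g, "curr",
    prev = "prev",
    cfg = walk_config(p = 1, q = 1)
  )
  expect_equal(pr[["a"]] / pr[["b"]], 2, tolerance = 1e-12)
})

test_that("first-step distributions are weight-proportional", {
  net <- toy_similarity()
  pr <- transition_distribution(net, "mirA", cfg = walk_config())
  expect_equal(pr, c(mirB = 1))
  expect_length(transition_distribution(net, "mirC"), 0) # isolated
})

test_that("a single-edge path forces alternation and seeds reproduce corpora", {
  w <- matrix(0, 2, 2)
  w[1, 2] <- w[2, 1] <- 1
  diag(w) <- 1
  net <- similarity_network(w, ids = c("a", "b"))
  cfg <- walk_config(num_walks = 1, walk_length = 5, seed = 4)
  cor <- generate_walks(net, cfg, quiet = TRUE)
  from_a <- cor$walks[cor$walks[, 1] == 1, ]
  expect_equal(unname(from_a), c(1, 2, 1, 2, 1))

  cor2 <- generate_walks(net, cfg, quiet = TRUE)
  expect_identical(cor$walks, cor2$walks)

  # seeds must diverge on a graph with real branching
  branchy <- random_weighted_similarity(10, p_edge = 0.5, seed = 2)
  b1 <- generate_walks(branchy, walk_config(num_walks = 2, walk_length = 15, seed = 1), quiet = TRUE)
  b2 <- generate_walks(branchy, walk_config(num_walks = 2, walk_length = 15, seed = 2), quiet = TRUE)
  expect_false(identical(b1$walks, b2$walks))
})

test_that("star-graph first steps are uniform over leaves", {
  n_leaf <- 4
  w <- matrix(0, n_leaf + 1, n_leaf + 1)
  w[1, 1 + seq_len(n_leaf)] <- 1
  w[1 + seq_len(n_leaf), 1] <- 1
  diag(w) <- 1
  net <- similarity_network(w, ids = c("c", paste0("leaf", 1:n_leaf)))
  cor <- generate_walks(net,
    walk_config(num_walks = 1000, walk_length = 2, seed = 2),
    quiet = TRUE
  )
  second <- cor$walks[cor$walks[, 1] == 1, 2]
  counts <- tabulate(second - 1, nbins = n_leaf)
  # binomial(1000, 1/4): sd ~ 13.7, allow 5 sd
  expect_true(all(abs(counts - 250) < 70))
  expect_equal(sum(counts), 1000)
})

test_that("every consecutive walk pair is an edge of the source graph", {
  net <- random_weighted_similarity(15, p_edge = 0.3, seed = 8)
  adj <- net$weights > 0
  diag(adj) <- FALSE
  for (seed in 1:3) {
    cor <- generate_walks(net,
      walk_config(num_walks = 2, walk_length = 20, seed = seed),
      quiet = TRUE
    )
    a <- cor$walks[, -ncol(cor$walks)]
    b <- cor$walks[, -1]
    expect_true(all(adj[cbind(as.vector(a), as.vector(b))]))
  }
})

test_that("walk corpus size is num_walks x non-isolated nodes", {
  net <- toy_similarity() # mirC is isolated
  expect_message(
    cor <- generate_walks(net, walk_config(num_walks = 3, walk_length = 4)),
    "isolated"
  )
  expect_equal(nrow(cor$walks), 3 * 2)
  expect_false(3 %in% cor$walks) # isolated node never visited
})

test_that("p = q = 1 reduces to the weight-proportional walk on every node", {
  net <- random_weighted_similarity(12, p_edge = 0.4, seed = 3)
  g <- as_walk_graph(net)
  cfg <- walk_config(p = 1, q = 1)
  for (curr in seq_along(g$ids)) {
    nb <- g$nbr[(g$offsets[curr] + 1):g$offsets[curr + 1]] + 1
    if (g$offsets[curr + 1] == g$offsets[curr]) next
    for (prev in nb) {
      got <- transition_distribution(g, g$ids[curr],
        prev = g$ids[prev],
        cfg = cfg
      )
      w <- net$weights[curr, nb]
      expect_equal(unname(got), unname(w / sum(w)), tolerance = 1e-14)
    }
  }
})
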