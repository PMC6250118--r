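# Independent component-search oracle: exhaustive depth-first search on the
# pruned adjacency, written without igraph.
dfs_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0))
    }
  }
  comp
}

canon <- function(m) as.integer(factor(m, levels = unique(m)))

test_that("family clustering matches the constructed two-block example", {
  W <- matrix(-0.9, 6, 6)
  W[1:3, 1:3] <- 0; W[4:6, 4:6] <- 0
  tree <- cluster_families(W, cutoffs = c(-0.95, -0.5))
  expect_equal(tree$n_components, c(1L, 2L))
  expect_equal(canon(tree$partitions[[2]]), rep(1:2, each = 3))

  # fully cooperative layer: one component at every cutoff below zero
  z <- matrix(0, 5, 5)
  tr0 <- cluster_families(z, cutoffs = c(-0.9, -0.5, -0.1))
  expect_true(all(tr0$n_components == 1L))

  Wpos <- matrix(0.5, 3, 3); diag(Wpos) <- 0
  expect_error(cluster_families(Wpos), "\\[-1, 0\\]")
  expect_error(cluster_families(matrix(-0.5, 3, 3)), "diagonal")
})

test_that("components agree with an exhaustive DFS oracle on random matrices", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 20
    W <- matrix(-runif(n * n), n, n); diag(W) <- 0
    cuts <- sort(runif(4, -1, 0))
    tree <- cluster_families(W, cutoffs = cuts)
    S <- pmin(W, t(W))
    for (i in seq_along(cuts)) {
      adj <- S > cuts[i]; diag(adj) <- FALSE
      oracle <- dfs_components(adj)
      expect_equal(canon(tree$partitions[[i]]), canon(oracle))
    }
  }
})

test_that("partitions refine monotonically as the cutoff rises", {
  set.seed(3)
  n <- 15
  W <- matrix(-runif(n * n), n, n); diag(W) <- 0
  tree <- cluster_families(W)   # default sweep -1..0 by 0.05
  expect_true(all(diff(tree$n_components) >= 0))
  for (i in seq_len(length(tree$cutoffs) - 1)) {
    a <- tree$partitions[[i]]; b <- tree$partitions[[i + 1]]
    # finer partition: each later component lies inside one earlier component
    expect_true(all(tapply(a, b, function(x) length(unique(x))) == 1))
  }
})

test_that("family-to-class mapping reports labels, purity and agreement", {
  Who <- rbind(c(0.9, 0.1, 0), c(0.8, 0.2, 0), c(0.7, 0.1, 0.2))
  res <- map_families_to_classes(rep(1L, 3), Who)
  expect_identical(res$label, 0L)
  expect_equal(res$purity, 1)
  expect_equal(res$ari, 1)   # one family, one class: perfect agreement

  # two clean families aligned with two classes
  Who2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  res2 <- map_families_to_classes(c(1L, 1L, 2L, 2L), Who2)
  expect_identical(res2$label, c(0L, 1L))
  expect_equal(res2$ari, 1)
  expect_error(map_families_to_classes(c(1L, 1L), Who2), "all hidden")
})

test_that("random weights give near-chance family purity", {
  # Monte-Carlo oracle: majority share of a uniform multinomial assignment
  set.seed(8)
  K <- 10; n <- 40
  Who <- matrix(runif(n * K), n, K)
  res <- map_families_to_classes(rep(1L, n), Who)
  draws <- replicate(400, max(tabulate(sample.int(K, n, replace = TRUE), K)) / n)
  expect_lt(abs(res$purity - mean(draws)), 3 * sd(draws) + 1e-9)
})

test_that("receptive-field products compose shapes and match a triple loop", {
  set.seed(5)
  A <- matrix(runif(24), 6, 4)
  B <- matrix(runif(12), 4, 3)
  M <- receptive_field_product(A, B, normalize = FALSE)
  expect_identical(dim(M), c(6L, 3L))
  brute <- matrix(0, 6, 3)
  for (i in 1:6) for (k in 1:3) for (j in 1:4) brute[i, k] <- brute[i, k] + A[i, j] * B[j, k]
  expect_equal(M, brute)
  # linear in each argument
  expect_equal(receptive_field_product(2 * A, B, normalize = FALSE), 2 * M)
  # normalized columns span [0, 1]
  Mn <- receptive_field_product(A, B)
  expect_true(all(apply(Mn, 2, min) == 0) && all(apply(Mn, 2, max) == 1))
  expect_error(receptive_field_product(A, matrix(0, 5, 2)), "compose")

  # block toy: one hidden neuron per class with disjoint pixel blocks
  Wih <- matrix(0, 6, 2); Wih[1:3, 1] <- 1; Wih[4:6, 2] <- 1
  Who <- diag(2)
  maps <- receptive_field_product(Wih, Who, normalize = FALSE)
  expect_equal(maps[, 1], c(1, 1, 1, 0, 0, 0))
  expect_equal(maps[, 2], c(0, 0, 0, 1, 1, 1))
})

test_that("forward/reciprocal correlation is exact for transposes and null for noise", {
  set.seed(9)
  Who <- matrix(runif(60), 20, 3)
  expect_equal(forward_reciprocal_correlation(Who, t(Who)), 1)
  expect_identical(forward_reciprocal_correlation(matrix(1, 4, 2), matrix(runif(8), 2, 4)),
                   NA_real_)
  # independent matrices: r within 3 sigma of the permutation null
  r_obs <- forward_reciprocal_correlation(Who, matrix(runif(60), 3, 20))
  null <- replicate(500, cor(as.vector(Who), sample(as.vector(Who))))
  expect_lt(abs(r_obs - mean(null)), 3 * sd(null))
  expect_error(forward_reciprocal_correlation(Who, matrix(0, 3, 10)), "align")
})

test_that("reciprocal lesion zeroes and freezes exactly that group", {
  net <- build_network(tiny_config(seed = 3L))
  net$groups$reciprocal$W[] <- 0.4
  Wih <- net$groups$ff_in_hidden$W
  lesion_reciprocal(net)
  expect_true(all(net$groups$reciprocal$W == 0))
  expect_false(net$groups$reciprocal$plastic)
  expect_identical(net$groups$ff_in_hidden$W, Wih)

  # lesioning an all-zero group changes no behavior
  n1 <- build_network(tiny_config(seed = 4L))
  n2 <- build_network(tiny_config(seed = 4L))
  lesion_reciprocal(n2)
  set.seed(2)
  s1 <- { set.seed(2); for (t in 1:60) simulate_step(n1, as.numeric(runif(8) < 0.3)); n1$hidden$a }
  s2 <- { set.seed(2); for (t in 1:60) simulate_step(n2, as.numeric(runif(8) < 0.3)); n2$hidden$a }
  expect_equal(s1, s2)

  n3 <- build_network(tiny_config(seed = 5L, enabled = c(reciprocal = FALSE)))
  expect_error(lesion_reciprocal(n3), "not enabled")
})
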