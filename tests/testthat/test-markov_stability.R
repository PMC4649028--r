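test_that("linearized stability at t = 1 is Newman-Girvan modularity", {
  # two disjoint triangles, one community each: R = 0.5
  A <- clique_graph(2, 3)
  g <- positive_subgraph(A, min_component_size = 1)
  B <- stability_matrix(g, 1, mode = "linearized")
  expect_equal(stability_score(B, rep(1:2, each = 3)), 0.5, tolerance = 1e-12)
  # random graphs, random partitions, vs igraph's independent implementation
  set.seed(14)
  for (r in 1:20) {
    A <- random_graph(20, 0.2)
    g <- positive_subgraph(A, min_component_size = 1)
    B <- stability_matrix(g, 1, mode = "linearized")
    memb <- sample(1:4, nrow(A), replace = TRUE)
    gi <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(stability_score(B, memb), igraph::modularity(gi, memb),
                 tolerance = 1e-12)
  }
})

test_that("stability closed forms hold at the boundaries", {
  set.seed(15)
  A <- random_graph(15, 0.3)
  g <- positive_subgraph(A, min_component_size = 1)
  n <- length(g$nodes)
  for (t in c(0, 0.3, 1, 5, 40)) {
    for (mode in c("exponential", "linearized")) {
      B <- stability_matrix(g, t, mode = mode)
      expect_lt(abs(stability_score(B, rep(1, n))), 1e-10)  # all-in-one = 0
    }
  }
  B0 <- stability_matrix(g, 0, mode = "exponential")
  expect_equal(stability_score(B0, seq_len(n)), 1 - sum(g$pi^2),
               tolerance = 1e-12)
  # exponential and linearized agree to first order in t
  memb <- sample(1:3, n, replace = TRUE)
  gap <- vapply(c(1e-3, 1e-4), function(t) {
    abs(stability_score(stability_matrix(g, t, "exponential"), memb) -
        stability_score(stability_matrix(g, t, "linearized"), memb))
  }, numeric(1))
  expect_lt(gap[2], gap[1] / 50)   # O(t^2) scaling: 10x smaller t, ~100x gap
})

test_that("generalized Louvain recovers disconnected cliques exactly", {
  A <- clique_graph(3, 4)
  g <- positive_subgraph(A, min_component_size = 1)
  B <- stability_matrix(g, 1, mode = "linearized")
  truth <- rep(1:3, each = 4)
  for (s in 1:20) {
    opt <- louvain_optimize(B, n_restarts = 3, seed = s)
    expect_equal(adjusted_rand_index(opt$membership, truth), 1)
    expect_equal(opt$score, 2 / 3, tolerance = 1e-12)  # known optimum
  }
  # a single edge collapses to one community at t = 1
  A2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  g2 <- positive_subgraph(A2, min_component_size = 1)
  B2 <- stability_matrix(g2, 1, mode = "linearized")
  expect_identical(max(louvain_optimize(B2, 5, seed = 1)$membership), 1L)
})

test_that("Louvain beats trivial baselines and finds planted partitions", {
  set.seed(16)
  # planted partition: 4 blocks of 15, p_in 0.5, p_out 0.02
  n <- 60; truth <- rep(1:4, each = 15)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    A[i, j] <- A[j, i] <- rbinom(1, 1, if (truth[i] == truth[j]) 0.5 else 0.02)
  dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
  g <- positive_subgraph(A, min_component_size = 1)
  B <- stability_matrix(g, 1, mode = "linearized")
  opt <- louvain_optimize(B, n_restarts = 10, seed = 3)
  keep <- match(g$nodes, paste0("n", 1:n))
  expect_gte(adjusted_rand_index(opt$membership, truth[keep]), 0.9)
  # never below the all-in-one (0) or singleton scores
  for (t in c(0.5, 1, 3)) {
    Bt <- stability_matrix(g, t, mode = "linearized")
    o <- louvain_optimize(Bt, n_restarts = 5, seed = 7)
    expect_gte(o$score, 0 - 1e-12)
    expect_gte(o$score, stability_score(Bt, seq_along(g$nodes)) - 1e-12)
  }
})

test_that("Markov-time scans coarsen and respect components", {
  # disconnected components never merge under the exponential mode
  A <- clique_graph(2, 5)
  g <- positive_subgraph(A, min_component_size = 1)
  res <- scan_markov_times(g, default_time_grid(15), mode = "exponential",
                          n_restarts = 5, seed = 21)
  expect_true(all(res$k >= 2))
  # ring of cliques: community count trends downward with t
  k <- 6; s <- 5; n <- k * s
  A <- clique_graph(k, s)
  for (b in seq_len(k)) {
    from <- (b - 1) * s + 1
    to <- (b %% k) * s + 2
    A[from, to] <- A[to, from] <- 1
  }
  g2 <- positive_subgraph(A, min_component_size = 1)
  res2 <- scan_markov_times(g2, default_time_grid(24), mode = "exponential",
                           n_restarts = 10, seed = 22)
  q <- length(res2$k) %/% 4
  expect_lte(max(res2$k[(length(res2$k) - q + 1):length(res2$k)]),
             min(res2$k[1:q]))
  # a single-point grid reduces to one modularity optimization
  res3 <- scan_markov_times(g2, 1, mode = "linearized", n_restarts = 10,
                           seed = 23)
  B <- stability_matrix(g2, 1, mode = "linearized")
  opt <- louvain_optimize(B, n_restarts = 10, seed = 23)
  expect_equal(res3$R[1], opt$score, tolerance = 1e-12)
})

test_that("plateau selection picks the longest stable k > 2", {
  fake <- function(kseq, times = seq_along(kseq)) {
    parts <- lapply(kseq, function(k) {
      p <- rep(seq_len(k), length.out = 12)
      names(p) <- paste0("n", 1:12)
      p
    })
    structure(list(times = times, k = kseq, R = rep(1, length(kseq)),
                   partitions = parts, vi_consecutive = rep(0, length(kseq)),
                   mode = "linearized", n_restarts = 1, seed = 1,
                   nodes = paste0("n", 1:12)),
              class = "stability_result")
  }
  res <- fake(c(8, 6, 4, 4, 4, 4, 2, 2))
  sel <- select_partition(res)
  expect_identical(sel$k, 4)
  expect_equal(sel$t, 4)            # midpoint of grid points 3..6
  expect_equal(sel$run_length, 4)
  # reversing the grid changes nothing
  rev_res <- fake(rev(c(8, 6, 4, 4, 4, 4, 2, 2)), times = 8:1)
  sel_rev <- select_partition(rev_res)
  expect_equal(sel_rev$k, sel$k)
  expect_equal(sel_rev$run_length, sel$run_length)
  # ties break toward larger k
  sel2 <- select_partition(fake(c(5, 5, 3, 3, 2)))
  expect_equal(sel2$k, 5)
  # k never above 2 -> error
  expect_error(select_partition(fake(c(2, 2, 1, 1))), "k >= 3")
})

test_that("variation of information matches its closed forms", {
  p1 <- c(a = 1, b = 1, c = 2, d = 2)
  expect_equal(variation_of_information(p1, p1), 0)
  p2 <- c(a = 1, b = 2, c = 1, d = 2)
  expect_equal(variation_of_information(p1, p2), 2 * log(2),
               tolerance = 1e-12)
  n <- 16
  singles <- setNames(seq_len(n), paste0("x", seq_len(n)))
  lumped <- setNames(rep(1, n), paste0("x", seq_len(n)))
  expect_equal(variation_of_information(singles, lumped), log(n),
               tolerance = 1e-12)
  expect_error(variation_of_information(p1, c(a = 1, b = 1, e = 2, f = 2)),
               "different node sets")
})

test_that("adjusted Rand index agrees with the mclust implementation", {
  set.seed(17)
  for (r in 1:10) {
    p1 <- sample(1:4, 30, replace = TRUE)
    p2 <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(p1, p2),
                 mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("positive subgraph drops isolated nodes and minor components", {
  ids <- c("a", "b", "c", "d", "e", "f", "g")
  rho <- diag(7); dimnames(rho) <- list(ids, ids)
  p <- matrix(1, 7, 7, dimnames = dimnames(rho))
  link <- function(x, y, r) {
    rho[x, y] <<- rho[y, x] <<- r
    p[x, y] <<- p[y, x] <<- 0.001
  }
  link("a", "b", 0.9); link("b", "c", 0.9); link("c", "d", 0.9)
  link("a", "c", 0.9)
  link("e", "f", 0.9)                       # dyad
  net <- build_network(rho, p)
  g <- positive_subgraph(net, min_component_size = 4)
  expect_setequal(g$nodes, c("a", "b", "c", "d"))
  expect_setequal(g$minor, c("e", "f"))
  expect_setequal(g$isolated, "g")
  expect_equal(sum(g$d), 2 * g$m)
  expect_equal(sum(g$pi), 1)
})
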