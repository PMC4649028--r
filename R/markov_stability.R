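#' Positive-subgraph structure for stability clustering
#'
#' Extracts the unweighted positive subgraph of a co-occurrence network and
#' prepares the quantities Markov stability needs: adjacency `A`, degrees
#' `d`, total edge weight `m` and stationary distribution `pi = d / 2m`.
#' Nodes without positive edges carry no diffusion process and are dropped;
#' connected components smaller than `min_component_size` cannot express
#' community structure under the community-number selection rule and are
#' set aside as minor components. Both groups are reported.
#'
#' @param net a `cooccurrence_network`, or a symmetric 0/1 adjacency matrix.
#' @param min_component_size smallest component retained for clustering
#'   (default 4; use 1 to keep everything).
#' @return a `stability_graph`: list with `A`, `nodes`, `d`, `m`, `pi`,
#'   `isolated` (nodes with no positive edge) and `minor` (nodes in
#'   components below the size cutoff).
#' @export
positive_subgraph <- function(net, min_component_size = 4) {
  if (inherits(net, "cooccurrence_network")) {
    nodes <- net$nodes
    A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    e <- net$edges[net$edges$sign == "positive", , drop = FALSE]
    if (nrow(e)) {
      ia <- match(e$otu_a, nodes); ib <- match(e$otu_b, nodes)
      A[cbind(ia, ib)] <- 1
      A[cbind(ib, ia)] <- 1
    }
  } else {
    A <- as.matrix(net)
    stopifnot(isSymmetric(unname(A)))
    if (is.null(rownames(A)))
      dimnames(A) <- list(paste0("n", seq_len(nrow(A))),
                          paste0("n", seq_len(nrow(A))))
    nodes <- rownames(A)
  }
  diag(A) <- 0
  d <- rowSums(A)
  isolated <- nodes[d == 0]
  keep <- d > 0
  A <- A[keep, keep, drop = FALSE]
  comp <- graph_components(A)
  sizes <- table(comp)
  minor_comp <- names(sizes)[sizes < min_component_size]
  minor <- rownames(A)[comp %in% minor_comp]
  keep2 <- !(comp %in% minor_comp)
  A <- A[keep2, keep2, drop = FALSE]
  if (nrow(A) == 0)
    stop("no components of size >= ", min_component_size,
         " in the positive subgraph", call. = FALSE)
  d <- rowSums(A)
  m <- sum(d) / 2
  structure(list(A = A, nodes = rownames(A), d = d, m = m, pi = d / (2 * m),
                 isolated = isolated, minor = minor),
            class = "stability_graph")
}

# connected component labels by repeated BFS on a dense adjacency
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(A[frontier, , drop = FALSE] > 0) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Markov-stability quality matrix
#'
#' For a graph with adjacency `A`, degrees `d`, total weight `m` and
#' stationary distribution `pi`, the exponential-mode matrix is
#' `B(t) = Pi exp(-t (I - D^-1 A)) - pi pi^T` (symmetric by detailed
#' balance); the linearized mode is `B(t) = (1-t) Pi + t A/(2m) - pi pi^T`,
#' which at `t = 1` makes `trace(H^T B H)` the Newman-Girvan modularity.
#' The stability of a partition is `R(t, H) = trace(H^T B(t) H)`; the
#' all-in-one partition scores exactly 0 at every `t`.
#'
#' @param graph a `stability_graph`.
#' @param t Markov time, `t >= 0`.
#' @param mode `"exponential"` or `"linearized"`.
#' @param eig optional cached eigendecomposition from
#'   [stability_eigen()] (exponential mode only).
#' @return symmetric matrix `B(t)`.
#' @export
stability_matrix <- function(graph, t, mode = c("exponential", "linearized"),
                             eig = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "stability_graph"), t >= 0)
  pp <- outer(graph$pi, graph$pi)
  if (mode == "linearized") {
    B <- t * graph$A / (2 * graph$m) - pp
    diag(B) <- diag(B) + (1 - t) * graph$pi
    return(B)
  }
  if (is.null(eig)) eig <- stability_eigen(graph)
  scale <- exp(-t * (1 - eig$values))
  V <- eig$vectors
  M <- V %*% (scale * t(V))
  s <- sqrt(graph$d)
  B <- (s * M * rep(s, each = length(s))) / (2 * graph$m) - pp
  (B + t(B)) / 2
}

#' Cached spectral decomposition for exponential-mode stability
#'
#' Eigendecomposition of the symmetrized random-walk operator
#' `D^-1/2 A D^-1/2`, computed once per graph and reused across Markov
#' times.
#'
#' @param graph a `stability_graph`.
#' @export
stability_eigen <- function(graph) {
  s <- sqrt(graph$d)
  Asym <- graph$A / outer(s, s)
  eigen(Asym, symmetric = TRUE)
}

#' Stability score of a partition
#'
#' @param B quality matrix from [stability_matrix()].
#' @param membership integer community labels aligned with `B`'s rows.
#' @return `R = trace(H^T B H)`.
#' @export
stability_score <- function(B, membership) {
  sum(vapply(split(seq_along(membership), membership),
             function(ix) sum(B[ix, ix]), numeric(1)))
}

#' Optimize a quality matrix by generalized Louvain
#'
#' Greedy node moving plus aggregation on `Q(H) = trace(H^T B H)`,
#' restarted from `n_restarts` random node orders; the best-scoring
#' partition is returned. Deterministic under `seed`.
#'
#' @param B symmetric quality matrix.
#' @param n_restarts number of random restarts.
#' @param seed integer RNG seed.
#' @return list with `membership` (named, contiguous 1-based labels) and
#'   `score`.
#' @export
louvain_optimize <- function(B, n_restarts = 20, seed) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  n <- nrow(B)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      ord <- sample.int(n) - 1L
      memb <- louvain_dense(B, ord)
      sc <- stability_score(B, memb)
      if (is.null(best) || sc > best$score + 1e-12)
        best <- list(membership = memb, score = sc)
    }
  })
  memb <- relabel_contiguous(best$membership)
  names(memb) <- rownames(B)
  list(membership = memb, score = best$score)
}

relabel_contiguous <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' Default logarithmic Markov-time grid
#'
#' @param n number of grid points.
#' @param from,to grid endpoints.
#' @export
default_time_grid <- function(n = 60, from = 1e-2, to = 1e2) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Scan Markov times
#'
#' Optimizes stability at every Markov time of an ascending grid and
#' records the best partition, its score `R(t)`, the community count
#' `k(t)` and the variation of information between consecutive-time
#' partitions.
#'
#' @param graph a `stability_graph`.
#' @param time_grid ascending Markov times (default [default_time_grid()]).
#' @param mode `"exponential"` (default for graphs up to 2000 nodes) or
#'   `"linearized"`.
#' @param n_restarts Louvain restarts per time point.
#' @param seed integer RNG seed.
#' @return a `stability_result`: list with `times`, `k`, `R`,
#'   `partitions` (list of named memberships), `vi_consecutive`, `mode`,
#'   `n_restarts`, `seed`.
#' @export
scan_markov_times <- function(graph, time_grid = default_time_grid(),
                              mode = NULL, n_restarts = 20, seed) {
  stopifnot(inherits(graph, "stability_graph"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (length(graph$nodes) == 0) stop("empty graph", call. = FALSE)
  if (is.null(mode))
    mode <- if (length(graph$nodes) <= 2000) "exponential" else "linearized"
  time_grid <- sort(time_grid)
  eig <- if (mode == "exponential") stability_eigen(graph) else NULL
  partitions <- vector("list", length(time_grid))
  R <- k <- numeric(length(time_grid))
  for (i in seq_along(time_grid)) {
    B <- stability_matrix(graph, time_grid[i], mode = mode, eig = eig)
    opt <- louvain_optimize(B, n_restarts = n_restarts,
                            seed = seed + i - 1L)
    partitions[[i]] <- opt$membership
    R[i] <- opt$score
    k[i] <- max(opt$membership)
  }
  vi <- c(NA_real_, vapply(seq_along(time_grid)[-1], function(i)
    variation_of_information(partitions[[i - 1]], partitions[[i]]),
    numeric(1)))
  structure(list(times = time_grid, k = k, R = R, partitions = partitions,
                 vi_consecutive = vi, mode = mode, n_restarts = n_restarts,
                 seed = seed, nodes = graph$nodes),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d Markov times in [%.3g, %.3g], k in [%d, %d] (%s mode)\n",
              length(x$times), min(x$times), max(x$times),
              min(x$k), max(x$k), x$mode))
  invisible(x)
}

#' Select the partition with the longest stable community number
#'
#' Among community counts larger than `k_min - 1`, finds the longest
#' contiguous run of Markov-time grid points whose optimal partitions have
#' the same community count and are mutually consistent (pairwise variation
#' of information at most `vi_tol`), and returns the partition at the run's
#' midpoint. Ties are broken toward the larger community count, then the
#' smaller Markov time.
#'
#' @param result a `stability_result`.
#' @param k_min smallest admissible community number (default 3, i.e. the
#'   rule considers only `k > 2`).
#' @param vi_tol within-run coherence tolerance; default `0.05 log(n)`.
#' @return list with `membership`, `k`, `t` (midpoint time), `run_times`
#'   (the plateau's time range), `run_length`.
#' @export
select_partition <- function(result, k_min = 3, vi_tol = NULL) {
  stopifnot(inherits(result, "stability_result"))
  ord <- order(result$times)
  times <- result$times[ord]; kk <- result$k[ord]
  parts <- result$partitions[ord]
  n <- length(parts[[1]])
  if (is.null(vi_tol)) vi_tol <- 0.05 * log(n)
  if (!any(kk >= k_min))
    stop("no partition with k >= ", k_min,
         " on the time grid; inspect the network and thresholds",
         call. = FALSE)
  best <- NULL
  i <- 1
  while (i <= length(kk)) {
    j <- i
    while (j < length(kk) && kk[j + 1] == kk[i]) j <- j + 1
    if (kk[i] >= k_min) {
      # longest coherent sub-run (all pairwise VI <= vi_tol) within [i, j]
      sub <- longest_coherent(parts, i, j, vi_tol)
      cand <- list(len = sub[2] - sub[1] + 1, k = kk[i],
                   from = sub[1], to = sub[2])
      if (is.null(best) ||
          cand$len > best$len ||
          (cand$len == best$len && cand$k > best$k) ||
          (cand$len == best$len && cand$k == best$k &&
           times[cand$from] < times[best$from]))
        best <- cand
    }
    i <- j + 1
  }
  mid <- floor((best$from + best$to) / 2)
  list(membership = parts[[mid]], k = best$k, t = times[mid],
       run_times = c(times[best$from], times[best$to]),
       run_length = best$len)
}

# longest contiguous sub-interval of [i, j] with all pairwise VI <= tol
longest_coherent <- function(parts, i, j, tol) {
  if (i == j) return(c(i, j))
  idx <- i:j
  nn <- length(idx)
  vim <- matrix(0, nn, nn)
  for (a in seq_len(nn - 1))
    for (b in (a + 1):nn)
      vim[a, b] <- vim[b, a] <-
        variation_of_information(parts[[idx[a]]], parts[[idx[b]]])
  best <- c(1, 1)
  for (a in seq_len(nn)) {
    b <- a
    while (b < nn && all(vim[a:b, b + 1] <= tol))
      b <- b + 1
    if (b - a > best[2] - best[1]) best <- c(a, b)
  }
  c(idx[best[1]], idx[best[2]])
}

#' Variation of information between two partitions
#'
#' `VI = H(X) + H(Y) - 2 I(X; Y)` in nats; 0 iff the partitions coincide
#' up to relabeling, at most `log(n)`.
#'
#' @param p1,p2 community label vectors over the same nodes (names, when
#'   present, must match as sets).
#' @export
variation_of_information <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions are over different node sets", call. = FALSE)
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions are over different node sets", call. = FALSE)
  }
  n <- length(p1)
  joint <- table(p1, p2) / n
  px <- rowSums(joint); py <- colSums(joint)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- sum(joint[joint > 0] *
              log(joint[joint > 0] / outer(px, py)[joint > 0]))
  max(h(px) + h(py) - 2 * mi, 0)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same nodes.
#'
#' @param p1,p2 community label vectors (aligned by names when present).
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) p2 <- p2[names(p1)]
  stopifnot(length(p1) == length(p2))
  tab <- table(p1, p2)
  n <- length(p1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
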