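# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the vectorized implementations.

std_metadata <- function() {
  g <- expand.grid(replicate = 1:3,
                   compartment = c("bulk", "drilosphere", "rhizosphere"),
                   depth = c("topsoil", "subsoil"),
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s.%s.%d", g$depth, g$compartment, g$replicate)
  sample_metadata(g[, c("sample_id", "depth", "compartment", "replicate")])
}

random_table <- function(n_otu, n_samp = 18, lambda = 8,
                         sample_ids = std_metadata()$sample_id) {
  m <- matrix(rpois(n_otu * n_samp, lambda), n_otu, n_samp,
              dimnames = list(sprintf("Otu%03d", seq_len(n_otu)),
                              sample_ids[seq_len(n_samp)]))
  count_table(m)
}

brute_prevalence <- function(m, min_reads, min_samples) {
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    n_ok <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] >= min_reads) n_ok <- n_ok + 1
    keep[i] <- n_ok >= min_samples
  }
  rownames(m)[keep]
}

brute_core <- function(m, meta, min_replicates = 2) {
  rel <- m
  for (j in seq_len(ncol(m))) rel[, j] <- m[, j] / sum(m[, j])
  cells <- unique(paste(meta$depth, meta$compartment))
  members <- character()
  for (i in seq_len(nrow(m))) {
    ok <- TRUE
    for (cl in cells) {
      idx <- which(paste(meta$depth, meta$compartment) == cl)
      if (sum(m[i, idx] > 0) < min_replicates) ok <- FALSE
    }
    if (ok && sd(rel[i, ]) > mean(rel[i, ])) ok <- FALSE
    if (ok) members <- c(members, rownames(m)[i])
  }
  members
}

brute_network_edges <- function(rho, p, rho_pos = 0.6, rho_neg = -0.6,
                                alpha = 0.05) {
  out <- NULL
  ids <- rownames(rho)
  for (i in seq_len(nrow(rho))) for (j in seq_len(ncol(rho))) {
    if (i >= j) next
    r <- rho[i, j]
    if (is.na(r)) next
    if (p[i, j] < alpha && (r > rho_pos || r < rho_neg))
      out <- rbind(out, data.frame(
        otu_a = min(ids[i], ids[j]), otu_b = max(ids[i], ids[j]),
        sign = if (r > 0) "positive" else "negative",
        stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(data.frame(otu_a = character(),
                                      otu_b = character(),
                                      sign = character()))
  out[order(out$otu_a, out$otu_b), ]
}

brute_negative_tally <- function(edges, partition) {
  neg <- edges[edges$sign == "negative", , drop = FALSE]
  lab <- function(o) {
    v <- partition[o]
    ifelse(is.na(v), "unclustered", as.character(unname(v)))
  }
  tal <- list()
  for (k in seq_len(nrow(neg))) {
    for (dir in 1:2) {
      a <- if (dir == 1) neg$otu_a[k] else neg$otu_b[k]
      b <- if (dir == 1) neg$otu_b[k] else neg$otu_a[k]
      key <- paste(lab(a), lab(b), b, sep = "\r")
      tal[[key]] <- (if (is.null(tal[[key]])) 0 else tal[[key]]) + 1
    }
  }
  tal
}

# random symmetric 0/1 adjacency with no isolated nodes guaranteed removed
random_graph <- function(n, p_edge = 0.2) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
  A <- A + t(A)
  keep <- rowSums(A) > 0
  A <- A[keep, keep, drop = FALSE]
  dimnames(A) <- list(paste0("n", seq_len(nrow(A))),
                      paste0("n", seq_len(nrow(A))))
  A
}

# k disconnected cliques of size s
clique_graph <- function(k, s) {
  n <- k * s
  A <- matrix(0, n, n)
  for (b in seq_len(k)) {
    ix <- (b - 1) * s + seq_len(s)
    A[ix, ix] <- 1
  }
  diag(A) <- 0
  dimnames(A) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  A
}

# exchangeable Dirichlet-multinomial null table via the generator
null_table <- function(seed, n_otus = 150) {
  ds <- generate_dataset(synthetic_design(
    n_otus = n_otus, n_clusters = 0, cluster_size = 0, n_core = 0,
    background_scale = 1, base_sd = 1, background_sd = 0, effect_size = 1,
    seed = seed))
  ds$counts
}
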