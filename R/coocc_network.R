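#' Pairwise Spearman correlation matrix
#'
#' Spearman rank correlation (average ranks for ties) between all OTU
#' pairs across samples. Constant OTU rows yield `NA` against all partners.
#'
#' @param table a `count_table` (relative abundances for network work) or a
#'   numeric matrix with OTUs in rows.
#' @return symmetric matrix with unit diagonal.
#' @export
spearman_matrix <- function(table) {
  m <- if (inherits(table, "count_table")) table$counts else table
  if (ncol(m) < 3) stop("need at least 3 samples", call. = FALSE)
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  const <- apply(m, 1, function(r) length(unique(r)) == 1)
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Compositionality-corrected correlation p-values (ReBoot-style)
#'
#' Estimates, for every OTU pair, the significance of the Spearman
#' correlation of relative abundances against a null that preserves the
#' compositional structure: in each of `n_iter` iterations every OTU row is
#' independently permuted across samples, each sample is re-closed to
#' relative abundance, and the full Spearman matrix is recomputed.
#' A matching bootstrap distribution (samples resampled with replacement,
#' re-closed) is also computed. All correlations are Fisher-z transformed
#' and a two-sided normal p-value is derived per pair.
#'
#' Two conventions are available. `"permutation"` (default) z-scores the
#' observed coefficient against the renormalized permutation null,
#' `z = (z_obs - mean(z_null)) / sd(z_null)`; it is calibrated at the
#' nominal level on exchangeable data and immune to the rank-tie
#' attenuation that bootstrap resampling introduces. `"pooled"` compares
#' the bootstrap and null distributions with a pooled variance,
#' `z = (mean(z_boot) - mean(z_null)) / sqrt(var(z_boot) + var(z_null))`,
#' the convention of the CCREPE implementation; it is markedly
#' conservative (see the package vignette).
#'
#' @param table the prevalence-filtered raw `count_table`.
#' @param n_iter number of permutation and bootstrap iterations (>= 100).
#' @param seed integer RNG seed (required).
#' @param method `"permutation"` or `"pooled"`.
#' @return list with `p` (symmetric matrix of p-values; 1 on the diagonal
#'   and for pairs involving a constant row), `rho` (observed Spearman on
#'   relative abundances), `boot_mean` and `boot_sd` (bootstrap
#'   distribution of rho, back-transformed), `null_mean` (permutation-null
#'   mean of rho), and `provenance`.
#' @export
reboot_pvalues <- function(table, n_iter = 1000, seed,
                           method = c("permutation", "pooled")) {
  stopifnot(inherits(table, "count_table"))
  method <- match.arg(method)
  if (n_iter < 100) stop("n_iter must be >= 100", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  m <- table$counts
  n_otu <- nrow(m); n_samp <- ncol(m)
  rel <- close_columns(m)
  rho_obs <- spearman_matrix(rel)
  zsum_n <- zsq_n <- zsum_b <- zsq_b <- matrix(0, n_otu, n_otu)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      perm <- m
      for (i in seq_len(n_otu)) perm[i, ] <- perm[i, sample.int(n_samp)]
      zn <- fisher_z(rank_cor(close_columns(perm)))
      zsum_n <- zsum_n + zn; zsq_n <- zsq_n + zn * zn
      boot <- m[, sample.int(n_samp, replace = TRUE), drop = FALSE]
      zb <- fisher_z(rank_cor(close_columns(boot)))
      zsum_b <- zsum_b + zb; zsq_b <- zsq_b + zb * zb
    }
  })
  mean_n <- zsum_n / n_iter
  var_n <- pmax(zsq_n / n_iter - mean_n^2, 0) * n_iter / (n_iter - 1)
  mean_b <- zsum_b / n_iter
  var_b <- pmax(zsq_b / n_iter - mean_b^2, 0) * n_iter / (n_iter - 1)
  z <- if (method == "pooled") {
    (mean_b - mean_n) / sqrt(var_b + var_n)
  } else {
    (fisher_z(rho_obs) - mean_n) / sqrt(var_n)
  }
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(p)] <- 1
  const <- apply(m, 1, function(r) length(unique(r)) == 1)
  p[const, ] <- 1; p[, const] <- 1
  diag(p) <- 1
  dimnames(p) <- dimnames(rho_obs) <- list(rownames(m), rownames(m))
  dm <- list(rownames(m), rownames(m))
  boot_mean <- tanh(mean_b); dimnames(boot_mean) <- dm
  boot_sd <- sqrt(var_b); dimnames(boot_sd) <- dm
  null_mean <- tanh(mean_n); dimnames(null_mean) <- dm
  list(p = p, rho = rho_obs, boot_mean = boot_mean, boot_sd = boot_sd,
       null_mean = null_mean,
       provenance = list(n_iter = n_iter, seed = seed, method = method))
}

# column closure to relative abundance (zero columns left zero)
close_columns <- function(m) {
  cs <- colSums(m)
  sweep(m, 2, ifelse(cs == 0, 1, cs), "/")
}

# Spearman matrix without the constant-row bookkeeping (internal hot path);
# constant rows give NaN, mapped to 0 so they never look significant
rank_cor <- function(m) {
  r <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  r[!is.finite(r)] <- 0
  r
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))

#' Build a signed co-occurrence network
#'
#' An edge is set between two OTUs when the correlation is significant
#' (`p < alpha`) and the observed Spearman coefficient exceeds `rho_pos`
#' (positive edge) or falls below `rho_neg` (negative edge). OTUs without
#' any edge remain in the node set.
#'
#' @param rho symmetric Spearman matrix (e.g. `reboot_pvalues()$rho`).
#' @param p symmetric p-value matrix aligned with `rho`.
#' @param rho_pos positive-edge threshold (default 0.6).
#' @param rho_neg negative-edge threshold (default -0.6).
#' @param alpha significance level (default 0.05).
#' @param provenance optional list (seeds, n_iter) stamped on the network.
#' @return a `cooccurrence_network`: list with `nodes`, `edges`
#'   (data.frame otu_a, otu_b, rho, p, sign with `otu_a < otu_b`),
#'   `thresholds`, `provenance`.
#' @export
build_network <- function(rho, p, rho_pos = 0.6, rho_neg = -0.6, alpha = 0.05,
                          provenance = list()) {
  stopifnot(identical(dim(rho), dim(p)), isTRUE(all.equal(rownames(rho), rownames(p))))
  nodes <- rownames(rho)
  ut <- upper.tri(rho)
  sel <- ut & !is.na(rho) & p < alpha & (rho > rho_pos | rho < rho_neg)
  idx <- which(sel, arr.ind = TRUE)
  a <- nodes[idx[, 1]]; b <- nodes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(
    otu_a = as.character(a), otu_b = as.character(b),
    rho = as.numeric(rho[idx]), p = as.numeric(p[idx]),
    sign = as.character(ifelse(rho[idx] > 0, "positive", "negative")),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$otu_a, edges$otu_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(rho_pos = rho_pos, rho_neg = rho_neg,
                                   alpha = alpha),
                 provenance = provenance),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %d nodes, %d positive / %d negative edges\n",
              length(x$nodes), sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Negative edges of a network
#'
#' @param net a `cooccurrence_network`.
#' @return the negative-sign subset of the edge table.
#' @export
negative_edges <- function(net) {
  net$edges[net$edges$sign == "negative", , drop = FALSE]
}
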