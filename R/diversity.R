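#' Shannon diversity index
#'
#' Natural-log Shannon index `-sum(p_i log p_i)` over the non-zero
#' proportions of one sample.
#'
#' @param counts non-negative numeric vector of counts for one sample.
#' @return non-negative real; 0 for a single-OTU sample.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0) stop("all-zero sample", call. = FALSE)
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Analytic rarefaction curve
#'
#' Expected richness at each subsampling depth under draws without
#' replacement, `E[S_d] = sum_o (1 - choose(N - N_o, d)/choose(N, d))`
#' (hypergeometric expectation; no Monte Carlo).
#'
#' @param counts non-negative numeric vector of counts for one sample.
#' @param depths integer depths, each at most `sum(counts)`.
#' @return data.frame with columns `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  n <- sum(counts)
  if (any(depths > n))
    stop("depth exceeds sample read count", call. = FALSE)
  if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
  # vegan warns heuristically when a vector looks unlike count data; the
  # hypergeometric expectation itself is exact for any non-negative counts
  es <- vapply(depths, function(d)
    as.numeric(suppressWarnings(
      vegan::rarefy(matrix(counts, nrow = 1), sample = d))),
    numeric(1))
  data.frame(depth = depths, expected_richness = es)
}

#' Per-sample diversity summary
#'
#' @param table a raw `count_table` (ideally subsampled to equal depth).
#' @return data.frame with `sample_id`, `richness` (observed OTUs) and
#'   `shannon` (natural log).
#' @export
diversity_summary <- function(table) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  data.frame(
    sample_id = colnames(m),
    richness = as.integer(colSums(m > 0)),
    shannon = apply(m, 2, shannon_index),
    row.names = NULL)
}

#' Per-OTU one-way ANOVA with Tukey HSD and Bonferroni adjustment
#'
#' Tests each OTU's relative abundance against a grouping factor with
#' one-way ANOVA, follows up with Tukey's HSD pairwise comparisons and a
#' compact letter display at `alpha`, and Bonferroni-adjusts the ANOVA
#' p-values across the OTUs tested.
#'
#' @param table a relative `count_table`.
#' @param meta a `sample_metadata` aligned with the table's samples.
#' @param factor one of `"compartment"`, `"depth"`, `"cell"` (the depth x
#'   compartment interaction).
#' @param alpha significance level for the letter display.
#' @return data.frame, one row per tested OTU: `otu_id`, `F`, `p_raw`,
#'   `p_bonferroni`, `tukey_pairs` (string `pair=p;...`), `letters`
#'   (string `level=letters;...`), `degenerate` flag.
#' @export
per_otu_anova <- function(table, meta, factor = c("compartment", "depth", "cell"),
                          alpha = 0.05) {
  stopifnot(inherits(table, "count_table"))
  factor <- match.arg(factor)
  meta <- meta[match(sample_ids(table), meta$sample_id), ]
  g <- switch(factor,
              compartment = meta$compartment,
              depth = meta$depth,
              cell = paste(meta$depth, meta$compartment, sep = "."))
  g <- base::factor(g)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  small <- names(which(table(g) < 2))
  if (length(small)) {
    warning("group(s) with <2 replicates skipped from testing: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    table <- new_count_table(table$counts[, keep, drop = FALSE],
                             is_relative = table$is_relative,
                             check_integer = FALSE)
    g <- droplevels(g[keep])
  }
  rel <- to_relative(table)$counts
  rows <- lapply(rownames(rel), function(o) {
    y <- rel[o, ]
    if (stats::var(y) == 0)
      return(data.frame(otu_id = o, F = NA_real_, p_raw = NA_real_,
                        tukey_pairs = "", letters = "", degenerate = TRUE,
                        stringsAsFactors = FALSE))
    fit <- stats::aov(y ~ g)
    s <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    letters <- compact_letters(rownames(tk), tk[, "p adj"], levels(g), alpha)
    data.frame(
      otu_id = o, F = s[["F value"]][1], p_raw = s[["Pr(>F)"]][1],
      tukey_pairs = paste(rownames(tk), signif(tk[, "p adj"], 4),
                          sep = "=", collapse = ";"),
      letters = paste(names(letters), letters, sep = "=", collapse = ";"),
      degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_tests <- sum(!out$degenerate)
  out$p_bonferroni <- pmin(1, out$p_raw * n_tests)
  out[, c("otu_id", "F", "p_raw", "p_bonferroni", "tukey_pairs",
          "letters", "degenerate")]
}

# compact letter display by insert-and-absorb: non-significant pairs share
# a letter, significant pairs never do
compact_letters <- function(pair_names, pair_p, levels, alpha) {
  sig <- matrix(FALSE, length(levels), length(levels),
                dimnames = list(levels, levels))
  for (i in seq_along(pair_names)) {
    ab <- strsplit(pair_names[i], "-", fixed = TRUE)[[1]]
    if (length(ab) != 2 || !all(ab %in% levels)) next
    sig[ab[1], ab[2]] <- sig[ab[2], ab[1]] <- pair_p[i] < alpha
  }
  groups <- list()           # each element: set of levels sharing a letter
  for (lv in levels) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (!any(sig[lv, groups[[k]]])) {
        groups[[k]] <- c(groups[[k]], lv)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- lv
  }
  # absorb redundant groups (subset of another)
  keep <- rep(TRUE, length(groups))
  for (k in seq_along(groups))
    for (j in seq_along(groups))
      if (k != j && keep[j] && all(groups[[k]] %in% groups[[j]]) &&
          length(groups[[k]]) < length(groups[[j]]))
        keep[k] <- FALSE
  groups <- groups[keep]
  out <- vapply(levels, function(lv)
    paste(letters[which(vapply(groups, function(gr) lv %in% gr, logical(1)))],
          collapse = ""), character(1))
  out
}

#' PerMANOVA on Hellinger-transformed abundances
#'
#' Permutational multivariate ANOVA (pseudo-F from among/within sums of
#' squared Euclidean distances of the Hellinger matrix; p-value
#' `(1 + #{permuted F >= observed}) / (1 + n_perm)` under free permutation
#' of sample labels).
#'
#' @param hellinger numeric matrix from [hellinger_transform()]
#'   (OTUs x samples).
#' @param meta a `sample_metadata` covering the matrix columns.
#' @param factor `"compartment"`, `"depth"` or `"cell"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @return list with `pseudo_F`, `p`, `n_perm`.
#' @export
permanova <- function(hellinger, meta, factor = c("compartment", "depth", "cell"),
                      n_perm = 999, seed) {
  factor <- match.arg(factor)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  meta <- meta[match(colnames(hellinger), meta$sample_id), ]
  g <- switch(factor,
              compartment = meta$compartment,
              depth = meta$depth,
              cell = paste(meta$depth, meta$compartment, sep = "."))
  if (length(unique(g)) < 2) stop("need at least two groups", call. = FALSE)
  dat <- data.frame(g = base::factor(g))
  x <- t(hellinger)
  # stable under column (sample) order permutations: sort by sample id
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]
  dat <- dat[ord, , drop = FALSE]
  fit <- with_seed(seed,
    vegan::adonis2(x ~ g, data = dat, permutations = n_perm,
                   method = "euclidean"))
  list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1], n_perm = n_perm)
}
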