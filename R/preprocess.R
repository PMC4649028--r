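#' Subsample reads to a common depth
#'
#' Draws, for every sample, `depth` reads uniformly without replacement
#' (multivariate hypergeometric), so that all sample columns sum to exactly
#' `depth`. This mirrors rarefying to the minimum number of reads per
#' sample before diversity and network analyses.
#'
#' @param table a raw `count_table`.
#' @param depth positive integer, or `"auto-min"` for the minimum sample sum.
#' @param seed integer RNG seed (required; draws are deterministic given it).
#' @return a raw `count_table` with every column summing to `depth`.
#' @export
subsample_counts <- function(table, depth = "auto-min", seed) {
  stopifnot(inherits(table, "count_table"), !table$is_relative)
  if (missing(seed)) stop("'seed' is required for subsampling", call. = FALSE)
  cs <- colSums(table$counts)
  if (identical(depth, "auto-min")) depth <- min(cs)
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  low <- which(cs < depth)
  if (length(low))
    stop(sprintf("depth %d exceeds reads in sample '%s' (%d)",
                 depth, colnames(table$counts)[low[1]], as.integer(cs[low[1]])),
         call. = FALSE)
  m <- table$counts
  out <- m
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      if (cs[j] == depth) next            # already at depth: untouched
      reads <- rep.int(seq_len(nrow(m)), m[, j])
      keep <- sample(reads, depth, replace = FALSE)
      out[, j] <- tabulate(keep, nbins = nrow(m))
    }
  })
  new_count_table(out, is_relative = FALSE)
}

#' Convert counts to relative abundance
#'
#' @param table a raw `count_table`.
#' @return a `count_table` with `is_relative = TRUE`; all-zero samples stay
#'   zero with a warning.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (table$is_relative) return(table)
  cs <- colSums(table$counts)
  if (any(cs == 0))
    warning("all-zero sample(s) left as zero: ",
            paste(colnames(table$counts)[cs == 0], collapse = ", "))
  m <- sweep(table$counts, 2, ifelse(cs == 0, 1, cs), "/")
  new_count_table(m, is_relative = TRUE, check_integer = FALSE)
}

#' Hellinger transform
#'
#' Square root of relative abundance: entry `sqrt(count / sample sum)`.
#' Each non-empty sample column has unit Euclidean norm, making Euclidean
#' distances on the result appropriate for ordination and PerMANOVA.
#'
#' @param table a `count_table` (raw or relative).
#' @return a numeric matrix (OTUs x samples).
#' @export
hellinger_transform <- function(table) {
  stopifnot(inherits(table, "count_table"))
  sqrt(to_relative(table)$counts)
}

#' Adjust counts by 16S rRNA gene copy number
#'
#' Divides every OTU's reads by the mean 16S rRNA gene copies per genome of
#' its deepest classified rank found in the lookup table, walking genus ->
#' family -> order -> class -> phylum -> domain and falling back to the
#' `root` average. Converts read abundances into genome-equivalent
#' abundances.
#'
#' @param table a raw `count_table`.
#' @param tax a `taxonomy_table` covering all OTUs of `table`.
#' @param cn a `copy_number_table` with a `root` entry.
#' @return a real-valued `count_table` (raw orientation, non-integer).
#' @export
copy_number_adjust <- function(table, tax, cn) {
  stopifnot(inherits(table, "count_table"), !table$is_relative,
            inherits(tax, "taxonomy_table"), inherits(cn, "copy_number_table"))
  idx <- match(otu_ids(table), tax$otu_id)
  if (anyNA(idx))
    stop("OTU(s) missing from taxonomy: ",
         paste(otu_ids(table)[is.na(idx)], collapse = ", "), call. = FALSE)
  copies <- vapply(idx, function(i) lookup_copies(tax[i, ], cn), numeric(1))
  m <- table$counts / copies
  new_count_table(m, is_relative = FALSE, check_integer = FALSE)
}

# walk the lineage from genus up; unclassified ranks and ranks absent from
# the lookup are skipped; the rank "root" entry is the final fallback
lookup_copies <- function(tax_row, cn) {
  for (rank in rev(.TAX_RANKS)) {
    if (!isTRUE(tax_row[[paste0(rank, "_classified")]])) next
    hit <- which(cn$rank == rank & cn$name == tax_row[[rank]])
    if (length(hit)) return(cn$mean_copies[hit[1]])
  }
  root <- which(cn$rank == "root")
  cn$mean_copies[root[1]]
}

#' Correct a qPCR total by the copy-number discrepancy
#'
#' Rescales a per-sample qPCR total (16S copies per g dry weight) by the
#' ratio of copy-number-adjusted to raw read sums in that sample, turning a
#' gene-copy total into a genome-equivalent total.
#'
#' @param qpcr_total numeric, total 16S copies per g dry weight.
#' @param raw raw `count_table`.
#' @param adjusted output of [copy_number_adjust()] on `raw`.
#' @param sample sample id present in both tables.
#' @export
correct_qpcr_total <- function(qpcr_total, raw, adjusted, sample) {
  stopifnot(identical(otu_ids(raw), otu_ids(adjusted)),
            sample %in% sample_ids(raw), sample %in% sample_ids(adjusted))
  rs <- sum(raw$counts[, sample])
  if (rs == 0) stop("sample '", sample, "' has zero raw reads", call. = FALSE)
  qpcr_total * sum(adjusted$counts[, sample]) / rs
}

#' Prevalence filter for network estimation
#'
#' Keeps OTUs with at least `min_reads` reads in at least `min_samples`
#' samples (defaults 6 and 3), the inclusion rule for co-occurrence
#' network estimation. The sample set is unchanged.
#'
#' @param table a raw `count_table`.
#' @param min_reads minimum reads per qualifying sample.
#' @param min_samples minimum number of qualifying samples.
#' @export
prevalence_filter <- function(table, min_reads = 6, min_samples = 3) {
  stopifnot(inherits(table, "count_table"), min_reads >= 1, min_samples >= 1)
  keep <- rowSums(table$counts >= min_reads) >= min_samples
  new_count_table(table$counts[keep, , drop = FALSE],
                  is_relative = table$is_relative, check_integer = FALSE)
}

# evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
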