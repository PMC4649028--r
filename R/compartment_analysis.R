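#' Intrinsic core microbiome
#'
#' An OTU belongs to the intrinsic core when (a) it is present (count > 0
#' after subsampling) in at least 2 of the 3 biological replicates of every
#' depth x compartment cell in scope, and (b) the standard deviation of its
#' relative abundance over all in-scope samples does not exceed its mean.
#'
#' @param table a raw, subsampled `count_table`.
#' @param meta a `sample_metadata` covering the table's samples.
#' @param min_replicates presence requirement per cell (default 2).
#' @return a `core_set`: list with `members` (data.frame otu_id,
#'   mean_rel_abund, sd_rel_abund), `fraction_of_reads` (summed relative
#'   abundance of members over the evaluated table), `pct_otus`, `scope`.
#' @export
core_microbiome <- function(table, meta, min_replicates = 2) {
  scoped_core(table, meta, scope = "all", min_replicates = min_replicates)
}

#' @rdname core_microbiome
#' @param scope `"all"`, `"topsoil"` or `"subsoil"`; the core criteria are
#'   evaluated on the scope's cells and samples only.
#' @export
scoped_core <- function(table, meta, scope = c("all", "topsoil", "subsoil"),
                        min_replicates = 2) {
  stopifnot(inherits(table, "count_table"))
  scope <- match.arg(scope)
  meta <- meta[match(sample_ids(table), meta$sample_id), ]
  in_scope <- if (scope == "all") rep(TRUE, nrow(meta)) else meta$depth == scope
  if (!any(in_scope)) stop("no samples in scope '", scope, "'", call. = FALSE)
  m <- table$counts[, in_scope, drop = FALSE]
  sm <- meta[in_scope, ]
  cells <- paste(sm$depth, sm$compartment, sep = ".")
  tab <- table(cells)
  if (any(tab < min_replicates))
    stop("design cell(s) with fewer than ", min_replicates, " replicates: ",
         paste(names(tab)[tab < min_replicates], collapse = ", "),
         call. = FALSE)
  present <- m > 0
  per_cell_ok <- vapply(unique(cells), function(cl)
    rowSums(present[, cells == cl, drop = FALSE]) >= min_replicates,
    logical(nrow(m)))
  per_cell_ok <- matrix(per_cell_ok, nrow = nrow(m))
  rel <- close_columns(m)
  mu <- rowMeans(rel)
  sdev <- apply(rel, 1, stats::sd)
  core <- rowSums(per_cell_ok) == length(unique(cells)) & sdev <= mu
  members <- data.frame(otu_id = rownames(m)[core],
                        mean_rel_abund = mu[core],
                        sd_rel_abund = sdev[core],
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(members = members,
                 fraction_of_reads = sum(m[core, , drop = FALSE]) / sum(m),
                 pct_otus = 100 * sum(core) / nrow(m),
                 scope = scope),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> scope %s: %d OTUs, %.2f%% of reads\n",
              x$scope, nrow(x$members), 100 * x$fraction_of_reads))
  invisible(x)
}

#' Ternary compartment coordinates
#'
#' Per OTU, the mean relative abundance in each compartment (averaged over
#' that compartment's replicates within the depth scope), re-closed to sum
#' to 1; barycentric coordinates for ternary plots. OTUs whose total reads
#' fall below `min_abundance` are excluded.
#'
#' @param table a raw `count_table`.
#' @param meta a `sample_metadata`.
#' @param depth_scope `"all"`, `"topsoil"` or `"subsoil"`.
#' @param min_abundance minimum total absolute abundance (default 5).
#' @return data.frame: `otu_id`, `bulk`, `drilosphere`, `rhizosphere`
#'   (coordinates summing to 1), `total_abundance`.
#' @export
ternary_coordinates <- function(table, meta,
                                depth_scope = c("all", "topsoil", "subsoil"),
                                min_abundance = 5) {
  stopifnot(inherits(table, "count_table"))
  depth_scope <- match.arg(depth_scope)
  meta <- meta[match(sample_ids(table), meta$sample_id), ]
  in_scope <- if (depth_scope == "all") rep(TRUE, nrow(meta))
              else meta$depth == depth_scope
  m <- table$counts[, in_scope, drop = FALSE]
  sm <- meta[in_scope, ]
  comps <- c("bulk", "drilosphere", "rhizosphere")
  if (!all(comps %in% sm$compartment))
    stop("all three compartments must be present in scope", call. = FALSE)
  rel <- close_columns(m)
  prof <- vapply(comps, function(cp)
    rowMeans(rel[, sm$compartment == cp, drop = FALSE]), numeric(nrow(m)))
  tot <- rowSums(m)
  keep <- tot >= min_abundance & rowSums(prof) > 0
  prof <- prof[keep, , drop = FALSE] / rowSums(prof[keep, , drop = FALSE])
  data.frame(otu_id = rownames(m)[keep],
             bulk = prof[, "bulk"],
             drilosphere = prof[, "drilosphere"],
             rhizosphere = prof[, "rhizosphere"],
             total_abundance = tot[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Attribute co-occurrence clusters to design cells
#'
#' For every community, sums its members' relative abundances per sample,
#' averages within each depth x compartment cell, normalizes the profile
#' across the six cells, and attributes the community to the argmax cell
#' (ties broken toward the lexicographically first cell and flagged). Also
#' emits a complete-linkage sample ordering on Euclidean distances of the
#' per-sample community profiles (dendrogram analogue).
#'
#' @param partition named community membership (e.g.
#'   `select_partition()$membership`).
#' @param table a raw `count_table` containing the partition's OTUs.
#' @param meta a `sample_metadata`.
#' @return a `cluster_attribution`: list with `attribution` (data.frame
#'   community, depth, compartment, tie), `profiles` (community x cell,
#'   rows sum to 1), `sample_order`.
#' @export
attribute_clusters <- function(partition, table, meta) {
  stopifnot(inherits(table, "count_table"), !is.null(names(partition)))
  meta <- meta[match(sample_ids(table), meta$sample_id), ]
  cells <- paste(meta$depth, meta$compartment, sep = ".")
  cell_levels <- sort(unique(cells))
  rel <- close_columns(table$counts)
  comms <- sort(unique(partition))
  prof <- matrix(0, length(comms), length(cell_levels),
                 dimnames = list(as.character(comms), cell_levels))
  by_sample <- matrix(0, length(comms), ncol(rel),
                      dimnames = list(as.character(comms), colnames(rel)))
  for (ci in seq_along(comms)) {
    members <- names(partition)[partition == comms[ci]]
    members <- intersect(members, rownames(rel))
    if (!length(members)) {
      warning("community ", comms[ci], " has no OTUs in the table; skipped")
      next
    }
    samp_sum <- colSums(rel[members, , drop = FALSE])
    by_sample[ci, ] <- samp_sum
    prof[ci, ] <- vapply(cell_levels, function(cl)
      mean(samp_sum[cells == cl]), numeric(1))
  }
  rs <- rowSums(prof)
  prof[rs > 0, ] <- prof[rs > 0, , drop = FALSE] / rs[rs > 0]
  att <- lapply(seq_along(comms), function(ci) {
    p <- prof[ci, ]
    top <- which(p == max(p))
    cell <- cell_levels[top[1]]
    dc <- strsplit(cell, ".", fixed = TRUE)[[1]]
    data.frame(community = comms[ci], depth = dc[1], compartment = dc[2],
               tie = length(top) > 1, stringsAsFactors = FALSE)
  })
  hc <- stats::hclust(stats::dist(t(by_sample)), method = "complete")
  structure(list(attribution = do.call(rbind, att), profiles = prof,
                 sample_order = colnames(by_sample)[hc$order]),
            class = "cluster_attribution")
}

#' Cross-cluster negative-correlation table
#'
#' For each ordered cluster pair (X, Y), lists the OTUs of cluster Y ranked
#' by how many negative edges they have into cluster X. Nodes that appear
#' only via negative edges (no community label) are reported under the
#' label `"unclustered"`.
#'
#' @param net a `cooccurrence_network` with negative edges.
#' @param partition named community membership over the positive subgraph.
#' @param tax optional `taxonomy_table` used to append the deepest
#'   classified name per OTU.
#' @return data.frame: `cluster_from` (X), `cluster_to` (Y), `otu_id` (in
#'   Y), `n_negative` (edges into X), optionally `taxon`; empty when the
#'   network has no negative edges.
#' @export
cross_cluster_negative_table <- function(net, partition, tax = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  neg <- negative_edges(net)
  empty <- data.frame(cluster_from = character(), cluster_to = character(),
                      otu_id = character(), n_negative = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(neg)) return(empty)
  lab <- function(o) {
    hit <- unname(partition[match(o, names(partition))])
    ifelse(is.na(hit), "unclustered", as.character(hit))
  }
  # one record per directed edge endpoint: OTU b of cluster Y has a negative
  # edge into the cluster of its partner a
  long <- rbind(
    data.frame(cluster_from = lab(neg$otu_a), cluster_to = lab(neg$otu_b),
               otu_id = neg$otu_b, stringsAsFactors = FALSE,
               row.names = NULL),
    data.frame(cluster_from = lab(neg$otu_b), cluster_to = lab(neg$otu_a),
               otu_id = neg$otu_a, stringsAsFactors = FALSE,
               row.names = NULL))
  agg <- stats::aggregate(list(n_negative = rep(1L, nrow(long))),
                          long, FUN = sum)
  agg <- agg[order(agg$cluster_from, agg$cluster_to, -agg$n_negative,
                   agg$otu_id), ]
  rownames(agg) <- NULL
  if (!is.null(tax))
    agg$taxon <- deepest_classified(tax, agg$otu_id)
  agg
}

# deepest classified rank name per OTU ("<name>" or "unclassified")
deepest_classified <- function(tax, otus) {
  idx <- match(otus, tax$otu_id)
  vapply(idx, function(i) {
    if (is.na(i)) return(NA_character_)
    for (rank in rev(.TAX_RANKS))
      if (isTRUE(tax[[paste0(rank, "_classified")]][i]))
        return(tax[[rank]][i])
    "unclassified"
  }, character(1))
}

#' Shared-OTU summary across compartments
#'
#' Per depth, counts OTUs present (count > 0 in at least one replicate) in
#' every compartment-set intersection (Venn cells).
#'
#' @param table a raw `count_table`.
#' @param meta a `sample_metadata`.
#' @return data.frame: `depth`, `bulk`, `drilosphere`, `rhizosphere`
#'   (logical membership pattern), `n_otus`.
#' @export
shared_otu_summary <- function(table, meta) {
  stopifnot(inherits(table, "count_table"))
  meta <- meta[match(sample_ids(table), meta$sample_id), ]
  comps <- c("bulk", "drilosphere", "rhizosphere")
  out <- list()
  for (dp in c("topsoil", "subsoil")) {
    pres <- vapply(comps, function(cp) {
      sel <- meta$depth == dp & meta$compartment == cp
      rowSums(table$counts[, sel, drop = FALSE] > 0) > 0
    }, logical(nrow(table$counts)))
    pres <- matrix(pres, nrow = nrow(table$counts), ncol = length(comps),
                   dimnames = list(NULL, comps))
    for (b in 0:1) for (d in 0:1) for (r in 0:1) {
      if (b + d + r == 0) next
      inset <- pres[, "bulk"] == b & pres[, "drilosphere"] == d &
        pres[, "rhizosphere"] == r
      out[[length(out) + 1]] <- data.frame(
        depth = dp, bulk = as.logical(b), drilosphere = as.logical(d),
        rhizosphere = as.logical(r), n_otus = sum(inset),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
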