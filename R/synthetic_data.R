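#' Synthetic study design
#'
#' Parameters of the Dirichlet-multinomial OTU-table generator that
#' emulates a two-depth x three-compartment x three-replicate soil design
#' (18 samples). Four compartment-linked clusters of co-occurring OTUs, a
#' ubiquitous low-variability core, and a rare, highly variable background
#' are planted on top of a compositional count model.
#'
#' Abundance model, per OTU o and sample s (all on an arbitrary unit
#' scale, closed to proportions before counting): background OTUs have a
#' heavy-tailed log-normal base abundance and independent per-sample
#' log-normal noise; cluster OTUs share a per-(cluster, sample) log-normal
#' factor (driving within-cluster co-occurrence) and are multiplied by
#' `effect_size` in the samples of their home cell; core OTUs have a
#' constant elevated mean with only mild per-OTU spread. Proportions are
#' drawn into a Dirichlet with concentration `dirichlet_alpha` and then a
#' multinomial at a per-sample depth uniform in `depth_range`.
#'
#' @param n_otus total OTUs (clusters + core + background).
#' @param n_clusters number of planted co-occurrence clusters.
#' @param cluster_size OTUs per cluster.
#' @param n_core planted ubiquitous low-variability OTUs.
#' @param effect_size multiplicative enrichment of a cluster's OTUs in its
#'   home depth x compartment cell (>= 1).
#' @param depth_range integer (min, max) reads per sample.
#' @param dirichlet_alpha Dirichlet concentration (overdispersion control).
#' @param cluster_cells data.frame with columns `depth`, `compartment`
#'   assigning each cluster a home cell; default mirrors a bulk-topsoil,
#'   bulk-subsoil, drilosphere and rhizosphere cluster.
#' @param cluster_sd sd of the shared per-(cluster, sample) log factor.
#' @param core_sd sd of the independent per-sample log noise of core OTUs
#'   (small, so the core stays below the sd <= mean screen).
#' @param base_sd sd of the log-normal base abundance of background OTUs.
#' @param background_sd sd of the independent per-sample log noise of
#'   background OTUs.
#' @param cluster_scale,core_scale,background_scale mean abundance units of
#'   the three OTU classes.
#' @param seed integer RNG seed (required).
#' @return a `synthetic_design` list.
#' @export
synthetic_design <- function(n_otus = 1000, n_clusters = 4, cluster_size = 10,
                             n_core = 8, effect_size = 8,
                             depth_range = c(4800, 5200),
                             dirichlet_alpha = 200,
                             cluster_cells = NULL,
                             cluster_sd = 1.2, core_sd = 0.6,
                             base_sd = 0.7, background_sd = 0.4,
                             cluster_scale = 14, core_scale = 280,
                             background_scale = 0.25,
                             seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_core + n_clusters * cluster_size > n_otus)
    stop("n_core + total cluster OTUs exceeds n_otus", call. = FALSE)
  if (effect_size < 1) stop("effect_size must be >= 1", call. = FALSE)
  if (any(depth_range <= 0) || depth_range[1] > depth_range[2])
    stop("invalid depth_range", call. = FALSE)
  if (is.null(cluster_cells)) {
    pool <- data.frame(
      depth = c("topsoil", "subsoil", "topsoil", "topsoil",
                "subsoil", "subsoil"),
      compartment = c("bulk", "bulk", "drilosphere", "rhizosphere",
                      "drilosphere", "rhizosphere"),
      stringsAsFactors = FALSE)
    cluster_cells <- pool[rep_len(seq_len(6), n_clusters), , drop = FALSE]
    rownames(cluster_cells) <- NULL
  }
  stopifnot(nrow(cluster_cells) == n_clusters)
  structure(list(n_otus = n_otus, n_clusters = n_clusters,
                 cluster_size = cluster_size, n_core = n_core,
                 effect_size = effect_size, depth_range = depth_range,
                 dirichlet_alpha = dirichlet_alpha,
                 cluster_cells = cluster_cells, cluster_sd = cluster_sd,
                 core_sd = core_sd,
                 base_sd = base_sd, background_sd = background_sd,
                 cluster_scale = cluster_scale, core_scale = core_scale,
                 background_scale = background_scale, seed = seed),
            class = "synthetic_design")
}

#' Generate a synthetic dataset
#'
#' Draws an OTU count table, sample metadata, taxonomy, genus copy
#' numbers, per-sample qPCR totals and a ground-truth record from a
#' [synthetic_design()]. Fully deterministic given the design's seed.
#'
#' @param design a `synthetic_design`.
#' @return list with `counts` (raw `count_table`), `metadata`, `taxonomy`,
#'   `copy_numbers`, `qpcr` (named numeric, copies per g dry weight), and
#'   `truth` (list: `labels` per OTU — `"cluster<i>"`, `"core"` or
#'   `"background"` —, `cluster_cells`, `core_otus`, `expected_cell_profile`
#'   (OTU x cell expected relative abundance, cells closed to 1),
#'   `copy_numbers`, `seed`).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  meta <- expand.grid(replicate = 1:3,
                      compartment = c("bulk", "drilosphere", "rhizosphere"),
                      depth = c("topsoil", "subsoil"),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s.%s.%d", meta$depth, meta$compartment,
                            meta$replicate)
  meta <- sample_metadata(meta[, c("sample_id", "depth", "compartment",
                                   "replicate")])
  n_samp <- nrow(meta)
  otus <- sprintf("Otu%03d", seq_len(d$n_otus))
  n_clu <- d$n_clusters * d$cluster_size
  labels <- c(rep(paste0("cluster", seq_len(d$n_clusters)),
                  each = d$cluster_size),
              rep("core", d$n_core),
              rep("background", d$n_otus - n_clu - d$n_core))
  names(labels) <- otus
  cells <- paste(meta$depth, meta$compartment, sep = ".")
  home_cell <- paste(d$cluster_cells$depth, d$cluster_cells$compartment,
                     sep = ".")

  out <- with_seed(d$seed, {
    base <- numeric(d$n_otus)
    base[labels == "background"] <-
      d$background_scale * stats::rlnorm(sum(labels == "background"),
                                         0, d$base_sd)
    base[labels == "core"] <-
      d$core_scale * stats::rlnorm(d$n_core, 0, 0.15)
    is_clu <- grepl("^cluster", labels)
    base[is_clu] <- d$cluster_scale * stats::rlnorm(n_clu, 0, 0.3)

    units <- matrix(base, d$n_otus, n_samp)
    # independent per-sample noise on background and (mildly) core OTUs
    bg <- labels == "background"
    units[bg, ] <- units[bg, ] *
      matrix(stats::rlnorm(sum(bg) * n_samp, 0, d$background_sd),
             sum(bg), n_samp)
    co <- labels == "core"
    units[co, ] <- units[co, ] *
      matrix(stats::rlnorm(sum(co) * n_samp, 0, d$core_sd),
             sum(co), n_samp)
    # shared per-(cluster, sample) factor and home-cell enrichment
    for (ci in seq_len(d$n_clusters)) {
      rows <- labels == paste0("cluster", ci)
      shared <- stats::rlnorm(n_samp, 0, d$cluster_sd)
      units[rows, ] <- units[rows, ] * rep(shared, each = sum(rows))
      home <- cells == home_cell[ci]
      units[rows, home] <- units[rows, home] * d$effect_size
    }
    props <- close_columns(units)
    depths <- sample(seq(d$depth_range[1], d$depth_range[2]), n_samp,
                     replace = TRUE)
    counts <- matrix(0, d$n_otus, n_samp, dimnames = list(otus, meta$sample_id))
    for (j in seq_len(n_samp)) {
      g <- stats::rgamma(d$n_otus, shape = d$dirichlet_alpha * props[, j])
      p <- g / sum(g)
      counts[, j] <- stats::rmultinom(1, depths[j], p)
    }
    # taxonomy: genera assigned round-robin; a slice of background OTUs is
    # left genus-unclassified to exercise the copy-number fallback walk
    genera <- sprintf("Genus%02d", rep_len(1:20, d$n_otus))
    phyla <- sprintf("Phylum%02d", rep_len(1:5, d$n_otus))
    lineage <- sprintf(
      "Bacteria;%s;Class%s;Order%s;Family%02d;%s;",
      phyla, substr(phyla, 7, 8), substr(phyla, 7, 8),
      rep_len(1:10, d$n_otus), genera)
    uncls <- bg & (seq_len(d$n_otus) %% 7 == 0)
    lineage[uncls] <- sub("Genus[0-9]+;$", "unclassified;", lineage[uncls])
    tax <- taxonomy_table(otus, lineage)
    copies <- stats::setNames(sample(1:10, 20, replace = TRUE),
                              sprintf("Genus%02d", 1:20))
    cn <- copy_number_table(data.frame(
      rank = c(rep("genus", 20), rep("family", 10), "root"),
      name = c(names(copies), sprintf("Family%02d", 1:10), "root"),
      mean_copies = c(as.numeric(copies),
                      rep(mean(copies), 10), mean(copies)),
      stringsAsFactors = FALSE))
    qpcr <- stats::setNames(
      depths * 2e5 * stats::rlnorm(n_samp, 0, 0.3), meta$sample_id)

    expected <- vapply(sort(unique(cells)), function(cl) {
      e <- base
      for (ci in seq_len(d$n_clusters)) {
        rows <- labels == paste0("cluster", ci)
        e[rows] <- e[rows] *
          exp(d$cluster_sd^2 / 2) * ifelse(home_cell[ci] == cl,
                                           d$effect_size, 1)
      }
      e[bg] <- e[bg] * exp(d$background_sd^2 / 2)
      e / sum(e)
    }, numeric(d$n_otus))
    rownames(expected) <- otus

    list(counts = count_table(counts), metadata = meta, taxonomy = tax,
         copy_numbers = cn, qpcr = qpcr,
         truth = list(labels = labels, cluster_cells = d$cluster_cells,
                      core_otus = otus[labels == "core"],
                      expected_cell_profile = expected,
                      copy_numbers = copies, seed = d$seed))
  })
  out
}

#' Hand-sized worked example
#'
#' A 12-OTU x 18-sample fixture whose prevalence-filter, core-microbiome
#' and ternary outcomes are designed to be checked by hand: exactly OTUs
#' 1-7 survive the default (6 reads, 3 samples) filter, exactly OTUs 1-2
#' form the intrinsic core (OTU 5 joins for the topsoil scope), OTU 3 sits
#' at the rhizosphere tip of the ternary plot and OTU 6 at the bulk tip,
#' and the minimum sample depth is 100 reads. The same tables ship as TSV
#' under `inst/extdata` (`micro_*.tsv`).
#'
#' @return list with `counts`, `metadata`, `taxonomy`, `copy_numbers` and
#'   `expected` (list: `filter_survivors`, `core`, `topsoil_core`,
#'   `min_depth`).
#' @export
worked_micro_example <- function() {
  meta <- expand.grid(replicate = 1:3,
                      compartment = c("bulk", "drilosphere", "rhizosphere"),
                      depth = c("topsoil", "subsoil"),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s.%s.%d", meta$depth, meta$compartment,
                            meta$replicate)
  meta <- sample_metadata(meta[, c("sample_id", "depth", "compartment",
                                   "replicate")])
  cell <- paste(meta$depth, meta$compartment, sep = ".")
  rep_ <- meta$replicate
  n <- nrow(meta)
  row <- function(f) vapply(seq_len(n), f, numeric(1))
  counts <- rbind(
    Otu01 = rep(60, n),                                        # core, abundant
    Otu02 = rep(12, n),                                        # core, even
    Otu03 = row(function(i) if (grepl("rhizosphere", cell[i])) 40 else 0),
    Otu04 = row(function(i) if (grepl("drilosphere", cell[i])) 25 else 1),
    Otu05 = row(function(i) if (meta$depth[i] == "topsoil") 20 else 0),
    Otu06 = row(function(i) if (grepl("bulk", cell[i])) 20 else 0),
    Otu07 = row(function(i)
      if (meta$depth[i] == "topsoil" &&
          (rep_[i] <= 2 && meta$compartment[i] != "rhizosphere" ||
           rep_[i] == 1 && meta$compartment[i] == "rhizosphere")) 7 else 0),
    Otu08 = row(function(i)
      if (cell[i] == "subsoil.bulk") c(6, 6, 5)[rep_[i]] else 0),
    Otu09 = row(function(i)
      if (meta$depth[i] == "topsoil" &&
          meta$compartment[i] != "rhizosphere") 5 else 0),
    Otu10 = row(function(i)
      if (cell[i] == "subsoil.rhizosphere" && rep_[i] == 1) 1 else 0),
    Otu11 = row(function(i)
      if (cell[i] == "subsoil.drilosphere" && rep_[i] <= 2) 4 else 0),
    Otu12 = row(function(i) if (meta$depth[i] == "subsoil") 3 else 0))
  colnames(counts) <- meta$sample_id
  tax <- taxonomy_table(
    rownames(counts),
    c("Bacteria;Actinobacteria;ClassA;OrderA;FamilyA;GenusA;",
      "Bacteria;Proteobacteria;ClassB;OrderB;FamilyB;GenusB;",
      "Bacteria;Proteobacteria;ClassB;OrderB;FamilyB;GenusC;",
      "Bacteria;Bacteroidetes;ClassC;OrderC;FamilyC;GenusD;",
      "Bacteria;Actinobacteria;ClassA;OrderA;FamilyA;unclassified;",
      "Bacteria;Acidobacteria;ClassD;OrderD;unclassified;unclassified;",
      "Bacteria;Verrucomicrobia;ClassE;OrderE;FamilyE;GenusE;",
      "Bacteria;Planctomycetes;ClassF;OrderF;FamilyF;GenusF;",
      "Bacteria;unclassified;unclassified;unclassified;unclassified;unclassified;",
      "Bacteria;Firmicutes;ClassG;OrderG;FamilyG;GenusG;",
      "Bacteria;Chloroflexi;ClassH;OrderH;FamilyH;GenusH;",
      "Bacteria;Gemmatimonadetes;ClassI;OrderI;FamilyI;GenusI;"))
  cn <- copy_number_table(data.frame(
    rank = c("genus", "genus", "genus", "genus", "family", "order",
             "domain", "root"),
    name = c("GenusA", "GenusB", "GenusC", "GenusD", "FamilyA", "OrderD",
             "Bacteria", "root"),
    mean_copies = c(2, 4, 4, 6, 3, 1.5, 4.2, 4.2),
    stringsAsFactors = FALSE))
  list(counts = count_table(counts), metadata = meta, taxonomy = tax,
       copy_numbers = cn,
       expected = list(
         filter_survivors = sprintf("Otu%02d", 1:7),
         core = c("Otu01", "Otu02"),
         topsoil_core = c("Otu01", "Otu02", "Otu05"),
         min_depth = 100))
}
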