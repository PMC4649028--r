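#' OTU count table
#'
#' Central container for OTU-by-sample read counts. Rows are OTUs, columns
#' are samples, regardless of the orientation of the file the table came
#' from. Raw tables hold non-negative integers; after normalization
#' (`is_relative = TRUE`) every non-empty sample column sums to 1.
#'
#' @param counts numeric matrix, OTUs in rows and samples in columns, with
#'   unique non-empty dimnames.
#' @param is_relative logical; `TRUE` for relative-abundance tables.
#' @return an object of class `count_table`: a list with elements `counts`
#'   and `is_relative`.
#' @export
count_table <- function(counts, is_relative = FALSE) {
  new_count_table(counts, is_relative = is_relative, check_integer = !is_relative)
}

# internal constructor; check_integer = FALSE admits real-valued tables
# (copy-number-adjusted counts) that are never parsed from files
new_count_table <- function(counts, is_relative = FALSE, check_integer = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix", call. = FALSE)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("'counts' must have OTU rownames and sample colnames", call. = FALSE)
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  storage.mode(counts) <- "double"
  if (anyDuplicated(rownames(counts)))
    stop("duplicate otu_ids in count table", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample_ids in count table", call. = FALSE)
  if (any(counts < 0) || anyNA(counts))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (check_integer && any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (is_relative) {
    cs <- colSums(counts)
    bad <- which(cs > 0 & abs(cs - 1) > 1e-9)
    if (length(bad))
      stop(sprintf("relative table column '%s' does not sum to 1",
                   colnames(counts)[bad[1]]), call. = FALSE)
  }
  structure(list(counts = counts, is_relative = is_relative),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d OTUs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_relative) "relative" else "raw counts"))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' @rdname count_table
#' @param x a `count_table`.
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Read an OTU count table
#'
#' Supports plain TSV (first column `otu_id`, one column per sample) and the
#' mothur `.shared` dialect (sample-per-row; `label`, `Group` and `numOtus`
#' columns are consumed and the table is transposed to the package's
#' OTU-rows convention).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"mothur_shared"`.
#' @return a raw [count_table()].
#' @export
read_count_table <- function(path, dialect = c("tsv", "mothur_shared")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("parse error in '", path, "': need a header line and at least one data row",
         call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "")
  if (dialect == "mothur_shared") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(raw)))
      stop("parse error in '", path,
           "': mothur shared header must contain label/Group/numOtus (line 1)",
           call. = FALSE)
    otu_cols <- setdiff(names(raw), need)
    m <- t(as.matrix(raw[, otu_cols, drop = FALSE]))
    colnames(m) <- raw$Group
    rownames(m) <- otu_cols
  } else {
    if (ncol(raw) < 2)
      stop("parse error in '", path, "': TSV needs otu_id plus sample columns (line 1)",
           call. = FALSE)
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- as.character(raw[[1]])
  }
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
    stop(sprintf("validation error in '%s': non-numeric count at OTU '%s', sample '%s'",
                 path, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  storage.mode(m) <- "double"
  count_table(m, is_relative = FALSE)
}

#' Write a count table as TSV
#'
#' Raw tables round-trip bit-exactly through [read_count_table()].
#'
#' @param x a `count_table`.
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy table
#'
#' Accepts mothur `.cons.taxonomy` (columns `OTU`, `Size`, `Taxonomy`) or a
#' two-column TSV (`otu_id`, `lineage`). Bootstrap confidence values in
#' parentheses are stripped; rank names containing the token "unclassified"
#' (case-insensitive) are flagged as unclassified. Lineages shorter than six
#' ranks are padded with unclassified placeholders.
#'
#' @param path file path.
#' @param dialect `"mothur_cons"` or `"tsv"`.
#' @return a `taxonomy_table`: data.frame with `otu_id`, the six ranks
#'   domain...genus, and logical columns `<rank>_classified`.
#' @export
read_taxonomy <- function(path, dialect = c("mothur_cons", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "")
  if (dialect == "mothur_cons") {
    if (!all(c("OTU", "Taxonomy") %in% names(raw)))
      stop("parse error in '", path, "': expected OTU and Taxonomy columns",
           call. = FALSE)
    ids <- as.character(raw$OTU)
    lineages <- as.character(raw$Taxonomy)
  } else {
    if (ncol(raw) < 2)
      stop("parse error in '", path, "': expected otu_id and lineage columns",
           call. = FALSE)
    ids <- as.character(raw[[1]])
    lineages <- as.character(raw[[2]])
  }
  if (anyDuplicated(ids))
    stop("duplicate otu_id in taxonomy: ", ids[duplicated(ids)][1], call. = FALSE)
  taxonomy_table(ids, lineages)
}

#' Build a taxonomy table from lineage strings
#'
#' @param otu_id character vector of OTU identifiers.
#' @param lineage character vector of semicolon-separated lineages
#'   (domain;phylum;class;order;family;genus), optionally with bootstrap
#'   values in parentheses and a trailing semicolon.
#' @export
taxonomy_table <- function(otu_id, lineage) {
  stopifnot(length(otu_id) == length(lineage))
  clean <- gsub("\\([^)]*\\)", "", lineage)   # strip bootstrap annotations
  clean <- sub(";\\s*$", "", clean)
  parts <- strsplit(clean, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(.TAX_RANKS)           # pad with NA
    p
  }, character(length(.TAX_RANKS))))
  colnames(m) <- .TAX_RANKS
  m[is.na(m)] <- "unclassified"
  classified <- !grepl("unclassified", m, ignore.case = TRUE)
  dim(classified) <- dim(m)
  # enforce contiguity: nothing classified below an unclassified rank
  for (r in 2:length(.TAX_RANKS))
    classified[, r] <- classified[, r] & classified[, r - 1]
  out <- data.frame(otu_id = as.character(otu_id), m,
                    stringsAsFactors = FALSE, check.names = FALSE)
  cls <- as.data.frame(classified)
  names(cls) <- paste0(.TAX_RANKS, "_classified")
  out <- cbind(out, cls)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `depth` (topsoil/subsoil), `compartment`
#' (bulk/drilosphere/rhizosphere) and `replicate`.
#'
#' @param path file path.
#' @export
read_sample_metadata <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  sample_metadata(raw)
}

#' Validate a sample-metadata data.frame
#'
#' @param df data.frame with columns `sample_id`, `depth`, `compartment`,
#'   `replicate`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "depth", "compartment", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  if (!all(df$depth %in% c("topsoil", "subsoil")))
    stop("depth must be 'topsoil' or 'subsoil'", call. = FALSE)
  if (!all(df$compartment %in% c("bulk", "drilosphere", "rhizosphere")))
    stop("compartment must be bulk/drilosphere/rhizosphere", call. = FALSE)
  if (any(df$replicate < 1 | df$replicate != round(df$replicate)))
    stop("replicate must be a positive integer", call. = FALSE)
  cell <- paste(df$depth, df$compartment)
  if (anyDuplicated(paste(cell, df$replicate)))
    stop("replicate ids must be unique within a depth x compartment cell",
         call. = FALSE)
  df <- df[, c(need, setdiff(names(df), need))]
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read a 16S copy-number lookup table
#'
#' TSV with columns `rank`, `name`, `mean_copies` (mean 16S rRNA gene
#' copies per genome, rrnDB pan-taxa style). An entry with rank `root`
#' provides the fallback used when no rank of an OTU's lineage resolves.
#'
#' @param path file path.
#' @export
read_copy_numbers <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  copy_number_table(raw)
}

#' Validate a copy-number lookup data.frame
#'
#' @param df data.frame with columns `rank`, `name`, `mean_copies`.
#' @export
copy_number_table <- function(df) {
  need <- c("rank", "name", "mean_copies")
  if (!all(need %in% names(df)))
    stop("copy-number table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$mean_copies <= 0) || anyNA(df$mean_copies))
    stop("mean_copies must be positive", call. = FALSE)
  if (!any(df$rank == "root"))
    stop("copy-number table must contain a rank 'root' default entry",
         call. = FALSE)
  class(df) <- c("copy_number_table", "data.frame")
  df
}

#' Cross-validate counts, metadata and taxonomy
#'
#' Raises only when a sample in the count table has no metadata record;
#' everything else (missing taxonomy, all-zero rows or columns) is reported.
#'
#' @param table a `count_table`.
#' @param meta a `sample_metadata`.
#' @param tax optional `taxonomy_table`.
#' @return a list with character vectors `errors` and `warnings` (both may
#'   be empty).
#' @export
validate_tables <- function(table, meta, tax = NULL) {
  warnings <- character()
  missing_meta <- setdiff(sample_ids(table), meta$sample_id)
  if (length(missing_meta))
    stop("sample(s) absent from metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  if (!is.null(tax)) {
    missing_tax <- setdiff(otu_ids(table), tax$otu_id)
    if (length(missing_tax))
      warnings <- c(warnings, paste0("OTU without taxonomy: ", missing_tax))
  }
  zr <- rownames(table$counts)[rowSums(table$counts) == 0]
  if (length(zr)) warnings <- c(warnings, paste0("all-zero OTU: ", zr))
  zc <- colnames(table$counts)[colSums(table$counts) == 0]
  if (length(zc)) warnings <- c(warnings, paste0("all-zero sample: ", zc))
  list(errors = character(), warnings = warnings)
}

#' Export a co-occurrence network
#'
#' `write_edge_list()` writes a TSV with columns source, target, rho, p,
#' sign; `write_network_graphml()` writes GraphML with thresholds and seeds
#' stored as graph attributes.
#'
#' @param net a `cooccurrence_network` (see [build_network()]).
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  df <- net$edges[, c("otu_a", "otu_b", "rho", "p", "sign")]
  names(df)[1:2] <- c("source", "target")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net, sign = "both")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a co-occurrence network to igraph
#'
#' @param net a `cooccurrence_network`.
#' @param sign `"positive"`, `"negative"` or `"both"` edge subset.
#' @export
as_igraph <- function(net, sign = c("positive", "negative", "both")) {
  sign <- match.arg(sign)
  e <- net$edges
  if (sign != "both") e <- e[e$sign == sign, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("otu_a", "otu_b", "rho", "p", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  for (nm in names(net$thresholds))
    g <- igraph::set_graph_attr(g, nm, net$thresholds[[nm]])
  for (nm in names(net$provenance))
    g <- igraph::set_graph_attr(g, nm, net$provenance[[nm]])
  g
}
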