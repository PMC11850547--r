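#' Coerce to a feature table
#'
#' A feature table is the universal input of the package: a taxa-by-samples
#' matrix of non-negative integer counts with taxon IDs as row names and
#' sample IDs as column names. Data frames in the package's TSV layout
#' (first column `taxon_id`, one column per sample) are converted.
#'
#' @param x A matrix with dimnames, or a data frame whose first column is
#'   `taxon_id`.
#' @return An integer matrix, taxa as rows, samples as columns.
#' @export
as_feature_table <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2 || !names(x)[1] %in% c("taxon_id", "taxon"))
      stop("data-frame feature tables need a leading 'taxon_id' column")
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x)) stop("feature table must be a matrix or data frame")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("feature table needs taxon row names and sample column names")
  storage.mode(x) <- "double"
  validate_feature_table(x)
  storage.mode(x) <- "integer"
  x
}

validate_feature_table <- function(x) {
  if (anyDuplicated(rownames(x))) stop("duplicate taxon IDs in feature table")
  if (anyDuplicated(colnames(x))) stop("duplicate sample IDs in feature table")
  if (anyNA(x)) stop("feature table contains missing counts")
  if (any(x < 0)) stop("feature table counts must be non-negative")
  if (any(abs(x - round(x)) > 1e-8)) stop("feature table counts must be integers")
  invisible(x)
}

#' Read a feature table from TSV or BIOM
#'
#' TSV tables are tab-separated with a header row of sample IDs and a first
#' column `taxon_id`. Files ending in `.biom` are parsed as BIOM
#' (JSON, format 1.0) via the biomformat package.
#'
#' @param path Path to a `.tsv`/`.txt` or `.biom` file.
#' @return Integer matrix, taxa x samples.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table file not found: ", path)
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(as_feature_table(m))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty feature table: ", path)
  as_feature_table(as.data.frame(df))
}

#' Write a feature table
#'
#' @param table Feature table (taxa x samples integer matrix).
#' @param path Output path; `.biom` selects BIOM (JSON) output, anything else
#'   the package's TSV layout.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- as_feature_table(table)
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM requires the biomformat package")
    b <- biomformat::make_biom(table)
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- tibble::as_tibble(table, rownames = "taxon_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata is a TSV with one row per sample; `sample_id`, `subject_id`,
#' `habitat` and `group` columns are mandatory.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "subject_id", "habitat", "group")
  miss <- setdiff(needed, names(md))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample IDs in metadata")
  md
}

#' Read a taxonomy lineage table
#'
#' TSV with a `taxon_id` column and ranked lineage columns
#' (`kingdom`, `phylum`, `class`, `order`, `family`, `genus`).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tx <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"taxon_id" %in% names(tx)) stop("taxonomy table needs a 'taxon_id' column")
  if (anyDuplicated(tx$taxon_id)) stop("duplicate taxon IDs in taxonomy table")
  tx
}

#' Collapse a feature table to a taxonomic rank
#'
#' Counts are summed over features sharing the lineage value at `rank`;
#' features with a missing or empty lineage at that rank are pooled into
#' an `"Unassigned"` bucket. Per-sample totals are conserved.
#'
#' @param table Feature table.
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return Collapsed feature table (rank labels as row names).
#' @export
collapse_taxonomy <- function(table, taxonomy, rank) {
  table <- as_feature_table(table)
  rank <- match.arg(rank, c("phylum", "class", "order", "family", "genus"))
  if (!rank %in% names(taxonomy)) stop("taxonomy table has no '", rank, "' column")
  key <- taxonomy[[rank]][match(rownames(table), taxonomy$taxon_id)]
  key[is.na(key) | key == ""] <- "Unassigned"
  out <- rowsum(table + 0, group = key)
  as_feature_table(out)
}

#' Load a configured set of pipeline inputs
#'
#' Reads the feature tables, metadata, optional taxonomy and optional tree
#' named by a pipeline configuration, and validates that their IDs
#' cross-reference. The configuration is a named list (or a YAML file path)
#' with elements `feature_tables` (named character vector/list of paths),
#' `metadata`, and optionally `taxonomy` and `tree`.
#'
#' @param config Named list or path to a YAML file.
#' @return A list with `tables`, `metadata`, `taxonomy` (or NULL),
#'   `tree` (or NULL).
#' @export
load_inputs <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$feature_tables) || is.null(config$metadata))
    stop("config needs 'feature_tables' and 'metadata' entries")
  tables <- lapply(config$feature_tables, read_feature_table)
  metadata <- read_sample_metadata(config$metadata)
  all_samples <- unlist(lapply(tables, colnames), use.names = FALSE)
  unknown <- setdiff(metadata$sample_id, all_samples)
  if (length(unknown))
    stop("metadata references samples absent from the feature tables: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy) else NULL
  tree <- if (!is.null(config$tree)) ape::read.tree(config$tree) else NULL
  if (!is.null(tree)) {
    taxa <- unique(unlist(lapply(tables, rownames), use.names = FALSE))
    lost <- setdiff(taxa, tree$tip.label)
    if (length(lost))
      stop("taxa absent from the tree: ", paste(utils::head(lost, 5), collapse = ", "))
  }
  message(sprintf("loaded %d feature table(s), %d samples of metadata",
                  length(tables), nrow(metadata)))
  list(tables = tables, metadata = metadata, taxonomy = taxonomy, tree = tree)
}

#' Write / read a distance matrix as TSV
#'
#' Square layout with a sample-ID header row and first column.
#' @param dm A `dist` object or square matrix.
#' @param path Output path.
#' @return `path` (writer) or a `dist` (reader).
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- tibble::as_tibble(m, rownames = "sample_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}
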