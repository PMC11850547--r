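#' Rarefy a feature table to even depth
#'
#' Subsamples each sample without replacement to exactly `depth` total
#' counts (via [vegan::rrarefy()]). Samples whose total is below `depth`
#' are dropped and reported in the `"dropped"` attribute (and a message).
#'
#' @param table Feature table (taxa x samples).
#' @param depth Target depth; defaults to the minimum sample total.
#' @param seed Optional integer seed for reproducible subsampling.
#' @return Rarefied feature table with equal column sums; attribute
#'   `"dropped"` lists removed sample IDs.
#' @export
rarefy <- function(table, depth = NULL, seed = NULL) {
  table <- as_feature_table(table)
  totals <- colSums(table)
  if (is.null(depth)) depth <- min(totals)
  if (depth < 1) stop("rarefaction depth must be >= 1")
  keep <- totals >= depth
  if (!any(keep)) stop("rarefaction depth ", depth, " exceeds every sample total")
  dropped <- colnames(table)[!keep]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(utils::head(dropped, 5), collapse = ", "))
  sub <- table[, keep, drop = FALSE]
  # vegan warns when the smallest positive count exceeds 1; irrelevant for
  # subsampling arbitrary tables, so muffle that specific warning
  run <- function() withCallingHandlers(
    t(vegan::rrarefy(t(sub), depth)),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- dropped
  out
}

#' Alpha diversity indices for a single count vector
#'
#' With `p_t = count_t / total` over taxa with positive counts:
#' Shannon entropy `H = -sum p log2 p` (bits by default), Simpson index
#' `D = 1 - sum p^2`, Pielou evenness `J = H / log2(S)` for `S` observed
#' taxa (undefined, `NA`, when `S = 1`), and richness `S`.
#'
#' @param counts Non-negative count vector with at least one positive entry.
#' @param base Logarithm base for Shannon/Pielou (2 = bits, the default;
#'   `exp(1)` for nats).
#' @return One-row tibble: shannon, simpson, pielou, richness.
#' @export
alpha_indices <- function(counts, base = 2) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("all-zero count vector: alpha diversity undefined")
  p <- counts[counts > 0] / sum(counts)
  s <- length(p)
  h <- -sum(p * log(p, base = base))
  tibble::tibble(
    shannon = h,
    simpson = 1 - sum(p^2),
    pielou = if (s >= 2) h / log(s, base = base) else NA_real_,
    richness = s)
}

#' Alpha diversity for every sample of a feature table
#'
#' @param table Feature table.
#' @inheritParams alpha_indices
#' @return Tibble with one row per sample: sample_id plus the
#'   [alpha_indices()] columns.
#' @export
alpha_diversity <- function(table, base = 2) {
  table <- as_feature_table(table)
  purrr::map_dfr(colnames(table), function(s) {
    dplyr::bind_cols(tibble::tibble(sample_id = s), alpha_indices(table[, s]
, base = base))
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 * sum_t min(x_t, y_t) / (sum_t x_t + sum_t y_t)`,
#' computed with [vegan::vegdist()].
#'
#' @param table Feature table with >= 2 samples, each with a positive total.
#' @return A `dist` object over samples; entries in [0, 1].
#' @export
bray_curtis <- function(table) {
  table <- as_feature_table(table)
  if (ncol(table) < 2) stop("need at least 2 samples")
  zero <- colnames(table)[colSums(table) == 0]
  if (length(zero))
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "))
  vegan::vegdist(t(table), method = "bray")
}

#' Unweighted UniFrac distance matrix
#'
#' Presence/absence phylogenetic dissimilarity: the branch length unique to
#' one of the two samples' induced subtrees divided by the branch length of
#' their union. Computed with [picante::unifrac()]; every taxon observed in
#' the table must be a tip of the rooted tree.
#'
#' @param table Feature table.
#' @param tree Rooted `phylo` tree with non-negative branch lengths.
#' @return A `dist` object over samples; entries in [0, 1].
#' @export
unweighted_unifrac <- function(table, tree) {
  table <- as_feature_table(table)
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  present <- rownames(table)[rowSums(table) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  comm <- t(table[intersect(rownames(table), tree$tip.label), , drop = FALSE])
  tr <- ape::keep.tip(tree, colnames(comm))
  stats::as.dist(as.matrix(picante::unifrac(comm, tr)))
}
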