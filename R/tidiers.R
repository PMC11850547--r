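#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired differential-abundance fit
#'
#' @param x A `microref_da`.
#' @param ... Unused.
#' @return The per-taxon results tibble (taxon, logfc, se, ci_low, ci_high,
#'   p_value, q_value, significant).
#' @export
tidy.microref_da <- function(x, ...) x$results

#' One-row summary of a paired differential-abundance fit
#'
#' @param x A `microref_da`.
#' @param ... Unused.
#' @return Tibble: n_taxa, n_pairs, bias, bias_components, n_significant,
#'   fdr_level.
#' @export
glance.microref_da <- function(x, ...) {
  tibble::tibble(n_taxa = nrow(x$results), n_pairs = x$n_pairs,
                 bias = x$bias, bias_components = x$bias_components,
                 n_significant = sum(x$results$significant),
                 fdr_level = x$fdr_level)
}

#' Tidy a screening report
#'
#' @param x A `microref_screen`.
#' @param ... Unused.
#' @return Per-taxon tibble (taxon, prop_within, selected).
#' @export
tidy.microref_screen <- function(x, ...) x$taxa

#' One-row summary of a screening report
#'
#' @param x A `microref_screen`.
#' @param ... Unused.
#' @return Tibble: n_subjects, n_taxa, n_selected, threshold.
#' @export
glance.microref_screen <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_taxa = nrow(x$taxa),
                 n_selected = sum(x$taxa$selected), threshold = x$threshold)
}

#' Tidy a logFC PCA
#'
#' @param x A `microref_pca`.
#' @param ... Unused.
#' @return Scores tibble (subject_id, group, PC columns).
#' @export
tidy.microref_pca <- function(x, ...) x$scores

#' One-row summary of a logFC PCA
#'
#' @param x A `microref_pca`.
#' @param ... Unused.
#' @return Tibble: pc1_var, pc2_var, separation.
#' @export
glance.microref_pca <- function(x, ...) {
  tibble::tibble(pc1_var = x$var_explained[1],
                 pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_,
                 separation = x$separation)
}
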