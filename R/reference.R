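#' Reference interval of an alpha-diversity measure
#'
#' Central 95% of the reference cohort after outlier exclusion: outliers
#' are removed (Tukey 1.5 IQR fences by default), then the 2.5th and
#' 97.5th percentiles of the remainder are taken with linear interpolation
#' between order statistics (`h = (n - 1) q + 1`, [stats::quantile()]
#' type 7).
#'
#' @param values Numeric vector (NAs dropped); >= 4 values required, and a
#'   `low_n` flag is raised below 20.
#' @param outlier_rule `"tukey"` (1.5 IQR fences, default), `"3sd"`
#'   (mean +/- 3 sd) or `"none"`.
#' @param probs Percentile pair defining the interval.
#' @return One-row tibble: lower, upper, n_used, n_outliers_excluded, low_n.
#' @export
alpha_reference_interval <- function(values,
                                     outlier_rule = c("tukey", "3sd", "none"),
                                     probs = c(0.025, 0.975)) {
  outlier_rule <- match.arg(outlier_rule)
  x <- values[!is.na(values)]
  if (length(x) < 4) stop("need at least 4 values for a reference interval")
  low_n <- length(x) < 20
  if (low_n) warning("fewer than 20 values: reference interval is unstable")
  keep <- switch(outlier_rule,
    none = rep(TRUE, length(x)),
    tukey = {
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr
    },
    `3sd` = abs(x - mean(x)) <= 3 * stats::sd(x))
  xin <- x[keep]
  qs <- stats::quantile(xin, probs, names = FALSE, type = 7)
  tibble::tibble(lower = qs[1], upper = qs[2],
                 n_used = length(xin),
                 n_outliers_excluded = sum(!keep),
                 low_n = low_n)
}

#' Per-taxon reference ranges from a reference-cohort DA fit
#'
#' The screening range of each taxon is the reference cohort's 95%
#' confidence interval of the paired logFC, taken verbatim from the fit.
#' An optional prediction-interval mode widens the range to
#' `logfc +/- z * sd * sqrt(1 + 1/n)` where `sd = se * sqrt(n)`; unlike
#' the confidence interval of the mean, this mode targets the spread of an
#' individual subject's value and does not shrink with the cohort size.
#'
#' @param reference_da A `microref_da` fit.
#' @param mode `"ci"` (default) or `"prediction"`.
#' @return Tibble: taxon, range_low, range_high, degenerate (zero-width
#'   range flag).
#' @export
taxon_reference_ranges <- function(reference_da, mode = c("ci", "prediction")) {
  stopifnot(inherits(reference_da, "microref_da"))
  mode <- match.arg(mode)
  r <- reference_da$results
  if (any(!is.finite(r$ci_low) | !is.finite(r$ci_high)))
    stop("reference fit contains non-finite confidence bounds")
  if (mode == "ci") {
    lo <- r$ci_low; hi <- r$ci_high
  } else {
    n <- reference_da$n_pairs
    zc <- stats::qnorm(1 - (1 - reference_da$conf_level) / 2)
    half <- zc * r$se * sqrt(n) * sqrt(1 + 1 / n)
    lo <- r$logfc - half; hi <- r$logfc + half
  }
  tibble::tibble(taxon = r$taxon, range_low = lo, range_high = hi,
                 degenerate = hi - lo <= 0)
}

#' Screen a cohort of subject logFC profiles against reference ranges
#'
#' A subject is in-range for a taxon iff
#' `range_low <= f <= range_high` (closed interval; boundary values count
#' as within). Per taxon, the proportion of screened subjects in range is
#' reported; taxa whose proportion does not exceed `threshold` (0 by
#' default: no subject in range) are selected into the profile.
#'
#' @param subject_fcs Long tibble (subject_id, taxon, f) as produced by
#'   [subject_logfc_profiles()].
#' @param ranges Tibble from [taxon_reference_ranges()].
#' @param threshold Selection threshold on the in-range proportion.
#' @return Object of class `microref_screen`: `taxa` (tibble: taxon,
#'   prop_within, selected), `flags` (long tibble: subject_id, taxon, f,
#'   within), `n_subjects`, `threshold`.
#' @export
screen_cohort <- function(subject_fcs, ranges, threshold = 0) {
  taxa <- intersect(unique(subject_fcs$taxon), ranges$taxon)
  if (!length(taxa)) stop("no taxa shared between profiles and ranges")
  flags <- dplyr::inner_join(subject_fcs, ranges, by = "taxon")
  flags$within <- flags$f >= flags$range_low & flags$f <= flags$range_high
  per_taxon <- flags |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(prop_within = mean(.data$within), .groups = "drop")
  per_taxon$selected <- per_taxon$prop_within <= threshold
  structure(list(taxa = per_taxon,
                 flags = flags[, c("subject_id", "taxon", "f", "within")],
                 n_subjects = length(unique(subject_fcs$subject_id)),
                 threshold = threshold),
            class = "microref_screen")
}

#' @export
print.microref_screen <- function(x, ...) {
  cat("Reference-range screening report\n")
  cat(sprintf("  %d subjects screened on %d taxa; %d taxa selected (threshold %.2f)\n",
              x$n_subjects, nrow(x$taxa), sum(x$taxa$selected), x$threshold))
  invisible(x)
}

#' Profile taxa selected by a screening report
#'
#' Taxa whose in-range proportion is at or below the threshold (default 0:
#' the fold change deviates from the reference range in every screened
#' subject).
#'
#' @param report A `microref_screen`.
#' @param threshold Proportion threshold; defaults to the report's.
#' @return Character vector of selected taxon IDs.
#' @export
select_profile_taxa <- function(report, threshold = report$threshold) {
  stopifnot(inherits(report, "microref_screen"))
  report$taxa$taxon[report$taxa$prop_within <= threshold]
}

#' PCA separation of groups on selected-taxon logFC profiles
#'
#' Column-centered (not scaled) principal component analysis by singular
#' value decomposition, plus a separation score: the distance between the
#' two group centroids in the PC1-PC2 plane divided by the pooled
#' within-group standard deviation of sample-to-centroid distances.
#'
#' @param logfc_matrix Subjects x taxa numeric matrix (>= 3 subjects,
#'   >= 2 taxa), or a long tibble (subject_id, taxon, f).
#' @param groups Group labels aligned with the matrix rows (>= 2 groups).
#' @return Object of class `microref_pca`: `scores` (tibble: subject_id,
#'   group, PC1, PC2, ...), `var_explained`, `separation`.
#' @export
pca_separation <- function(logfc_matrix, groups) {
  if (is.data.frame(logfc_matrix)) {
    wide <- tidyr::pivot_wider(logfc_matrix, names_from = "taxon",
                               values_from = "f")
    m <- as.matrix(wide[, -1]); rownames(m) <- wide$subject_id
    logfc_matrix <- m
  }
  if (nrow(logfc_matrix) < 3 || ncol(logfc_matrix) < 2)
    stop("need >= 3 subjects and >= 2 taxa")
  groups <- as.factor(groups)
  if (length(groups) != nrow(logfc_matrix)) stop("groups do not match the rows")
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  centered <- scale(logfc_matrix, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) stop("rank-0 matrix: no variation to decompose")
  pc <- stats::prcomp(logfc_matrix, center = TRUE, scale. = FALSE)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2, ncol(pc$x))
  xy <- pc$x[, seq_len(k), drop = FALSE]
  centroids <- apply(xy, 2, function(col) tapply(col, groups, mean))
  centroids <- matrix(centroids, nrow = nlevels(groups))
  between <- stats::dist(centroids)
  resid2 <- numeric(nrow(xy))
  for (g in levels(groups)) {
    idx <- groups == g
    ctr <- colMeans(xy[idx, , drop = FALSE])
    resid2[idx] <- rowSums(sweep(xy[idx, , drop = FALSE], 2, ctr)^2)
  }
  pooled_sd <- sqrt(sum(resid2) / max(1, nrow(xy) - nlevels(groups)))
  scores <- tibble::as_tibble(pc$x, rownames = "subject_id")
  scores$group <- as.character(groups)
  structure(list(scores = scores[, c("subject_id", "group",
                                     setdiff(names(scores), c("subject_id", "group")))],
                 var_explained = var_explained,
                 separation = max(as.matrix(between)[lower.tri(as.matrix(between))]) /
                   max(pooled_sd, .Machine$double.eps)),
            class = "microref_pca")
}

#' @export
print.microref_pca <- function(x, ...) {
  cat("PCA of logFC profiles\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance; separation score %.2f\n",
              100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1, x$var_explained[2], 0),
              x$separation))
  invisible(x)
}
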