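assoc_row <- function(method, statistic, p_value, n_perm = NA_integer_, ...) {
  tibble::tibble(method = method, statistic = statistic, p_value = p_value,
                 n_perm = as.integer(n_perm), ...)
}

#' Single-factor PERMANOVA on a distance matrix
#'
#' Pseudo-F from the Gower-centered decomposition of the distance matrix
#' into between- and within-group sums of squares ([vegan::adonis2()]);
#' `R^2 = SS_between / SS_total`; the p-value is
#' `(1 + #{permuted F >= observed}) / (1 + n_perm)` with raw label
#' permutations.
#'
#' @param dm `dist` object (or square symmetric matrix).
#' @param labels Grouping factor aligned with the samples of `dm`;
#'   >= 2 groups, each with >= 2 samples.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return One-row tibble: method, statistic (R^2), f, p_value, n_perm,
#'   degenerate (TRUE when total sum of squares is 0; then R^2/F/p are NA).
#' @export
permanova <- function(dm, labels, n_perm = 999, seed = NULL) {
  dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels do not match the distance matrix samples")
  if (nlevels(droplevels(labels)) < 2) stop("PERMANOVA needs >= 2 groups")
  if (any(table(droplevels(labels)) < 2)) stop("every group needs >= 2 samples")
  if (sum(dm^2) == 0)
    return(assoc_row("permanova", NA_real_, NA_real_, n_perm,
                     f = NA_real_, degenerate = TRUE))
  run <- function() {
    df <- data.frame(g = labels)
    vegan::adonis2(dm ~ g, data = df, permutations = n_perm)
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  assoc_row("permanova", fit$R2[1], fit$`Pr(>F)`[1], n_perm,
            f = fit$F[1], degenerate = FALSE)
}

#' Mantel test between two distance matrices
#'
#' Spearman rank correlation between corresponding off-diagonal entries;
#' the p-value permutes the rows/columns of the second matrix jointly
#' ([vegan::mantel()] with `method = "spearman"`).
#'
#' @param dm1,dm2 `dist` objects over the same samples in the same order.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return One-row tibble: method, statistic (rho), p_value, n_perm.
#' @export
mantel_test <- function(dm1, dm2, n_perm = 999, seed = NULL) {
  dm1 <- stats::as.dist(dm1); dm2 <- stats::as.dist(dm2)
  if (attr(dm1, "Size") != attr(dm2, "Size"))
    stop("distance matrices have different sizes")
  l1 <- attr(dm1, "Labels"); l2 <- attr(dm2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices cover different samples (or a different order)")
  run <- function() vegan::mantel(dm1, dm2, method = "spearman",
                                  permutations = n_perm)
  fit <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  p <- fit$signif
  assoc_row("mantel", unname(fit$statistic), p, n_perm)
}

#' Spearman rank correlation
#'
#' Midrank-based rho with a two-sided p-value from the t approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return One-row tibble: method, statistic (rho), p_value.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  assoc_row("spearman", unname(ct$estimate), ct$p.value)
}

#' Chi-square or Fisher's exact test for a 2x2 contingency table
#'
#' Uses the standard rule: if any expected cell count is below 5, a
#' two-sided Fisher's exact test (sum of table probabilities no larger
#' than the observed one); otherwise Pearson's chi-square without
#' continuity correction (toggle with `correct`).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @param correct Apply Yates continuity correction on the chi-square
#'   branch (off by default).
#' @return One-row tibble: method ("fisher" or "chisq"), statistic (odds
#'   ratio estimate for Fisher, X^2 for chi-square), p_value.
#' @export
contingency_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("contingency_test expects a 2x2 table")
  if (anyNA(table) || any(table < 0) || any(table != round(table)))
    stop("cell counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(table)
    assoc_row("fisher", unname(ft$estimate), ft$p.value)
  } else {
    ct <- stats::chisq.test(table, correct = correct)
    assoc_row("chisq", unname(ct$statistic), ct$p.value)
  }
}

# exact two-sided rank-sum p by enumerating all C(n, nA) group assignments
# on the pooled midranks; feasible for pooled n <= 20
rank_sum_exact_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a); n <- length(r)
  obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  combs <- utils::combn(n, na)
  sums <- colSums(matrix(r[combs], nrow = na))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks throughout. For pooled sample sizes up to 20 the two-sided
#' p-value is computed by exhaustive enumeration of all group assignments
#' (valid under ties); larger samples use the normal approximation with
#' tie correction and no continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @return One-row tibble: method ("ranksum_exact" or "ranksum_normal"),
#'   statistic (rank-sum W of `a`), p_value.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input vector")
  r <- rank(c(a, b))
  w <- sum(r[seq_along(a)])
  if (length(a) + length(b) <= 20) {
    assoc_row("ranksum_exact", w, rank_sum_exact_p(a, b))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    assoc_row("ranksum_normal", w, wt$p.value)
  }
}
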