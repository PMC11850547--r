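#' Build a paired design from sample metadata
#'
#' Finds the subjects holding one sample in each of two habitats.
#'
#' @param metadata Tibble with `sample_id`, `subject_id`, `habitat` columns
#'   (and typically `group`).
#' @param habitats Length-2 character vector: habitat A, habitat B. Log
#'   fold changes downstream are A vs B (positive = more abundant in A).
#' @param group Optional filter on the metadata `group` column.
#' @return Tibble with columns subject_id, sample_a, sample_b; one row per
#'   complete pair.
#' @export
paired_design <- function(metadata, habitats, group = NULL) {
  if (length(habitats) != 2) stop("habitats must name exactly two habitats")
  md <- metadata
  if (!is.null(group)) md <- md[md$group %in% group, , drop = FALSE]
  md <- md[md$habitat %in% habitats, c("sample_id", "subject_id", "habitat")]
  if (anyDuplicated(md[, c("subject_id", "habitat")]))
    stop("a subject appears more than once in a habitat")
  wide <- tidyr::pivot_wider(md, names_from = "habitat", values_from = "sample_id")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  tibble::tibble(subject_id = wide$subject_id,
                 sample_a = wide[[habitats[1]]],
                 sample_b = wide[[habitats[2]]])
}

#' Estimate the global compositional bias of raw paired logFC estimates
#'
#' The per-taxon raw estimates are grand-centered by construction, so the
#' bulk (non-differential) taxa sit at minus the mean true fold change --
#' a shared offset that must be removed before the estimates are comparable
#' across taxa. This step locates that bulk: univariate Gaussian mixtures
#' with K = 1, 2, 3 components are fitted by expectation-maximization
#' (deterministic quantile-based initializations, up to 500 iterations,
#' log-likelihood tolerance 1e-8), K is chosen by BIC, and the mean of the
#' component holding the largest total membership is returned (ties break
#' to the component whose mean is closest to the overall median).
#'
#' @param raw_estimates Numeric vector of raw per-taxon estimates; with
#'   fewer than 10 values the median is returned instead and flagged.
#' @param max_k Largest number of mixture components tried.
#' @param max_iter,tol E-M iteration cap and log-likelihood tolerance.
#' @return The bias estimate (scalar) with attributes `k` (components
#'   selected) and `fallback` (TRUE when the median fallback was used).
#' @export
estimate_bias_em <- function(raw_estimates, max_k = 3, max_iter = 500, tol = 1e-8) {
  x <- raw_estimates[is.finite(raw_estimates)]
  if (length(x) < 10) {
    warning("fewer than 10 estimates: falling back to the median")
    return(structure(stats::median(x), k = NA_integer_, fallback = TRUE))
  }
  best <- NULL
  for (k in seq_len(max_k)) {
    for (fit in gmm_em_restarts(x, k, max_iter, tol)) {
      if (is.null(best) || fit$bic < best$bic) best <- fit
    }
  }
  # largest-membership component; ties to the mean closest to the median
  memb <- best$weight * length(x)
  top <- which(memb >= max(memb) - 1e-9)
  if (length(top) > 1) top <- top[which.min(abs(best$mean[top] - stats::median(x)))]
  structure(unname(best$mean[top]), k = length(best$mean), fallback = FALSE)
}

gmm_em_restarts <- function(x, k, max_iter, tol) {
  n <- length(x)
  inits <- list(stats::quantile(x, (seq_len(k) - 0.5) / k, names = FALSE),
                stats::quantile(x, seq_len(k) / (k + 1), names = FALSE))
  lapply(unique(inits), function(mu0) gmm_em(x, k, mu0, max_iter, tol))
}

gmm_em <- function(x, k, mu, max_iter, tol) {
  n <- length(x)
  sd_floor <- max(1e-8, 1e-3 * stats::sd(x))
  if (k == 1) {
    m <- mean(x); s <- max(stats::sd(x) * sqrt((n - 1) / n), sd_floor)
    ll <- sum(stats::dnorm(x, m, s, log = TRUE))
    return(list(mean = m, sd = s, weight = 1, loglik = ll,
                bic = -2 * ll + 2 * log(n)))
  }
  w <- rep(1 / k, k)
  s <- rep(max(stats::sd(x), sd_floor), k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], s[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    s <- pmax(s, sd_floor)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  npar <- 3 * k - 1
  list(mean = mu, sd = s, weight = w, loglik = ll,
       bic = -2 * ll + npar * log(length(x)))
}

#' Bias-corrected paired-habitat differential abundance
#'
#' Fits the paired two-habitat log-linear model with per-subject
#' sampling-fraction offsets. Observed counts carry an unknown per-sample
#' sampling fraction, so within-subject log-ratios confound the biological
#' fold change with the difference of log sampling fractions. The model:
#' (1) log-transforms counts with a pseudo-count, `y = log(O + pc)`;
#' (2) takes within-subject differences `d_it = y_iAt - y_iBt` over
#' complete pairs; (3) removes the per-subject nuisance offset
#' `delta_i = mean_t d_it` (the estimated difference of log sampling
#' fractions plus the mean true fold change); (4) averages the residuals
#' over subjects into raw per-taxon estimates; (5) removes the shared
#' compositional bias located by [estimate_bias_em()]; (6) attaches
#' normal-theory standard errors, two-sided p-values, Benjamini-Hochberg
#' q-values and 95% confidence intervals.
#'
#' @param table_a,table_b Feature tables for habitat A and habitat B with
#'   identical taxon sets.
#' @param design Pairing tibble from [paired_design()] (columns subject_id,
#'   sample_a, sample_b); >= 3 complete pairs.
#' @param pseudo_count Added before the log (default 1).
#' @param conf_level Confidence level of the intervals.
#' @param fdr_level Significance threshold on the q-value.
#' @return Object of class `microref_da`: list with `results` (tibble:
#'   taxon, logfc, se, ci_low, ci_high, p_value, q_value, significant),
#'   `offsets` (tibble: subject_id, delta), `bias`, `n_pairs`,
#'   `pseudo_count`, `conf_level`, `fdr_level`. Log fold changes are
#'   natural-log, habitat A relative to habitat B.
#' @export
fit_paired_da <- function(table_a, table_b, design,
                          pseudo_count = 1, conf_level = 0.95,
                          fdr_level = 0.05) {
  table_a <- as_feature_table(table_a)
  table_b <- as_feature_table(table_b)
  mism <- c(setdiff(rownames(table_a), rownames(table_b)),
            setdiff(rownames(table_b), rownames(table_a)))
  if (length(mism))
    stop("taxon sets differ between the tables: ",
         paste(utils::head(mism, 5), collapse = ", "))
  table_b <- table_b[rownames(table_a), , drop = FALSE]
  design <- design[design$sample_a %in% colnames(table_a) &
                   design$sample_b %in% colnames(table_b), , drop = FALSE]
  n <- nrow(design)
  if (n < 3) stop("need at least 3 complete pairs")

  ya <- log(table_a[, design$sample_a, drop = FALSE] + pseudo_count)
  yb <- log(table_b[, design$sample_b, drop = FALSE] + pseudo_count)
  d <- ya - yb                               # taxa x pairs
  delta <- colMeans(d)                       # per-subject nuisance offset
  e <- sweep(d, 2, delta)                    # residuals
  beta_raw <- rowMeans(e)
  bias <- estimate_bias_em(beta_raw)
  beta <- beta_raw - as.numeric(bias)
  se <- apply(e, 1, stats::sd) / sqrt(n)
  z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  q <- bh_adjust(p)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  results <- tibble::tibble(
    taxon = rownames(d),
    logfc = beta, se = se,
    ci_low = beta - zc * se, ci_high = beta + zc * se,
    p_value = p, q_value = q,
    significant = q < fdr_level)
  structure(list(results = results,
                 offsets = tibble::tibble(subject_id = design$subject_id,
                                          delta = unname(delta)),
                 bias = as.numeric(bias),
                 bias_components = attr(bias, "k"),
                 n_pairs = n, pseudo_count = pseudo_count,
                 conf_level = conf_level, fdr_level = fdr_level),
            class = "microref_da")
}

#' @export
print.microref_da <- function(x, ...) {
  cat("Paired-habitat differential abundance fit\n")
  cat(sprintf("  %d taxa, %d complete pairs; bias = %.4f (%s mixture component(s))\n",
              nrow(x$results), x$n_pairs, x$bias,
              ifelse(is.na(x$bias_components), "fallback", x$bias_components)))
  cat(sprintf("  %d taxa significant at FDR < %.2f\n",
              sum(x$results$significant), x$fdr_level))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to the
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Bias-corrected within-subject logFC profile for one subject
#'
#' Computes the subject's within-pair log-ratios and anchors them to a
#' reference-cohort fit: the subject's nuisance offset is the median of
#' `d_t - logfc_t^ref` over taxa (a robust choice, so that a handful of
#' disease-shifted taxa cannot drag the offset), and the profile is
#' `f_t = d_t - offset`.
#'
#' @param counts_a,counts_b Count vectors for the subject's habitat-A and
#'   habitat-B samples, aligned to the reference taxa (named, or in the
#'   reference row order).
#' @param reference_da A `microref_da` fit of the reference cohort.
#' @param pseudo_count Added before the log; use the reference fit's value.
#' @return Tibble: taxon, d (raw log-ratio), f (bias-corrected logFC), with
#'   the subject offset in attribute `"offset"`.
#' @export
per_subject_logfc <- function(counts_a, counts_b, reference_da,
                              pseudo_count = reference_da$pseudo_count) {
  stopifnot(inherits(reference_da, "microref_da"))
  taxa <- reference_da$results$taxon
  if (!is.null(names(counts_a))) counts_a <- counts_a[taxa]
  if (!is.null(names(counts_b))) counts_b <- counts_b[taxa]
  if (length(counts_a) != length(taxa) || length(counts_b) != length(taxa))
    stop("count vectors are not aligned to the reference taxa")
  if (anyNA(counts_a) || anyNA(counts_b))
    stop("count vectors are not aligned to the reference taxa")
  if (sum(counts_a) == 0 || sum(counts_b) == 0)
    stop("all-zero count vector: per-subject logFC undefined")
  d <- log(counts_a + pseudo_count) - log(counts_b + pseudo_count)
  offset <- stats::median(d - reference_da$results$logfc)
  tibble::tibble(taxon = taxa, d = unname(d), f = unname(d - offset)) |>
    structure(offset = offset)
}

#' Within-subject logFC profiles for a whole cohort
#'
#' Applies [per_subject_logfc()] to every complete pair of a design.
#'
#' @param table_a,table_b Feature tables of the cohort to profile.
#' @param design Pairing tibble (subject_id, sample_a, sample_b).
#' @param reference_da Reference-cohort `microref_da` fit.
#' @return Long tibble: subject_id, taxon, f.
#' @export
subject_logfc_profiles <- function(table_a, table_b, design, reference_da) {
  table_a <- as_feature_table(table_a)
  table_b <- as_feature_table(table_b)
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    fc <- per_subject_logfc(table_a[, design$sample_a[i]],
                            table_b[, design$sample_b[i]], reference_da)
    tibble::tibble(subject_id = design$subject_id[i], taxon = fc$taxon, f = fc$f)
  })
}
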