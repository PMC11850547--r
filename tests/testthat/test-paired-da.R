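test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  withr::with_seed(31, {
    for (rep in 1:200) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p))
      expect_true(all(q >= p - 1e-12))
      # monotone: larger p never gets smaller q
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-12))
    }
  })
})

test_that("E-M bias estimator finds the dominant mixture component", {
  withr::with_seed(41, {
    # single tight cluster
    b1 <- estimate_bias_em(rnorm(100, -1, 0.01))
    expect_equal(as.numeric(b1), -1, tolerance = 0.01)
    # 90/10 mixture, 50 seeds: always near the dominant mean
    errs <- vapply(1:50, function(i) {
      x <- c(rnorm(180, -0.5, 0.1), rnorm(20, 1.5, 0.1))
      as.numeric(estimate_bias_em(x)) - (-0.5)
    }, numeric(1))
    expect_true(all(abs(errs) < 0.05))
  })
})

test_that("E-M tie-break and small-sample fallback behave as documented", {
  withr::with_seed(42, {
    x <- c(rnorm(100, -1, 0.05), rnorm(100, 1, 0.05))
    b <- estimate_bias_em(x)
    expect_true(min(abs(as.numeric(b) - c(-1, 1))) < 0.05)
    expect_identical(as.numeric(estimate_bias_em(x)),
                     as.numeric(estimate_bias_em(x)))  # deterministic
  })
  expect_warning(bsmall <- estimate_bias_em(c(1, 2, 3)), "median")
  expect_equal(as.numeric(bsmall), 2)
  expect_true(attr(bsmall, "fallback"))
})

test_that("E-M component means agree with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::with_seed(43, {
    x <- c(rnorm(150, 0, 0.2), rnorm(50, 2, 0.2))
    b <- as.numeric(estimate_bias_em(x))
    mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    dominant <- mc$parameters$mean[which.max(table(mc$classification))]
    expect_equal(b, unname(dominant), tolerance = 0.05)
  })
})

test_that("paired DA fit recovers planted fold changes and is order-invariant", {
  co <- make_small_cohort(seed = 51, n_ref = 40, n_taxa = 80)
  des <- paired_design(co$metadata, c("stool", "saliva"))
  fit <- fit_paired_da(co$tables$stool, co$tables$saliva, des)
  r <- tidy(fit)
  g <- co$truth$gamma[r$taxon]
  mc <- (rowMeans(co$tables$stool) + rowMeans(co$tables$saliva))[r$taxon] / 2
  sel <- g != 0 & mc >= 10
  expect_gt(cor(r$logfc[sel], g[sel]), 0.95)
  expect_true(all(r$ci_low <= r$logfc & r$logfc <= r$ci_high))
  expect_equal(r$ci_high - r$logfc, 1.959964 * r$se, tolerance = 1e-5)
  expect_equal(r$q_value, bh_adjust(r$p_value))

  # invariance to taxon and subject ordering
  perm_t <- sample(nrow(co$tables$stool))
  perm_s <- sample(nrow(des))
  fit2 <- fit_paired_da(co$tables$stool[perm_t, ], co$tables$saliva, des[perm_s, ])
  r2 <- tidy(fit2)
  expect_equal(r2[match(r$taxon, r2$taxon), ], r, ignore_attr = TRUE)
})

test_that("raw estimates are grand-centered and errors are informative", {
  co <- make_small_cohort(seed = 52, n_ref = 20, n_taxa = 40)
  des <- paired_design(co$metadata, c("stool", "saliva"))
  fit <- fit_paired_da(co$tables$stool, co$tables$saliva, des)
  # beta_raw = beta + bias sums to ~0 by construction of the centering
  expect_equal(sum(tidy(fit)$logfc + fit$bias), 0, tolerance = 1e-8)
  expect_error(fit_paired_da(co$tables$stool, co$tables$saliva, des[1:2, ]),
               "3 complete pairs")
  tb <- co$tables$saliva
  rownames(tb)[1] <- "other_taxon"
  expect_error(fit_paired_da(co$tables$stool, tb, des), "taxon sets differ")
})

test_that("CI half-widths shrink as 1/sqrt(n_pairs)", {
  widths <- vapply(c(20, 80, 320), function(n) {
    co <- make_small_cohort(seed = 53, n_ref = n, n_taxa = 40,
                            diff_fraction = 0)
    des <- paired_design(co$metadata, c("stool", "saliva"))
    fit <- fit_paired_da(co$tables$stool, co$tables$saliva, des)
    median(tidy(fit)$se) * 1.96
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.25)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.25)
})

test_that("per-subject logFC is near zero under the null and depth-invariant", {
  co <- make_small_cohort(seed = 54, n_ref = 45, n_taxa = 60,
                          diff_fraction = 0)
  des <- paired_design(co$metadata, c("stool", "saliva"))
  fit <- fit_paired_da(co$tables$stool[, des$sample_a[1:40]],
                       co$tables$saliva[, des$sample_b[1:40]], des[1:40, ])
  held <- des[41:45, ]
  for (i in seq_len(nrow(held))) {
    fc <- per_subject_logfc(co$tables$stool[, held$sample_a[i]],
                            co$tables$saliva[, held$sample_b[i]], fit)
    expect_lt(median(abs(fc$f)), 3 * 0.5)   # within noise of zero
  }
  # re-drawing both habitats at 5x depth leaves the profile invariant up to
  # counting noise: no systematic shift (the anchored offset absorbs the
  # depth change) and typical per-taxon changes stay small
  st5 <- redraw_counts(co, "stool", depth_factor = 5, seed = 7)
  sa5 <- redraw_counts(co, "saliva", depth_factor = 5, seed = 8)
  f1 <- per_subject_logfc(co$tables$stool[, held$sample_a[1]],
                          co$tables$saliva[, held$sample_b[1]], fit)
  f2 <- per_subject_logfc(st5[, held$sample_a[1]],
                          sa5[, held$sample_b[1]], fit)
  abund <- co$tables$stool[, held$sample_a[1]] >= 10 &
           co$tables$saliva[, held$sample_b[1]] >= 10
  delta <- (f2$f - f1$f)[abund]
  expect_lt(abs(median(delta)), 0.1)      # log(5) = 1.61 fully absorbed
  expect_lt(median(abs(delta)), 0.2)
  expect_error(per_subject_logfc(rep(0, 60), co$tables$saliva[, 1], fit),
               "all-zero")
})

test_that("cohort profiling returns one profile per designed pair", {
  co <- make_small_cohort(seed = 55, n_ref = 12, n_taxa = 20)
  des <- paired_design(co$metadata, c("stool", "saliva"))
  fit <- fit_paired_da(co$tables$stool, co$tables$saliva, des)
  prof <- subject_logfc_profiles(co$tables$stool, co$tables$saliva, des, fit)
  expect_equal(nrow(prof), nrow(des) * 20)
  expect_setequal(unique(prof$subject_id), des$subject_id)
  expect_true(all(is.finite(prof$f)))
})
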