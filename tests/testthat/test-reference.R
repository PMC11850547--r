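test_that("reference interval matches a sort-and-interpolate oracle", {
  x <- as.numeric(1:1000)
  ri <- alpha_reference_interval(x)
  expect_equal(ri$lower, 25.975)
  expect_equal(ri$upper, 975.025)
  expect_equal(ri$n_used, 1000)
  expect_equal(ri$n_outliers_excluded, 0)
  withr::with_seed(61, {
    for (rep in 1:50) {
      v <- rnorm(sample(30:300, 1))
      ri <- alpha_reference_interval(v, outlier_rule = "none")
      expect_equal(ri$lower, oracle_percentile(v, 0.025))
      expect_equal(ri$upper, oracle_percentile(v, 0.975))
    }
  })
})

test_that("reference interval handles constants, outliers and small n", {
  cst <- alpha_reference_interval(rep(3.2, 25))
  expect_equal(c(cst$lower, cst$upper), c(3.2, 3.2))
  withr::with_seed(62, {
    clean <- rnorm(500)
    spiked <- c(clean, 100)
    ri_clean <- alpha_reference_interval(clean)
    ri_spiked <- alpha_reference_interval(spiked)
    expect_gte(ri_spiked$n_outliers_excluded, 1)
    expect_lt(abs(ri_spiked$upper - ri_clean$upper), 0.15)
    expect_lt(abs(ri_spiked$lower - ri_clean$lower), 0.15)
  })
  expect_warning(ri <- alpha_reference_interval(rnorm(10)), "fewer than 20")
  expect_true(ri$low_n)
  expect_error(alpha_reference_interval(c(1, 2, 3)), "at least 4")
})

test_that("reference interval covers the central ~95% after exclusion", {
  withr::with_seed(63, {
    for (rep in 1:5) {
      v <- rnorm(400)
      ri <- alpha_reference_interval(v)
      q <- quantile(v, c(0.25, 0.75)); iqr <- q[2] - q[1]
      kept <- v[v >= q[1] - 1.5 * iqr & v <= q[2] + 1.5 * iqr]
      frac <- mean(kept >= ri$lower & kept <= ri$upper)
      expect_gte(frac, 0.93)
      expect_lte(frac, 0.97)
    }
  })
})

test_that("taxon reference ranges are the fit's confidence bounds, verbatim", {
  co <- make_small_cohort(seed = 64, n_ref = 25, n_taxa = 30)
  des <- paired_design(co$metadata, c("stool", "saliva"))
  fit <- fit_paired_da(co$tables$stool, co$tables$saliva, des)
  rng <- taxon_reference_ranges(fit)
  r <- tidy(fit)
  expect_equal(rng$range_low, r$ci_low)
  expect_equal(rng$range_high, r$ci_high)
  expect_equal(nrow(rng), nrow(r))
  expect_false(any(rng$degenerate))
  # degenerate (zero-width) ranges are flagged
  fit0 <- fit
  fit0$results$se[1] <- 0
  fit0$results$ci_low[1] <- fit0$results$ci_high[1] <- fit0$results$logfc[1]
  expect_true(taxon_reference_ranges(fit0)$degenerate[1])
  # prediction mode widens every range
  pr <- taxon_reference_ranges(fit, mode = "prediction")
  expect_true(all(pr$range_low <= rng$range_low))
  expect_true(all(pr$range_high >= rng$range_high))
})

test_that("screening flags in-range values on closed intervals", {
  ranges <- tibble::tibble(taxon = c("t1", "t2"),
                           range_low = c(-0.35, 0), range_high = c(0.49, 1),
                           degenerate = FALSE)
  fcs <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 2),
    taxon = rep(c("t1", "t2"), 2),
    f = c(0.49, 2, -0.35, -1))   # boundaries count as within
  rep_ <- screen_cohort(fcs, ranges)
  tt <- tidy(rep_)
  expect_equal(tt$prop_within[tt$taxon == "t1"], 1)
  expect_equal(tt$prop_within[tt$taxon == "t2"], 0)
  expect_equal(select_profile_taxa(rep_), "t2")
  # all inside -> nothing selected
  all_in <- fcs; all_in$f <- c(0, 0.5, 0, 0.5)
  expect_length(select_profile_taxa(screen_cohort(all_in, ranges)), 0)
  expect_error(screen_cohort(dplyr::mutate(fcs, taxon = "zz"), ranges),
               "no taxa shared")
})

test_that("profile selection is monotone in the threshold", {
  withr::with_seed(65, {
    ranges <- tibble::tibble(taxon = paste0("t", 1:20),
                             range_low = -0.3, range_high = 0.3,
                             degenerate = FALSE)
    fcs <- tidyr::expand_grid(subject_id = paste0("s", 1:10),
                              taxon = paste0("t", 1:20))
    fcs$f <- rnorm(nrow(fcs), 0, 0.6)
    rep_ <- screen_cohort(fcs, ranges)
    s0 <- select_profile_taxa(rep_, threshold = 0)
    s01 <- select_profile_taxa(rep_, threshold = 0.1)
    expect_true(all(s0 %in% s01))
    props <- tidy(rep_)$prop_within
    expect_true(all(props >= 0 & props <= 1))
    expect_true(all(abs(props * 10 - round(props * 10)) < 1e-9))
  })
})

test_that("planted disease effects are recovered by screening", {
  hits <- 0; false_sel <- numeric(0)
  for (s in 1:5) {
    cfg <- synthetic_config(n_reference = 80, n_pd = 10, n_taxa = 150,
                            habitats = c("stool", "saliva"),
                            habitat_totals = NULL, pair_counts = NULL,
                            pd_effect_magnitude = 3, n_disease_taxa = 5,
                            seed = 600 + s)
    co <- generate_cohort(cfg)
    des_ref <- paired_design(co$metadata, c("stool", "saliva"), group = "reference")
    des_pd <- paired_design(co$metadata, c("stool", "saliva"), group = "PD")
    fit <- fit_paired_da(co$tables$stool[, des_ref$sample_a],
                         co$tables$saliva[, des_ref$sample_b], des_ref)
    prof <- subject_logfc_profiles(co$tables$stool, co$tables$saliva, des_pd, fit)
    sel <- select_profile_taxa(screen_cohort(prof, taxon_reference_ranges(fit)))
    hits <- hits + all(co$truth$disease_taxa %in% sel)
    false_sel <- c(false_sel, length(setdiff(sel, co$truth$disease_taxa)))
  }
  expect_gte(hits, 4)   # planted set recovered in nearly every replicate
})

test_that("prediction-interval ranges keep healthy subjects in range", {
  # the confidence interval of the mean logFC shrinks with cohort size while
  # an individual's spread does not; the prediction-interval mode targets the
  # individual and therefore passes healthy subjects
  cfg <- synthetic_config(n_reference = 90, n_pd = 0, n_taxa = 100,
                          habitats = c("stool", "saliva"),
                          habitat_totals = NULL, pair_counts = NULL,
                          pd_effect_magnitude = 0, seed = 66)
  co <- generate_cohort(cfg)
  des <- paired_design(co$metadata, c("stool", "saliva"))
  fit <- fit_paired_da(co$tables$stool[, des$sample_a[1:80]],
                       co$tables$saliva[, des$sample_b[1:80]], des[1:80, ])
  prof <- subject_logfc_profiles(co$tables$stool, co$tables$saliva,
                                 des[81:90, ], fit)
  scr <- screen_cohort(prof, taxon_reference_ranges(fit, mode = "prediction"))
  expect_lte(sum(tidy(scr)$selected), 1)
  expect_gt(mean(scr$flags$within), 0.85)
})

test_that("PCA separation scores planted group structure", {
  withr::with_seed(67, {
    m <- rbind(matrix(rnorm(20 * 8, 0, 1), 20), matrix(rnorm(10 * 8, 5, 1), 10))
    rownames(m) <- paste0("s", 1:30)
    colnames(m) <- paste0("t", 1:8)
    g <- rep(c("reference", "PD"), c(20, 10))
    pc <- pca_separation(m, g)
    expect_gt(pc$separation, 2)
    ve <- pc$var_explained
    expect_true(all(ve >= 0))
    expect_true(all(diff(ve) <= 1e-12))
    expect_equal(sum(ve), 1)
    # rotation invariance of variance shares
    q <- qr.Q(qr(matrix(rnorm(64), 8)))
    pc2 <- pca_separation(m %*% q, g)
    expect_equal(pc2$var_explained, ve, tolerance = 1e-8)
    # degenerate input
    expect_error(pca_separation(matrix(1, 5, 3,
                                       dimnames = list(paste0("s", 1:5), paste0("t", 1:3))),
                                rep(c("a", "b"), c(2, 3))), "rank-0")
  })
})
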