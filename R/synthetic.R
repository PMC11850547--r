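#' Configuration for the synthetic paired-habitat cohort generator
#'
#' The defaults reproduce the design of the motivating study: a reference
#' group of 171 healthy subjects and a disease (PD) group of 10 subjects,
#' sampled in blood, saliva and stool with partial pairing (117/124/98
#' samples per habitat; 77 blood-saliva, 65 saliva-stool and 72 blood-stool
#' complete pairs), 150 taxa of which 10% carry a true between-habitat
#' fold change of magnitude 2 on the natural-log scale with alternating
#' signs, log-normal sequencing depths, and a disease effect of magnitude 3
#' planted on 5 taxa in saliva.
#'
#' @param n_reference,n_pd Subject counts for the reference and disease groups.
#' @param n_taxa Number of taxa.
#' @param habitats Habitat labels; the first two are the differential pair
#'   unless `diff_pair` says otherwise.
#' @param pairing_fraction Used when `habitat_totals`/`pair_counts` are NULL:
#'   target fraction of subjects, per habitat pair, holding both samples.
#'   Each subject receives each habitat independently with probability
#'   `sqrt(pairing_fraction)`, so pairs occur at rate `pairing_fraction`.
#' @param habitat_totals,pair_counts Optional exact design: named per-habitat
#'   sample totals and named per-pair complete-pair counts (names like
#'   `"blood:saliva"`). Solved by inclusion-exclusion; an infeasible design
#'   errors. Both or neither must be given.
#' @param baseline_log_mean,baseline_log_sd Per-taxon baseline log-abundance
#'   alpha_t ~ Normal(mean, sd).
#' @param diff_fraction Fraction of taxa with a nonzero habitat fold change.
#' @param diff_magnitude |gamma_t| for differential taxa (natural log).
#' @param sign_mode `"alternate"` (default) alternates the sign of gamma_t
#'   across differential taxa; `"positive"` makes all positive.
#' @param subject_sd SD of the subject random effect u_i.
#' @param noise_sd SD of the residual epsilon.
#' @param depth_log_mean,depth_log_sd Log-normal sequencing-depth parameters;
#'   realized depths are rounded and floored at 100 reads.
#' @param pd_effect_magnitude |theta_t| added to disease taxa for PD subjects
#'   in `pd_habitat`.
#' @param n_disease_taxa Size of the planted disease taxon set.
#' @param diff_pair Habitat pair carrying gamma: the first habitat gains
#'   +gamma/2, the second -gamma/2.
#' @param pd_habitat Habitat where the disease effect localizes (saliva by
#'   default: the disease modeled is periodontal, i.e. oral).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reference = 171,
                             n_pd = 10,
                             n_taxa = 150,
                             habitats = c("blood", "saliva", "stool"),
                             pairing_fraction = 1,
                             habitat_totals = c(blood = 117, saliva = 124, stool = 98),
                             pair_counts = c("blood:saliva" = 77,
                                             "saliva:stool" = 65,
                                             "blood:stool" = 72),
                             baseline_log_mean = 0,
                             baseline_log_sd = 1.5,
                             diff_fraction = 0.1,
                             diff_magnitude = 2,
                             sign_mode = c("alternate", "positive"),
                             subject_sd = 0.5,
                             noise_sd = 0.5,
                             depth_log_mean = log(30000),
                             depth_log_sd = 0.5,
                             pd_effect_magnitude = 3,
                             n_disease_taxa = 5,
                             diff_pair = habitats[1:2],
                             pd_habitat = if ("saliva" %in% habitats) "saliva" else habitats[length(habitats)],
                             seed = 1L) {
  sign_mode <- match.arg(sign_mode)
  cfg <- list(n_reference = n_reference, n_pd = n_pd, n_taxa = n_taxa,
              habitats = habitats, pairing_fraction = pairing_fraction,
              habitat_totals = habitat_totals, pair_counts = pair_counts,
              baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
              diff_fraction = diff_fraction, diff_magnitude = diff_magnitude,
              sign_mode = sign_mode, subject_sd = subject_sd, noise_sd = noise_sd,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              pd_effect_magnitude = pd_effect_magnitude,
              n_disease_taxa = n_disease_taxa, diff_pair = diff_pair,
              pd_habitat = pd_habitat, seed = as.integer(seed))
  for (f in c("n_reference", "n_taxa"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) stop("configuration error: ", f, " must be positive")
  if (cfg$n_pd < 0) stop("configuration error: n_pd must be >= 0")
  if (length(habitats) < 2 || anyDuplicated(habitats)) stop("configuration error: need >= 2 distinct habitats")
  if (pairing_fraction < 0 || pairing_fraction > 1) stop("configuration error: pairing_fraction must be in [0,1]")
  if (diff_fraction < 0 || diff_fraction > 1) stop("configuration error: diff_fraction must be in [0,1]")
  for (f in c("baseline_log_sd", "subject_sd", "noise_sd", "depth_log_sd"))
    if (cfg[[f]] < 0) stop("configuration error: ", f, " must be >= 0")
  if (xor(is.null(habitat_totals), is.null(pair_counts)))
    stop("configuration error: habitat_totals and pair_counts must be given together")
  if (!all(diff_pair %in% habitats)) stop("configuration error: diff_pair not among habitats")
  if (!pd_habitat %in% habitats) stop("configuration error: pd_habitat not among habitats")
  if (n_disease_taxa > n_taxa) stop("configuration error: n_disease_taxa > n_taxa")
  structure(cfg, class = "synthetic_config")
}

# Solve subject-to-habitat membership from exact per-habitat totals and
# per-pair counts (2 or 3 habitats) by inclusion-exclusion.
solve_membership <- function(n, habitats, totals, pairs) {
  if (is.list(pairs)) pairs <- unlist(pairs)
  if (is.list(totals)) totals <- unlist(totals)
  if (!all(habitats %in% names(totals)))
    stop("habitat_totals must name every habitat")
  key <- function(a, b) {
    k1 <- paste(a, b, sep = ":"); k2 <- paste(b, a, sep = ":")
    if (k1 %in% names(pairs)) return(pairs[[k1]])
    if (k2 %in% names(pairs)) return(pairs[[k2]])
    stop("pair_counts missing entry for ", k1)
  }
  membership <- matrix(FALSE, n, length(habitats), dimnames = list(NULL, habitats))
  if (length(habitats) == 2) {
    p <- key(habitats[1], habitats[2])
    only1 <- totals[[habitats[1]]] - p
    only2 <- totals[[habitats[2]]] - p
    if (only1 < 0 || only2 < 0 || p + only1 + only2 != n)
      stop("infeasible pairing design")
    idx <- c(rep(1, p), rep(2, only1), rep(3, only2))
    membership[idx <= 2, habitats[1]] <- TRUE
    membership[idx %in% c(1, 3), habitats[2]] <- TRUE
    return(membership)
  }
  if (length(habitats) != 3)
    stop("exact pairing designs support 2 or 3 habitats")
  h <- habitats
  p12 <- key(h[1], h[2]); p13 <- key(h[1], h[3]); p23 <- key(h[2], h[3])
  triple <- n - sum(unlist(totals[h])) + p12 + p13 + p23
  d12 <- p12 - triple; d13 <- p13 - triple; d23 <- p23 - triple
  s1 <- totals[[h[1]]] - triple - d12 - d13
  s2 <- totals[[h[2]]] - triple - d12 - d23
  s3 <- totals[[h[3]]] - triple - d13 - d23
  cells <- c(triple, d12, d13, d23, s1, s2, s3)
  if (any(cells < 0) || sum(cells) != n)
    stop("infeasible pairing design (totals/pair_counts/n inconsistent)")
  sets <- list(h, h[1:2], h[c(1, 3)], h[2:3], h[1], h[2], h[3])
  lab <- rep(seq_along(sets), cells)
  for (i in seq_len(n)) membership[i, sets[[lab[i]]]] <- TRUE
  membership
}

#' Generate a synthetic paired-habitat cohort with known ground truth
#'
#' For subject i, habitat h and taxon t the latent log-abundance is
#' `log A = alpha_t + u_i + s_h(t) + theta_t * pd + eps` where `s_h(t)` is
#' `+gamma_t/2` in the first habitat of `diff_pair`, `-gamma_t/2` in the
#' second and 0 elsewhere, and `theta_t` applies to disease taxa of PD
#' subjects in `pd_habitat`. Sequencing depth is drawn log-normally
#' (rounded, floored at 100 reads) and counts are multinomial given the
#' relative latent abundances, so observed counts are compositional: they
#' carry the per-sample sampling fraction, not absolute abundance.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `microref_cohort`: `tables` (one taxa-x-samples
#'   count matrix per habitat), `metadata` (tibble: sample_id, subject_id,
#'   habitat, group, covariates), `truth` (gamma, disease_taxa,
#'   subject_effects, depths, baseline, diff_pair, pd_habitat), `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  taxa <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
  subj_ref <- sprintf("R%03d", seq_len(cfg$n_reference))
  subj_pd <- if (cfg$n_pd > 0) sprintf("P%03d", seq_len(cfg$n_pd)) else character()
  subjects <- c(subj_ref, subj_pd)
  group <- c(rep("reference", cfg$n_reference), rep("PD", cfg$n_pd))

  # habitat membership for the reference group; PD subjects are fully sampled
  if (!is.null(cfg$habitat_totals)) {
    memb_ref <- solve_membership(cfg$n_reference, cfg$habitats,
                                 cfg$habitat_totals, cfg$pair_counts)
    memb_ref <- memb_ref[sample.int(cfg$n_reference), , drop = FALSE]
  } else if (cfg$pairing_fraction >= 1) {
    memb_ref <- matrix(TRUE, cfg$n_reference, length(cfg$habitats),
                       dimnames = list(NULL, cfg$habitats))
  } else {
    q <- sqrt(cfg$pairing_fraction)
    memb_ref <- matrix(stats::runif(cfg$n_reference * length(cfg$habitats)) < q,
                       cfg$n_reference, length(cfg$habitats),
                       dimnames = list(NULL, cfg$habitats))
  }
  membership <- rbind(memb_ref,
                      matrix(TRUE, cfg$n_pd, length(cfg$habitats),
                             dimnames = list(NULL, cfg$habitats)))
  rownames(membership) <- subjects
  for (a in seq_along(cfg$habitats)) for (b in seq_len(a - 1)) {
    n_pairs <- sum(membership[seq_len(cfg$n_reference), a] &
                   membership[seq_len(cfg$n_reference), b])
    if (n_pairs < 3)
      stop("pairing design yields fewer than 3 complete reference pairs for ",
           cfg$habitats[b], ":", cfg$habitats[a],
           "; downstream inference is impossible")
  }

  # latent parameters
  alpha <- stats::rnorm(cfg$n_taxa, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(alpha) <- taxa
  gamma <- stats::setNames(numeric(cfg$n_taxa), taxa)
  n_diff <- round(cfg$diff_fraction * cfg$n_taxa)
  if (n_diff > 0) {
    diff_taxa <- sample(taxa, n_diff)
    sgn <- if (cfg$sign_mode == "alternate")
      rep_len(c(1, -1), n_diff) else rep(1, n_diff)
    gamma[diff_taxa] <- sgn * cfg$diff_magnitude
  }
  disease_taxa <- if (cfg$n_disease_taxa > 0) sample(taxa, cfg$n_disease_taxa) else character()
  theta <- stats::setNames(numeric(cfg$n_taxa), taxa)
  theta[disease_taxa] <- cfg$pd_effect_magnitude
  u <- stats::setNames(stats::rnorm(length(subjects), 0, cfg$subject_sd), subjects)
  shift <- stats::setNames(numeric(cfg$n_taxa), taxa)

  covars <- generate_covariates(length(subjects))
  meta <- list(); counts <- list(); depths <- numeric(); relab <- list()
  for (h in cfg$habitats) {
    hab_shift <- if (h == cfg$diff_pair[1]) gamma / 2
                 else if (h == cfg$diff_pair[2]) -gamma / 2
                 else shift
    keep <- which(membership[, h])
    if (!length(keep)) next
    m <- matrix(0L, cfg$n_taxa, length(keep),
                dimnames = list(taxa, paste(subjects[keep], h, sep = "_")))
    for (j in seq_along(keep)) {
      i <- keep[j]
      loga <- alpha + u[i] + hab_shift +
        (if (group[i] == "PD" && h == cfg$pd_habitat) theta else shift) +
        stats::rnorm(cfg$n_taxa, 0, cfg$noise_sd)
      depth <- max(100, round(stats::rlnorm(1, cfg$depth_log_mean, cfg$depth_log_sd)))
      prob <- exp(loga - max(loga))
      prob <- prob / sum(prob)
      m[, j] <- stats::rmultinom(1, depth, prob)[, 1]
      depths[colnames(m)[j]] <- depth
      relab[[colnames(m)[j]]] <- prob
    }
    counts[[h]] <- m
    meta[[h]] <- tibble::tibble(sample_id = colnames(m),
                                subject_id = subjects[keep],
                                habitat = h,
                                group = group[keep])
  }
  metadata <- dplyr::bind_rows(meta)
  covars$subject_id <- subjects
  metadata <- dplyr::left_join(metadata, covars, by = "subject_id")

  structure(list(
    tables = counts,
    metadata = metadata,
    truth = list(gamma = gamma, disease_taxa = disease_taxa,
                 subject_effects = u, depths = depths, baseline = alpha,
                 theta = theta, diff_pair = cfg$diff_pair,
                 pd_habitat = cfg$pd_habitat,
                 rel_abundance = do.call(cbind, relab)),
    config = cfg), class = "microref_cohort")
}

#' Re-draw the counts of one habitat at a rescaled depth
#'
#' Draws fresh multinomial counts for every sample of a habitat from the
#' cohort's stored latent relative abundances, with depths multiplied by
#' `depth_factor`. The latent composition is untouched, so any downstream
#' shift in fitted fold changes isolates the effect of sequencing depth --
#' the compositional invariance a bias-corrected model should exhibit.
#'
#' @param cohort A `microref_cohort`.
#' @param habitat Habitat whose samples are re-drawn.
#' @param depth_factor Multiplier on each sample's realized depth.
#' @param seed Optional integer seed.
#' @return A feature table (taxa x samples) for the habitat.
#' @export
redraw_counts <- function(cohort, habitat, depth_factor = 1, seed = NULL) {
  stopifnot(inherits(cohort, "microref_cohort"))
  if (!habitat %in% names(cohort$tables)) stop("unknown habitat: ", habitat)
  old <- cohort$tables[[habitat]]
  run <- function() {
    m <- old
    for (s in colnames(old)) {
      depth <- max(100, round(cohort$truth$depths[[s]] * depth_factor))
      m[, s] <- stats::rmultinom(1, depth, cohort$truth$rel_abundance[, s])[, 1]
    }
    m
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Generate a random rooted bifurcating tree over a taxon set
#'
#' Required for unweighted UniFrac when no real phylogeny is available.
#' Branch lengths are positive; the newick serialization round-trips
#' losslessly through [ape::write.tree()] / [ape::read.tree()].
#'
#' @param taxon_ids Tip labels (>= 2, unique).
#' @param seed Optional integer seed.
#' @return An [ape::rtree()] `phylo` object, rooted, with `length(taxon_ids)`
#'   tips.
#' @export
generate_tree <- function(taxon_ids, seed = NULL) {
  if (length(taxon_ids) < 2) stop("need at least 2 taxa for a tree")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon IDs")
  gen <- function() {
    tr <- ape::rtree(length(taxon_ids), rooted = TRUE)
    tr$tip.label <- taxon_ids[as.integer(sub("^t", "", tr$tip.label))]
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    tr
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

# truncated-normal sampling by rejection: simple and exact
rtruncnorm_rej <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate subject covariates matching the study's cohort table
#'
#' Age ~ Normal(45.0, 14.9) truncated to [18, 89]; male probability 0.48;
#' BMI ~ Normal(25.0, 5.1) truncated to [14, 50]; alcohol-consumption
#' probability 0.453; smoking probability 0.10. All parameters overridable.
#'
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @param age_mean,age_sd,age_range,male_prob,bmi_mean,bmi_sd,bmi_range,alcohol_prob,smoking_prob
#'   Distribution parameters.
#' @return Tibble with columns age, sex ("M"/"F"), bmi, alcohol, smoking.
#' @export
generate_covariates <- function(n, seed = NULL,
                                age_mean = 45.0, age_sd = 14.9, age_range = c(18, 89),
                                male_prob = 0.48,
                                bmi_mean = 25.0, bmi_sd = 5.1, bmi_range = c(14, 50),
                                alcohol_prob = 0.453, smoking_prob = 0.10) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive count")
  gen <- function() tibble::tibble(
    age = rtruncnorm_rej(n, age_mean, age_sd, age_range[1], age_range[2]),
    sex = ifelse(stats::runif(n) < male_prob, "M", "F"),
    bmi = rtruncnorm_rej(n, bmi_mean, bmi_sd, bmi_range[1], bmi_range[2]),
    alcohol = stats::runif(n) < alcohol_prob,
    smoking = stats::runif(n) < smoking_prob)
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Write a synthetic cohort to disk
#'
#' Feature tables as TSV (one per habitat), metadata as TSV, ground truth as
#' JSON.
#'
#' @param cohort A `microref_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "microref_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (h in names(cohort$tables))
    write_feature_table(cohort$tables[[h]], file.path(dir, paste0("counts_", h, ".tsv")))
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
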