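# Independent brute-force oracles used to validate the package's
# implementations. Deliberately naive: written straight from definitions,
# sharing no code with R/.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, back in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Unweighted UniFrac by exhaustive branch enumeration: walk every edge,
# collect the tips below it, classify it as unique/shared for the pair.
oracle_unifrac_pair <- function(tree, present_x, present_y) {
  tips_below <- function(node) {
    ntip <- length(tree$tip.label)
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  uniq <- 0; total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tb <- tips_below(tree$edge[e, 2])
    inx <- any(tb %in% present_x); iny <- any(tb %in% present_y)
    if (inx || iny) total <- total + tree$edge.length[e]
    if (xor(inx, iny)) uniq <- uniq + tree$edge.length[e]
  }
  uniq / total
}

# Percentiles by explicit sort-and-interpolate under h = (n-1)q + 1.
oracle_percentile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Small fully-paired two-habitat cohort for reuse across tests.
make_small_cohort <- function(seed = 42, n_ref = 30, n_pd = 0, n_taxa = 60, ...) {
  cfg <- synthetic_config(n_reference = n_ref, n_pd = n_pd, n_taxa = n_taxa,
                          habitats = c("stool", "saliva"),
                          habitat_totals = NULL, pair_counts = NULL,
                          seed = seed, ...)
  generate_cohort(cfg)
}
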