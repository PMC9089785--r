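# Shared fixtures and independent oracles. Oracles here are deliberately
# brute-force and stay independent of the package's implementation paths.

# Small, fast scenario: one marker gene per cluster keeps the gene universe
# near the ~190 role genes so count generation stays cheap.
tiny_scenario <- function(n_cells = 400, seed = 1L, ...) {
  sim_scenario(n_cells = n_cells, marker_genes_per_cluster = 1,
               n_genes = 200, seed = seed, ...)
}

# Random sparse nonnegative integer matrix as an sc_counts fixture.
random_counts <- function(n_cells = 8, n_genes = 5, seed = 42) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_cells * n_genes, 0.8), nrow = n_cells)
  rownames(m) <- sprintf("BC%03d", seq_len(n_cells))
  colnames(m) <- sprintf("G%03d", seq_len(n_genes))
  sc_counts(m)
}

# Brute-force rank-sum tail by enumerating every subset of size m of the
# midranks: the exact oracle for ranksum_p (tie-aware, mid-p optional).
brute_ranksum <- function(values, member,
                          alternative = c("greater", "less", "two.sided"),
                          midp = FALSE) {
  alternative <- match.arg(alternative)
  r <- rank(values)
  m <- sum(member)
  w_obs <- sum(r[member])
  sums <- utils::combn(length(values), m, function(idx) sum(r[idx]))
  half <- function(x) if (midp) x / 2 else x
  eps <- 1e-9
  switch(alternative,
    greater = mean(sums > w_obs + eps) + half(mean(abs(sums - w_obs) <= eps)),
    less = mean(sums < w_obs - eps) + half(mean(abs(sums - w_obs) <= eps)),
    two.sided = {
      ctr <- m * (length(values) + 1) / 2
      dev <- abs(w_obs - ctr)
      min(1, mean(abs(sums - ctr) > dev + eps) +
            half(mean(abs(abs(sums - ctr) - dev) <= eps)))
    })
}

# Run the clonotype arm of the pipeline on a cohort with truth clusters.
clonal_linkage <- function(cohort) {
  pairs <- filter_productive_pairs(cohort$contigs)
  cs <- call_clonotypes(pairs)
  cs <- assign_tiers(cs, compute_high_threshold(cs))
  tiers <- cs$cells$tier[match(cohort$truth$barcode, cs$cells$barcode)]
  list(clonotypes = cs,
       report = linkage_report(tier_cluster_table(tiers,
                                                  cohort$truth$cluster)))
}
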