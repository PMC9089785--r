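# Synthetic paired scRNA + TCR cohort generator. Emits the four inputs the
# pipeline consumes (UMI counts, HTO counts, TCR contigs, gene signatures via
# the shipped lists) together with ground-truth labels, with the statistical
# structure the downstream analysis assumes: negative-binomial counts with
# cluster/signature/phase fold shifts, multinomial hashtags with doublets and
# ambient background, and a clone-size law with tier-conditional cluster
# assignment. Presets are calibrated to published aggregate proportions.

.default_clusters <- c("naive", "T_CM", "T_EM", "transitional", "early_T_EX",
                       "terminal_T_EX", "T_RM", "dividing", "IFN_hi")
.exhausted_clusters <- c("early_T_EX", "terminal_T_EX")
.tier_levels <- c("unique", "shared", "moderate", "high")

#' Describe a synthetic cohort scenario
#'
#' Bundles every parameter of the generative model. Defaults describe a
#' mid-sized kidney-infiltrating CD8 T cell cohort: 9 phenotypic clusters,
#' overdispersed NB counts with log-normal gene baselines, 6 hashtags with a
#' 5\% doublet rate, and a clone-size law with a geometric body and an
#' expanded tail.
#'
#' @param n_cells total droplets (doublets included).
#' @param cluster_names ordered cluster labels.
#' @param cluster_props cluster probabilities for cells outside the TCR
#'   repertoire (and the fallback for all tiers when `tier_cluster_probs`
#'   is `NULL`). Must sum to 1.
#' @param n_genes gene universe size (>= the ~380 role genes).
#' @param baseline_mean mean scale of the log-normal gene baseline means.
#' @param dispersion NB dispersion (1/size); variance = mu + dispersion*mu^2.
#' @param marker_genes_per_cluster,marker_lfc per-cluster marker program:
#'   each cluster gets this many dedicated genes shifted by `marker_lfc`
#'   (log2) in its cells.
#' @param signature_effects named list; each element
#'   `list(genes=, clusters=, lfc=)` shifts `genes` by `lfc` (log2, recycled
#'   over `clusters`) in cells of those clusters. Default plants the
#'   exhaustion program at +1.5 in early and +2.5 in terminal exhaustion.
#' @param phase_props K x 3 matrix (G1, S, G2M) of per-cluster phase
#'   probabilities; default 90/5/5 except the dividing cluster at 20/40/40.
#' @param phase_lfc log2 shift applied to a phase's marker genes in cells of
#'   that phase.
#' @param n_hashtags,hto_mean,ambient_hto_rate,doublet_rate hashtag model:
#'   singlets get Poisson(`hto_mean`) on their own hashtag and
#'   Poisson(`ambient_hto_rate`) elsewhere; doublets the sum of two such
#'   profiles.
#' @param clone_size_law list with `tcr_frac` (fraction of singlet cells
#'   carrying a TCR), per-tier cell budgets `high_frac`, `guard_frac`
#'   (clones of size `high_threshold - 1` pinning the quartile cumulation),
#'   `moderate_frac`, `shared_frac` (remainder is unique), `high_threshold`
#'   and `high_size_max`.
#' @param tier_cluster_probs 4 x K matrix (rows unique/shared/moderate/high)
#'   of cluster probabilities conditional on clone tier; `NULL` means all
#'   tiers follow `cluster_props` (tier independent of cluster).
#' @param chain_defect_rate fraction (of the TCR cell count) of extra cells
#'   given deliberately defective chain sets to exercise filtering.
#' @param seed integer RNG seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_cells = 10000,
                         cluster_names = .default_clusters,
                         cluster_props = NULL,
                         n_genes = 1000,
                         baseline_mean = 1.0,
                         dispersion = 0.5,
                         marker_genes_per_cluster = 25,
                         marker_lfc = 2.0,
                         signature_effects = NULL,
                         phase_props = NULL,
                         phase_lfc = 2.0,
                         n_hashtags = 6,
                         hto_mean = 150,
                         ambient_hto_rate = 3,
                         doublet_rate = 0.05,
                         clone_size_law = NULL,
                         tier_cluster_probs = NULL,
                         chain_defect_rate = 0.03,
                         seed = 1L) {
  K <- length(cluster_names)
  cluster_props <- cluster_props %||% rep(1 / K, K)
  names(cluster_props) <- cluster_names
  if (is.null(signature_effects)) {
    eff_cl <- intersect(.exhausted_clusters, cluster_names)
    signature_effects <- if (length(eff_cl))
      list(exhaustion = list(genes = exhaustion_genes, clusters = eff_cl,
                             lfc = c(1.5, 2.5)[seq_along(eff_cl)]))
    else list()
  }
  if (is.null(phase_props)) {
    phase_props <- matrix(rep(c(0.90, 0.05, 0.05), each = K), nrow = K,
                          dimnames = list(cluster_names, c("G1", "S", "G2M")))
    if ("dividing" %in% cluster_names)
      phase_props["dividing", ] <- c(0.20, 0.40, 0.40)
  }
  clone_size_law <- utils::modifyList(
    list(tcr_frac = 0.85, high_frac = 0.24, guard_frac = 0.015,
         moderate_frac = 0.05, shared_frac = 0.18,
         high_threshold = 13L, high_size_max = 20L),
    clone_size_law %||% list())
  if (!is.null(tier_cluster_probs)) {
    tier_cluster_probs <- as.matrix(tier_cluster_probs)
    rownames(tier_cluster_probs) <- .tier_levels
    colnames(tier_cluster_probs) <- cluster_names
  }
  sc <- structure(list(
    n_cells = as.integer(n_cells), cluster_names = cluster_names,
    cluster_props = cluster_props, n_genes = as.integer(n_genes),
    baseline_mean = baseline_mean, dispersion = dispersion,
    marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
    marker_lfc = marker_lfc, signature_effects = signature_effects,
    phase_props = phase_props, phase_lfc = phase_lfc,
    n_hashtags = as.integer(n_hashtags), hto_mean = hto_mean,
    ambient_hto_rate = ambient_hto_rate, doublet_rate = doublet_rate,
    clone_size_law = clone_size_law,
    tier_cluster_probs = tier_cluster_probs,
    chain_defect_rate = chain_defect_rate, seed = as.integer(seed),
    free_defaults = character()), class = "sim_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario's internal consistency
#' @param sc a `sim_scenario`.
#' @return `sc` invisibly; raises a configuration error otherwise.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  chk_prob <- function(p, what) {
    if (any(p < -1e-12)) .stop_fmt("configuration error: negative mass in %s", what)
    if (abs(sum(p) - 1) > 1e-9)
      .stop_fmt("configuration error: %s sums to %.12f, not 1", what, sum(p))
  }
  chk_prob(sc$cluster_props, "cluster_props")
  for (i in seq_len(nrow(sc$phase_props)))
    chk_prob(sc$phase_props[i, ], sprintf("phase_props[%d,]", i))
  if (!is.null(sc$tier_cluster_probs))
    for (t in rownames(sc$tier_cluster_probs))
      chk_prob(sc$tier_cluster_probs[t, ],
               sprintf("tier_cluster_probs['%s',]", t))
  law <- sc$clone_size_law
  tot <- law$high_frac + law$guard_frac + law$moderate_frac + law$shared_frac
  if (tot >= 1)
    .stop_fmt("configuration error: clone-law tier fractions sum to %.3f >= 1", tot)
  if (law$high_threshold < 5)
    .stop_fmt("configuration error: high_threshold must be >= 5")
  if (sc$doublet_rate < 0 || sc$doublet_rate >= 1)
    .stop_fmt("configuration error: doublet_rate must be in [0,1)")
  if (sc$n_genes < nrow(.gene_table(sc)))
    .stop_fmt("configuration error: n_genes=%d below the %d role genes",
              sc$n_genes, nrow(.gene_table(sc)))
  invisible(sc)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %d cells, %d genes, %d clusters, %d hashtags, seed %d\n",
              x$n_cells, x$n_genes, length(x$cluster_names), x$n_hashtags,
              x$seed))
  law <- x$clone_size_law
  cat(sprintf("  clone law: tcr_frac=%.2f high>=%d (%.0f%% of cells), doublets %.1f%%\n",
              law$tcr_frac, law$high_threshold, 100 * law$high_frac,
              100 * x$doublet_rate))
  if (length(x$free_defaults))
    cat("  free defaults:", paste(x$free_defaults, collapse = "; "), "\n")
  invisible(x)
}

# Gene table: id/symbol/role. Role genes come first, filler after.
.gene_table <- function(sc) {
  mito <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
            "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
            "mt-Cytb")
  ribo <- c(paste0("Rps", 1:12), paste0("Rpl", 1:12))
  hb <- c("Hba-a1", "Hba-a2", "Hbb-bs", "Hbb-bt")
  sig_genes <- unique(unlist(lapply(sc$signature_effects, `[[`, "genes")))
  mk <- unlist(lapply(seq_along(sc$cluster_names), function(k)
    sprintf("Mrk%d_%02d", k, seq_len(sc$marker_genes_per_cluster))))
  roles <- c(rep("mito", length(mito)), rep("ribo", length(ribo)),
             rep("hemoglobin", length(hb)), rep("signature", length(sig_genes)),
             rep("s_phase", length(s_phase_genes)),
             rep("g2m_phase", length(g2m_phase_genes)),
             rep("marker", length(mk)))
  sym <- c(mito, ribo, hb, sig_genes, s_phase_genes, g2m_phase_genes, mk)
  n_fill <- sc$n_genes - length(sym)
  if (n_fill > 0) {
    sym <- c(sym, sprintf("Gene%04d", seq_len(n_fill)))
    roles <- c(roles, rep("filler", n_fill))
  }
  data.frame(id = sprintf("ENSMUSG%08d", seq_along(sym)), symbol = sym,
             role = roles, stringsAsFactors = FALSE)
}

# Draw clone sizes in [lo, hi] summing exactly to `budget`. The top bracket
# may exceed hi by < lo when the remainder cannot be split legally.
.fill_sizes <- function(budget, lo, hi) {
  if (budget <= 0) return(integer())
  if (budget < lo) return(integer())  # caller folds sub-lo remainders
  sizes <- integer()
  rem <- budget
  while (rem >= lo) {
    if (rem < 2 * lo) { sizes <- c(sizes, rem); rem <- 0; break }
    smax <- min(hi, rem)
    s <- if (smax == lo) lo else sample(lo:smax, 1)
    if (rem - s > 0 && rem - s < lo)
      s <- if (rem <= hi) rem else rem - lo
    sizes <- c(sizes, s)
    rem <- rem - s
  }
  if (rem > 0) {  # 1..lo-1 left: bump earlier clones
    i <- 1L
    while (rem > 0) {
      j <- which(sizes < hi)
      if (!length(j)) j <- length(sizes)
      k <- j[1L + (i - 1L) %% length(j)]
      sizes[k] <- sizes[k] + 1L
      rem <- rem - 1L
      i <- i + 1L
    }
  }
  stopifnot(sum(sizes) == budget)
  sizes
}

# Plan the clone-size multiset from the law. Budgets are deterministic given
# n_tcr; sizes within brackets are random. Guard clones (size thr-1) ensure
# the cell-weighted top-quartile cumulation lands exactly at thr.
.plan_clones <- function(law, n_tcr) {
  thr <- law$high_threshold
  b_high <- round(law$high_frac * n_tcr)
  n_guard <- ceiling(law$guard_frac * n_tcr / (thr - 1))
  b_guard <- n_guard * (thr - 1)
  b_mod <- round(law$moderate_frac * n_tcr)
  b_shared <- round(law$shared_frac * n_tcr)
  # one clone of exactly thr guarantees the threshold is an observed size;
  # bracket remainders that cannot legally fill a clone fold into the
  # unique tier so cells are always conserved
  s_high <- if (b_high >= thr) {
    s <- .fill_sizes(b_high - thr, thr, law$high_size_max)
    left <- (b_high - thr) - sum(s)
    if (left > 0 && length(s)) { s[1] <- s[1] + left }
    c(thr, s)
  } else integer()
  s_mod <- if (thr - 1 >= 6) .fill_sizes(b_mod, 5L, thr - 1L)
           else rep(5L, b_mod %/% 5)
  s_shared <- .fill_sizes(b_shared, 2L, 4L)
  b_unique <- n_tcr - sum(s_high) - b_guard - sum(s_mod) - sum(s_shared)
  if (b_unique < 0)
    .stop_fmt("configuration error: clone law infeasible for %d TCR cells", n_tcr)
  sizes <- c(s_high, rep(thr - 1L, n_guard), s_mod, s_shared,
             rep(1L, b_unique))
  sizes <- as.integer(sizes)
  tier <- cut(sizes, c(0, 1, 4, thr - 0.5, Inf), labels = .tier_levels)
  list(sizes = sizes, tier = as.character(tier), threshold = thr)
}

.tier_probs_or_default <- function(sc) {
  if (!is.null(sc$tier_cluster_probs)) return(sc$tier_cluster_probs)
  m <- matrix(rep(sc$cluster_props, each = 4), nrow = 4,
              dimnames = list(.tier_levels, sc$cluster_names))
  m
}

.encode_nt <- function(i, width = 12) {
  digits <- integer(width)
  for (p in seq_len(width)) { digits[p] <- i %% 4L; i <- i %/% 4L }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

.encode_aa <- function(i) sprintf("CASS%04dF", i %% 10000L)

#' Simulate a complete synthetic cohort
#'
#' Draws cells, clusters, phases, hashtags, UMI counts, and a TCR repertoire
#' from a [sim_scenario]. Clone member cells' clusters are i.i.d. from the
#' tier-conditional cluster distribution of the clone's tier (tier taken from
#' the planted clone size against the law's threshold); cells outside the
#' repertoire follow `cluster_props`. A `chain_defect_rate` fraction of extra
#' cells receive deliberately malformed chain sets (missing/extra/
#' nonproductive chains) and carry no clone id.
#'
#' @param sc a [sim_scenario].
#' @return Object of class `sim_cohort`: list with `counts` ([sc_counts]),
#'   `hto` (integer matrix), `contigs` (data.frame in the contig-table
#'   layout), `truth` (per-cell data.frame: barcode, cluster, sample,
#'   doublet, phase, clone_id, clone_size, tier, defect), `clone_sizes`,
#'   `high_threshold`, and the `scenario`. Fully reproducible from
#'   `sc$seed`.
#' @export
simulate_cohort <- function(sc) {
  validate_scenario(sc)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sc$seed)

  n <- sc$n_cells
  K <- length(sc$cluster_names)
  genes <- .gene_table(sc)
  barcodes <- sprintf("CELL%06d-1", seq_len(n))

  ## -- hashtags & doublets ---------------------------------------------
  n_dbl <- round(sc$doublet_rate * n)
  doublet <- rep(FALSE, n)
  if (n_dbl > 0) doublet[sample.int(n, n_dbl)] <- TRUE
  hashtags <- paste0("HTO", seq_len(sc$n_hashtags))
  h1 <- sample.int(sc$n_hashtags, n, replace = TRUE)
  h2 <- ifelse(doublet,
               ((h1 - 1L + sample.int(sc$n_hashtags - 1L, n, replace = TRUE)) %%
                  sc$n_hashtags) + 1L,
               NA_integer_)
  sample_of_origin <- ifelse(doublet, NA_character_, hashtags[h1])

  hto <- matrix(stats::rpois(n * sc$n_hashtags, sc$ambient_hto_rate),
                nrow = n, dimnames = list(barcodes, hashtags))
  hto[cbind(seq_len(n), h1)] <- hto[cbind(seq_len(n), h1)] +
    stats::rpois(n, sc$hto_mean)
  idx2 <- which(doublet)
  if (length(idx2)) {
    hto[cbind(idx2, h2[idx2])] <- hto[cbind(idx2, h2[idx2])] +
      stats::rpois(length(idx2), sc$hto_mean)
    # second cell of the pair also contributes ambient background
    hto[idx2, ] <- hto[idx2, ] +
      matrix(stats::rpois(length(idx2) * sc$n_hashtags, sc$ambient_hto_rate),
             nrow = length(idx2))
  }
  storage.mode(hto) <- "integer"

  ## -- clone plan & cluster assignment ---------------------------------
  law <- sc$clone_size_law
  eligible <- which(!doublet)
  n_tcr <- round(law$tcr_frac * length(eligible))
  plan <- .plan_clones(law, n_tcr)
  n_defect <- round(sc$chain_defect_rate * n_tcr)
  if (n_tcr + n_defect > length(eligible))
    .stop_fmt("configuration error: %d TCR + %d defect cells exceed %d singlets",
              n_tcr, n_defect, length(eligible))
  picked <- sample(eligible, n_tcr + n_defect)
  tcr_cells <- picked[seq_len(n_tcr)]
  defect_cells <- picked[n_tcr + seq_len(n_defect)]

  clone_id <- rep(NA_integer_, n)
  clone_id[tcr_cells] <- rep(seq_along(plan$sizes), plan$sizes)
  tier <- rep(NA_character_, n)
  tier[tcr_cells] <- rep(plan$tier, plan$sizes)

  tp <- .tier_probs_or_default(sc)
  cluster <- character(n)
  no_tcr <- setdiff(seq_len(n), tcr_cells)
  cluster[no_tcr] <- sample(sc$cluster_names, length(no_tcr), replace = TRUE,
                            prob = sc$cluster_props)
  for (t in .tier_levels) {
    idx <- which(!is.na(tier) & tier == t)
    if (length(idx))
      cluster[idx] <- sample(sc$cluster_names, length(idx), replace = TRUE,
                             prob = tp[t, ])
  }

  ## -- phases -----------------------------------------------------------
  phase <- character(n)
  for (k in seq_len(K)) {
    idx <- which(cluster == sc$cluster_names[k])
    if (length(idx))
      phase[idx] <- sample(colnames(sc$phase_props), length(idx),
                           replace = TRUE, prob = sc$phase_props[k, ])
  }

  ## -- counts -----------------------------------------------------------
  baseline <- sc$baseline_mean *
    stats::rlnorm(nrow(genes), meanlog = -0.5, sdlog = 1)
  lfc <- matrix(0, nrow = n, ncol = nrow(genes))  # log2 fold shifts
  cl_idx <- match(cluster, sc$cluster_names)
  for (k in seq_len(K)) {
    cols <- which(genes$symbol %in%
                    sprintf("Mrk%d_%02d", k, seq_len(sc$marker_genes_per_cluster)))
    if (length(cols)) lfc[cl_idx == k, cols] <- sc$marker_lfc
  }
  for (se in sc$signature_effects) {
    cols <- which(genes$symbol %in% se$genes)
    lf <- rep_len(se$lfc, length(se$clusters))
    for (j in seq_along(se$clusters))
      lfc[cluster == se$clusters[j], cols] <-
        lfc[cluster == se$clusters[j], cols] + lf[j]
  }
  s_cols <- which(genes$role == "s_phase")
  g2m_cols <- which(genes$role == "g2m_phase")
  lfc[phase == "S", s_cols] <- lfc[phase == "S", s_cols] + sc$phase_lfc
  lfc[phase == "G2M", g2m_cols] <- lfc[phase == "G2M", g2m_cols] + sc$phase_lfc

  mu <- sweep(2^lfc, 2, baseline, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / sc$dispersion),
                   nrow = n)
  rownames(counts) <- barcodes
  colnames(counts) <- genes$id
  counts <- sc_counts(counts, barcodes = barcodes,
                      features = genes[, c("id", "symbol")])

  ## -- TCR contigs ------------------------------------------------------
  mk_contig <- function(bc, chain, prod, key)
    data.frame(barcode = bc, chain = chain,
               productive = ifelse(prod, "True", "False"),
               cdr3 = .encode_aa(key),
               cdr3_nt = paste0(if (chain[1] == "TRA") "TGTGCA" else "TGTGCC",
                                vapply(key, .encode_nt, "")),
               stringsAsFactors = FALSE)
  ct <- list(
    mk_contig(barcodes[tcr_cells], "TRA", TRUE, clone_id[tcr_cells]),
    mk_contig(barcodes[tcr_cells], "TRB", TRUE, clone_id[tcr_cells]))
  if (n_defect > 0) {
    kinds <- sample(c("no_alpha", "no_beta", "multi_alpha", "nonproductive"),
                    n_defect, replace = TRUE)
    off <- length(plan$sizes)
    for (i in seq_len(n_defect)) {
      bc <- barcodes[defect_cells[i]]
      key <- off + i
      ct[[length(ct) + 1L]] <- switch(kinds[i],
        no_alpha = mk_contig(bc, "TRB", TRUE, key),
        no_beta = mk_contig(bc, "TRA", TRUE, key),
        multi_alpha = rbind(mk_contig(bc, "TRA", TRUE, key),
                            mk_contig(bc, "TRA", TRUE, key + 100000L),
                            mk_contig(bc, "TRB", TRUE, key)),
        nonproductive = rbind(mk_contig(bc, "TRA", FALSE, key),
                              mk_contig(bc, "TRB", TRUE, key)))
    }
  }
  contigs <- do.call(rbind, ct)
  contigs <- contigs[order(contigs$barcode, contigs$chain), ]
  rownames(contigs) <- NULL

  truth <- data.frame(
    barcode = barcodes, cluster = cluster, sample = sample_of_origin,
    doublet = doublet, phase = phase, clone_id = clone_id,
    clone_size = ifelse(is.na(clone_id), NA_integer_,
                        plan$sizes[clone_id]),
    tier = tier,
    defect = seq_len(n) %in% defect_cells,
    stringsAsFactors = FALSE)

  structure(list(counts = counts, hto = hto, contigs = contigs,
                 truth = truth, clone_sizes = plan$sizes,
                 high_threshold = plan$threshold, scenario = sc),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d cells, %d genes, %d clones (threshold %d), %d contig rows\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              length(x$clone_sizes), x$high_threshold, nrow(x$contigs)))
  invisible(x)
}

# Build a 4 x K tier-conditional cluster matrix: pinned masses per tier, the
# rest spread over unpinned clusters proportionally to cluster_props.
.build_tier_probs <- function(cluster_names, cluster_props, pinned) {
  m <- matrix(NA_real_, nrow = 4, ncol = length(cluster_names),
              dimnames = list(.tier_levels, cluster_names))
  free <- character()
  for (t in .tier_levels) {
    pin <- pinned[[t]] %||% numeric()
    rest <- setdiff(cluster_names, names(pin))
    mass <- 1 - sum(pin)
    if (mass < 0) .stop_fmt("configuration error: pinned masses for tier '%s' exceed 1", t)
    w <- cluster_props[rest] / sum(cluster_props[rest])
    m[t, names(pin)] <- pin
    m[t, rest] <- mass * w
    free <- c(free, sprintf("%s: %s spread over {%s}", t,
                            format(mass, digits = 3),
                            paste(rest, collapse = ",")))
  }
  list(probs = m, free = free)
}

#' Scenario preset calibrated to the MRL/lpr cohort aggregates
#'
#' High-frequency clones (top quartile, threshold 13 cells) place 79\% of
#' their cells in the union of the two exhausted clusters; the high-tier mass
#' is split between early and terminal exhaustion proportionally to the
#' baseline cluster mix. All other tier-conditional masses are free defaults
#' spread proportionally to `cluster_props` and recorded in
#' `$free_defaults`.
#'
#' @param n_cells cohort size (default 10,000).
#' @param seed RNG seed.
#' @return A [sim_scenario].
#' @export
preset_mrl <- function(n_cells = 10000, seed = 1L) {
  props <- c(naive = 0.05, T_CM = 0.06, T_EM = 0.10, transitional = 0.20,
             early_T_EX = 0.22, terminal_T_EX = 0.14, T_RM = 0.12,
             dividing = 0.05, IFN_hi = 0.06)
  # split the printed 0.79 aggregate between the two exhausted clusters
  # proportionally to their baseline masses (free default)
  w <- props[.exhausted_clusters] / sum(props[.exhausted_clusters])
  pinned <- list(high = 0.79 * w)
  tb <- .build_tier_probs(names(props), props, pinned)
  sc <- sim_scenario(
    n_cells = n_cells, cluster_names = names(props), cluster_props = props,
    clone_size_law = list(high_threshold = 13L, high_size_max = 20L),
    tier_cluster_probs = tb$probs, seed = seed)
  sc$free_defaults <- c(
    "high-tier 0.79 exhausted mass split early/terminal by cluster_props",
    tb$free)
  sc
}

#' Scenario preset calibrated to the FcgR2B-/-.Yaa cohort aggregates
#'
#' Pins every printed proportion: P(exhausted | high) = 0.344 with
#' P(terminal | high) = 0.173 (so early = 0.171), P(transitional | high) =
#' 0.239, P(terminal | unique) = 0.0312, P(transitional | unique) = 0.171,
#' and the all-cells exhausted marginal 0.231, with a clone law whose
#' top-quartile threshold is 40 cells. The unique/shared/moderate exhausted
#' mass is solved from the marginal against the law's deterministic tier
#' cell-weights; shared and moderate tiers share the unique tier's
#' conditional vector (free default). Raises a configuration error if the
#' solve leaves a negative mass.
#'
#' @inheritParams preset_mrl
#' @return A [sim_scenario].
#' @export
preset_yaa <- function(n_cells = 10000, seed = 1L) {
  props <- c(naive = 0.07, T_CM = 0.09, T_EM = 0.13, transitional = 0.19,
             early_T_EX = 0.148, terminal_T_EX = 0.083, T_RM = 0.15,
             dividing = 0.06, IFN_hi = 0.079)
  law <- list(tcr_frac = 0.85, high_frac = 0.24, guard_frac = 0.015,
              moderate_frac = 0.05, shared_frac = 0.18,
              high_threshold = 40L, high_size_max = 60L)
  w_high <- law$high_frac
  exh_high <- 0.344
  marginal <- 0.231
  exh_rest <- (marginal - exh_high * w_high) / (1 - w_high)
  term_unique <- 0.0312
  early_unique <- exh_rest - term_unique
  if (early_unique < 0)
    .stop_fmt(paste("configuration error: marginal 0.231 infeasible -",
                    "solved non-high exhausted mass below the pinned 0.0312"))
  pin_u <- c(terminal_T_EX = term_unique, early_T_EX = early_unique,
             transitional = 0.171)
  pinned <- list(
    unique = pin_u, shared = pin_u, moderate = pin_u,
    high = c(terminal_T_EX = 0.173, early_T_EX = exh_high - 0.173,
             transitional = 0.239))
  tb <- .build_tier_probs(names(props), props, pinned)
  sc <- sim_scenario(
    n_cells = n_cells, cluster_names = names(props), cluster_props = props,
    clone_size_law = law, tier_cluster_probs = tb$probs, seed = seed)
  sc$free_defaults <- c(
    sprintf("non-high exhausted mass solved to %.4f from the 0.231 marginal",
            exh_rest),
    "shared/moderate tiers share the unique tier's conditional vector",
    tb$free)
  sc
}

#' Generate null cohorts with tier independent of cluster
#'
#' Replaces the scenario's tier-conditional cluster distributions with the
#' marginal `cluster_props` for every tier, so tier and cluster are
#' independent by construction, and simulates `n_reps` cohorts under derived
#' sub-seeds. Used to calibrate the enrichment test's type-I error.
#'
#' @param sc a [sim_scenario].
#' @param n_reps number of replicate cohorts.
#' @param seed base seed for the replicate sub-seeds.
#' @return List of `sim_cohort` objects.
#' @export
simulate_null <- function(sc, n_reps, seed = sc$seed) {
  sc$tier_cluster_probs <- NULL  # all tiers follow cluster_props
  lapply(seq_len(n_reps), function(r) {
    sc$seed <- .sub_seed(seed, r)
    simulate_cohort(sc)
  })
}

#' Write a cohort's four inputs to disk
#'
#' Emits the same formats the readers consume: a Matrix Market count
#' directory, an HTO CSV, a contig CSV, and the truth table as TSV, so the
#' pipeline can be exercised end-to-end from files.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(cohort$counts, file.path(dir, "counts"))
  write_hto_counts(cohort$hto, file.path(dir, "hto_counts.csv"))
  utils::write.csv(cohort$contigs,
                   file.path(dir, "filtered_contig_annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Serialize / restore a scenario as YAML
#'
#' Matrices are stored as named row lists; `scenario_from_yaml` rebuilds the
#' `sim_scenario` and re-validates it.
#'
#' @param sc a [sim_scenario].
#' @param path YAML file path.
#' @return `path` invisibly / the restored scenario.
#' @export
scenario_to_yaml <- function(sc, path) {
  x <- unclass(sc)
  mat2list <- function(m) {
    l <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
    names(l) <- rownames(m)
    l
  }
  x$phase_props <- mat2list(sc$phase_props)
  if (!is.null(sc$tier_cluster_probs))
    x$tier_cluster_probs <- mat2list(sc$tier_cluster_probs)
  x$cluster_props <- as.list(sc$cluster_props)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname scenario_to_yaml
#' @export
scenario_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  list2mat <- function(l) {
    m <- do.call(rbind, lapply(l, function(r) unlist(r)))
    rownames(m) <- names(l)
    m
  }
  sc <- sim_scenario(
    n_cells = x$n_cells, cluster_names = x$cluster_names,
    cluster_props = unlist(x$cluster_props), n_genes = x$n_genes,
    baseline_mean = x$baseline_mean, dispersion = x$dispersion,
    marker_genes_per_cluster = x$marker_genes_per_cluster,
    marker_lfc = x$marker_lfc,
    signature_effects = lapply(x$signature_effects, function(se)
      list(genes = unlist(se$genes), clusters = unlist(se$clusters),
           lfc = unlist(se$lfc))),
    phase_props = list2mat(x$phase_props), phase_lfc = x$phase_lfc,
    n_hashtags = x$n_hashtags, hto_mean = x$hto_mean,
    ambient_hto_rate = x$ambient_hto_rate, doublet_rate = x$doublet_rate,
    clone_size_law = x$clone_size_law,
    tier_cluster_probs = if (!is.null(x$tier_cluster_probs))
      list2mat(x$tier_cluster_probs),
    chain_defect_rate = x$chain_defect_rate, seed = x$seed)
  sc$free_defaults <- unlist(x$free_defaults) %||% character()
  sc
}
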