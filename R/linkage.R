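# The headline statistics: clone-tier x cluster enrichment with multiplicity
# correction, exhaustion score by clonal abundance, per-cluster cell-cycle
# enrichment, and the machine-readable report.

.pearson_chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(stat = 0, p = 1, expected = c(0, 0, 0, 0)))
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n)
}

#' Tier-by-cluster contingency table
#'
#' Cells lacking either label are dropped with a recorded count; the grand
#' total equals the cells carrying both labels.
#'
#' @param tiers per-cell tier labels (NA allowed).
#' @param clusters aligned per-cell cluster labels (NA allowed).
#' @return Integer matrix tiers x clusters (tier rows in
#'   unique/shared/moderate/high order where present) with attribute
#'   `n_dropped`.
#' @export
tier_cluster_table <- function(tiers, clusters) {
  stopifnot(length(tiers) == length(clusters))
  ok <- !is.na(tiers) & !is.na(clusters)
  if (!any(ok)) .stop_fmt("no cells with both a tier and a cluster label")
  tier_lv <- intersect(.tier_levels, unique(tiers[ok]))
  tab <- table(factor(tiers[ok], levels = tier_lv), factor(clusters[ok]))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  attr(m, "n_dropped") <- sum(!ok)
  m
}

#' Per-cluster enrichment of a focal tier against a reference
#'
#' For each cluster, a 2x2 Pearson chi-square (1 df, no continuity
#' correction) of focal-tier vs reference cells falling in vs out of the
#' cluster; Bonferroni correction over `n_comparisons` comparison groups
#' (default 9). When any expected count falls below 1 the exact
#' hypergeometric test is used instead and flagged. A global chi-square over
#' the full tier x cluster table is attached as attribute `global`.
#'
#' @param tab matrix from [tier_cluster_table()].
#' @param focal_tier focal tier row (default `"high"`).
#' @param reference `"unique"` (default), another tier row, or `"all"` for
#'   the all-cells marginal.
#' @param n_comparisons Bonferroni multiplier (default 9).
#' @return data.frame: cluster, n_focal, n_reference, obs_prop, ref_prop,
#'   chi_sq, df, p, p_adj, method.
#' @export
cluster_enrichment <- function(tab, focal_tier = "high",
                               reference = "unique", n_comparisons = 9) {
  if (!focal_tier %in% rownames(tab))
    .stop_fmt("focal tier '%s' absent from table", focal_tier)
  f <- tab[focal_tier, ]
  r <- if (identical(reference, "all")) colSums(tab)
       else if (reference %in% rownames(tab)) tab[reference, ]
       else .stop_fmt("reference tier '%s' absent from table", reference)
  nf <- sum(f); nr <- sum(r)
  rows <- lapply(colnames(tab), function(cl) {
    a <- f[[cl]]; b <- nf - a
    c_ <- r[[cl]]; d <- nr - c_
    cs <- .pearson_chisq_2x2(a, b, c_, d)
    if (any(cs$expected < 1)) {
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
      data.frame(cluster = cl, n_focal = a, n_reference = c_,
                 obs_prop = a / nf, ref_prop = c_ / nr,
                 chi_sq = NA_real_, df = NA_integer_, p = p,
                 method = "exact", stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = cl, n_focal = a, n_reference = c_,
                 obs_prop = a / nf, ref_prop = c_ / nr,
                 chi_sq = cs$stat, df = 1L, p = cs$p,
                 method = "chisq", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * n_comparisons)
  out <- out[, c("cluster", "n_focal", "n_reference", "obs_prop", "ref_prop",
                 "chi_sq", "df", "p", "p_adj", "method")]
  g <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  attr(out, "global") <- list(chi_sq = unname(g$statistic),
                              df = unname(g$parameter),
                              p = unname(g$p.value))
  out
}

#' Signature score by clone-frequency tier
#'
#' Per-tier mean/median score plus omnibus one-way ANOVA and
#' Kruskal-Wallis, and all-pairs Tukey HSD. Tiers with fewer than
#' `min_cells` cells are excluded with a warning.
#'
#' @param scores numeric per-cell signature scores.
#' @param tiers aligned per-cell tier labels (NA cells dropped).
#' @param min_cells minimum cells per tier (default 3).
#' @return List of class `tier_score_test`: `summary` (tier, n, mean,
#'   median in unique < shared < moderate < high order), `anova` (F, df,
#'   p), `kruskal` (H, df, p), `tukey` (data.frame of pairwise adjusted p).
#' @export
score_by_tier <- function(scores, tiers, min_cells = 3) {
  ok <- !is.na(tiers) & !is.na(scores)
  scores <- scores[ok]; tiers <- as.character(tiers[ok])
  cnt <- table(tiers)
  small <- names(cnt)[cnt < min_cells]
  if (length(small)) {
    warning("excluding tier(s) with < ", min_cells, " cells: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !tiers %in% small
    scores <- scores[keep]; tiers <- tiers[keep]
  }
  if (length(unique(tiers)) < 2) .stop_fmt("need >= 2 tiers with enough cells")
  lv <- intersect(.tier_levels, unique(tiers))
  tf <- factor(tiers, levels = lv)
  summ <- data.frame(
    tier = lv, n = as.integer(table(tf)),
    mean = as.numeric(tapply(scores, tf, mean)),
    median = as.numeric(tapply(scores, tf, stats::median)),
    stringsAsFactors = FALSE)
  if (stats::var(scores) == 0) {
    # fully degenerate: no between- or within-group variation
    pairs <- utils::combn(lv, 2, function(p) paste(p[2], p[1], sep = "-"))
    return(structure(list(
      summary = summ,
      anova = list(F = 0, df = c(length(lv) - 1L, length(scores) - length(lv)),
                   p = 1),
      kruskal = list(H = 0, df = length(lv) - 1L, p = 1),
      tukey = data.frame(pair = pairs, diff = 0, p_adj = 1,
                         stringsAsFactors = FALSE)), class = "tier_score_test"))
  }
  fit <- stats::aov(scores ~ tf)
  an <- summary(fit)[[1]]
  kw <- stats::kruskal.test(scores, tf)
  tk <- stats::TukeyHSD(fit)$tf
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(
    summary = summ,
    anova = list(F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
                 p = an[1, "Pr(>F)"]),
    kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                   p = kw$p.value),
    tukey = tukey), class = "tier_score_test")
}

#' @export
print.tier_score_test <- function(x, ...) {
  cat("<tier_score_test>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  ANOVA F=%.3f p=%.3g; Kruskal-Wallis H=%.3f p=%.3g\n",
              x$anova$F, x$anova$p, x$kruskal$H, x$kruskal$p))
  invisible(x)
}

#' Per-cluster cell-cycle enrichment
#'
#' For each cluster, a 2x2 chi-square of (cluster vs all other cells) by
#' (cycling = S or G2M vs G1), Bonferroni-corrected over the clusters, with
#' a direction flag: `cycling` when the cluster's cycling fraction exceeds
#' the rest's, `G1` otherwise.
#'
#' @param phase_table matrix from [phase_composition()].
#' @param n_comparisons Bonferroni multiplier (default: number of clusters).
#' @return data.frame: cluster, cycling_frac, rest_frac, chi_sq, df, p,
#'   p_adj, method, direction.
#' @export
cycle_enrichment <- function(phase_table, n_comparisons = nrow(phase_table)) {
  cyc <- phase_table[, "S"] + phase_table[, "G2M"]
  g1 <- phase_table[, "G1"]
  rows <- lapply(seq_len(nrow(phase_table)), function(i) {
    a <- cyc[i]; b <- g1[i]
    c_ <- sum(cyc) - a; d <- sum(g1) - b
    cs <- .pearson_chisq_2x2(a, b, c_, d)
    obs <- a / (a + b); rest <- c_ / (c_ + d)
    if (any(cs$expected < 1)) {
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
      data.frame(cluster = rownames(phase_table)[i], cycling_frac = obs,
                 rest_frac = rest, chi_sq = NA_real_, df = NA_integer_,
                 p = p, method = "exact",
                 direction = if (obs > rest) "cycling" else "G1",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = rownames(phase_table)[i], cycling_frac = obs,
                 rest_frac = rest, chi_sq = cs$stat, df = 1L, p = cs$p,
                 method = "chisq",
                 direction = if (obs > rest) "cycling" else "G1",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * n_comparisons)
  out[, c("cluster", "cycling_frac", "rest_frac", "chi_sq", "df", "p",
          "p_adj", "method", "direction")]
}

#' Machine-readable linkage summary
#'
#' Per tier (and for all cells), the percentage of cells in each cluster and
#' in each named cluster group, plus the per-cluster enrichment of the focal
#' tier against both the unique-tier and the all-cells reference and the
#' global tier x cluster chi-square. Percentages are on the 0-100 scale at
#' full precision.
#'
#' @param tab matrix from [tier_cluster_table()].
#' @param cluster_groups named list of cluster-name vectors (default: an
#'   `exhausted` group of the early/terminal exhaustion clusters present).
#' @param focal_tier,n_comparisons passed to [cluster_enrichment()].
#' @return List of class `linkage_report`: `pct_by_tier` (tiers+`all` x
#'   clusters), `group_pct_by_tier`, `enrichment_vs_unique`,
#'   `enrichment_vs_all`, `global`, `n_cells`.
#' @export
linkage_report <- function(tab, cluster_groups = NULL, focal_tier = "high",
                           n_comparisons = 9) {
  if (is.null(cluster_groups)) {
    exh <- intersect(.exhausted_clusters, colnames(tab))
    cluster_groups <- if (length(exh)) list(exhausted = exh) else list()
  }
  counts <- rbind(tab, all = colSums(tab))
  pct <- 100 * counts / rowSums(counts)
  group_pct <- sapply(cluster_groups, function(g)
    rowSums(pct[, intersect(g, colnames(pct)), drop = FALSE]))
  if (!is.matrix(group_pct))
    group_pct <- matrix(group_pct, nrow = nrow(pct),
                        dimnames = list(rownames(pct), names(cluster_groups)))
  enr_u <- if (focal_tier %in% rownames(tab) && "unique" %in% rownames(tab))
    cluster_enrichment(tab, focal_tier, "unique", n_comparisons) else NULL
  enr_a <- if (focal_tier %in% rownames(tab))
    cluster_enrichment(tab, focal_tier, "all", n_comparisons) else NULL
  structure(list(
    pct_by_tier = pct, group_pct_by_tier = group_pct,
    enrichment_vs_unique = enr_u, enrichment_vs_all = enr_a,
    global = if (!is.null(enr_u)) attr(enr_u, "global")
             else if (!is.null(enr_a)) attr(enr_a, "global"),
    n_cells = sum(tab)), class = "linkage_report")
}

#' @export
print.linkage_report <- function(x, ...) {
  cat(sprintf("<linkage_report> %d cells\n", x$n_cells))
  cat("cluster-group percentages by tier:\n")
  print(round(x$group_pct_by_tier, 2))
  invisible(x)
}
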