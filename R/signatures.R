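# Per-cell gene-signature scoring (within-cell Wilcoxon rank-sum of
# signature genes vs the rest of the measured genes) and cell-cycle phase
# scoring with expression-matched control gene sets.

#' Score a gene signature in every cell
#'
#' Within each cell, a one-sided Wilcoxon rank-sum compares the cell's
#' normalized expression over the signature genes against all other measured
#' genes (alternative: signature higher). The score is `-log10(p)` of the
#' enrichment side (p floored at 1e-300); cells where the depletion side is
#' smaller are flagged `depleted`. Exact tie-aware mid-p is used for gene
#' universes up to `exact_max_genes`; tie-corrected normal approximation
#' (no continuity correction) beyond — both give p = 0.5 (score ~0.30) for
#' a completely uninformative cell.
#'
#' @param norm real matrix cells x genes (log-normalized).
#' @param sig_genes character vector of signature gene symbols.
#' @param symbols gene symbols aligned with `norm` columns (default
#'   colnames).
#' @param name signature name for messages.
#' @param exact_max_genes exact-path universe ceiling (default 200).
#' @return data.frame: barcode, score, p, direction
#'   (`enriched`/`depleted`).
#' @export
score_signature_per_cell <- function(norm, sig_genes,
                                     symbols = colnames(norm),
                                     name = "signature",
                                     exact_max_genes = 200) {
  norm <- as.matrix(norm)
  member <- symbols %in% sig_genes
  if (!any(member)) .stop_fmt("signature '%s' has no genes in the matrix", name)
  if (sum(member) >= ncol(norm) / 2)
    .stop_fmt("signature '%s' covers >= half the gene universe", name)
  n_cells <- nrow(norm)
  score <- p_out <- numeric(n_cells)
  direction <- character(n_cells)
  for (i in seq_len(n_cells)) {
    v <- norm[i, ]
    p_hi <- as.numeric(ranksum_p(v, member, "greater", midp = TRUE,
                                 exact_max_n = exact_max_genes))
    p_lo <- as.numeric(ranksum_p(v, member, "less", midp = TRUE,
                                 exact_max_n = exact_max_genes))
    p_out[i] <- p_hi
    score[i] <- -log10(max(p_hi, 1e-300))
    direction[i] <- if (p_lo < p_hi) "depleted" else "enriched"
  }
  data.frame(barcode = rownames(norm) %||% as.character(seq_len(n_cells)),
             score = score, p = p_out, direction = direction,
             stringsAsFactors = FALSE)
}

#' Cell-cycle phase scores and assignment
#'
#' Phase-set score per cell = mean normalized expression of the phase genes
#' minus the mean of a seeded control set matched on population-average
#' expression: genes are split into `n_bins` equal-frequency bins by mean
#' expression and each phase gene contributes `n_ctrl` control genes drawn
#' from its bin (phase genes excluded from the pools; sampled with
#' replacement when a pool is small). A cell is G1 iff both scores are <= 0,
#' otherwise the argmax phase.
#'
#' @param norm real matrix cells x genes.
#' @param s_genes,g2m_genes phase marker symbol lists (defaults shipped:
#'   [s_phase_genes], [g2m_phase_genes]); each must intersect the matrix in
#'   >= 5 genes.
#' @param symbols gene symbols aligned with columns.
#' @param n_bins expression bins (default 24).
#' @param n_ctrl control genes per phase gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return data.frame: barcode, s_score, g2m_score, phase.
#' @export
score_cell_cycle <- function(norm, s_genes = s_phase_genes,
                             g2m_genes = g2m_phase_genes,
                             symbols = colnames(norm),
                             n_bins = 24, n_ctrl = 100, seed = 0L) {
  norm <- as.matrix(norm)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  mu <- colMeans(norm)
  r <- rank(mu, ties.method = "first")
  bin <- as.integer(ceiling(r / (length(mu) / n_bins)))
  phase_cols <- list(S = which(symbols %in% s_genes),
                     G2M = which(symbols %in% g2m_genes))
  for (ph in names(phase_cols))
    if (length(phase_cols[[ph]]) < 5)
      .stop_fmt("%s phase set intersects only %d matrix genes (need >= 5)",
                ph, length(phase_cols[[ph]]))
  in_any_phase <- seq_along(mu) %in% unlist(phase_cols)
  score_one <- function(cols) {
    ctrl <- unlist(lapply(cols, function(g) {
      pool <- which(bin == bin[g] & !in_any_phase)
      if (!length(pool)) pool <- which(!in_any_phase)
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
    rowMeans(norm[, cols, drop = FALSE]) - rowMeans(norm[, ctrl, drop = FALSE])
  }
  s_score <- score_one(phase_cols$S)
  g2m_score <- score_one(phase_cols$G2M)
  phase <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  data.frame(barcode = rownames(norm) %||% as.character(seq_len(nrow(norm))),
             s_score = s_score, g2m_score = g2m_score, phase = phase,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-cluster cell-cycle phase composition
#'
#' @param phases per-cell phase labels (G1/S/G2M).
#' @param labels aligned per-cell cluster labels.
#' @return Integer matrix clusters x phases (columns G1, S, G2M); row sums
#'   equal cluster sizes.
#' @export
phase_composition <- function(phases, labels) {
  stopifnot(length(phases) == length(labels))
  tab <- table(factor(labels), factor(phases, levels = c("G1", "S", "G2M")))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}
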