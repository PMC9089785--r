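# SNN-graph community detection with a resolution sweep, and one-vs-rest
# Wilcoxon marker detection.

#' Build a shared-nearest-neighbor graph over cells
#'
#' k-nearest neighbors by Euclidean distance in the embedding (neighbor sets
#' include the cell itself, so duplicated cells share identical sets); edge
#' weight between two cells is the Jaccard overlap of their neighbor sets;
#' weights below `prune` are dropped. Exact neighbor search, blocked to
#' bound memory.
#'
#' @param embedding numeric matrix, cells x dimensions.
#' @param k neighbors per cell including self (default 20; must be < cells).
#' @param prune Jaccard floor (default 1/15).
#' @return Undirected weighted [igraph::graph] with one vertex per cell
#'   (names from rownames).
#' @export
build_snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) .stop_fmt("k=%d must be smaller than the number of cells (%d)", k, n)
  sq <- rowSums(embedding^2)
  block <- max(1L, min(n, floor(2e7 / n)))
  nn <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- outer(sq[idx], sq, `+`) - 2 * tcrossprod(embedding[idx, , drop = FALSE],
                                                   embedding)
    d2[cbind(seq_along(idx), idx)] <- -Inf  # self always first
    nn[idx, ] <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
  }
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(adj)  # |N_i intersect N_j|
  inter <- methods::as(inter, "TsparseMatrix")
  keep <- inter@i < inter@j
  i <- inter@i[keep] + 1L
  j <- inter@j[keep] + 1L
  jac <- inter@x[keep] / (2 * k - inter@x[keep])
  ok <- jac >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  if (!is.null(rownames(embedding)))
    igraph::V(g)$name <- rownames(embedding)
  g
}

#' Seeded Louvain clustering at a given resolution
#'
#' Modularity community detection on the SNN graph; labels are relabeled
#' `0..K-1` by descending cluster size (ties by first occurrence) and are
#' deterministic given the seed.
#'
#' @param graph weighted undirected graph from [build_snn_graph()].
#' @param resolution modularity resolution parameter (> 0).
#' @param seed RNG seed.
#' @return Integer vector of labels, named by vertex name.
#' @export
louvain_cluster <- function(graph, resolution = 0.9, seed = 0L) {
  if (igraph::vcount(graph) == 0) .stop_fmt("empty graph")
  stopifnot(resolution > 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  raw <- igraph::membership(cl)
  sizes <- table(raw)
  new_ids <- rank(-as.vector(sizes), ties.method = "first") - 1L
  lab <- as.integer(new_ids[match(raw, as.integer(names(sizes)))])
  names(lab) <- igraph::V(graph)$name
  lab
}

#' Cluster across a grid of resolutions
#'
#' Runs seeded Louvain clustering at every grid point (shared seed) and
#' summarizes the clustering progression: cluster count per resolution plus
#' a parent-to-child crossover table — for each cluster at resolution r, the
#' fraction of its cells inherited by each cluster at the next resolution
#' (rows sum to 1).
#'
#' @param graph graph from [build_snn_graph()].
#' @param resolutions increasing grid (default 0.1 to 2.0 by 0.1).
#' @param seed RNG seed shared across grid points.
#' @return List of class `resolution_sweep`: `summary` (data.frame
#'   resolution, n_clusters), `labels` (matrix cells x resolutions),
#'   `crossover` (list of row-stochastic matrices, one per consecutive
#'   resolution pair).
#' @export
resolution_sweep <- function(graph, resolutions = seq(0.1, 2.0, by = 0.1),
                             seed = 0L) {
  stopifnot(length(resolutions) >= 1, all(diff(resolutions) > 0))
  labs <- sapply(resolutions, function(r) louvain_cluster(graph, r, seed))
  colnames(labs) <- sprintf("res_%g", resolutions)
  n_clusters <- apply(labs, 2, function(l) length(unique(l)))
  crossover <- list()
  if (length(resolutions) > 1) {
    for (i in seq_len(length(resolutions) - 1)) {
      tab <- table(labs[, i], labs[, i + 1])
      crossover[[sprintf("res_%g_to_%g", resolutions[i], resolutions[i + 1])]] <-
        tab / rowSums(tab)
    }
  }
  structure(list(
    summary = data.frame(resolution = resolutions,
                         n_clusters = as.integer(n_clusters)),
    labels = labs, crossover = crossover), class = "resolution_sweep")
}

#' @export
print.resolution_sweep <- function(x, ...) {
  cat("<resolution_sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For each cluster, each gene detected in at least `min_pct` of the cluster
#' or of the rest is tested with a two-sided Wilcoxon rank-sum (exact under
#' ties when both groups have <= 10 cells, tie-corrected normal otherwise).
#' Average log fold change is the difference of group means of the
#' log-normalized values. Rows are kept when `|avg_lfc| >= min_lfc` and
#' reported when the Bonferroni-adjusted p (over genes tested in that
#' cluster) is <= `max_adj_p`. Clusters with fewer than 3 cells are skipped
#' with a warning.
#'
#' @param norm real matrix cells x genes (log-normalized).
#' @param labels per-cell cluster labels.
#' @param min_pct detection fraction floor (default 0.10).
#' @param min_lfc absolute average log fold change floor (default 0.25).
#' @param max_adj_p adjusted-p ceiling for reporting (default 0.01).
#' @return data.frame: cluster, gene, avg_lfc, pct_in, pct_out, p, adj_p,
#'   ordered within cluster by adj_p then descending |avg_lfc|.
#' @export
find_markers <- function(norm, labels, min_pct = 0.10, min_lfc = 0.25,
                         max_adj_p = 0.01) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) .stop_fmt("need >= 2 clusters")
  norm <- as.matrix(norm)
  genes <- colnames(norm) %||% as.character(seq_len(ncol(norm)))
  out <- list()
  for (cl in sort(unique(labels))) {
    in_idx <- which(labels == cl)
    if (length(in_idx) < 3) {
      warning(sprintf("cluster '%s' has %d cells; skipped", cl,
                      length(in_idx)), call. = FALSE)
      next
    }
    out_idx <- which(labels != cl)
    pct_in <- colMeans(norm[in_idx, , drop = FALSE] > 0)
    pct_out <- colMeans(norm[out_idx, , drop = FALSE] > 0)
    tested <- which(pct_in >= min_pct | pct_out >= min_pct)
    if (!length(tested)) next
    lfc <- colMeans(norm[in_idx, tested, drop = FALSE]) -
      colMeans(norm[out_idx, tested, drop = FALSE])
    member <- seq_len(nrow(norm)) %in% in_idx
    use_exact <- length(in_idx) <= 10 && length(out_idx) <= 10
    p <- vapply(tested, function(gi)
      as.numeric(ranksum_p(norm[, gi], member, alternative = "two.sided",
                           exact_max_n = if (use_exact) 20 else 0)),
      0)
    adj <- pmin(1, p * length(tested))
    keep <- abs(lfc) >= min_lfc & adj <= max_adj_p
    if (!any(keep)) next
    df <- data.frame(cluster = cl, gene = genes[tested][keep],
                     avg_lfc = unname(lfc[keep]),
                     pct_in = unname(pct_in[tested][keep]),
                     pct_out = unname(pct_out[tested][keep]),
                     p = p[keep], adj_p = adj[keep],
                     stringsAsFactors = FALSE)
    out[[cl]] <- df[order(df$adj_p, -abs(df$avg_lfc)), ]
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = character(), gene = character(),
               avg_lfc = numeric(), pct_in = numeric(), pct_out = numeric(),
               p = numeric(), adj_p = numeric())
  rownames(res) <- NULL
  res
}
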