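# Hashtag demultiplexing, QC filtering, normalization, variable-gene
# selection, covariate regression/scaling, and PCA — everything between the
# raw count tables and the clustering input.

#' Centered log-ratio normalization of HTO counts
#'
#' Per cell: `ln(1 + c_j) - mean_j ln(1 + c_j)`. Every row means 0; an
#' all-zero cell stays all-zero. Computed for reporting; singlet calling
#' itself uses raw UMI fractions (see [call_singlets()]).
#'
#' @param hto integer matrix cells x hashtags.
#' @return Real matrix of the same shape.
#' @export
clr_normalize_hto <- function(hto) {
  l <- log1p(hto)
  sweep(l, 1, rowMeans(l), `-`)
}

#' Call singlets, doublets and negatives from HTO counts
#'
#' A cell is a singlet when a single hashtag carries strictly more than
#' `singlet_threshold` of its total HTO UMIs (the "more than 70 percent"
#' rule, applied to raw fractions); otherwise a doublet. Cells with fewer
#' than `min_total` total HTO UMIs are uncallable and flagged negative.
#'
#' @param hto integer matrix cells x hashtags (>= 2 hashtags).
#' @param singlet_threshold strict lower bound on the top hashtag's fraction.
#' @param min_total minimum total HTO UMIs for a call.
#' @return data.frame: barcode, call (`singlet`/`doublet`/`negative`),
#'   hashtag (NA unless singlet), max_fraction, total.
#' @export
call_singlets <- function(hto, singlet_threshold = 0.70, min_total = 10) {
  stopifnot(ncol(hto) >= 2)
  total <- rowSums(hto)
  top <- max.col(hto, ties.method = "first")
  max_frac <- ifelse(total > 0, hto[cbind(seq_len(nrow(hto)), top)] / total, 0)
  call <- ifelse(total < min_total, "negative",
                 ifelse(max_frac > singlet_threshold, "singlet", "doublet"))
  data.frame(
    barcode = rownames(hto) %||% as.character(seq_len(nrow(hto))),
    call = call,
    hashtag = ifelse(call == "singlet", colnames(hto)[top], NA_character_),
    max_fraction = max_frac, total = total,
    stringsAsFactors = FALSE)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Removes cells detecting fewer than `min_genes` genes or with a
#' mitochondrial UMI fraction strictly greater than `max_mito_frac`
#' (a fraction of exactly 0.10 is kept — "greater than 10 percent" is
#' strict).
#'
#' @param x an [sc_counts] object.
#' @param mito_genes feature ids or symbols of mitochondrial genes; by
#'   default genes whose symbol starts with `mt-` (case-insensitive).
#' @param min_genes minimum detected genes (default 200; "fewer than 200"
#'   removes a 199-gene cell).
#' @param max_mito_frac strict upper bound on the mito UMI fraction.
#' @return List: `counts` (filtered [sc_counts]), `report` (data.frame with
#'   kept/removed counts by reason), `kept` (logical per input cell),
#'   `qc` (per-cell n_genes and mito_frac).
#' @export
qc_filter <- function(x, mito_genes = NULL, min_genes = 200,
                      max_mito_frac = 0.10) {
  stopifnot(inherits(x, "sc_counts"))
  m <- x$counts
  if (is.null(mito_genes)) {
    mito_idx <- grep("^mt-", x$features$symbol, ignore.case = TRUE)
  } else {
    mito_idx <- which(x$features$id %in% mito_genes |
                        x$features$symbol %in% mito_genes)
  }
  n_genes <- Matrix::rowSums(m > 0)
  tot <- Matrix::rowSums(m)
  mito <- if (length(mito_idx))
    Matrix::rowSums(m[, mito_idx, drop = FALSE]) else rep(0, nrow(m))
  mito_frac <- ifelse(tot > 0, mito / tot, 0)
  low_genes <- n_genes < min_genes
  high_mito <- mito_frac > max_mito_frac
  kept <- !low_genes & !high_mito
  if (!any(kept))
    warning("no cells survive QC filtering", call. = FALSE)
  report <- data.frame(
    reason = c("kept", "low_genes", "high_mito", "both"),
    cells = c(sum(kept), sum(low_genes & !high_mito),
              sum(high_mito & !low_genes), sum(low_genes & high_mito)))
  out <- sc_counts(m[kept, , drop = FALSE], barcodes = x$barcodes[kept],
                   features = x$features)
  list(counts = out, report = report, kept = kept,
       qc = data.frame(barcode = x$barcodes, n_genes = as.integer(n_genes),
                       mito_frac = mito_frac, stringsAsFactors = FALSE))
}

#' Log-normalize UMI counts
#'
#' `log_base(1 + count / cell_total * scale_factor)`; scale-invariant within
#' a cell and monotone in count. Default base 2, scale factor 10,000.
#'
#' @param x an [sc_counts] object with no all-zero cells (post-QC).
#' @param scale_factor library-size scale (default 10,000).
#' @param log_base logarithm base (default 2).
#' @return Sparse real matrix, cells x genes, dimnames barcode x gene id.
#' @export
log_normalize <- function(x, scale_factor = 10000, log_base = 2) {
  stopifnot(inherits(x, "sc_counts"))
  tot <- Matrix::rowSums(x$counts)
  if (any(tot == 0))
    .stop_fmt("all-zero cell(s) present; run qc_filter first")
  m <- x$counts
  # operate on the sparse slots directly: zeros map to zero
  mT <- methods::as(Matrix::t(m), "CsparseMatrix")  # genes x cells for slot math
  cell_of <- rep(seq_len(ncol(mT)), diff(mT@p))
  mT@x <- log1p(mT@x / tot[cell_of] * scale_factor) / log(log_base)
  out <- Matrix::t(mT)
  dimnames(out) <- dimnames(m)
  out
}

#' Select variable genes by binned dispersion
#'
#' Per gene, mean and dispersion `log(variance/mean)` of the normalized
#' values; genes are grouped into `n_bins` equal-frequency bins by mean and
#' the dispersion z-scored within each bin. Genes with z >= `z_min` and mean
#' inside `mean_bounds` are returned ordered by descending z. A bin with a
#' single gene (or zero dispersion spread) gets z = 0.
#'
#' @param norm sparse or dense real matrix, cells x genes.
#' @param n_bins number of mean-expression bins (default 20).
#' @param z_min dispersion z-score cutoff (default 1.0).
#' @param mean_bounds allowed (min, max) mean expression (default 0.1, 8).
#' @return Character vector of selected gene ids (descending z), with the
#'   full per-gene table in attribute `stats`.
#' @export
select_variable_genes <- function(norm, n_bins = 20, z_min = 1.0,
                                  mean_bounds = c(0.1, 8)) {
  mu <- Matrix::colMeans(norm)
  ex2 <- Matrix::colMeans(norm^2)
  n <- nrow(norm)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), NA_real_)
  ok <- !is.na(disp)
  if (sum(ok) < n_bins)
    .stop_fmt("need >= %d genes with nonzero mean, have %d", n_bins, sum(ok))
  # equal-frequency bins over genes with defined dispersion; ties broken by
  # gene order via rank(ties.method = "first")
  bin <- rep(NA_integer_, length(mu))
  r <- rank(mu[ok], ties.method = "first")
  bin[ok] <- as.integer(ceiling(r / (sum(ok) / n_bins)))
  z <- rep(NA_real_, length(mu))
  for (b in unique(bin[ok])) {
    idx <- which(!is.na(bin) & bin == b)
    if (length(idx) < 2 || stats::sd(disp[idx]) == 0) {
      z[idx] <- 0
    } else {
      z[idx] <- (disp[idx] - mean(disp[idx])) / stats::sd(disp[idx])
    }
  }
  sel <- which(!is.na(z) & z >= z_min & mu >= mean_bounds[1] &
                 mu <= mean_bounds[2])
  sel <- sel[order(z[sel], decreasing = TRUE)]
  ids <- colnames(norm)[sel] %||% as.character(sel)
  attr(ids, "stats") <- data.frame(
    gene = colnames(norm) %||% as.character(seq_along(mu)),
    mean = mu, dispersion = disp, bin = bin, z = z,
    selected = seq_along(mu) %in% sel, stringsAsFactors = FALSE)
  ids
}

#' Compute standard per-cell covariates for regression
#'
#' Total UMI, mitochondrial fraction, and ribosomal / hemoglobin content
#' scores, the latter defined as the fraction of the cell's UMIs falling in
#' genes whose symbol matches the respective prefixes (configurable; the
#' score definition is a package choice — see the methods vignette).
#'
#' @param x an [sc_counts] object.
#' @param ribo_prefixes,hb_prefixes,mito_prefix symbol prefix sets.
#' @return data.frame: barcode, total_umi, mito_frac, ribo_score, hb_score.
#' @export
cell_covariates <- function(x, ribo_prefixes = c("Rps", "Rpl"),
                            hb_prefixes = c("Hba", "Hbb"),
                            mito_prefix = "mt-") {
  m <- x$counts
  tot <- Matrix::rowSums(m)
  frac_for <- function(prefixes) {
    idx <- grep(paste0("^(", paste(prefixes, collapse = "|"), ")"),
                x$features$symbol, ignore.case = TRUE)
    if (!length(idx)) return(rep(0, nrow(m)))
    ifelse(tot > 0, Matrix::rowSums(m[, idx, drop = FALSE]) / tot, 0)
  }
  data.frame(barcode = x$barcodes, total_umi = as.numeric(tot),
             mito_frac = frac_for(mito_prefix),
             ribo_score = frac_for(ribo_prefixes),
             hb_score = frac_for(hb_prefixes), stringsAsFactors = FALSE)
}

#' Regress out covariates and z-scale genes
#'
#' Per gene: ordinary least squares of normalized expression on the
#' covariates (with intercept); residuals are z-scored per gene and clipped
#' to `±clip`. Zero-variance covariates are dropped with a warning;
#' remaining rank deficiency is tolerated through the QR solve.
#'
#' @param norm real matrix cells x genes (restricted to variable genes).
#' @param covariates data.frame or matrix of per-cell covariates (finite).
#' @param clip clip bound on the scaled values (default 10).
#' @return Dense matrix of clipped z-scores, attribute `dropped_covariates`.
#' @export
regress_and_scale <- function(norm, covariates, clip = 10) {
  Y <- as.matrix(norm)
  X <- as.matrix(covariates[, setdiff(colnames(covariates), "barcode"),
                            drop = FALSE])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) .stop_fmt("covariates must be finite")
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    warning("dropping zero-variance covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  X <- cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
  qr_x <- qr(X)
  res <- qr.resid(qr_x, Y)
  mu <- colMeans(res)
  sd <- apply(res, 2, stats::sd)
  # genes fully explained by the covariates (or constant) scale to zero,
  # not to rescaled numerical noise
  vy <- apply(Y, 2, stats::var)
  degenerate <- vy <= 0 | sd^2 <= 1e-12 * vy
  sd[degenerate] <- Inf
  z <- sweep(sweep(res, 2, mu, `-`), 2, sd, `/`)
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  attr(z, "dropped_covariates") <- dropped
  z
}

#' Principal component embedding of the scaled matrix
#'
#' Exact PCA via the eigendecomposition of the smaller-dimension covariance
#' (equivalent to truncated SVD). Emits the per-component variance for elbow
#' inspection; component variances are non-increasing.
#'
#' @param scaled dense matrix cells x genes (already centered/scaled).
#' @param n_components number of components (default 50, capped by
#'   `min(dim) - 1`; larger requests are an error).
#' @return List of class `pca_embedding`: `embedding` (cells x components),
#'   `sdev` (component standard deviations), `var_explained`, `rotation`.
#' @export
run_pca <- function(scaled, n_components = 50) {
  scaled <- as.matrix(scaled)
  if (n_components > min(dim(scaled)))
    .stop_fmt("n_components=%d exceeds min(dim)=%d", n_components,
              min(dim(scaled)))
  ctr <- sweep(scaled, 2, colMeans(scaled), `-`)
  n <- nrow(ctr)
  if (ncol(ctr) <= n) {
    cv <- crossprod(ctr) / (n - 1)
    eig <- eigen(cv, symmetric = TRUE)
    k <- n_components
    rot <- eig$vectors[, seq_len(k), drop = FALSE]
    emb <- ctr %*% rot
    sdev <- sqrt(pmax(eig$values[seq_len(k)], 0))
  } else {
    gram <- tcrossprod(ctr) / (n - 1)
    eig <- eigen(gram, symmetric = TRUE)
    k <- n_components
    vals <- pmax(eig$values[seq_len(k)], 0)
    u <- eig$vectors[, seq_len(k), drop = FALSE]
    emb <- u %*% diag(sqrt(vals * (n - 1)), k)
    rot <- crossprod(ctr, u) %*% diag(1 / sqrt(pmax(vals * (n - 1), 1e-300)), k)
    sdev <- sqrt(vals)
  }
  rownames(emb) <- rownames(scaled)
  colnames(emb) <- paste0("PC", seq_len(ncol(emb)))
  structure(list(embedding = emb, sdev = sdev,
                 var_explained = sdev^2 / sum(apply(ctr, 2, stats::var)),
                 rotation = rot),
            class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf("<pca_embedding> %d cells x %d components; top-5 var: %s\n",
              nrow(x$embedding), ncol(x$embedding),
              paste(sprintf("%.1f%%", 100 * utils::head(x$var_explained, 5)),
                    collapse = " ")))
  invisible(x)
}
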