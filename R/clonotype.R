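# TCR chain filtering, clonotype calling at nucleotide CDR3 resolution, and
# clone-frequency tiering including the top-quartile high-frequency
# threshold.

#' Filter barcodes to productive single alpha/beta pairs
#'
#' Nonproductive contigs are removed first; a barcode is then kept only when
#' exactly one TRA and exactly one TRB contig remain. Exclusions are counted
#' by reason (no alpha, no beta, multiple alpha, multiple beta).
#'
#' @param contigs data.frame from [read_contigs()] (columns barcode, chain,
#'   productive, cdr3_nt; `productive` logical or "True"/"False").
#' @return data.frame: barcode, cdr3_nt_a, cdr3_nt_b; attribute `report`
#'   (data.frame reason/barcodes) counts exclusions.
#' @export
filter_productive_pairs <- function(contigs) {
  prod <- if (is.logical(contigs$productive)) contigs$productive
          else as.character(contigs$productive) %in% c("True", "true", "TRUE")
  keep <- contigs[prod & contigs$chain %in% c("TRA", "TRB"), , drop = FALSE]
  all_bc <- unique(contigs$barcode)
  n_a <- table(factor(keep$barcode[keep$chain == "TRA"], levels = all_bc))
  n_b <- table(factor(keep$barcode[keep$chain == "TRB"], levels = all_bc))
  reason <- ifelse(n_a == 0, "no_alpha",
            ifelse(n_b == 0, "no_beta",
            ifelse(n_a > 1, "multi_alpha",
            ifelse(n_b > 1, "multi_beta", "kept"))))
  kept_bc <- all_bc[reason == "kept"]
  a <- keep[keep$chain == "TRA", ]
  b <- keep[keep$chain == "TRB", ]
  out <- data.frame(
    barcode = kept_bc,
    cdr3_nt_a = a$cdr3_nt[match(kept_bc, a$barcode)],
    cdr3_nt_b = b$cdr3_nt[match(kept_bc, b$barcode)],
    stringsAsFactors = FALSE)
  rep_tab <- as.data.frame(table(reason), stringsAsFactors = FALSE)
  names(rep_tab) <- c("reason", "barcodes")
  attr(out, "report") <- rep_tab
  out
}

#' Call clonotypes by exact paired-CDR3 nucleotide identity
#'
#' Barcodes are partitioned by exact string equality of the
#' (alpha cdr3_nt, beta cdr3_nt) pair. Clone ids are ordered by descending
#' size, ties by first occurrence. Sum of clone sizes equals the number of
#' input barcodes.
#'
#' @param pairs data.frame from [filter_productive_pairs()].
#' @return List of class `clonotype_set`: `clonotypes` (data.frame
#'   clone_id, cdr3_nt_a, cdr3_nt_b, size), `cells` (data.frame barcode,
#'   clone_id).
#' @export
call_clonotypes <- function(pairs) {
  key <- paste(pairs$cdr3_nt_a, pairs$cdr3_nt_b, sep = "|")
  sizes <- table(key)
  ord <- order(-as.vector(sizes), match(names(sizes), key))
  keys <- names(sizes)[ord]
  clone_id <- match(key, keys)
  first <- match(keys, key)
  clonotypes <- data.frame(
    clone_id = seq_along(keys),
    cdr3_nt_a = pairs$cdr3_nt_a[first],
    cdr3_nt_b = pairs$cdr3_nt_b[first],
    size = as.integer(sizes[ord]),
    stringsAsFactors = FALSE)
  structure(list(
    clonotypes = clonotypes,
    cells = data.frame(barcode = pairs$barcode, clone_id = clone_id,
                       stringsAsFactors = FALSE)),
    class = "clonotype_set")
}

#' @export
print.clonotype_set <- function(x, ...) {
  cat(sprintf("<clonotype_set> %d clonotypes over %d cells (largest %d)\n",
              nrow(x$clonotypes), nrow(x$cells), max(x$clonotypes$size)))
  invisible(x)
}

#' Compute the high-frequency (top-quartile) clone-size threshold
#'
#' Cell-weighted (default): cumulate cells over clones from the largest size
#' down; the threshold is the smallest observed clone size s such that cells
#' in clones of size >= s comprise at most 25 percent of all cells.
#' Clone-weighted alternative: the 75th percentile of clone sizes. Either
#' way the threshold is floored at 5 so the high tier never absorbs the
#' moderate tier's lower bound. All clones of size 1 gives an infinite
#' threshold (no high tier) with a warning.
#'
#' @param x a `clonotype_set` or an integer vector of clone sizes.
#' @param basis `"cell_weighted"` or `"clone_weighted"`.
#' @param quantile_cells top cell-mass quantile (default 0.25).
#' @return List of class `tier_threshold`: `high_threshold`, `basis`.
#' @export
compute_high_threshold <- function(x, basis = c("cell_weighted",
                                                "clone_weighted"),
                                   quantile_cells = 0.25) {
  basis <- match.arg(basis)
  sizes <- if (inherits(x, "clonotype_set")) x$clonotypes$size else as.integer(x)
  if (!length(sizes)) .stop_fmt("no clonotypes")
  if (all(sizes == 1)) {
    warning("all clones are singletons; no high-frequency tier", call. = FALSE)
    return(structure(list(high_threshold = Inf, basis = basis),
                     class = "tier_threshold"))
  }
  thr <- if (basis == "cell_weighted") {
    n_cells <- sum(sizes)
    us <- sort(unique(sizes), decreasing = TRUE)
    cum <- cumsum(vapply(us, function(s) sum(sizes[sizes == s]), 0))
    frac <- cum / n_cells
    ok <- which(frac <= quantile_cells)
    if (!length(ok)) max(sizes) else us[max(ok)]
  } else {
    ceiling(stats::quantile(sizes, 1 - quantile_cells, names = FALSE))
  }
  structure(list(high_threshold = max(5, thr), basis = basis),
            class = "tier_threshold")
}

#' Assign frequency tiers to clonotypes
#'
#' unique = size 1; shared = 2 to 4; moderate = more than 4 but below the
#' high threshold; high = at or above it. Every clonotype gets exactly one
#' tier.
#'
#' @param cs a `clonotype_set`.
#' @param threshold a `tier_threshold` from [compute_high_threshold()] (or a
#'   number).
#' @return `cs` with a `tier` column added to `$clonotypes` and `$cells`,
#'   plus `$high_threshold`.
#' @export
assign_tiers <- function(cs, threshold) {
  stopifnot(inherits(cs, "clonotype_set"))
  thr <- if (inherits(threshold, "tier_threshold"))
    threshold$high_threshold else threshold
  if (!is.infinite(thr) && thr < 5)
    .stop_fmt("high threshold must be >= 5 (moderate tier lower bound)")
  sz <- cs$clonotypes$size
  tier <- ifelse(sz == 1, "unique",
          ifelse(sz <= 4, "shared",
          ifelse(sz < thr, "moderate", "high")))
  cs$clonotypes$tier <- tier
  cs$cells$tier <- tier[cs$cells$clone_id]
  cs$high_threshold <- thr
  cs
}
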