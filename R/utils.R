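`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Open a path transparently, decompressing by extension
#'
#' Returns a local, uncompressed copy of `path` (the original path when it is
#' already plain text). Used so readers that cannot take connections (e.g.
#' [Matrix::readMM()]) still accept `.gz` files.
#' @keywords internal
.materialize <- function(path) {
  if (!file.exists(path)) .stop_fmt("file not found: '%s'", path)
  if (!grepl("\\.gz$", path)) return(path)
  out <- tempfile(fileext = sub("\\.gz$", "", basename(path)))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "raw", n = 512L * 1024L^2)
  writeBin(raw, out)
  out
}

#' Find the first existing variant of a 10x sidecar file
#' @keywords internal
.find_sidecar <- function(dir, stems) {
  for (s in stems) for (ext in c("", ".gz")) {
    p <- file.path(dir, paste0(s, ext))
    if (file.exists(p)) return(p)
  }
  .stop_fmt("none of [%s] found in '%s'", paste(stems, collapse = ", "), dir)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells; 1 for
#' identical partitions (up to label names), ~0 for independent ones. Used to
#' grade cluster recovery against ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return A number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Derive a bounded sub-seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
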