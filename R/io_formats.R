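# Readers and writers for the external formats the pipeline consumes and
# emits: 10x-style Matrix Market count directories, hashtag (HTO) count CSVs,
# 10x filtered_contig_annotations.csv TCR tables, GMT gene signatures, and the
# TSV/JSON results bundle. No scientific computation lives here.

#' Construct a cells-by-genes UMI count container
#'
#' Light S3 wrapper around a sparse cells x genes matrix plus a feature table.
#' Counts must be nonnegative integers; barcodes and feature ids unique.
#'
#' @param counts matrix or sparse Matrix, cells x genes.
#' @param barcodes character vector of cell barcodes (defaults to rownames).
#' @param features data.frame with columns `id` and `symbol` (defaults to
#'   colnames for both).
#' @return An object of class `sc_counts` with elements `counts` (dgCMatrix,
#'   cells x genes, dimnames barcodes x feature ids), `barcodes`, `features`.
#' @export
sc_counts <- function(counts, barcodes = NULL, features = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  barcodes <- barcodes %||% rownames(counts)
  if (is.null(features)) {
    features <- data.frame(id = colnames(counts), symbol = colnames(counts),
                           stringsAsFactors = FALSE)
  }
  if (is.null(barcodes)) .stop_fmt("barcodes required (no rownames on counts)")
  if (nrow(counts) != length(barcodes))
    .stop_fmt("integrity error: %d matrix rows vs %d barcodes",
              nrow(counts), length(barcodes))
  if (ncol(counts) != nrow(features))
    .stop_fmt("integrity error: %d matrix columns vs %d features",
              ncol(counts), nrow(features))
  if (anyDuplicated(barcodes)) .stop_fmt("duplicate barcodes")
  if (anyDuplicated(features$id)) .stop_fmt("duplicate feature ids")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    .stop_fmt("counts must be nonnegative integers")
  dimnames(counts) <- list(barcodes, features$id)
  structure(list(counts = counts, barcodes = barcodes, features = features),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %d cells x %d genes, %d nonzero\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Read a 10x-style Matrix Market count directory
#'
#' Expects `matrix.mtx[.gz]` plus barcode and feature sidecars
#' (`barcodes.tsv[.gz]`, `features.tsv[.gz]` or `genes.tsv[.gz]`). Feature
#' files with 2 (id, symbol) or 3 (id, symbol, type) columns are both
#' accepted. On-disk orientation (10x writes genes x cells) is auto-detected
#' by comparing matrix dimensions with sidecar lengths; a square matrix with
#' equal sidecars requires an explicit `orientation`.
#'
#' @param dir directory with the three files, plain or gzip.
#' @param orientation `"auto"` (default), `"genes_by_cells"`, or
#'   `"cells_by_genes"`.
#' @return An [sc_counts] object (always cells x genes in memory).
#' @export
read_count_matrix <- function(dir,
                              orientation = c("auto", "genes_by_cells",
                                              "cells_by_genes")) {
  orientation <- match.arg(orientation)
  mtx <- .find_sidecar(dir, "matrix.mtx")
  bc_path <- .find_sidecar(dir, "barcodes.tsv")
  ft_path <- .find_sidecar(dir, c("features.tsv", "genes.tsv"))
  m <- Matrix::readMM(.materialize(mtx))
  barcodes <- readLines(bc_path)  # readLines handles .gz transparently
  ft <- utils::read.table(ft_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(ft) < 2) ft$V2 <- ft$V1
  features <- data.frame(id = ft[[1]], symbol = ft[[2]],
                         stringsAsFactors = FALSE)
  nb <- length(barcodes); nf <- nrow(features)
  flip <- switch(orientation,
    genes_by_cells = TRUE,
    cells_by_genes = FALSE,
    auto = {
      if (nrow(m) == nf && ncol(m) == nb && !(nb == nf)) TRUE
      else if (nrow(m) == nb && ncol(m) == nf && !(nb == nf)) FALSE
      else if (nb == nf && nrow(m) == nb && ncol(m) == nb)
        .stop_fmt(paste("square matrix with equal sidecars: orientation is",
                        "ambiguous, pass `orientation` explicitly"))
      else .stop_fmt(
        "integrity error: matrix %dx%d matches neither %d barcodes x %d features orientation",
        nrow(m), ncol(m), nb, nf)
    })
  if (flip) m <- Matrix::t(m)
  if (nrow(m) != nb || ncol(m) != nf)
    .stop_fmt("integrity error: matrix %dx%d vs %d barcodes / %d features",
              nrow(m), ncol(m), nb, nf)
  sc_counts(m, barcodes = barcodes, features = features)
}

#' Write an [sc_counts] object as a 10x-style directory
#'
#' Writes `matrix.mtx` in the 10x genes x cells orientation with
#' `barcodes.tsv` and `features.tsv` (3 columns, type "Gene Expression").
#'
#' @param x an [sc_counts] object.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "sc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(x$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(x$features$id, x$features$symbol, "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a cells-by-hashtag HTO count table
#'
#' CSV with a leading barcode column and one column per hashtag.
#'
#' @param path CSV path (plain or gzip).
#' @return Integer matrix cells x hashtags with barcode rownames.
#' @export
read_hto_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3) .stop_fmt("HTO table needs a barcode column and >= 2 hashtags")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0)) .stop_fmt("HTO counts must be nonnegative integers")
  rownames(m) <- df[[1]]
  m
}

#' Write an HTO count matrix as CSV
#' @param m integer matrix cells x hashtags, barcode rownames.
#' @param path output CSV path.
#' @export
write_hto_counts <- function(m, path) {
  df <- data.frame(barcode = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 10x `filtered_contig_annotations.csv` TCR contig table
#'
#' Keeps TRA/TRB rows only; other chains (TRG, TRD, IGH, ...) are dropped and
#' counted. The 10x `productive` dialect ("True"/"False"/"None") is mapped to
#' logical, "None" meaning not productive.
#'
#' @param path CSV with at least columns barcode, chain, productive, cdr3,
#'   cdr3_nt.
#' @return data.frame with columns barcode, chain, productive, cdr3_aa,
#'   cdr3_nt; attributes `n_input` (input rows) and `n_dropped_chain`
#'   (non-alpha/beta rows removed). retained + dropped = input rows.
#' @export
read_contigs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("barcode", "chain", "productive", "cdr3", "cdr3_nt")
  miss <- setdiff(req, names(df))
  if (length(miss))
    .stop_fmt("contig table missing required column(s): %s",
              paste(miss, collapse = ", "))
  n_in <- nrow(df)
  keep <- df$chain %in% c("TRA", "TRB")
  n_drop <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  prod <- as.character(df$productive) %in% c("True", "true", "TRUE")
  out <- data.frame(barcode = df$barcode, chain = df$chain,
                    productive = prod, cdr3_aa = df$cdr3,
                    cdr3_nt = df$cdr3_nt, stringsAsFactors = FALSE)
  if (any(out$productive & (is.na(out$cdr3_nt) | out$cdr3_nt == "")))
    .stop_fmt("productive contig with empty cdr3_nt")
  attr(out, "n_input") <- n_in
  attr(out, "n_dropped_chain") <- n_drop
  out
}

#' Write a contig table in the 10x CSV dialect
#' @param contigs data.frame as returned by [read_contigs()].
#' @param path output CSV path.
#' @export
write_contigs <- function(contigs, path) {
  aa <- contigs$cdr3_aa %||% contigs$cdr3
  prod <- if (is.logical(contigs$productive)) contigs$productive
          else as.character(contigs$productive) %in% c("True", "true", "TRUE")
  df <- data.frame(barcode = contigs$barcode, chain = contigs$chain,
                   productive = ifelse(prod, "True", "False"),
                   cdr3 = aa, cdr3_nt = contigs$cdr3_nt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then genes. Genes repeated
#' within a line are deduplicated (first occurrence kept).
#'
#' @param path GMT path (plain or gzip).
#' @return Named list of character vectors, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      .stop_fmt("GMT line %d has %d field(s); need name, description, >=1 gene",
                i, length(parts))
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) .stop_fmt("GMT line %d has no genes", i)
    sigs[[parts[[1]]]] <- genes
  }
  sigs
}

#' Restrict a signature to genes present in a count matrix
#'
#' Matches on gene symbol. Absent genes are dropped with a warning; the
#' retained fraction is recorded.
#'
#' @param genes character vector of gene symbols.
#' @param x an [sc_counts] object (or a character vector of symbols).
#' @param name signature name for messages.
#' @return The retained symbols with attribute `retained_fraction`.
#' @export
match_signature <- function(genes, x, name = "signature") {
  universe <- if (inherits(x, "sc_counts")) x$features$symbol else x
  kept <- intersect(genes, universe)
  if (!length(kept))
    .stop_fmt("signature '%s' has no genes in the matrix", name)
  if (length(kept) < length(genes))
    warning(sprintf("signature '%s': %d/%d genes absent from matrix, dropped",
                    name, length(genes) - length(kept), length(genes)),
            call. = FALSE)
  attr(kept, "retained_fraction") <- length(kept) / length(genes)
  kept
}

#' Write a results bundle to disk
#'
#' Data frames are written as TSV, everything else as JSON; a `manifest.json`
#' lists every file with its row count (JSON entries get `NA` rows). Column
#' order of each table is preserved as given (deterministic).
#'
#' @param bundle named list of data.frames and/or lists.
#' @param dir output directory, created if needed.
#' @return The manifest as a data.frame (file, format, rows), invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(is.list(bundle))
  if (length(bundle) && is.null(names(bundle)))
    .stop_fmt("bundle entries must be named")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), format = character(),
                         rows = integer(), stringsAsFactors = FALSE)
  for (nm in names(bundle)) {
    obj <- bundle[[nm]]
    if (is.data.frame(obj)) {
      f <- paste0(nm, ".tsv")
      utils::write.table(obj, file.path(dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest <- rbind(manifest, data.frame(file = f, format = "tsv",
                                             rows = nrow(obj)))
    } else {
      f <- paste0(nm, ".json")
      jsonlite::write_json(obj, file.path(dir, f), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
      manifest <- rbind(manifest, data.frame(file = f, format = "json",
                                             rows = NA_integer_))
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
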