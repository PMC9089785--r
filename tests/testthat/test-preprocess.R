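test_that("CLR normalization matches its closed form", {
  hto <- rbind(c(0, 0, 0), c(4, 4, 4), c(7, 1, 0))
  clr <- clr_normalize_hto(hto)
  expect_equal(clr[1, ], c(0, 0, 0))
  expect_equal(clr[2, ], c(0, 0, 0))
  m <- (log(8) + log(2) + log(1)) / 3
  expect_equal(clr[3, ], c(log(8) - m, log(2) - m, -m))
  expect_equal(rowMeans(clr), rep(0, 3))
})

test_that("singlet calling applies the strict 70% rule and negative floor", {
  hto <- rbind(c(8, 1, 1),    # 0.8  -> singlet on hashtag 1
               c(6, 4, 0),    # 0.6  -> doublet
               c(7, 3, 0),    # 0.70 exactly -> doublet (strict)
               c(5, 1, 0),    # total 6 < 10 -> negative
               c(0, 96, 4))   # singlet on hashtag 2
  colnames(hto) <- paste0("HTO", 1:3)
  calls <- call_singlets(hto)
  expect_identical(calls$call,
                   c("singlet", "doublet", "doublet", "negative", "singlet"))
  expect_identical(calls$hashtag[c(1, 5)], c("HTO1", "HTO2"))
  expect_equal(calls$max_fraction[3], 0.7)
  # partition: every cell gets exactly one call
  expect_equal(sum(table(calls$call)), nrow(hto))
})

test_that("QC boundaries are exact and the filter is idempotent", {
  n_genes <- 250
  m <- matrix(0L, 5, n_genes)
  syms <- c(paste0("mt-G", 1:5), sprintf("g%03d", seq_len(n_genes - 5)))
  m[1, 6:204] <- 1L                 # 199 detected genes -> removed
  m[2, 6:205] <- 1L                 # 200 detected genes -> kept
  m[3, 6:250] <- 4L                 # kept: big cell, no mito
  m[4, 6:185] <- 1L; m[4, 1:5] <- 4L  # 185 genes -> removed (low genes)
  # cell 5: mito fraction exactly 30/300 = 0.10 -> kept (strict rule)
  m[5, 1] <- 30L; m[5, 6:245] <- 1L; m[5, 246:250] <- 6L
  rownames(m) <- paste0("c", 1:5)
  colnames(m) <- sprintf("id%03d", seq_len(n_genes))
  x <- sc_counts(m, features = data.frame(id = colnames(m), symbol = syms))
  res <- qc_filter(x)
  expect_equal(res$qc$mito_frac[5], 0.10)
  expect_identical(res$counts$barcodes, c("c2", "c3", "c5"))
  expect_equal(sum(res$report$cells[res$report$reason != "kept"]), 2)
  # idempotence
  res2 <- qc_filter(res$counts)
  expect_identical(res2$counts$barcodes, res$counts$barcodes)
  # mito fraction strictly above 0.10 is removed
  m[5, 1] <- 31L
  x2 <- sc_counts(m, features = x$features)
  expect_false("c5" %in% qc_filter(x2)$counts$barcodes)
})

test_that("log normalization has the stated closed form and invariances", {
  m <- rbind(c(10L, 0L, 0L), c(3L, 5L, 2L))
  rownames(m) <- c("a", "b"); colnames(m) <- c("g1", "g2", "g3")
  x <- sc_counts(m)
  norm <- as.matrix(log_normalize(x))
  expect_equal(norm["a", "g2"], 0)
  expect_equal(norm["a", "g1"], log2(1 + 10000))  # count == cell total
  # doubling all counts in a cell changes nothing
  x2 <- sc_counts(2L * m)
  expect_equal(as.matrix(log_normalize(x2)), norm)
  # monotone within a cell
  expect_true(all(diff(order(norm["b", ])) ==
                    diff(order(m[2, ]))))
  x0 <- sc_counts(rbind(m, c(0L, 0L, 0L)),
                  barcodes = c("a", "b", "zero"),
                  features = x$features)
  expect_error(log_normalize(x0), "all-zero")
})

test_that("variable-gene selection finds planted dispersion and is order-invariant", {
  set.seed(11)
  n <- 200; g <- 100
  norm <- matrix(rnorm(n * g, mean = 2, sd = 0.3), n, g)
  norm[norm < 0] <- 0
  norm[, 37] <- rnorm(n, mean = 2, sd = sqrt(10) * 0.3)  # 10x variance
  colnames(norm) <- sprintf("g%03d", 1:g)
  sel <- select_variable_genes(norm, z_min = 1.0, mean_bounds = c(0.1, 8))
  expect_true("g037" %in% sel)
  st <- attr(sel, "stats")
  expect_equal(st$gene[which.max(st$z)], "g037")
  # permutation invariance (as a set)
  perm <- sample(g)
  sel_p <- select_variable_genes(norm[, perm], z_min = 1.0)
  expect_setequal(sel_p, sel)
  # no dispersion signal -> empty selection
  flat <- matrix(rep(1:200 / 100, g), n, g,
                 dimnames = list(NULL, colnames(norm)))
  expect_length(select_variable_genes(flat), 0)
})

test_that("covariate regression leaves orthogonal, scaled, clipped residuals", {
  set.seed(21)
  n <- 120
  cov <- data.frame(total_umi = runif(n, 500, 3000),
                    mito_frac = runif(n, 0, 0.1))
  y1 <- 0.002 * cov$total_umi                      # exactly linear -> zeroed
  y2 <- rnorm(n) + 0.001 * cov$total_umi
  Y <- cbind(lin = y1, noisy = y2, flat = rep(2, n))
  z <- regress_and_scale(Y, cov, clip = 10)
  expect_equal(unname(z[, "lin"]), rep(0, n))
  expect_equal(unname(z[, "flat"]), rep(0, n))
  # OLS normal equations: residuals orthogonal to each covariate
  expect_lt(abs(sum(z[, "noisy"] * (cov$total_umi - mean(cov$total_umi)))),
            1e-6 * n * sd(cov$total_umi))
  expect_equal(mean(z[, "noisy"]), 0, tolerance = 1e-10)
  expect_equal(sd(z[, "noisy"]), 1, tolerance = 1e-10)
  expect_true(all(abs(z) <= 10))
  # zero-variance covariates drop to a plain z-score
  cov0 <- data.frame(a = rep(1, n), b = rep(0, n))
  expect_warning(z0 <- regress_and_scale(Y[, "noisy", drop = FALSE], cov0),
                 "zero-variance")
  expect_equal(unname(z0[, 1]), unname(scale(Y[, "noisy"])[, 1]))
})

test_that("PCA matches dense SVD truncation and handles rank-1 input", {
  set.seed(31)
  X <- matrix(rnorm(50 * 30), 50, 30)
  k <- 5
  p <- run_pca(X, n_components = k)
  ctr <- sweep(X, 2, colMeans(X))
  sv <- svd(ctr)
  # reconstruction from top-k equals the SVD truncation oracle
  recon_pkg <- p$embedding %*% t(p$rotation)
  recon_svd <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  expect_equal(recon_pkg, recon_svd, tolerance = 1e-8)
  expect_equal(p$sdev, sv$d[1:k] / sqrt(49), tolerance = 1e-8)
  expect_true(all(diff(p$sdev) <= 1e-8))

  # rank-1: first component captures everything
  r1 <- outer(rnorm(40), rnorm(6))
  pr <- run_pca(r1, n_components = 3)
  expect_gt(pr$var_explained[1], 0.999)
  expect_lt(pr$sdev[2] / pr$sdev[1], 1e-6)

  # cell-permutation invariance up to sign
  perm <- sample(50)
  p2 <- run_pca(X[perm, ], n_components = k)
  for (j in 1:k) {
    cor_j <- cor(p$embedding[perm, j], p2$embedding[, j])
    expect_equal(abs(cor_j), 1, tolerance = 1e-6)
  }
  expect_error(run_pca(X, n_components = 31), "exceeds")
})
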