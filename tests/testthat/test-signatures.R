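test_that("per-cell signature score matches exact enumeration oracles", {
  set.seed(51)
  # universe of 50 genes, 3-gene signature: full brute-force enumeration
  v50 <- sample(0:6, 50, replace = TRUE)  # ties present
  syms <- sprintf("g%02d", 1:50)
  sig <- c("g03", "g17", "g42")
  norm <- matrix(v50, 1, 50, dimnames = list("cell", syms))
  res <- score_signature_per_cell(norm, sig, symbols = syms)
  p_ref <- brute_ranksum(v50, syms %in% sig, "greater", midp = TRUE)
  expect_equal(res$p, p_ref, tolerance = 1e-12)
  expect_equal(res$score, -log10(p_ref))

  # 26-gene universe, 5-gene signature, several random cells
  syms2 <- sprintf("h%02d", 1:26)
  sig2 <- sample(syms2, 5)
  for (i in 1:5) {
    v <- sample(0:3, 26, replace = TRUE)
    nm <- matrix(v, 1, 26, dimnames = list("c", syms2))
    r <- score_signature_per_cell(nm, sig2, symbols = syms2)
    expect_equal(r$p, brute_ranksum(v, syms2 %in% sig2, "greater",
                                    midp = TRUE), tolerance = 1e-12)
  }
})

test_that("signature score behaves at the null center and extremes", {
  syms <- sprintf("g%02d", 1:40)
  sig <- syms[1:5]
  # all-equal expression: one-sided mid-p is exactly 0.5
  flat <- matrix(1, 1, 40, dimnames = list("c", syms))
  r <- score_signature_per_cell(flat, sig, symbols = syms)
  expect_equal(r$p, 0.5)
  expect_equal(r$score, -log10(0.5))
  # the 5 signature genes hold the 5 largest values: smallest possible mid-p
  v <- c(rep(100, 5), seq_len(35))
  top <- matrix(v, 1, 40, dimnames = list("c", syms))
  rt <- score_signature_per_cell(top, sig, symbols = syms)
  expect_equal(rt$p, 0.5 / choose(40, 5), tolerance = 1e-12)
  expect_equal(rt$direction, "enriched")
  # depleted direction flags when signature genes rank lowest
  rb <- score_signature_per_cell(top, syms[6:10], symbols = syms)
  expect_equal(rb$direction, "depleted")
})

test_that("signature score is invariant to non-signature permutation and monotone", {
  set.seed(53)
  syms <- sprintf("g%02d", 1:60)
  sig <- syms[6:10]
  v <- runif(60)
  nm <- matrix(v, 1, 60, dimnames = list("c", syms))
  base <- score_signature_per_cell(nm, sig, symbols = syms)$score
  # permute values among non-signature genes only
  idx <- which(!(syms %in% sig))
  v2 <- v; v2[idx] <- v[sample(idx)]
  p2 <- score_signature_per_cell(matrix(v2, 1, 60,
                                        dimnames = list("c", syms)),
                                 sig, symbols = syms)$score
  expect_equal(p2, base, tolerance = 1e-12)
  # uniform positive shift of signature genes never decreases the score
  for (shift in c(0.1, 0.5, 2)) {
    v3 <- v; v3[syms %in% sig] <- v3[syms %in% sig] + shift
    p3 <- score_signature_per_cell(matrix(v3, 1, 60,
                                          dimnames = list("c", syms)),
                                   sig, symbols = syms)$score
    expect_gte(p3, base - 1e-12)
    base <- p3
  }
  expect_error(score_signature_per_cell(nm, c("nope1", "nope2"),
                                        symbols = syms), "no genes")
  expect_error(score_signature_per_cell(nm, syms[1:30], symbols = syms),
               "half")
})

test_that("null signature p-values are uniform across cells", {
  set.seed(55)
  n <- 1000; g <- 120
  norm <- matrix(rnorm(n * g), n, g,
                 dimnames = list(NULL, sprintf("g%03d", 1:g)))
  sig <- sample(colnames(norm), 10)
  res <- score_signature_per_cell(norm, sig, symbols = colnames(norm),
                                  exact_max_genes = 0)  # continuous: normal path
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cell-cycle scoring is deterministic and assigns planted phases", {
  sc <- tiny_scenario(n_cells = 600, seed = 23)
  co <- simulate_cohort(sc)
  # desk-scale gene panel: scale the detected-gene floor down with it
  qc <- qc_filter(co$counts, min_genes = 50)
  norm <- log_normalize(qc$counts)
  syms <- qc$counts$features$symbol
  cc1 <- score_cell_cycle(norm, symbols = syms, seed = 7)
  cc2 <- score_cell_cycle(norm, symbols = syms, seed = 7)
  expect_identical(cc1, cc2)
  tr <- co$truth[qc$kept, ]
  expect_gte(mean(cc1$phase[tr$phase == "S"] == "S"), 0.9)
  expect_gte(mean(cc1$phase[tr$phase == "G2M"] == "G2M"), 0.9)
  # phase invariant: G1 iff both scores <= 0, else argmax
  g1 <- cc1$s_score <= 0 & cc1$g2m_score <= 0
  expect_identical(cc1$phase == "G1", g1)
  expect_true(all(cc1$phase[!g1] ==
                    ifelse(cc1$s_score[!g1] >= cc1$g2m_score[!g1],
                           "S", "G2M")))
})

test_that("cell-cycle scoring handles empty cells and thin phase sets", {
  syms <- c(s_phase_genes[1:6], g2m_phase_genes[1:6],
            sprintf("f%02d", 1:48))
  norm <- matrix(0, 2, 60, dimnames = list(c("empty", "also"), NULL))
  cc <- score_cell_cycle(norm, symbols = syms, n_bins = 4, n_ctrl = 10,
                         seed = 1)
  expect_equal(cc$s_score, c(0, 0))
  expect_identical(cc$phase, c("G1", "G1"))
  expect_error(score_cell_cycle(norm, s_genes = s_phase_genes[1:4],
                                symbols = syms, n_bins = 4),
               ">= 5")
})

test_that("phase composition tables conserve cluster sizes", {
  phases <- c("G1", "G1", "S", "G2M", "G1", "S", "G1", "G1", "G2M", "G1")
  labels <- c("a", "a", "a", "b", "b", "b", "b", "c", "c", "c")
  tab <- phase_composition(phases, labels)
  expect_identical(colnames(tab), c("G1", "S", "G2M"))
  expect_equal(unname(rowSums(tab)), c(3, 4, 3))
  # hand count
  expect_equal(unname(tab["a", ]), c(2, 1, 0))
  expect_equal(unname(tab["b", ]), c(2, 1, 1))
  expect_equal(unname(tab["c", ]), c(2, 0, 1))
  all_g1 <- phase_composition(rep("G1", 4), rep(c("x", "y"), 2))
  expect_true(all(all_g1[, c("S", "G2M")] == 0))
})
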