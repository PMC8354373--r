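test_that("generators are pure functions of their seed", {
  a <- simulate_cell_profiles(200, c(A = 30, B = 30), 20, seed = 7)
  b <- simulate_cell_profiles(200, c(A = 30, B = 30), 20, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$gene_annot, b$gene_annot)

  t1 <- simulate_tissue_expression(100, "x", 40,
                                   list(list(size = 10, strength = 0.5)),
                                   seed = 3)
  t2 <- simulate_tissue_expression(100, "x", 40,
                                   list(list(size = 10, strength = 0.5)),
                                   seed = 3)
  expect_identical(t1$expr, t2$expr)

  l1 <- simulate_ld_reference(100, 60, seed = 5)
  l2 <- simulate_ld_reference(100, 60, seed = 5)
  expect_identical(l1$dosage, l2$dosage)
  s1 <- simulate_sumstats(l1, cbind(base = rep(1, 100)), c(base = 0), 1e4,
                          seed = 2, window_bp = 1e6)
  s2 <- simulate_sumstats(l1, cbind(base = rep(1, 100)), c(base = 0), 1e4,
                          seed = 2, window_bp = 1e6)
  expect_identical(s1$sumstats$z, s2$sumstats$z)

  g1 <- simulate_gene_coordinates(50, seed = 9)
  expect_identical(g1, simulate_gene_coordinates(50, seed = 9))
  expect_equal(nrow(g1), 50)
  expect_true(all(g1$start < g1$end))
  expect_true(all(g1$gc >= 0 & g1$gc <= 1))
})

test_that("planted markers raise own-type specificity; null fold does not", {
  cp <- suppressMessages(
    simulate_cell_profiles(2000, c(A = 250, B = 250, C = 250, D = 250),
                           50, fold_change = 8, seed = 1))
  s <- suppressMessages(compute_specificity(cp$counts, cp$cell_meta))
  mk <- intersect(cp$truth$markers$A, rownames(s))
  bg <- setdiff(rownames(s), unlist(cp$truth$markers))
  expect_gt(min(s[mk, "A"]), median(s[bg, "A"]))
  # marker sets disjoint
  expect_equal(anyDuplicated(unlist(cp$truth$markers)), 0)

  cp0 <- suppressMessages(
    simulate_cell_profiles(1000, c(A = 150, B = 150, C = 150, D = 150),
                           50, fold_change = 1, seed = 2))
  s0 <- suppressMessages(compute_specificity(cp0$counts, cp0$cell_meta))
  expect_lt(max(abs(colMeans(s0) - 0.25)), 0.02)

  expect_error(simulate_cell_profiles(100, c(A = 10, B = 10), 60, seed = 1),
               "exceeds")
  expect_error(simulate_cell_profiles(100, c(A = 10, B = 10), 5,
                                      fold_change = 0.5, seed = 1), ">= 1")
})

test_that("planted blocks are correlated within, not between, and only at home", {
  tx <- simulate_tissue_expression(
    500, c("home", "away"), 150,
    blocks = list(list(size = 60, strength = 0.8, tissue = "home"),
                  list(size = 40, strength = 0.8)),
    seed = 11)
  within_r <- function(mat, genes) {
    r <- cor(t(mat[genes, ]))
    mean(abs(r[upper.tri(r)]))
  }
  b1 <- names(tx$truth$block)[tx$truth$block == 1]
  b2 <- names(tx$truth$block)[tx$truth$block == 2]
  r12 <- abs(cor(t(tx$expr$home[b1, ]), t(tx$expr$home[b2, ])))
  expect_gt(within_r(tx$expr$home, b1), mean(r12))     # within > between
  expect_gt(within_r(tx$expr$home, b2), mean(r12))
  # tissue-specific block correlated at home only
  expect_gt(within_r(tx$expr$home, b1), within_r(tx$expr$away, b1) + 0.3)
  # shared block correlated everywhere
  expect_gt(within_r(tx$expr$away, b2), 0.6)

  # near-degenerate limit: strength -> 1 gives near-perfect correlation
  lim <- simulate_tissue_expression(50, "x", 60,
                                    list(list(size = 10, strength = 0.99)),
                                    seed = 2)
  expect_gt(within_r(lim$expr$x, names(lim$truth$block)[lim$truth$block == 1]),
            0.95)
  expect_error(simulate_tissue_expression(50, "x", 10,
                                          list(list(size = 5, strength = 0.5)),
                                          noise_sd = 0, seed = 1), "noise_sd")
  expect_error(simulate_tissue_expression(50, "x", 10,
                                          list(list(size = 60, strength = 0.5)),
                                          seed = 1), "exceeds")
})

test_that("LD panel attains the target within-block correlation", {
  ld <- simulate_ld_reference(2000, 500, block_size = 20,
                              within_block_rho = 0.6, chrom_length = 2e7,
                              seed = 1)
  expect_true(all(diff(ld$map$pos) > 0))
  expect_true(all(ld$map$maf > 0 & ld$map$maf <= 0.5))
  rs <- unlist(lapply(unique(ld$block)[1:40], function(b) {
    C <- cor(t(ld$dosage[ld$block == b, ]))
    C[upper.tri(C)]
  }))
  expect_lt(abs(mean(rs) - 0.6), 0.05)

  ld0 <- simulate_ld_reference(400, 300, block_size = 20,
                               within_block_rho = 0, seed = 2)
  r0 <- cor(t(ld0$dosage[1:100, ]))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.06)

  expect_error(simulate_ld_reference(100, 50, maf_range = c(0, 0.6)),
               "maf_range")
  expect_error(simulate_ld_reference(100, 50, within_block_rho = 1), "rho")
})

test_that("summary statistics obey the stratified heritability model", {
  ld <- simulate_ld_reference(10000, 100, block_size = 20,
                              within_block_rho = 0.5, chrom_length = 1e8,
                              seed = 3)
  annot <- cbind(base = rep(1, 10000),
                 cat = rep(c(1, 0), each = 10, length.out = 10000))
  rownames(annot) <- ld$map$snp
  sc <- compute_ld_scores(ld, annot, window_bp = 1e6)

  # tau = 0: mean chi-square is 1 within 3 standard errors
  ss0 <- simulate_sumstats(ld, annot, c(base = 0, cat = 0), N = 1e4,
                           seed = 4, ld_scores = sc)
  expect_lt(abs(mean(ss0$sumstats$z^2) - 1), 3 * sqrt(2 / 10000))

  # planted tau on one category lifts chi-square inside it
  ss1 <- simulate_sumstats(ld, annot, c(base = 0, cat = 1e-4), N = 1e4,
                           seed = 5, ld_scores = sc)
  chi2 <- ss1$sumstats$z^2
  expect_gt(mean(chi2[annot[, "cat"] == 1]), mean(chi2[annot[, "cat"] == 0]))

  # negative variance is refused with the offending SNP named
  expect_error(simulate_sumstats(ld, annot, c(base = -1, cat = 0), N = 1e4,
                                 seed = 6, ld_scores = sc), "rs")
})
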