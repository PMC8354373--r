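test_that("LD scores equal the brute-force pairwise oracle on small panels", {
  for (cfg in list(list(n = 20, rho = 0, win = 1e5),
                   list(n = 30, rho = 0.5, win = 2e5),
                   list(n = 50, rho = 0.7, win = 5e4))) {
    ld <- simulate_ld_reference(cfg$n, 50, block_size = 5,
                                within_block_rho = cfg$rho,
                                chrom_length = 1e6, seed = cfg$n)
    annot <- cbind(base = rep(1, cfg$n),
                   cat = rep(c(1, 0), length.out = cfg$n))
    rownames(annot) <- ld$map$snp
    got <- compute_ld_scores(ld, annot, window_bp = cfg$win)
    expect_equal(got, oracle_ld_scores(ld$dosage, ld$map, annot, cfg$win),
                 tolerance = 1e-10)
  }
})

test_that("LD score expectations: independence centers at 1, twins add up", {
  ld <- simulate_ld_reference(300, 400, block_size = 10,
                              within_block_rho = 0, chrom_length = 1e6,
                              seed = 2)
  annot <- cbind(base = rep(1, 300))
  rownames(annot) <- ld$map$snp
  ell <- compute_ld_scores(ld, annot, window_bp = 1e6)  # window spans all
  expect_lt(abs(mean(ell[, "base"]) - 1), 0.05)

  # duplicated SNP: perfect-LD twin makes both scores >= 2
  twin <- ld
  twin$dosage <- rbind(ld$dosage[1:10, ], dup = ld$dosage[5, ])
  twin$map <- rbind(ld$map[1:10, ],
                    data.frame(snp = "dup", chrom = "1",
                               pos = ld$map$pos[10] + 1,
                               maf = ld$map$maf[5]))
  a2 <- cbind(base = rep(1, 11))
  rownames(a2) <- twin$map$snp
  e2 <- compute_ld_scores(twin, a2, window_bp = 1e6)
  expect_gte(e2["dup", "base"], 2 - 1e-6)
  expect_gte(e2[twin$map$snp[5], "base"], 2 - 1e-6)

  mono <- ld
  mono$dosage[3, ] <- 1
  expect_error(compute_ld_scores(mono, annot, 1e6), "monomorphic")
})

test_that("gene annotations use half-open flanked intervals and inclusive kME", {
  coords <- data.frame(gene = c("GA", "GB"), chrom = "1",
                       start = c(10000, 5e6), end = c(20000, 5.01e6))
  snp_map <- data.frame(
    snp = paste0("s", 1:6), chrom = "1",
    pos = c(5000, 119999, 120000, 121000, 4.95e6, 5.05e6),
    maf = c(0.2, 0.2, 0.2, 0.2, 0.04, 0.2))
  kme <- c(GA = 0.50, GB = 0.49)
  col <- build_gene_annotation(c("GA", "GB"), kme, coords, snp_map,
                               kme_threshold = 0.5, flank_bp = 1e5,
                               maf_min = 0.05)
  expect_equal(unname(col[c("s1", "s2")]), c(1L, 1L))  # inside [0, 120000)
  expect_equal(unname(col[c("s3", "s4")]), c(0L, 0L))  # half-open upper bound
  expect_equal(unname(col["s5"]), 0L)                  # MAF fails (GB excluded anyway)
  expect_equal(unname(col["s6"]), 0L)                  # GB kME 0.49 < 0.5
  kme2 <- c(GA = 0.50, GB = 0.50)
  col2 <- build_gene_annotation(c("GA", "GB"), kme2, coords, snp_map,
                                kme_threshold = 0.5, flank_bp = 1e5,
                                maf_min = 0.05)
  expect_equal(unname(col2["s6"]), 1L)                 # kME 0.50 included

  expect_warning(z <- build_gene_annotation("GA", c(GA = 0.1), coords,
                                            snp_map), "all zero")
  expect_true(all(z == 0L))
})

test_that("region exclusion removes regression SNPs by half-open intervals", {
  snp_map <- data.frame(snp = paste0("s", 1:10), chrom = "1",
                        pos = seq(100, 1000, by = 100))
  expect_equal(exclude_region(snp_map, NULL), 1:10)
  keep <- exclude_region(snp_map,
                         data.frame(chrom = "1", start = 250, end = 550))
  expect_length(keep, 7)                     # drops pos 300, 400, 500
  expect_false(any(snp_map$pos[keep] %in% c(300, 400, 500)))
  expect_error(exclude_region(snp_map,
                              data.frame(chrom = "1", start = 0, end = 2000)),
               "no SNPs remain")
})

test_that("regression recovers a base-only model and flags collinearity", {
  ld <- simulate_ld_reference(3000, 300, block_size = 20,
                              within_block_rho = 0.5, chrom_length = 3e7,
                              seed = 8)
  annot <- cbind(base = rep(1, 3000))
  rownames(annot) <- ld$map$snp
  sc <- compute_ld_scores(ld, annot, 1e6)
  tau_b <- 1e-4
  taus <- sapply(1:10, function(s) {
    ss <- simulate_sumstats(ld, annot, c(base = tau_b), 1e4, seed = 20 + s,
                            ld_scores = sc)
    fit <- stratified_regression(ss$sumstats, sc, baseline = "base",
                                 target = character(0), n_blocks = 100)
    c(fit$coefficients$tau[1], fit$intercept)
  })
  expect_lt(abs(mean(taus[1, ]) / tau_b - 1), 0.15)
  # the intercept is near-collinear with N*l_base here, so it is noisy;
  # check calibration relative to its own spread across seeds
  expect_lt(abs(mean(taus[2, ]) - 1),
            3 * stats::sd(taus[2, ]) / sqrt(ncol(taus)))

  # intercept-only data: chi-square independent of the LD scores
  set.seed(1)
  ss0 <- data.frame(snp = ld$map$snp, z = rnorm(3000), n = 1e4)
  fit0 <- stratified_regression(ss0, sc, baseline = "base",
                                target = character(0), n_blocks = 100)
  expect_lt(abs(fit0$coefficients$tau[1]) / (3 * fit0$coefficients$se[1]), 1)
  expect_lt(abs(fit0$intercept - mean(ss0$z^2)), 3 * fit0$intercept_se)

  sc_dup <- cbind(sc, base2 = sc[, "base"])
  expect_error(stratified_regression(ss0, sc_dup,
                                     baseline = c("base", "base2"),
                                     target = character(0), n_blocks = 100),
               "collinear|rank")
  expect_error(stratified_regression(ss0, sc, baseline = c("base", "base"),
                                     target = character(0), n_blocks = 100),
               "duplicated")
})

test_that("estimates are invariant to sumstats row order; SE shrinks with panel size", {
  ld <- simulate_ld_reference(2000, 300, block_size = 20,
                              within_block_rho = 0.5, chrom_length = 2e7,
                              seed = 9)
  set.seed(9)
  annot <- cbind(base = rep(1, 2000), target = rbinom(2000, 1, 0.2))
  rownames(annot) <- ld$map$snp
  sc <- compute_ld_scores(ld, annot, 1e6)
  ss <- simulate_sumstats(ld, annot, c(base = 0, target = 5e-5), 1e4,
                          seed = 10, ld_scores = sc)$sumstats
  f1 <- stratified_regression(ss, sc, "base", "target", n_blocks = 50)
  perm <- sample(nrow(ss))
  f2 <- stratified_regression(ss[perm, ], sc, "base", "target", n_blocks = 50)
  expect_equal(f1$coefficients$tau, f2$coefficients$tau, tolerance = 1e-10)
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 1e-10)

  # jackknife SE shrinks roughly as 1/sqrt(n_snps)
  ld_big <- simulate_ld_reference(8000, 300, block_size = 20,
                                  within_block_rho = 0.5, chrom_length = 8e7,
                                  seed = 9)
  set.seed(9)
  annot_b <- cbind(base = rep(1, 8000), target = rbinom(8000, 1, 0.2))
  rownames(annot_b) <- ld_big$map$snp
  sc_b <- compute_ld_scores(ld_big, annot_b, 1e6)
  se_small <- mean(sapply(1:5, function(s)
    stratified_regression(
      simulate_sumstats(ld, annot, c(base = 0, target = 0), 1e4,
                        seed = 30 + s, ld_scores = sc)$sumstats,
      sc, "base", "target", n_blocks = 50)$coefficients$se[2]))
  se_big <- mean(sapply(1:5, function(s)
    stratified_regression(
      simulate_sumstats(ld_big, annot_b, c(base = 0, target = 0), 1e4,
                        seed = 40 + s, ld_scores = sc_b)$sumstats,
      sc_b, "base", "target", n_blocks = 50)$coefficients$se[2]))
  expect_gt(se_big / se_small, 0.3)   # ~ sqrt(2000/8000) = 0.5
  expect_lt(se_big / se_small, 0.8)

  # adding an uncorrelated target leaves tau_base within jackknife noise
  ss_n <- simulate_sumstats(ld, annot, c(base = 1e-4, target = 0), 1e4,
                            seed = 77, ld_scores = sc)$sumstats
  f_base <- stratified_regression(ss_n, sc, "base", character(0),
                                  n_blocks = 50)
  f_with <- stratified_regression(ss_n, sc, "base", "target", n_blocks = 50)
  d <- abs(f_base$coefficients$tau[1] - f_with$coefficients$tau[1])
  expect_lt(d, 3 * f_with$coefficients$se[1])
})

test_that("heritability battery flags follow the family-wise threshold", {
  ld <- simulate_ld_reference(2000, 200, block_size = 10,
                              within_block_rho = 0.5, chrom_length = 2e7,
                              seed = 12)
  set.seed(12)
  baseline <- cbind(base = rep(1L, 2000))
  rownames(baseline) <- ld$map$snp
  mods <- list(m1 = rbinom(2000, 1, 0.2), m2 = rbinom(2000, 1, 0.2))
  annot_m1 <- cbind(baseline, m1 = mods$m1)
  gwas <- list(
    linked = simulate_sumstats(ld, annot_m1, c(base = 0, m1 = 1e-4), 1e4,
                               seed = 13)$sumstats,
    null = simulate_sumstats(ld, annot_m1, c(base = 0, m1 = 0), 1e4,
                             seed = 14)$sumstats)
  bat <- run_heritability_battery(mods, gwas, ld, baseline,
                                  n_blocks = 50, alpha = 0.05)
  thr <- attr(bat, "threshold")
  expect_equal(thr, 0.05 / 4)
  expect_equal(bat$bonferroni_significant, bat$p < thr)
  expect_equal(bat$nominal, bat$p < 0.05 & bat$p >= thr)
  expect_true(bat$bonferroni_significant[bat$module == "m1" &
                                           bat$gwas == "linked"])
  expect_false(any(bat$bonferroni_significant[bat$gwas == "null" &
                                                bat$module == "m2"]))
})
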