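test_that("signed adjacency has its closed-form values", {
  x <- c(1, 2, 3, 4)
  expr <- rbind(g1 = x, g2 = 2 * x + 1,          # r = 1
                g3 = -x,                         # r = -1 with g1
                g4 = c(1, -1, 1, -1) * 1.0)      # r = 0 with g5
  expr <- rbind(expr, g5 = c(1, 1, -1, -1))
  a <- signed_adjacency(expr, 6)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 0)
  expect_equal(a["g4", "g5"], 0.5^6)
  expect_equal(a["g4", "g5"], 0.015625)
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))

  expect_error(signed_adjacency(rbind(g1 = x, g2 = rep(2, 4)), 6), "g2")
  expect_error(signed_adjacency(expr[, 1:2], 6), "3 samples")
})

test_that("TOM matches the definitional triple-loop oracle", {
  # saturation: complete graph
  ones <- matrix(1, 5, 5)
  expect_equal(topological_overlap(ones), ones)
  # no edge, no shared neighbors
  iso <- diag(4)
  expect_equal(topological_overlap(iso)[1, 2], 0)

  set.seed(7)
  for (i in 1:25) {
    a <- matrix(runif(16), 4, 4)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- topological_overlap(a)
    expect_equal(unname(tom), oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }
  bad <- matrix(runif(16), 4, 4); diag(bad) <- 1
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("network construction is invariant to sample order and affine gene rescaling", {
  set.seed(8)
  expr <- matrix(rnorm(30 * 20), 30, 20,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
  a <- signed_adjacency(expr, 6)
  perm <- sample(20)
  expect_equal(signed_adjacency(expr[, perm], 6), a)
  resc <- expr * rgamma(30, 2) + rnorm(30)   # positive slope, per-gene affine
  expect_equal(signed_adjacency(resc, 6), a, tolerance = 1e-12)
})

test_that("soft-power selection honors the target and is deterministic", {
  tx <- make_planted_blocks(n_genes = 300, strength = 0.7, n_samples = 80,
                            seed = 5, sizes = c(40, 30, 30))
  expr <- tx$expr$t
  got <- pick_soft_power(expr, candidates = c(2, 4, 6, 8, 10),
                         target_fit = 0)
  expect_equal(got$beta, 2)  # target 0: smallest candidate wins
  expect_equal(got, pick_soft_power(expr, candidates = c(2, 4, 6, 8, 10),
                                    target_fit = 0))
  expect_equal(got$fit_table$beta, c(2, 4, 6, 8, 10))
  sel <- suppressWarnings(pick_soft_power(expr, candidates = c(2, 4, 6, 8, 10),
                                          target_fit = 0.8))
  # chosen power recomputed from the returned table: smallest reaching the
  # target, else the best-fitting one
  tab <- sel$fit_table
  reach <- tab$beta[!is.na(tab$fit_r2) & tab$fit_r2 >= 0.8]
  expected_beta <- if (length(reach)) reach[1] else tab$beta[which.max(tab$fit_r2)]
  expect_equal(sel$beta, expected_beta)
  expect_error(pick_soft_power(expr[1:5, ], candidates = c(2, 4)), "10 genes")
})

test_that("perfectly separated blocks are recovered exactly and are a k-means fixed point", {
  tom <- matrix(0, 60, 60, dimnames = list(sprintf("g%02d", 1:60),
                                           sprintf("g%02d", 1:60)))
  tom[1:35, 1:35] <- 1
  tom[36:60, 36:60] <- 1
  labels <- cluster_modules(tom, cut_height = 0.5, min_size = 10)
  expect_equal(unname(labels[1:35]), rep("turquoise", 35))  # larger block first
  expect_equal(unname(labels[36:60]), rep("blue", 25))

  # matching expression: two uncorrelated shared factors
  set.seed(1)
  f1 <- rnorm(50); f2 <- rnorm(50)
  expr <- rbind(matrix(rep(f1, 35), 35, byrow = TRUE),
                matrix(rep(f2, 25), 25, byrow = TRUE)) +
    matrix(rnorm(60 * 50, 0, 0.05), 60)
  rownames(expr) <- names(labels)
  ref <- kmeans_refine(expr, labels, min_size = 10)
  expect_equal(ref$labels, labels)
  expect_equal(ref$moved, 0L)
})

test_that("eigengenes and kME have their closed-form values", {
  set.seed(2)
  base <- rnorm(40)
  expr <- rbind(g1 = 3 * base + 2, g2 = -1.5 * (3 * base + 2) + 7,
                g3 = base + rnorm(40, 0, 1))
  labels <- c(g1 = "turquoise", g2 = "turquoise", g3 = "grey")
  me <- module_eigengenes(expr, labels)
  # 2-gene module: first PC via direct SVD of the standardized matrix
  xs <- t(scale(t(expr[1:2, ])))
  sv <- svd(xs)
  pc <- sv$v[, 1]
  if (mean(cor(t(xs), pc)) < 0) pc <- -pc
  expect_equal(unname(me[, "turquoise"]), pc, tolerance = 1e-10)

  kme <- module_membership(expr, me)
  expect_equal(abs(unname(kme["g1", "turquoise"])), 1, tolerance = 1e-10)
  # sign equivariance: flipping all members flips the eigengene
  me_f <- module_eigengenes(rbind(g1 = -expr["g1", ], g2 = -expr["g2", ]),
                            c(g1 = "turquoise", g2 = "turquoise"))
  expect_equal(unname(me_f[, 1]), -unname(me[, 1]), tolerance = 1e-10)

  # identical-gene module: eigengene is the common standardized profile
  same <- rbind(h1 = base, h2 = base, h3 = base)
  me_s <- module_eigengenes(same, c(h1 = "blue", h2 = "blue", h3 = "blue"))
  zs <- scale(base)[, 1]
  expect_equal(unname(me_s[, 1]), zs / sqrt(sum(zs^2)), tolerance = 1e-10)
  expect_equal(unname(module_membership(same, me_s)[, 1]), rep(1, 3))

  # 5-gene toy kME equals brute-force correlation
  expr5 <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(paste0("x", 1:5), NULL))
  lab5 <- setNames(c(rep("turquoise", 3), "grey", "grey"), rownames(expr5))
  me5 <- module_eigengenes(expr5, lab5)
  kme5 <- module_membership(expr5, me5)
  for (g in rownames(expr5))
    expect_equal(kme5[g, 1], cor(expr5[g, ], me5[, 1]))
})

test_that("k-means refinement fixes a mislabeled gene and is monotone", {
  tx <- make_planted_blocks(n_genes = 200, strength = 0.85, n_samples = 100,
                            seed = 6, sizes = c(50, 40, 30))
  expr <- tx$expr$t
  truth <- tx$truth$block
  labels <- setNames(
    c("turquoise", "blue", "brown")[pmax(truth, 1)], names(truth))
  labels[truth == 0] <- "grey"
  # corrupt one block-1 gene
  victim <- names(truth)[truth == 1][1]
  labels[victim] <- "blue"
  ref <- kmeans_refine(expr, labels, min_size = 10)
  expect_equal(unname(ref$labels[victim]), "turquoise")

  # objective sum(1 - kME(own)) never increases over single-step refinements
  objective <- function(lab) {
    me <- module_eigengenes(expr, lab)
    kme <- module_membership(expr, me)
    ass <- names(lab)[lab != "grey"]
    sum(1 - kme[cbind(ass, lab[ass])])
  }
  lab <- labels
  prev <- objective(lab)
  for (i in 1:5) {
    lab <- kmeans_refine(expr, lab, max_iter = 1, min_size = 10)$labels
    cur <- objective(lab)
    expect_lte(cur, prev + 1e-8)
    prev <- cur
  }
})

test_that("refinement does not degrade planted-block recovery across seeds", {
  skip_if_not_installed("mclust")
  wins <- 0L
  n_runs <- 50L
  for (i in seq_len(n_runs)) {
    tx <- make_planted_blocks(n_genes = 300, strength = 0.6, n_samples = 80,
                              seed = 1000 + i, sizes = c(40, 30, 30))
    expr <- tx$expr$t
    tom <- topological_overlap(signed_adjacency(expr, 6))
    init <- cluster_modules(tom, cut_height = 0.94, min_size = 20)
    ref <- kmeans_refine(expr, init, min_size = 20)
    truth <- tx$truth$block[names(init)]
    ari0 <- mclust::adjustedRandIndex(init, truth)
    ari1 <- mclust::adjustedRandIndex(ref$labels, truth)
    if (ari1 >= ari0 - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins / n_runs, 0.9)
})

test_that("kME filter keeps nearly all true members of a planted module", {
  tx <- make_planted_blocks(n_genes = 500, strength = 0.8, n_samples = 150,
                            seed = 12, sizes = c(50, 40, 30))
  expr <- tx$expr$t
  net <- build_network(expr, beta = 6, min_size = 20)
  b1 <- names(tx$truth$block)[tx$truth$block == 1]
  mod <- names(which.max(table(net$labels[b1])))
  kept <- b1[net$kme[b1, mod] >= 0.5]
  expect_gte(length(kept) / length(b1), 0.95)
})
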