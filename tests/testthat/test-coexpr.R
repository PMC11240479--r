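test_that("bicor is affine-invariant and tracks Pearson on clean data", {
  x <- rnorm(30)
  X <- rbind(a = x, b = 2 * x + 1)
  expect_equal(bicor_matrix(X)["a", "b"], 1)

  set.seed(1)
  n <- 5000
  u <- rnorm(n)
  Y <- rbind(a = u, b = 0.6 * u + sqrt(1 - 0.36) * rnorm(n))
  bc <- bicor_matrix(Y)["a", "b"]
  pc <- cor(Y["a", ], Y["b", ])
  expect_lt(abs(bc - pc), 0.02)
  expect_error(bicor_matrix(Y[, 1:3]), "4 samples")
})

test_that("bicor resists a gross outlier better than Pearson", {
  set.seed(2)
  n <- 60
  u <- rnorm(n)
  a <- u
  b <- 0.9 * u + sqrt(1 - 0.81) * rnorm(n)
  a[1] <- 25  # gross outlier
  bc <- bicor_matrix(rbind(a = a, b = b))["a", "b"]
  pc <- cor(a, b)
  expect_lt(abs(bc - 0.9), abs(pc - 0.9))
})

test_that("zero-MAD rows fall back to Pearson", {
  set.seed(3)
  x <- rnorm(20)
  spiky <- c(rep(0, 11), rnorm(9))  # median absolute deviation is zero
  X <- rbind(a = x, b = x + rnorm(20, 0, 0.01), s = spiky)
  bc <- bicor_matrix(X)
  expect_true(all(is.finite(bc)))
  expect_gt(bc["a", "b"], 0.99)
})

test_that("cut height maps the top fraction of correlations", {
  cm <- matrix(0.4, 5, 5)
  diag(cm) <- 1
  expect_equal(cut_height_from_top_fraction(cm, 0.3), 0.6)  # all off-diag equal c -> 1 - c
  set.seed(4)
  vals <- runif(190)
  cm2 <- matrix(0, 20, 20)
  cm2[upper.tri(cm2)] <- vals
  cm2 <- cm2 + t(cm2)
  diag(cm2) <- 1
  h <- cut_height_from_top_fraction(cm2, 0.01)
  expect_equal(h, 1 - quantile(vals, 0.99), ignore_attr = TRUE)
  # top_frac -> 1 approaches 1 - min correlation
  expect_equal(cut_height_from_top_fraction(cm2, 0.999), 1 - min(vals),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("static-height module detection respects blocks, size and gene order", {
  blocks <- matrix(0, 40, 40, dimnames = list(paste0("g", 1:40), paste0("g", 1:40)))
  blocks[1:20, 1:20] <- 0.9
  blocks[21:40, 21:40] <- 0.9
  diag(blocks) <- 1
  lab <- detect_modules(blocks, height = 0.5, min_size = 15)
  expect_equal(length(unique(na.omit(lab$module))), 2L)
  expect_equal(ari(lab$module, rep(c("x", "y"), each = 20)), 1)

  # gene-order invariance
  perm <- sample(40)
  lab2 <- detect_modules(blocks[perm, perm], height = 0.5, min_size = 15)
  m <- match(lab$gene, lab2$gene)
  expect_equal(ari(lab$module, lab2$module[m]), 1)

  # all-zero correlations leave everything unassigned, as does an
  # unreachable min_size
  flat <- diag(40)
  expect_true(all(is.na(detect_modules(flat, height = 0.5, min_size = 2)$module)))
  expect_true(all(is.na(detect_modules(blocks, height = 0.5, min_size = 30)$module)))
})

test_that("module eigengenes have the stated SVD properties", {
  set.seed(5)
  z <- rnorm(25)
  X <- t(sapply(1:10, function(i) 3 * z + rnorm(25, 0, 0.05)))
  me <- module_eigengene(X)
  expect_equal(sum(me^2), 1)  # unit norm
  expect_gt(abs(cor(me, z)), 0.99)
  expect_gte(mean(cor(t(X), me)), 0)  # sign convention

  # negating all member genes negates the eigengene
  me_neg <- module_eigengene(-X)
  expect_equal(me_neg, -me, tolerance = 1e-8)

  # the eigengene explains at least as much standardized variance as the
  # second singular direction
  Z <- t(scale(t(X)))
  sv <- svd(Z)
  expect_gte(sv$d[1], sv$d[2])
  expect_equal(abs(sum(sv$v[, 1] * me)), 1, tolerance = 1e-8)

  expect_warning(module_eigengene(rbind(X, 0)), "constant")
  expect_error(module_eigengene(X[1, , drop = FALSE]), "at least 2")
})

test_that("module merging is iterative, greedy and terminates at the threshold", {
  set.seed(6)
  z <- rnorm(30)
  mk <- function(r, n, tag) {
    out <- t(sapply(seq_len(n), function(i) r * z + sqrt(1 - r^2) * rnorm(30)))
    rownames(out) <- paste0(tag, seq_len(n))
    out
  }
  X <- rbind(mk(0.97, 10, "a"), mk(0.96, 10, "b"), mk(0.95, 10, "c"))
  colnames(X) <- paste0("s", 1:30)
  labels <- tibble::tibble(gene = rownames(X), module = rep(c("A", "B", "C"), each = 10))
  merged <- merge_modules(labels, X, threshold = 0.8)
  # three modules pairwise above threshold collapse into one
  expect_equal(nrow(merged$eigengenes), 1L)

  # post-condition: no remaining pair above threshold
  set.seed(7)
  X2 <- rbind(mk(0.95, 10, "a"),
              t(sapply(1:10, function(i) rnorm(30))))
  rownames(X2) <- c(paste0("a", 1:10), paste0("u", 1:10))
  labels2 <- tibble::tibble(gene = rownames(X2), module = rep(c("A", "U"), each = 10))
  merged2 <- merge_modules(labels2, X2, threshold = 0.8)
  if (nrow(merged2$eigengenes) > 1) {
    cc <- cor(t(merged2$eigengenes))
    expect_lte(max(cc[upper.tri(cc)]), 0.8)
  }
})

test_that("kME membership assigns significant genes to their best module", {
  X <- block_expression(n_per_block = 15, n_noise = 10, n_samples = 40, seed = 8)
  labels <- tibble::tibble(gene = rownames(X),
                           module = c(rep("M1", 15), rep("M2", 15), rep(NA, 10)))
  me <- clonesect:::eigengene_matrix(X, labels)
  km <- kme(X, me)
  expect_true(all(abs(km$kme) <= 1))
  # a tight member gene has kME near 1 for its own module
  expect_gt(km$kme["a1", "M1"], 0.9)
  a_members <- km$membership[km$membership$gene %in% paste0("a", 1:15), ]
  expect_true(all(a_members$module == "M1"))
  # genes significant for both modules go to the larger kME
  both <- km$membership[km$membership$gene == "a1", ]
  expect_equal(both$module, "M1")
})

test_that("permuted genes rarely reach significant kME (null calibration)", {
  # 200 permuted copies stand in for the larger sweep (runtime)
  set.seed(9)
  X <- block_expression(n_per_block = 20, n_noise = 0, n_samples = 40, seed = 9)
  labels <- tibble::tibble(gene = rownames(X), module = rep(c("M1", "M2"), each = 20))
  me <- clonesect:::eigengene_matrix(X, labels)
  perm <- t(sapply(1:200, function(i) sample(X[1, ])))
  rownames(perm) <- paste0("p", 1:200)
  km <- kme(perm, me, alpha = 0.05)
  expect_lte(nrow(km$membership) / 200, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  universe <- paste0("g", 1:100)
  gl <- universe[1:10]
  gs <- universe[6:15]  # overlap 5
  res <- fisher_enrichment(list(L = gl), list(S = gs), universe)
  p_oracle <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$overlap, 5L)

  # disjoint list and set
  res0 <- fisher_enrichment(list(L = universe[1:10]), list(S = universe[90:100]), universe)
  expect_equal(res0$p, 1)
  # set equal to universe forces the overlap
  res1 <- fisher_enrichment(list(L = gl), list(S = universe), universe)
  expect_equal(res1$p, 1)
  expect_error(fisher_enrichment(list(L = gl), list(S = gs), character()), "empty universe")
})

test_that("module-clone correlation ranks modules against cumulative abundance", {
  tree <- tiny_tree()
  fr <- matrix(runif(2 * 20, 0.05, 0.4), 2, 20,
               dimnames = list(c("clone1", "clone2"), paste0("s", 1:20)))
  cum <- cumulative_fractions(fr, tree)
  me <- rbind(M1 = cum["clone1", ] / sqrt(sum(cum["clone1", ]^2)),
              M2 = rnorm(20))
  colnames(me) <- colnames(fr)
  mc <- module_clone_correlation(me, fr, tree)
  expect_equal(unname(mc$r[mc$module == "M1" & mc$clone == "clone1"]), 1,
               tolerance = 1e-10)
  top1 <- mc$module[mc$top & mc$clone == "clone1"]
  expect_equal(top1, "M1")
  expect_error(module_clone_correlation(me[, 1:3], fr[, 1:3], tree), "4 shared")
})
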