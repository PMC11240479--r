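test_that("expected VAF follows the copy-number-weighted mixture", {
  # truncal heterozygous diploid at purity 0.8
  expect_equal(expected_vaf(c(0.8), m = 1, t = 2), 0.4)
  # copy-neutral LOH in all malignant cells: VAF equals purity
  expect_equal(expected_vaf(c(0.6), m = 2, t = 2), 0.6)
  # arm loss deleting the mutant allele in 20% of malignant cells at purity 0.75
  v <- expected_vaf(c(0.6, 0.15), m = c(1, 0), t = c(2, 1))
  expect_equal(v, 0.6 / 1.85)
  # zero denominator is missing
  expect_true(is.na(expected_vaf(c(1), m = 0, t = 0)))
})

test_that("expected_vaf and cellular_prevalence are mutual inverses", {
  set.seed(1)
  for (i in 1:50) {
    m <- sample(1:3, 1)
    t_ <- m + sample(0:2, 1)
    t_bg <- sample(1:3, 1)
    phi <- runif(1)
    v <- phi * m / (phi * t_ + (1 - phi) * t_bg)
    expect_equal(cellular_prevalence(v, m = m, t = t_, t_bg = t_bg)$phi, phi,
                 tolerance = 1e-10)
  }
  # the documented special cases
  expect_equal(cellular_prevalence(0.4, m = 1, t = 2)$phi, 0.8)
  expect_equal(cellular_prevalence(0.6, m = 2, t = 2)$phi, 0.6)  # cn-LOH: phi = VAF
  expect_equal(cellular_prevalence(0, m = 1, t = 2)$phi, 0)
  expect_error(cellular_prevalence(0.1, m = 0, t = 2), "not observable")
})

test_that("prevalence CIs propagate binomial uncertainty", {
  res <- cellular_prevalence(0.4, m = 1, t = 2, alt = 4000, depth = 10000)
  expect_lt(res$lo, res$phi)
  expect_gt(res$hi, res$phi)
  wide <- cellular_prevalence(0.4, m = 1, t = 2, alt = 40, depth = 100)
  expect_gt(wide$hi - wide$lo, res$hi - res$lo)
})

test_that("event clustering pools prevalence by precision-weighted mean", {
  phi <- rbind(e1 = c(0.8, 0.6, 0.4), e2 = c(0.8, 0.6, 0.4))
  cl <- cluster_events(phi, k = 1)
  expect_equal(unname(cl$prevalence["c1", ]), c(0.8, 0.6, 0.4))
  single <- cluster_events(phi[1, , drop = FALSE])
  expect_equal(nrow(single$prevalence), 1L)
  # precision weighting: a high-variance member pulls less
  vr <- rbind(e1 = rep(0.01, 3), e2 = rep(1, 3))
  phi2 <- rbind(e1 = c(0.5, 0.5, 0.5), e2 = c(0.9, 0.9, 0.9))
  cl2 <- cluster_events(phi2, variances = vr, k = 1)
  expect_lt(max(abs(cl2$prevalence - (0.5 * (1 / 0.01) + 0.9) / (1 / 0.01 + 1))), 1e-9)
})

test_that("tree enumeration matches Cayley's formula at small k", {
  expect_equal(length(enumerate_trees(1)), 1L)
  expect_equal(length(enumerate_trees(3)), 3L)
  expect_equal(length(enumerate_trees(4)), 16L)
  expect_error(enumerate_trees(8), "k > 7")
})

test_that("frequency fitting solves the constrained least-squares problem", {
  # chain c1 -> c2 with prevalences (0.8, 0.3): exact-genotype (0.5, 0.3)
  prev <- matrix(c(0.8, 0.3), 2, 1, dimnames = list(c("c1", "c2"), "s1"))
  fit <- fit_tree_frequencies(c(NA, 1L), prev)
  expect_equal(unname(fit$fractions[, 1]), c(0.5, 0.3))
  expect_equal(fit$objective, 0)
  expect_equal(unname(1 - colSums(fit$fractions)), 0.2)

  # a child more prevalent than its parent violates the tree: positive
  # objective and the fitted child cumulative clipped below the parent's
  prev2 <- matrix(c(0.3, 0.5), 2, 1, dimnames = list(c("c1", "c2"), "s1"))
  fit2 <- fit_tree_frequencies(c(NA, 1L), prev2)
  expect_gt(fit2$objective, 0)
  expect_lte(fit2$cumulative["c2", 1], fit2$cumulative["c1", 1] + 1e-9)

  # fitted fractions always satisfy the fraction-matrix invariants
  expect_true(all(fit2$fractions >= 0))
  expect_true(all(colSums(fit2$fractions) <= 1 + 1e-9))
})

test_that("the active-set solver matches a dense grid search", {
  # independent oracle: brute-force search over the k = 2 simplex grid
  set.seed(7)
  for (rep in 1:5) {
    phi <- matrix(runif(2, 0, 1.2), 2, 1, dimnames = list(c("c1", "c2"), "s1"))
    fit <- fit_tree_frequencies(c(NA, 1L), phi)
    A <- rbind(c(1, 1), c(0, 1))
    grid <- seq(0, 1, by = 0.002)
    best <- Inf
    for (f1 in grid) {
      f2 <- grid[grid <= 1 - f1 + 1e-12]
      obj <- (phi[1] - (f1 + f2))^2 + (phi[2] - f2)^2
      best <- min(best, min(obj))
    }
    expect_lt(fit$objective, best + 1e-4)
  }
})

test_that("the true tree wins on noiseless prevalences and ties are flagged", {
  # noiseless 5-clone tumor: the generator guarantees identifiability, so the
  # true topology attains (numerically) zero objective and is selected
  cfg <- sim_config(n_clones = 5, n_sections = 40, n_cnv_per_branch = 0)
  tree <- simulate_phylogeny(cfg, seed = 31)
  fr <- simulate_section_fractions(tree, cfg, seed = 31)
  cum <- cumulative_fractions(fr, tree)
  rownames(cum) <- paste0("c", seq_len(nrow(cum)))  # rows already root-first
  clusters <- structure(list(membership = NULL, prevalence = cum),
                        class = "prevalence_clusters")
  fit <- select_best_tree(clusters)
  expect_lt(fit$objective, 1e-18)
  expect_false(fit$tie)
  fitted_idx <- match(fit$parent, names(fit$parent))
  true_idx <- match(tree$parent, tree$clone_ids)
  expect_equal(fitted_idx, true_idx, ignore_attr = TRUE)

  # crafted exact tie: a shallow clone fits equally under root or sibling
  prev <- rbind(c1 = rep(0.9, 4), c2 = rep(0.3, 4), c3 = rep(0.1, 4))
  tied <- select_best_tree(cluster_events(prev, k = 3))
  expect_true(tied$tie)
  expect_gte(nrow(tied$candidates), 2L)
})

test_that("purity helpers and relative copy number are exact", {
  prev <- matrix(c(1, 0.5, 0, 0), 2, 2, dimnames = list(c("c1", "c2"), c("s1", "s2")))
  fit <- fit_tree_frequencies(c(NA, 1L), prev)
  expect_equal(unname(purity_per_section(fit)), c(1, 0))
  expect_equal(relative_copy_number(2, 2), 2)
  expect_equal(relative_copy_number(1, 2), 1)
  expect_equal(relative_copy_number(3, 2), 3)
  expect_error(relative_copy_number(1, 0), "positive")
})
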