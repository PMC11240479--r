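test_that("per-locus calls follow the read thresholds", {
  expect_equal(call_locus(100, 100), "mutant")
  expect_equal(call_locus(0, 100), "wildtype")
  expect_equal(call_locus(1, 2), "indeterminate")
  # plenty of alt reads at low VAF is ambiguous, not wildtype
  expect_equal(call_locus(15, 985), "indeterminate")
  expect_equal(call_locus(c(100, 0, 1), c(100, 100, 2)),
               c("mutant", "wildtype", "indeterminate"))
  expect_error(call_locus(-1, 5), "nonnegative")
})

test_that("nucleus categories partition all 27 locus-call combinations", {
  calls <- c("mutant", "wildtype", "indeterminate")
  combos <- expand.grid(a = calls, b = calls, c = calls, stringsAsFactors = FALSE)
  cats <- apply(combos, 1, function(row) call_nucleus(unname(row))$category)
  expect_true(all(cats %in% c("called", "discrepant", "insufficient")))
  expect_equal(length(cats), 27L)

  # the stated rules
  expect_equal(call_nucleus(c("mutant", "mutant", "wildtype")),
               list(category = "called", malignant = TRUE))
  expect_equal(call_nucleus(c("wildtype", "wildtype", "mutant")),
               list(category = "discrepant", malignant = NA))
  expect_equal(call_nucleus(c("indeterminate", "indeterminate", "mutant")),
               list(category = "insufficient", malignant = NA))
  # two wildtype plus one indeterminate is called nonmalignant
  expect_equal(call_nucleus(c("wildtype", "wildtype", "indeterminate")),
               list(category = "called", malignant = FALSE))
  # one of each is unresolvable
  expect_equal(call_nucleus(c("mutant", "wildtype", "indeterminate"))$category,
               "insufficient")
  expect_error(call_nucleus(c("mutant", "mutant")), "expected 3")
})

test_that("nucleus clustering groups by expression profile", {
  set.seed(1)
  n <- 60
  lamA <- c(rep(8, 20), rep(1, 20), rep(2, 10))
  lamB <- c(rep(1, 20), rep(8, 20), rep(2, 10))
  counts <- cbind(
    matrix(rpois(50 * n / 2, lamA), 50, n / 2),
    matrix(rpois(50 * n / 2, lamB), 50, n / 2)
  )
  dimnames(counts) <- list(paste0("g", 1:50), paste0("nuc", 1:n))
  cl <- cluster_nuclei(counts)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(ari(cl$cluster, rep(1:2, each = n / 2)), 1)

  # duplicated nuclei land in the same cluster; explicit k is honored
  dup <- counts[, c(1, 1, 31, 31)]
  colnames(dup) <- paste0("d", 1:4)
  cld <- cluster_nuclei(dup, k = 2)
  expect_equal(cld$cluster[1], cld$cluster[2])
  expect_equal(cld$cluster[3], cld$cluster[4])
  expect_equal(length(unique(cluster_nuclei(counts, k = 3)$cluster)), 3L)
})

test_that("module upregulation test matches exact rank-sum enumeration", {
  # tiny fixture: 3 module genes vs 4 others, exact Wilcoxon by enumeration
  tv <- c(a = 5, b = 7, c = 9, d = 1, e = 2, f = 3, g = 4)
  p <- module_upregulation_test(tv, c("a", "b", "c"))
  # independent oracle: exhaustive enumeration of all 35 rank splits
  splits <- combn(7, 3)
  stat_obs <- sum(rank(tv)[1:3])
  stats_all <- apply(splits, 2, function(idx) sum(rank(tv)[idx]))
  oracle <- mean(stats_all >= stat_obs)
  expect_equal(p, oracle, tolerance = 1e-12)
  # extreme separation at scale gives a tiny p
  tv2 <- c(stats::setNames(rnorm(50, 10), paste0("m", 1:50)),
           stats::setNames(rnorm(950, 0), paste0("o", 1:950)))
  expect_lt(module_upregulation_test(tv2, paste0("m", 1:50)), 1e-3)
  expect_error(module_upregulation_test(tv, c("zz")), "empty module")
})

test_that("random modules give approximately uniform upregulation p-values", {
  set.seed(2)
  tv <- stats::setNames(rnorm(400), paste0("g", 1:400))
  ps <- replicate(300, {
    tv <- stats::setNames(rnorm(400), paste0("g", 1:400))
    module_upregulation_test(tv, sample(names(tv), 25))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
})

test_that("cluster-to-population mapping uses BH-corrected minima", {
  p <- matrix(c(1e-8, 0.5, 0.6,
                0.7, 1e-6, 0.9,
                1e-7, 0.8, 0.9), 3, 3, byrow = TRUE,
              dimnames = list(paste0("cl", 1:3), paste0("M", 1:3)))
  m <- map_clusters_to_populations(p, alpha = 0.05)
  expect_equal(m$module, c("M1", "M2", "M1"))  # two clusters may share a module
  none <- map_clusters_to_populations(matrix(0.5, 2, 2,
                                             dimnames = list(c("a", "b"), c("M1", "M2"))))
  expect_true(all(is.na(none$module)))
})

test_that("CNV-caller metrics equal brute-force confusion counts", {
  # perfect predictor
  truth <- tibble::tibble(nucleus = paste0("n", 1:6),
                          malignant = c(TRUE, TRUE, FALSE, FALSE, NA, TRUE))
  perfect <- tibble::tibble(nucleus = truth$nucleus,
                            predicted = ifelse(is.na(truth$malignant) | truth$malignant,
                                               "malignant", "nonmalignant"))
  m <- cnv_caller_metrics(perfect, truth)
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(1, 1, 1))
  expect_equal(m$n, 5L)  # unknown-truth nucleus excluded

  # all-malignant predictor on balanced truth
  truth2 <- tibble::tibble(nucleus = paste0("n", 1:10),
                           malignant = rep(c(TRUE, FALSE), 5))
  allm <- tibble::tibble(nucleus = truth2$nucleus, predicted = "malignant")
  m2 <- cnv_caller_metrics(allm, truth2)
  expect_equal(c(m2$sensitivity, m2$specificity, m2$accuracy), c(1, 0, 0.5))

  # random fixture vs direct recount
  set.seed(3)
  truth3 <- tibble::tibble(nucleus = paste0("n", 1:200),
                           malignant = sample(c(TRUE, FALSE, NA), 200, replace = TRUE))
  pred3 <- tibble::tibble(nucleus = truth3$nucleus,
                          predicted = sample(c("malignant", "nonmalignant"), 200,
                                             replace = TRUE))
  m3 <- cnv_caller_metrics(pred3, truth3)
  keep <- !is.na(truth3$malignant)
  pr <- pred3$predicted[keep] == "malignant"
  tr <- truth3$malignant[keep]
  expect_equal(m3$sensitivity, sum(pr & tr) / sum(tr))
  expect_equal(m3$specificity, sum(!pr & !tr) / sum(!tr))
  expect_equal(m3$accuracy, mean(pr == tr))
})

test_that("bulk and single-nucleus compositions agree for sampled nuclei", {
  set.seed(4)
  pops <- paste0("pop", 1:6)
  bulk <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  names(bulk) <- pops
  nucs <- table(factor(sample(pops, 300, replace = TRUE, prob = bulk), levels = pops))
  sn <- as.numeric(nucs) / 300
  names(sn) <- pops
  expect_gte(abundance_concordance(bulk, sn), 0.9)
  expect_equal(abundance_concordance(bulk, bulk), 1)
  # permuted composition destroys the concordance on average
  perm_r <- replicate(50, abundance_concordance(bulk, stats::setNames(sample(unname(sn)), names(sn))))
  expect_lt(abs(mean(perm_r)), 0.35)
  expect_error(abundance_concordance(bulk[1:2], sn[1:2]), "3 shared")
})

test_that("lower allele dropout yields more called nuclei", {
  frac_called <- sapply(c(0.3, 0.05), function(rate) {
    cfg <- sim_config(n_clones = 2, n_sections = 15, allele_dropout_rate = rate,
                      n_nuclei = 400, n_genes = 120, n_shared_program_genes = 0,
                      n_signature_genes_per_population = 20, n_cnv_per_branch = 0)
    tree <- simulate_phylogeny(cfg, seed = 5)
    fr <- simulate_section_fractions(tree, cfg, seed = 5)
    nuc <- simulate_nuclei(tree, fr, cfg, seed = 5)
    calls <- call_nuclei(nuc$genotype)
    mean(calls$category == "called")
  })
  expect_gt(frac_called[2], frac_called[1])
})
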