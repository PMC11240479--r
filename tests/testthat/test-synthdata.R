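test_that("simulated phylogenies satisfy clone-tree invariants (sweep)", {
  # 60 trees at k = 4 (scaled from a larger sweep for runtime); validate_clone_tree
  # checks root uniqueness, acyclicity and 0 <= m <= t
  cfg <- sim_config(n_clones = 4)
  for (seed in 1:60) {
    tree <- simulate_phylogeny(cfg, seed = seed)
    expect_silent(validate_clone_tree(tree))
    st <- tree$allele_state
    expect_true(all(st$m <= st$t & st$t >= 0))
  }
})

test_that("a hemizygous loss can delete an inherited mutant allele", {
  cfg <- sim_config(n_clones = 3, n_cnv_per_branch = 2, p_loss_hits_mutant = 1)
  hit <- FALSE
  for (seed in 1:40) {
    tree <- simulate_phylogeny(cfg, seed = seed)
    loss <- tree$cnv_segments[tree$cnv_segments$event == "loss", ]
    if (!nrow(loss)) next
    st <- tree$allele_state
    zero_one <- st[st$m == 0 & st$t == 1, ]
    if (nrow(zero_one)) {
      hit <- TRUE
      # the (0,1) state only appears below a loss branch
      expect_true(all(zero_one$t == 1))
    }
  }
  expect_true(hit)
})

test_that("single-clone tumors have truncal het-diploid mutations only", {
  tree <- simulate_phylogeny(sim_config(n_clones = 1, n_cnv_per_branch = 0), seed = 3)
  expect_equal(length(tree$clone_ids), 1L)
  expect_true(all(tree$allele_state$m == 1 & tree$allele_state$t == 2))
})

test_that("section fractions satisfy invariants and are reproducible", {
  cfg <- sim_config(n_clones = 4, n_sections = 50)
  tree <- simulate_phylogeny(cfg, seed = 5)
  fr1 <- simulate_section_fractions(tree, cfg, seed = 9)
  fr2 <- simulate_section_fractions(tree, cfg, seed = 9)
  expect_identical(fr1, fr2)
  expect_silent(validate_fractions(fr1, tree))
  expect_true(all(fr1 >= 0 & fr1 <= 1))
  expect_true(all(colSums(fr1) <= 1 + 1e-9))
})

test_that("plane rotation produces a composition breakpoint", {
  cfg <- sim_config(n_clones = 3, n_sections = 60, plane_rotation_section = 31)
  tree <- simulate_phylogeny(cfg, seed = 2)
  fr <- simulate_section_fractions(tree, cfg, seed = 2)
  pur <- purity_from_fractions(fr, tree)
  jumps <- abs(diff(pur))
  # the breakpoint jump dominates the smooth within-block steps
  expect_gt(jumps[30], 3 * stats::median(jumps[-30]))
})

test_that("read counts follow the binomial mixture model", {
  # truncal het diploid at purity 0.8: expected VAF 0.4; observed mean within 3 SE
  tree <- tiny_tree()
  fr <- matrix(c(0.8, 0), 2, 1, dimnames = list(c("clone1", "clone2"), "s1"))
  fr <- fr[, rep(1, 50), drop = FALSE]
  colnames(fr) <- paste0("s", 1:50)
  cfg <- sim_config(n_clones = 2, depth_mean = 1.7e4, n_sections = 50)
  counts <- simulate_read_counts(tree, fr, cfg, seed = 7)
  vaf <- compute_vaf(counts$alt, counts$ref)
  se <- sqrt(0.4 * 0.6 / (1.7e4 * 50))
  expect_lt(abs(mean(vaf["m1", ]) - 0.4), 3 * se)
  # a mutation with expected VAF 0 never yields alternate reads
  expect_true(all(counts$alt["m2", ] == 0))
})

test_that("doubling depth roughly halves VAF sampling variance", {
  tree <- tiny_tree()
  fr <- matrix(c(0.8, 0), 2, 1, dimnames = list(c("clone1", "clone2"), "s1"))
  fr <- fr[, rep(1, 300), drop = FALSE]
  colnames(fr) <- paste0("s", 1:300)
  v <- sapply(c(1000, 2000), function(d) {
    cfg <- sim_config(n_clones = 2, depth_mean = d, n_sections = 300)
    counts <- simulate_read_counts(tree, fr, cfg, seed = 11)
    var(compute_vaf(counts$alt, counts$ref)["m1", ])
  })
  expect_gt(v[1] / v[2], 1.5)
  expect_lt(v[1] / v[2], 2.7)
})

test_that("noiseless single-population expression is proportional to abundance", {
  cfg <- sim_config(n_clones = 1, n_sections = 30, noise_sd = 0, program_sd = 0,
                    n_shared_program_genes = 0, n_cnv_per_branch = 0,
                    n_genes = 250, n_normal_populations = 1)
  tree <- simulate_phylogeny(cfg, seed = 1)
  fr <- simulate_section_fractions(tree, cfg, seed = 1)
  ex <- simulate_expression(tree, fr, cfg, seed = 1)
  g <- ex$signature_genes[["clone1"]][1]
  X <- ex$tumor
  # marker expression = 0.5 * 1 (all populations) + signal * clone abundance
  expect_equal(unname(X[g, ]), unname(0.5 + fr["clone1", ]), tolerance = 1e-10)
})

test_that("CNV dosage strengthens correlation with the carrier clade abundance", {
  cfg <- sim_config(n_clones = 2, n_sections = 60, program_sd = 0,
                    n_shared_program_genes = 0, n_cnv_per_branch = 0, n_genes = 400,
                    n_signature_genes_per_population = 20)
  tree <- simulate_phylogeny(cfg, seed = 21)
  # plant gained segments on the subclone covering many background genes
  tree$cnv_segments <- tibble::tibble(chrom = paste0("chr", 1:8), start = 0L,
                                      end = 200000001L, clone = "clone2",
                                      total_copies = 3L, event = "gain")
  fr <- simulate_section_fractions(tree, cfg, seed = 21)
  ex <- simulate_expression(tree, fr, cfg, seed = 21)
  cum2 <- cumulative_fractions(fr, tree)["clone2", ]
  nonsig <- setdiff(rownames(ex$tumor), unlist(ex$signature_genes))
  dosed <- nonsig[ex$dosage[nonsig, "clone2"] > 1]
  flat <- nonsig[ex$dosage[nonsig, "clone2"] == 1]
  r_dosed <- mean(apply(ex$tumor[dosed, , drop = FALSE], 1, cor, y = cum2))
  r_flat <- mean(apply(ex$tumor[flat, , drop = FALSE], 1, cor, y = cum2))
  expect_gt(length(dosed), 30)
  expect_gt(r_dosed, r_flat + 0.2)
})

test_that("normal series carry no malignant-abundance signal beyond chance", {
  cfg <- sim_config(n_clones = 2, n_sections = 40, n_genes = 300,
                    n_signature_genes_per_population = 20, n_normals = 1,
                    n_normal_sections = 60, n_cnv_per_branch = 0)
  tree <- simulate_phylogeny(cfg, seed = 4)
  fr <- simulate_section_fractions(tree, cfg, seed = 4)
  ex <- simulate_expression(tree, fr, cfg, seed = 4)
  Xn <- ex$normals[[1]]
  # malignant marker genes in the normal series are flat noise: their pairwise
  # correlations match the null spread of the background genes
  mal_genes <- unlist(ex$signature_genes[tree$clone_ids])
  cc <- cor(t(Xn[mal_genes, ]))
  off <- cc[upper.tri(cc)]
  expect_lt(abs(mean(off)), 0.05)
  expect_lt(quantile(abs(off), 0.99), 4 / sqrt(ncol(Xn)))
})

test_that("nucleus genotype reads respect carrier state and dropout", {
  cfg0 <- sim_config(n_clones = 2, n_sections = 20, allele_dropout_rate = 0,
                     n_nuclei = 200, n_genes = 220,
                     n_signature_genes_per_population = 20, n_cnv_per_branch = 0)
  tree <- simulate_phylogeny(cfg0, seed = 6)
  fr <- simulate_section_fractions(tree, cfg0, seed = 6)
  nuc <- simulate_nuclei(tree, fr, cfg0, seed = 6)
  lab <- nuc$labels
  geno <- merge(nuc$genotype, lab, by = "nucleus")
  mal <- geno[geno$malignant, ]
  nonmal <- geno[!geno$malignant, ]
  # without dropout every truncal locus of a malignant nucleus shows mutant reads
  expect_true(all(mal$alt > 0))
  # nonmalignant nuclei never show mutant reads
  expect_true(all(nonmal$alt == 0))
})

test_that("allele dropout hits the reference and mutant allele symmetrically", {
  rate <- 0.2
  cfg <- sim_config(n_clones = 1, n_sections = 10, allele_dropout_rate = rate,
                    n_nuclei = 2000, n_genes = 120,
                    n_signature_genes_per_population = 20, n_cnv_per_branch = 0,
                    n_genotype_loci = 3)
  tree <- simulate_phylogeny(cfg, seed = 8)
  fr <- simulate_section_fractions(tree, cfg, seed = 8)
  nuc <- simulate_nuclei(tree, fr, cfg, seed = 8)
  geno <- merge(nuc$genotype, nuc$labels, by = "nucleus")
  mal <- geno[geno$malignant & geno$alt + geno$ref > 0, ]
  per_nuc <- tapply(mal$alt == 0, mal$nucleus, any)
  # closed form: a malignant nucleus shows >= 1 all-reference locus with
  # probability 1 - (1 - rate/2)^3 when dropout is allele-symmetric
  p_expect <- 1 - (1 - rate / 2)^3
  p_obs <- mean(per_nuc)
  se <- sqrt(p_expect * (1 - p_expect) / length(per_nuc))
  expect_lt(abs(p_obs - p_expect), 4 * se)
})

test_that("the identifiability screen rejects profiles admitting a second exact topology", {
  tree <- tiny_tree()
  # parent fraction always above child cumulative -> a sibling arrangement is
  # impossible at k = 2 (only one tree), so use a 3-clone chain
  parent <- c(clone1 = NA, clone2 = "clone1", clone3 = "clone2")
  tr3 <- clone_tree(parent,
                    tibble::tibble(mutation_id = "m1", clone = "clone1"),
                    allele_state = tibble::tibble(mutation_id = "m1", clone = names(parent),
                                                  m = 1L, t = 2L))
  S <- 20
  ambiguous <- rbind(clone1 = rep(0.9, S), clone2 = rep(0.3, S), clone3 = rep(0.1, S))
  expect_false(clonesect:::profiles_identifiable(ambiguous, tr3))
  # the subclone sweep pushes clone2 + clone3 above clone1 somewhere, so the
  # sibling arrangement is infeasible and only the true chain fits
  crossing <- rbind(clone1 = rep(0.9, S),
                    clone2 = 0.3 + 0.55 * sin(seq(0, pi, length.out = S)),
                    clone3 = rep(0.25, S))
  expect_true(clonesect:::profiles_identifiable(crossing, tr3))
})
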