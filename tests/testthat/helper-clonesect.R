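# Shared helpers for the test suite. All fixtures are built in code.

# Adjusted Rand index (independent of any clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# minimal two-clone tree: clone1 -> clone2, one het-diploid mutation per branch
tiny_tree <- function() {
  clone_tree(
    parent = c(clone1 = NA, clone2 = "clone1"),
    mutations = tibble::tibble(
      mutation_id = c("m1", "m2"), clone = c("clone1", "clone2"),
      chrom = c("chr1", "chr2"), start = c(100L, 200L), end = c(101L, 201L)
    ),
    allele_state = tibble::tibble(
      mutation_id = c("m1", "m1", "m2", "m2"),
      clone = c("clone1", "clone2", "clone1", "clone2"),
      m = c(1L, 1L, 0L, 1L), t = c(2L, 2L, 2L, 2L)
    )
  )
}

# expression matrix with two planted correlated blocks on a shared driver
block_expression <- function(n_per_block = 20, n_noise = 20, n_samples = 30,
                             noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n_samples)
  z2 <- rnorm(n_samples)
  X <- rbind(
    t(sapply(seq_len(n_per_block), function(i) z1 + rnorm(n_samples, 0, noise_sd))),
    t(sapply(seq_len(n_per_block), function(i) z2 + rnorm(n_samples, 0, noise_sd))),
    matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
  )
  noise_names <- if (n_noise > 0) paste0("n", seq_len(n_noise)) else character()
  rownames(X) <- c(paste0("a", seq_len(n_per_block)), paste0("b", seq_len(n_per_block)),
                   noise_names)
  colnames(X) <- paste0("s", seq_len(n_samples))
  X
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
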