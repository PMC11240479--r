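#' Simulation configuration for a serial-section tumor
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' desk-scale version of a serially sectioned IDH-mutant astrocytoma: five
#' clones, 69 usable sections, three diagnostic truncal amplicon loci at
#' ~17,000x mean coverage, four matched normal-brain section series of 94
#' sections each, and 809 genotyped nuclei.
#'
#' @param n_clones Number of malignant clones (root = truncal clone).
#' @param n_sections Number of serial tumor sections.
#' @param plane_rotation_section Optional section index at which the plane of
#'   sectioning rotates; clone mixing profiles are redrawn from that section
#'   on, producing a composition breakpoint. `NULL` for none.
#' @param n_mutations_per_branch Somatic SNVs placed on each branch.
#' @param n_cnv_per_branch Copy-number events placed on each branch.
#' @param p_loss_hits_mutant Probability that a hemizygous loss overlapping an
#'   inherited SNV deletes the mutant (rather than the reference) allele.
#' @param depth_mean Mean amplicon sequencing depth per mutation per section
#'   (Poisson).
#' @param n_genes Genes in the expression matrices.
#' @param n_signature_genes_per_population Marker genes per population
#'   (clones and nonmalignant cell types alike).
#' @param signal Amplitude added to the expression baseline for a
#'   population's marker genes.
#' @param noise_sd Gaussian noise SD on expression values.
#' @param program_sd Relative amplitude of the per-population latent program
#'   factor: a smooth random profile shared by a population's marker genes,
#'   scaled to `program_sd` times the standard deviation of that
#'   population's abundance-driven expression component. It models
#'   coordinated regulatory variation of a transcriptional program beyond
#'   cell composition, which tightens within-module correlations and
#'   dilutes between-module correlations, as in real coexpression data;
#'   0 disables.
#' @param cnv_dosage Named numeric multipliers applied to the expression of
#'   genes inside CNV segments: `gain`, `loss`, `cnloh`.
#' @param n_normal_populations Nonmalignant cell types mixed into sections.
#' @param n_normals Number of matched normal-brain section series.
#' @param n_normal_sections Sections per normal series.
#' @param n_shared_program_genes Genes loaded on a coexpression program active
#'   in tumor *and* every normal series (exercises differential coexpression
#'   specificity); 0 disables.
#' @param n_nuclei Nuclei in the single-nucleus simulation.
#' @param n_genotype_loci Truncal loci genotyped per nucleus.
#' @param nucleus_depth_mean Mean reads per locus per nucleus (Poisson).
#' @param allele_dropout_rate Probability that a heterozygous locus amplifies
#'   from a single allele (all-reference or all-alternate reads, equally
#'   likely).
#' @param nucleus_expr_scale Library-size factor for per-nucleus Poisson
#'   expression counts.
#' @param seed Integer seed driving the whole simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 5,
                       n_sections = 69,
                       plane_rotation_section = NULL,
                       n_mutations_per_branch = 3,
                       n_cnv_per_branch = 1,
                       p_loss_hits_mutant = 0.5,
                       depth_mean = 1.7e4,
                       n_genes = 1000,
                       n_signature_genes_per_population = 50,
                       signal = 1,
                       noise_sd = 0.05,
                       program_sd = 0.6,
                       cnv_dosage = c(gain = 1.5, loss = 0.5, cnloh = 1),
                       n_normal_populations = 3,
                       n_normals = 4,
                       n_normal_sections = 94,
                       n_shared_program_genes = 40,
                       n_nuclei = 809,
                       n_genotype_loci = 3,
                       nucleus_depth_mean = 200,
                       allele_dropout_rate = 0.1,
                       nucleus_expr_scale = 5,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_clones >= 1, n_sections >= 1, n_mutations_per_branch >= 1,
    n_cnv_per_branch >= 0, depth_mean > 0, n_genes >= 1,
    n_signature_genes_per_population >= 1, noise_sd >= 0, program_sd >= 0, signal > 0,
    allele_dropout_rate >= 0, allele_dropout_rate < 1,
    n_nuclei >= 1, n_genotype_loci >= 1, nucleus_depth_mean > 0,
    p_loss_hits_mutant >= 0, p_loss_hits_mutant <= 1
  )
  if (!is.null(plane_rotation_section)) {
    stopifnot(plane_rotation_section > 1, plane_rotation_section <= n_sections)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a clone phylogeny with SNVs and CNVs on branches
#'
#' Builds a rooted tree by attaching each new clone to a uniformly random
#' existing clone, then drops `n_mutations_per_branch` SNVs and
#' `n_cnv_per_branch` arm-scale CNV events on every branch. Allele states
#' start heterozygous diploid (m = 1, t = 2) in the clone of origin and all
#' descendants, and are rewritten by CNVs on descendant branches: a gain
#' duplicates the mutant or reference allele with equal probability
#' (t becomes 3); copy-neutral LOH duplicates the mutant allele (m = 2,
#' t = 2), the signature of a truncal TP53-style event whose VAF equals tumor
#' purity; a hemizygous loss (t = 1) deletes the mutant allele with
#' probability `p_loss_hits_mutant`, emulating a chr2q-style loss removing an
#' upstream truncal mutation from one clade.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to the current RNG stream).
#' @return A [clone_tree()].
#' @export
simulate_phylogeny <- function(config, seed = NULL) {
  with_seed(seed, {
    k <- config$n_clones
    ids <- paste0("clone", seq_len(k))
    parent <- c(NA_character_,
                if (k > 1) vapply(2:k, function(i) ids[sample.int(i - 1L, 1L)], ""))
    names(parent) <- ids

    n_mut <- config$n_mutations_per_branch
    muts <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      chrom <- paste0("chr", sample.int(22L, n_mut, replace = TRUE))
      pos <- sample.int(2e8L, n_mut)
      ref <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
      tibble::tibble(
        mutation_id = paste0(chrom, ":", pos, ":", ref, ">", alt),
        clone = ids[i], chrom = chrom, start = pos - 1L, end = pos
      )
    }))

    # arm-scale CNV segments on each branch
    cnv <- NULL
    if (config$n_cnv_per_branch > 0) {
      cnv <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
        n <- config$n_cnv_per_branch
        chrom <- paste0("chr", sample.int(22L, n, replace = TRUE))
        event <- sample(c("gain", "loss", "cn-LOH"), n, replace = TRUE)
        start <- ifelse(stats::runif(n) < 0.5, 0L, 120000000L)
        tibble::tibble(
          chrom = chrom, start = start, end = start + 120000000L,
          clone = ids[i],
          total_copies = c(gain = 3L, loss = 1L, `cn-LOH` = 2L)[event],
          event = event
        )
      }))
    }

    desc <- function(cl) {  # subtree ids including cl
      out <- cl
      repeat {
        nxt <- ids[!is.na(parent) & parent %in% out & !ids %in% out]
        if (!length(nxt)) break
        out <- c(out, nxt)
      }
      out
    }

    # baseline het-diploid state in carriers, wildtype-diploid elsewhere
    state <- expand.grid(mutation_id = muts$mutation_id, clone = ids,
                         stringsAsFactors = FALSE)
    state$m <- 0L
    state$t <- 2L
    for (i in seq_len(nrow(muts))) {
      carriers <- desc(muts$clone[i])
      sel <- state$mutation_id == muts$mutation_id[i] & state$clone %in% carriers
      state$m[sel] <- 1L
    }

    # CNVs rewrite allele states of mutations they cover in the clades below them
    if (!is.null(cnv)) {
      anc <- function(cl) {  # ancestors including cl
        out <- cl
        while (!is.na(parent[[out[length(out)]]])) out <- c(out, parent[[out[length(out)]]])
        out
      }
      for (i in seq_len(nrow(cnv))) {
        seg <- cnv[i, ]
        clade <- desc(seg$clone)
        hit <- muts$chrom == seg$chrom &
          intervals_overlap(muts$start, muts$end, seg$start, seg$end) &
          muts$clone %in% anc(seg$clone)
        for (mid in muts$mutation_id[hit]) {
          sel <- state$mutation_id == mid & state$clone %in% clade
          if (seg$event == "gain") {
            dup_mut <- stats::runif(1) < 0.5
            state$t[sel] <- 3L
            state$m[sel] <- pmin(state$m[sel] + as.integer(dup_mut & state$m[sel] > 0), 3L)
          } else if (seg$event == "loss") {
            hits_mut <- stats::runif(1) < config$p_loss_hits_mutant
            state$t[sel] <- 1L
            state$m[sel] <- if (hits_mut) 0L else pmin(state$m[sel], 1L)
          } else {  # cn-LOH duplicates the mutant allele
            state$t[sel] <- 2L
            state$m[sel] <- ifelse(state$m[sel] > 0, 2L, 0L)
          }
        }
      }
    }

    clone_tree(parent, muts, cnv, tibble::as_tibble(state))
  })
}

# smooth positive profile over sections: baseline + random Gaussian bumps;
# bump centers can be drawn preferentially where `weight` is high (used to
# place subclone sweeps inside their parent clade's territory)
smooth_profile <- function(n_sections, baseline, n_bumps = 2L,
                           amp_range = c(0.5, 1.5), width_range = c(0.1, 0.3),
                           weight = NULL) {
  s <- seq_len(n_sections)
  y <- rep(baseline, n_sections)
  for (b in seq_len(n_bumps)) {
    ctr <- if (is.null(weight)) {
      stats::runif(1, 1, n_sections)
    } else {
      sample.int(n_sections, 1L, prob = weight^2 + 1e-9) + stats::runif(1, -0.5, 0.5)
    }
    wid <- stats::runif(1, width_range[1], width_range[2]) * n_sections
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    y <- y + amp * exp(-((s - ctr)^2) / (2 * wid^2))
  }
  y
}

#' Simulate per-section clone fractions
#'
#' Clone composition is built hierarchically in cumulative space, mirroring
#' clonal succession along the section axis: tumor purity (the truncal
#' clone's cumulative abundance) follows a smooth profile spanning roughly
#' 0.35-0.85, and each child clone occupies a smoothly varying *share* of
#' its parent's clade, rising to near-complete local replacement (share up
#' to 0.95) at its bump peaks and receding to near zero elsewhere — the
#' sweep-in/sweep-out gradients seen in serially sectioned tumors. Exact-
#' genotype fractions are recovered as cumulative minus children, which
#' keeps them nonnegative, so the subclone-sum constraint holds by
#' construction. If `plane_rotation_section` is set, all profiles are
#' redrawn from that section on, giving a composition discontinuity.
#'
#' @param tree A [clone_tree()].
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return Clones x sections matrix of exact-genotype fractions with a
#'   `"nonmalignant"` attribute holding the per-section remainder.
#' @export
simulate_section_fractions <- function(tree, config, seed = NULL, max_redraws = 100) {
  with_seed(seed, {
    ids <- tree$clone_ids
    k <- length(ids)
    S <- config$n_sections
    root <- tree_root(tree)
    kids <- clone_children(tree)
    draw_block <- function(n) {
      cum <- matrix(0, k, n, dimnames = list(ids, NULL))
      pr_lo <- stats::runif(1, 0.30, 0.50)
      pr_hi <- stats::runif(1, 0.70, 0.90)
      b <- smooth_profile(n, baseline = 0)
      b <- (b - min(b)) / (max(b) - min(b) + 1e-12)
      cum[root, ] <- pr_lo + (pr_hi - pr_lo) * b
      todo <- root
      while (length(todo)) {
        cl <- todo[1]
        todo <- todo[-1]
        ch <- kids[[cl]]
        if (length(ch)) {
          # a child clone sweeps parts of its parent clade's territory in a
          # few bumps whose widths are fractions of the parent's effective
          # territory width: the parent keeps regions the child never
          # reached (nested clonal niches separate parent from child
          # prevalence profiles), while at sweep peaks the child replaces
          # up to 90% of the clade (the succession signal that identifies
          # the topology)
          s_axis <- seq_len(n)
          mu_p <- sum(s_axis * cum[cl, ]) / sum(cum[cl, ])
          w_p <- sqrt(sum(cum[cl, ] * (s_axis - mu_p)^2) / sum(cum[cl, ]))
          u <- t(vapply(ch, function(x) {
            h <- rep(0.01, n)
            for (bn in 1:3) {
              wid <- max(1.5, stats::runif(1, 0.35, 0.8) * w_p)
              ctr <- sample.int(n, 1L, prob = cum[cl, ]^2 + 1e-9) +
                stats::runif(1, -0.5, 0.5)
              amp <- if (bn == 1) 1 else stats::runif(1, 0.4, 1)
              h <- h + amp * exp(-((s_axis - ctr)^2) / (2 * wid^2))
            }
            0.90 * h / max(h)
          }, numeric(n)))
          tot <- colSums(u)
          u <- sweep(u, 2, pmax(1, tot / 0.95), "/")  # joint share cap
          for (i in seq_along(ch)) cum[ch[i], ] <- cum[cl, ] * u[i, ]
          todo <- c(todo, ch)
        }
      }
      cum
    }
    draw_cum <- function() {
      if (!is.null(config$plane_rotation_section)) {
        bp <- config$plane_rotation_section
        cbind(draw_block(bp - 1L), draw_block(S - bp + 1L))
      } else {
        draw_block(S)
      }
    }
    # The stated world is a tumor whose clonal architecture is recoverable
    # from its sections: profiles are redrawn until (i) every wrong topology
    # is infeasible by a margin well above amplicon noise and (ii) clone
    # prevalence profiles are mutually separated. See the methods vignette.
    cum <- draw_cum()
    tries <- 0L
    while (!profiles_identifiable(cum, tree) && tries < max_redraws) {
      cum <- draw_cum()
      tries <- tries + 1L
    }
    if (tries > 0) cs_log("simulate_section_fractions", redraws = tries)
    fr <- cum
    for (cl in ids) {
      if (length(kids[[cl]])) {
        fr[cl, ] <- cum[cl, ] - colSums(cum[kids[[cl]], , drop = FALSE])
      }
    }
    dimnames(fr) <- list(ids, paste0("s", seq_len(S)))
    attr(fr, "nonmalignant") <- 1 - colSums(fr)
    validate_fractions(fr, tree)
    cs_log("simulate_section_fractions", clones = k, sections = S)
    fr
  })
}

# Screen a cumulative-abundance draw for clonal identifiability:
# (i) margin: every topology other than the true one, when solved exactly
#     against the noiseless cumulative profiles, implies a negative
#     exact-genotype fraction of at least `margin` somewhere (so at
#     realistic sequencing noise no wrong tree can masquerade as exact);
# (ii) separation: pairwise Euclidean distance between clone cumulative
#     profiles is at least `sep_per_section * sqrt(S)` (so prevalence
#     clusters are resolvable).
# Trees with more than 7 clones skip the enumeration screen.
profiles_identifiable <- function(cum, tree, margin = 0.03, sep_per_section = 0.045) {
  k <- nrow(cum)
  if (k < 2) return(TRUE)
  dm <- as.matrix(stats::dist(cum))
  if (min(dm[upper.tri(dm)]) < sep_per_section * sqrt(ncol(cum))) return(FALSE)
  if (k > 7) return(TRUE)
  ids <- rownames(cum)
  ridx <- match(tree_root(tree), ids)
  perm <- c(ridx, setdiff(seq_len(k), ridx))
  cum_o <- cum[perm, , drop = FALSE]
  true_parent_int <- match(tree$parent[ids[perm]], ids[perm])
  for (tr in enumerate_trees(k)) {
    if (identical(as.integer(tr), as.integer(true_parent_int))) next
    f <- solve(subtree_matrix_int(tr), cum_o)
    if (max(-f) < margin) return(FALSE)
  }
  TRUE
}

#' Simulate amplicon read counts per mutation per section
#'
#' For each mutation and section the expected VAF follows the copy-number-
#' aware mixture model ([expected_vaf()]) at the section's clone fractions;
#' sequencing depth is Poisson around `depth_mean` and alternate-allele reads
#' are binomial at the expected VAF.
#'
#' @param tree A [clone_tree()].
#' @param fractions Output of [simulate_section_fractions()].
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return List with integer matrices `alt` and `ref` (mutations x sections)
#'   and the numeric matrix `expected` of model VAFs.
#' @export
simulate_read_counts <- function(tree, fractions, config, seed = NULL) {
  with_seed(seed, {
    ev <- expected_vaf_matrix(tree, fractions)
    n <- nrow(ev); S <- ncol(ev)
    depth <- matrix(stats::rpois(n * S, config$depth_mean), n, S)
    p <- ifelse(is.na(ev), 0, ev)
    alt <- matrix(stats::rbinom(n * S, as.vector(depth), as.vector(p)), n, S)
    ref <- depth - alt
    dimnames(alt) <- dimnames(ref) <- dimnames(ev)
    cs_log("simulate_read_counts", mutations = n, sections = S, depth_mean = config$depth_mean)
    list(alt = alt, ref = ref, expected = ev)
  })
}

# gene coordinates + population signatures + CNV dosage, shared by bulk and sn
build_gene_model <- function(tree, config) {
  k <- length(tree$clone_ids)
  n_pop <- k + config$n_normal_populations
  pops <- c(tree$clone_ids, paste0("normal", seq_len(config$n_normal_populations)))
  genes <- paste0("g", seq_len(config$n_genes))
  gene_meta <- tibble::tibble(
    gene = genes,
    chrom = paste0("chr", sample.int(22L, config$n_genes, replace = TRUE)),
    start = sample.int(200000000L, config$n_genes, replace = TRUE)
  )
  gene_meta$end <- gene_meta$start + 10000L

  nsig <- config$n_signature_genes_per_population
  need <- n_pop * nsig + config$n_shared_program_genes
  if (need > config$n_genes) stop("n_genes too small for the requested signature genes")
  sig_genes <- split(genes[seq_len(n_pop * nsig)], rep(seq_len(n_pop), each = nsig))
  shared_genes <- if (config$n_shared_program_genes > 0) {
    genes[n_pop * nsig + seq_len(config$n_shared_program_genes)]
  } else character()

  # marker genes of a clone are expressed in that clone and all descendants,
  # so their expression tracks *cumulative* clone abundance
  A <- subtree_matrix(tree)
  signature <- matrix(0.5, config$n_genes, n_pop, dimnames = list(genes, pops))
  for (i in seq_len(n_pop)) {
    carriers <- if (i <= k) tree$clone_ids[A[tree$clone_ids[i], ] > 0] else pops[i]
    signature[sig_genes[[i]], carriers] <- 0.5 + config$signal
  }

  # per-(gene, clone) dosage from CNV segments carried by the clone
  dosage <- matrix(1, config$n_genes, n_pop, dimnames = list(genes, pops))
  if (nrow(tree$cnv_segments)) {
    mult <- c(gain = unname(config$cnv_dosage["gain"]),
              loss = unname(config$cnv_dosage["loss"]),
              `cn-LOH` = unname(config$cnv_dosage["cnloh"]))
    for (i in seq_len(nrow(tree$cnv_segments))) {
      seg <- tree$cnv_segments[i, ]
      carriers <- tree$clone_ids[A[seg$clone, ] > 0]
      g <- genes_in_segment(gene_meta, seg)
      dosage[g, carriers] <- dosage[g, carriers, drop = FALSE] * mult[[seg$event]]
    }
  }

  list(pops = pops, gene_meta = gene_meta, signature = signature, dosage = dosage,
       signature_genes = stats::setNames(sig_genes, pops), shared_genes = shared_genes)
}

# population abundances (clones + normal cell types) for given clone fractions
population_abundance <- function(tree, fractions, config) {
  nm <- attr(fractions, "nonmalignant")
  if (is.null(nm)) nm <- pmax(0, 1 - colSums(fractions))
  n_np <- config$n_normal_populations
  S <- ncol(fractions)
  split_raw <- t(vapply(seq_len(n_np), function(i) smooth_profile(S, baseline = 0.05),
                        numeric(S)))
  split_frac <- sweep(split_raw, 2, colSums(split_raw), "/")
  ab <- rbind(fractions, sweep(split_frac, 2, nm, "*"))
  rownames(ab) <- c(rownames(fractions), paste0("normal", seq_len(n_np)))
  ab
}

#' Simulate bulk expression for tumor sections and matched normal series
#'
#' Expression is an abundance-weighted mixture of population signatures with
#' CNV dosage effects and Gaussian noise:
#' `expr(g, s) = sum_pop abundance(pop, s) * signature(g, pop) * dosage(g, pop) + N(0, noise_sd)`.
#' Each normal series has zero malignant abundance and its own nonmalignant
#' mixing profiles. A configurable shared coexpression program (active in the
#' tumor and in every normal series, driven by an independent smooth latent
#' factor per series) provides gene pairs correlated in both tissue classes.
#'
#' @inheritParams simulate_read_counts
#' @return List with `tumor` (genes x sections matrix), `normals` (list of
#'   genes x sections matrices), `gene_meta`, `signature`, `dosage`,
#'   `signature_genes` (named list per population), `shared_genes`, and
#'   `abundance` (populations x sections used for the tumor).
#' @export
simulate_expression <- function(tree, fractions, config, seed = NULL) {
  with_seed(seed, {
    gm <- build_gene_model(tree, config)
    ab <- population_abundance(tree, fractions, config)
    S <- ncol(fractions)

    mix <- function(abund) {
      X <- (gm$signature * gm$dosage) %*% abund
      X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X), ncol(X))
    }
    add_program <- function(X, genes, amplitude, z = NULL) {
      if (!length(genes) || amplitude == 0) return(X)
      if (is.null(z)) {
        z <- smooth_profile(ncol(X), baseline = 0)
        z <- (z - mean(z)) / stats::sd(z)
      }
      X[genes, ] <- X[genes, , drop = FALSE] + outer(rep(amplitude, length(genes)), z)
      X
    }
    # Each population's program carries coordinated regulatory variation
    # beyond abundance (one latent factor per population, scaled to the
    # population's own abundance-driven signal; clone programs are active in
    # the tumor only). The factor is defined as variation orthogonal to cell
    # composition: lightly smoothed noise residualized against all abundance
    # profiles, since at ~70 sections even independent smooth draws correlate
    # incidentally with the (equally smooth) composition profiles and would
    # contaminate eigengene-abundance correlations.
    latent_factor <- function(n, basis) {
      z <- as.numeric(stats::filter(stats::rnorm(n), rep(1 / 3, 3), circular = TRUE))
      z <- qr.resid(qr(cbind(1, t(basis))), z)
      (z - mean(z)) / stats::sd(z)
    }
    add_population_programs <- function(X, pops, abund) {
      for (p in pops) {
        drive <- config$signal * stats::sd(abund[p, ])
        X <- add_program(X, gm$signature_genes[[p]], config$program_sd * drive,
                         z = latent_factor(ncol(X), abund))
      }
      X
    }

    # marker genes of a clone track its *cumulative* abundance, so the
    # program amplitude is scaled to that
    drive_tumor <- rbind(cumulative_fractions(fractions, tree),
                         ab[setdiff(gm$pops, tree$clone_ids), , drop = FALSE])
    tumor <- add_population_programs(mix(ab), gm$pops, drive_tumor)
    tumor <- add_program(tumor, gm$shared_genes, config$signal / 2)
    colnames(tumor) <- colnames(fractions)

    k <- length(tree$clone_ids)
    normals <- lapply(seq_len(config$n_normals), function(i) {
      zero_fr <- matrix(0, k, config$n_normal_sections,
                        dimnames = list(tree$clone_ids,
                                        paste0("n", i, "_s", seq_len(config$n_normal_sections))))
      attr(zero_fr, "nonmalignant") <- rep(1, config$n_normal_sections)
      ab_n <- population_abundance(tree, zero_fr, config)
      normal_pops <- setdiff(gm$pops, tree$clone_ids)
      Xn <- add_population_programs(mix(ab_n), normal_pops, ab_n)
      Xn <- add_program(Xn, gm$shared_genes, config$signal / 2)
      colnames(Xn) <- colnames(zero_fr)
      Xn
    })

    cs_log("simulate_expression", genes = config$n_genes, sections = S,
           normals = config$n_normals)
    c(list(tumor = tumor, normals = normals, abundance = ab), gm)
  })
}

#' Simulate single-nucleus genotype reads and expression counts
#'
#' Each nucleus is assigned a section uniformly and a population from that
#' section's abundances. At each genotyped truncal locus, reads are Poisson in
#' depth and binomial in the allele fraction `m/t` of the nucleus's
#' population; with probability `allele_dropout_rate` a heterozygous locus
#' amplifies from a single allele (all-reference or all-alternate with equal
#' probability). Expression counts are Poisson around the population
#' signature scaled by `nucleus_expr_scale`.
#'
#' @inheritParams simulate_read_counts
#' @param loci Mutation ids to genotype; defaults to the first
#'   `n_genotype_loci` truncal mutations.
#' @return List with `genotype` (tibble: nucleus, locus, alt, ref), `counts`
#'   (genes x nuclei integer matrix) and `labels` (tibble: nucleus, section,
#'   population, malignant).
#' @export
simulate_nuclei <- function(tree, fractions, config, seed = NULL, loci = NULL) {
  with_seed(seed, {
    root <- tree_root(tree)
    truncal <- tree$mutations$mutation_id[tree$mutations$clone == root]
    if (is.null(loci)) loci <- utils::head(truncal, config$n_genotype_loci)
    gm <- build_gene_model(tree, config)
    ab <- population_abundance(tree, fractions, config)
    N <- config$n_nuclei
    S <- ncol(fractions)
    sec <- sample.int(S, N, replace = TRUE)
    pop <- vapply(sec, function(s) sample(rownames(ab), 1L, prob = ab[, s]), "")
    malignant <- pop %in% tree$clone_ids
    nuc <- paste0("nuc", seq_len(N))

    st <- tree$allele_state
    geno <- dplyr::bind_rows(lapply(seq_along(loci), function(j) {
      loc <- loci[j]
      mt <- merge(data.frame(clone = pop, ord = seq_len(N)),
                  st[st$mutation_id == loc, c("clone", "m", "t")],
                  by = "clone", all.x = TRUE, sort = FALSE)
      mt <- mt[order(mt$ord), ]
      m <- ifelse(is.na(mt$m), 0L, mt$m)   # nonmalignant populations: m = 0, t = 2
      t_ <- ifelse(is.na(mt$t), 2L, mt$t)
      p_alt <- ifelse(t_ > 0, m / t_, 0)
      het <- m > 0 & m < t_
      drop <- het & stats::runif(N) < config$allele_dropout_rate
      p_alt[drop] <- ifelse(stats::runif(sum(drop)) < 0.5, 0, 1)
      depth <- stats::rpois(N, config$nucleus_depth_mean)
      alt <- stats::rbinom(N, depth, p_alt)
      tibble::tibble(nucleus = nuc, locus = loc, alt = alt, ref = depth - alt)
    }))

    lam <- (gm$signature * gm$dosage)[, pop, drop = FALSE] * config$nucleus_expr_scale
    counts <- matrix(stats::rpois(length(lam), as.vector(lam)), nrow(lam), ncol(lam),
                     dimnames = list(rownames(gm$signature), nuc))

    cs_log("simulate_nuclei", nuclei = N, loci = length(loci))
    list(genotype = geno, counts = counts,
         labels = tibble::tibble(nucleus = nuc, section = sec, population = pop,
                                 malignant = malignant))
  })
}

#' Simulate a complete serial-section tumor with ground truth
#'
#' Runs the full generator under `config$seed`: phylogeny, section fractions,
#' amplicon read counts, bulk tumor + normal expression, and single-nucleus
#' data. The same seed reproduces every artifact exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `serial_tumor_sim` with elements `config`, `tree`,
#'   `fractions`, `counts`, `expression`, `nuclei`.
#' @export
simulate_serial_tumor <- function(config = sim_config()) {
  with_seed(config$seed, {
    tree <- simulate_phylogeny(config)
    fractions <- simulate_section_fractions(tree, config)
    counts <- simulate_read_counts(tree, fractions, config)
    expression <- simulate_expression(tree, fractions, config)
    nuclei <- simulate_nuclei(tree, fractions, config)
    structure(list(config = config, tree = tree, fractions = fractions,
                   counts = counts, expression = expression, nuclei = nuclei),
              class = "serial_tumor_sim")
  })
}

#' @export
print.serial_tumor_sim <- function(x, ...) {
  cat("<serial_tumor_sim> ", length(x$tree$clone_ids), " clones x ",
      ncol(x$fractions), " sections; ", nrow(x$expression$tumor), " genes; ",
      nrow(x$nuclei$labels), " nuclei (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write all simulation artifacts to a directory
#'
#' Emits plain-text files: `expression.tsv`, `normal_expression_<i>.tsv`,
#' `counts_alt.tsv`, `counts_ref.tsv`, `truth_tree.json`,
#' `truth_fractions.tsv`, `nuclei_genotypes.tsv`, `nuclei_counts.tsv`.
#'
#' @param sim A [simulate_serial_tumor()] result.
#' @param outdir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  write_expression_tsv(sim$expression$tumor, fp("expression.tsv"))
  for (i in seq_along(sim$expression$normals)) {
    write_expression_tsv(sim$expression$normals[[i]],
                         fp(sprintf("normal_expression_%d.tsv", i)))
  }
  write_expression_tsv(sim$counts$alt, fp("counts_alt.tsv"), id_col = "mutation_id")
  write_expression_tsv(sim$counts$ref, fp("counts_ref.tsv"), id_col = "mutation_id")
  write_clone_tree(sim$tree, fp("truth_tree.json"))
  write_fractions_tsv(sim$fractions, fp("truth_fractions.tsv"))
  readr::write_tsv(sim$nuclei$genotype, fp("nuclei_genotypes.tsv"), progress = FALSE)
  write_expression_tsv(sim$nuclei$counts, fp("nuclei_counts.tsv"))
  invisible(outdir)
}

#' Planted five-clone world with designed spatial niches
#'
#' A fixed, representative serial-section tumor for exercising the
#' transcriptional stages: a branching phylogeny (truncal clone with two
#' subclonal lineages, each with one further subclone) whose cumulative
#' abundance profiles are designed Gaussian niches — the truncal profile is a
#' broad plateau, the two lineages occupy opposite ends of the section axis,
#' and each deeper subclone sweeps part of its parent's niche. The geometry
#' is deterministic (only mutations, gene placement and noise vary with the
#' seed) and satisfies the identifiability screen with wide margins; pairwise
#' profile correlations stay moderate, so each clone's transcriptional
#' program is resolvable as its own coexpression module.
#'
#' @param config A [sim_config()]; `n_clones` is forced to 5.
#' @return A list of class `serial_tumor_sim` (see
#'   [simulate_serial_tumor()]) whose `fractions` are the designed niches.
#' @export
planted_clone_world <- function(config = sim_config(n_cnv_per_branch = 0)) {
  config$n_clones <- 5L
  with_seed(config$seed, {
    tree <- simulate_phylogeny(config)
    parent <- c(clone1 = NA_character_, clone2 = "clone1", clone3 = "clone1",
                clone4 = "clone2", clone5 = "clone3")
    tree$parent <- parent
    tree$mutations$clone <- rep(names(parent), each = config$n_mutations_per_branch)
    # rebuild allele states for the new topology (no CNVs in this world)
    st <- tree$allele_state
    A <- subtree_matrix(parent)
    for (i in seq_len(nrow(tree$mutations))) {
      carriers <- names(parent)[A[tree$mutations$clone[i], ] > 0]
      sel <- st$mutation_id == tree$mutations$mutation_id[i]
      st$m[sel] <- ifelse(st$clone[sel] %in% carriers, 1L, 0L)
      st$t[sel] <- 2L
    }
    tree$allele_state <- st
    validate_clone_tree(tree)

    S <- config$n_sections
    x <- seq(0, 1, length.out = S)
    g <- function(ctr, wid) exp(-((x - ctr)^2) / (2 * wid^2))
    W <- function(ctr, wid) exp(-((x - ctr) / wid)^4)  # flat-top niche window
    cum1 <- 0.45 + 0.35 * g(0.45, 0.12)
    s2 <- 0.90 * W(0.16, 0.16)
    s3 <- 0.90 * W(0.78, 0.15)
    sc <- pmax(1, (s2 + s3) / 0.95)
    cum2 <- cum1 * s2 / sc
    cum3 <- cum1 * s3 / sc
    cum4 <- cum2 * 0.90 * W(0.03, 0.065)
    cum5 <- cum3 * 0.90 * W(0.91, 0.065)
    cum <- rbind(clone1 = cum1, clone2 = cum2, clone3 = cum3,
                 clone4 = cum4, clone5 = cum5)
    fr <- cum
    kids <- clone_children(tree)
    for (cl in rownames(cum)) {
      if (length(kids[[cl]])) fr[cl, ] <- cum[cl, ] - colSums(cum[kids[[cl]], , drop = FALSE])
    }
    colnames(fr) <- paste0("s", seq_len(S))
    attr(fr, "nonmalignant") <- 1 - colSums(fr)
    validate_fractions(fr, tree)
    stopifnot(profiles_identifiable(cum, tree))

    counts <- simulate_read_counts(tree, fr, config)
    expression <- simulate_expression(tree, fr, config)
    nuclei <- simulate_nuclei(tree, fr, config)
    structure(list(config = config, tree = tree, fractions = fr,
                   counts = counts, expression = expression, nuclei = nuclei),
              class = "serial_tumor_sim")
  })
}
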