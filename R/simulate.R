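# Synthetic inbred-panel generator. Emulates the data structure of a
# renewable mouse panel proteomics study: ~75 inbred strains with 2-4
# replicate animals each, biallelic homozygous genotypes in LD blocks,
# planted cis effects near genes, trans hotspots, polygenic covariance
# through the realized kinship, protein-driven traits, and per-protein
# strain-wise missingness. Every planted effect is recorded in a truth
# ledger so downstream stages can be scored.

#' Simulation configuration
#'
#' Defaults mirror the design of a hybrid mouse diversity panel muscle
#' proteomics study: 75 inbred strains with 2-4 replicates, ~300 proteins of
#' which 10% carry a planted cis effect, one 30-target trans hotspot, a
#' polygenic:residual variance split of 0.15:0.10 on the log2 scale
#' (heritability 0.6), replicate noise matched to a ~9% linear-scale
#' coefficient of variation, and per-protein strain coverage between 70% and
#' 100%.
#'
#' @param seed Master seed (mandatory). Stage seeds are derived as
#'   `seed`, `seed + 1`, `seed + 2` for genotypes, proteome, traits.
#' @param n_strains Number of inbred strains.
#' @param replicates Integer range `c(min, max)` of replicate animals drawn
#'   uniformly per strain.
#' @param n_chromosomes,chrom_length_bp Genome layout.
#' @param n_snps Total SNP count (spread evenly over chromosomes).
#' @param ld_block_bp LD block length; SNPs within a block share a latent
#'   founder allele.
#' @param ld_rho Squared-copying correlation between SNPs of a block
#'   (1 = identical, 0 = independent).
#' @param maf_floor Minimum minor allele frequency for simulated SNPs.
#' @param n_genes,gene_length_bp Gene models placed uniformly along the genome.
#' @param n_proteins Number of proteins (each assigned a distinct host gene).
#' @param cis_fraction Fraction of proteins receiving a planted cis SNP effect.
#' @param cis_ve Range of strain-level variance explained by a planted cis
#'   effect.
#' @param cis_window_bp Planted cis SNPs fall within this distance of the
#'   protein's gene.
#' @param n_trans_hotspots,hotspot_targets,hotspot_ve Trans hotspots: each is
#'   one SNP affecting `hotspot_targets` proteins whose genes are trans to it.
#' @param sigma_u2,sigma_e2 Polygenic and residual strain-level variances of
#'   the log2 abundances.
#' @param replicate_sd Within-strain replicate noise SD on the log2 scale.
#' @param coverage Range of the per-protein fraction of strains in which the
#'   protein is quantified (whole strains are dropped, mirroring panels where
#'   proteins are quantified only in a subset of mice).
#' @param n_traits,proteins_per_trait,trait_noise Trait layer: each trait is a
#'   weighted sum of strain-mean protein abundances plus Gaussian noise with
#'   SD `trait_noise` times the signal SD.
#' @param causal_chain If `TRUE`, the first trait is driven (weight 1) by the
#'   planted cis protein with the largest variance explained, creating a full
#'   SNP -> protein -> trait causal chain.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_strains = 75,
                       replicates = c(2L, 4L),
                       n_chromosomes = 5,
                       chrom_length_bp = 1.2e8,
                       n_snps = 1000,
                       ld_block_bp = 4e6,
                       ld_rho = 0.9,
                       maf_floor = 0.15,
                       n_genes = 320,
                       gene_length_bp = 2e4,
                       n_proteins = 300,
                       cis_fraction = 0.1,
                       cis_ve = c(0.2, 0.6),
                       cis_window_bp = 10e6,
                       n_trans_hotspots = 1,
                       hotspot_targets = 30,
                       hotspot_ve = c(0.45, 0.60),
                       sigma_u2 = 0.15,
                       sigma_e2 = 0.10,
                       replicate_sd = 0.13,
                       coverage = c(0.7, 1.0),
                       n_traits = 5,
                       proteins_per_trait = 3,
                       trait_noise = 0.5,
                       causal_chain = TRUE) {
  if (missing(seed) || is.null(seed)) abort("sim_config: a master seed is mandatory")
  cfg <- as.list(environment())
  if (cfg$sigma_u2 < 0 || cfg$sigma_e2 < 0 || cfg$replicate_sd < 0 || cfg$trait_noise < 0) {
    abort("variances and noise SDs must be >= 0")
  }
  fr <- c(cfg$cis_fraction, cfg$ld_rho, cfg$maf_floor, cfg$coverage, cfg$cis_ve, cfg$hotspot_ve)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$maf_floor >= 0.5) abort("maf_floor must be < 0.5")
  if (cfg$n_genes < cfg$n_proteins) abort("need n_genes >= n_proteins")
  structure(cfg, class = "sim_config")
}

#' Simulate panel genotypes and gene models
#'
#' Homozygous dosages in `{0, 2}`: each LD block carries a latent founder
#' allele per strain (frequency drawn in `[maf_floor, 1 - maf_floor]`) and
#' every SNP of the block copies the founder with probability `sqrt(ld_rho)`,
#' giving an expected inter-SNP dosage correlation of `ld_rho` within blocks.
#' Gene models are placed uniformly along the chromosomes.
#'
#' @param cfg A [sim_config()].
#' @return List with `panel` (a [genotype_panel()]) and `genes` (gene tibble).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_strains
  chroms <- as.character(seq_len(cfg$n_chromosomes))
  blocks_per_chrom <- ceiling(cfg$chrom_length_bp / cfg$ld_block_bp)
  if (cfg$n_snps < cfg$n_chromosomes * blocks_per_chrom) {
    abort("n_snps is smaller than the number of LD blocks")
  }
  per_chrom <- diff(round(seq(0, cfg$n_snps, length.out = cfg$n_chromosomes + 1)))
  strains <- sprintf("strain_%03d", seq_len(n))

  dosage <- matrix(NA_real_, n, 0)
  meta <- vector("list", cfg$n_chromosomes)
  copy_p <- sqrt(cfg$ld_rho)
  for (ci in seq_along(chroms)) {
    m <- per_chrom[ci]
    pos <- sort(sample.int(cfg$chrom_length_bp, m))
    block <- (pos - 1) %/% cfg$ld_block_bp
    dos_c <- matrix(NA_real_, n, m)
    for (b in unique(block)) {
      idx <- which(block == b)
      f <- runif(1, cfg$maf_floor, 1 - cfg$maf_floor)
      founder <- rbinom(n, 1, f)
      for (j in idx) {
        copy <- rbinom(n, 1, copy_p)
        allele <- ifelse(copy == 1, founder, rbinom(n, 1, f))
        dos_c[, j] <- 2 * allele
      }
    }
    dosage <- cbind(dosage, dos_c)
    meta[[ci]] <- tibble(chrom = chroms[ci], pos = pos)
  }
  meta <- dplyr::bind_rows(meta)
  meta$snp_id <- sprintf("snp_%05d", seq_len(nrow(meta)))
  rownames(dosage) <- strains
  colnames(dosage) <- meta$snp_id

  genes <- tibble(
    gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
    chrom = sample(chroms, cfg$n_genes, replace = TRUE),
    start = sample.int(cfg$chrom_length_bp - cfg$gene_length_bp, cfg$n_genes),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  )
  genes$end <- genes$start + cfg$gene_length_bp - 1
  genes <- validate_genes(genes[c("gene_id", "chrom", "start", "end", "strand")])

  # variant annotation: intragenic SNPs get a gene-hosted consequence label
  host <- rep(NA_character_, nrow(meta))
  conseq <- rep("intergenic_variant", nrow(meta))
  for (ci in chroms) {
    gi <- genes[genes$chrom == ci, ]
    si <- which(meta$chrom == ci)
    if (nrow(gi) == 0 || length(si) == 0) next
    hit <- vapply(meta$pos[si], function(p) {
      k <- which(gi$start <= p & p <= gi$end)
      if (length(k) == 0) NA_integer_ else k[1]
    }, integer(1))
    host[si] <- ifelse(is.na(hit), NA_character_, gi$gene_id[hit])
  }
  intra <- !is.na(host)
  conseq[intra] <- sample(c("intron_variant", "missense_variant", "synonymous_variant",
                            "3_prime_UTR_variant"),
    sum(intra),
    replace = TRUE, prob = c(0.7, 0.1, 0.15, 0.05)
  )
  meta$ref <- sample(c("A", "C", "G", "T"), nrow(meta), replace = TRUE)
  meta$alt <- vapply(meta$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  meta$consequence <- conseq
  meta$host_gene <- host

  list(
    panel = genotype_panel(dosage, meta[c("snp_id", "chrom", "pos", "ref", "alt",
                                          "consequence", "host_gene")]),
    genes = genes
  )
}

gene_snp_distance <- function(pos, snp_chrom, gene) {
  ifelse(snp_chrom != gene$chrom, Inf,
    ifelse(pos >= gene$start & pos <= gene$end, 0,
      pmin(abs(pos - gene$start), abs(pos - gene$end))
    )
  )
}

#' Simulate a proteome over a genotype panel
#'
#' Each protein's strain-level value is `sum(x * beta) + u + e` with
#' `u ~ MVN(0, sigma_u2 * K)` for the realized identity-by-state kinship `K`
#' of the panel and `e ~ N(0, sigma_e2)`. Planted cis SNPs sit within
#' `cis_window_bp` of the protein's host gene; hotspot SNPs affect proteins
#' whose genes are on another chromosome or more than `cis_window_bp` away.
#' Effect sizes are parameterized as the fraction of strain-level variance
#' explained and converted to `beta` using the realized dosage variance.
#' Replicate samples add i.i.d. Gaussian noise; per-protein missingness drops
#' whole strains.
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#' @param genes Gene tibble from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return List with `abundance` (an [abundance_matrix()]) and `truth`
#'   (a `truth_ledger`: planted cis pairs, hotspot records, per-protein
#'   generative and realized heritability, protein-gene assignment).
#' @export
simulate_proteome <- function(panel, genes, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "genotype_panel"))
  set.seed(cfg$seed + 1)
  strains <- strain_ids(panel)
  n <- length(strains)
  p <- cfg$n_proteins
  prot_ids <- sprintf("prot_%04d", seq_len(p))
  prot_gene <- genes$gene_id[sample.int(nrow(genes), p)]
  meta <- panel$snp_meta
  dos <- panel$dosage

  K <- ibs_kinship(panel)
  # strain-level sample variance of u ~ MVN(0, sigma_u2 * K) is shrunk by the
  # panel-wide kinship: E[var(u)] = sigma_u2 * (1 - mean(K)) * n/(n-1); effect
  # sizes are calibrated against this realized noise variance so that the
  # variance-explained fractions hold on the strain means
  u_var_factor <- (mean(diag(unclass(K))) - mean(unclass(K))) * n / (n - 1)
  tot_var <- cfg$sigma_u2 * u_var_factor + cfg$sigma_e2

  ve_to_beta <- function(ve, x) {
    if (ve >= 1) abort("planted effect variance fraction must be < 1")
    vx <- var(x)
    sample(c(-1, 1), 1) * sqrt(ve / (1 - ve) * max(tot_var, 1e-12) / vx)
  }

  snp_var <- apply(dos, 2, var)

  # planted cis effects
  n_cis <- round(cfg$cis_fraction * p)
  cis_prot <- sort(sample.int(p, n_cis))
  cis <- vector("list", n_cis)
  genetic <- matrix(0, n, p, dimnames = list(strains, prot_ids))
  for (i in seq_along(cis_prot)) {
    g <- genes[genes$gene_id == prot_gene[cis_prot[i]], ]
    d <- gene_snp_distance(meta$pos, meta$chrom, g)
    cand <- which(d <= cfg$cis_window_bp & snp_var > 0)
    if (length(cand) == 0) next
    j <- if (length(cand) == 1) cand else sample(cand, 1)
    ve <- runif(1, cfg$cis_ve[1], cfg$cis_ve[2])
    beta <- ve_to_beta(ve, dos[, j])
    genetic[, cis_prot[i]] <- genetic[, cis_prot[i]] + dos[, j] * beta
    cis[[i]] <- tibble(
      protein_id = prot_ids[cis_prot[i]], snp_id = meta$snp_id[j],
      gene_id = g$gene_id, beta = beta, ve = ve
    )
  }
  cis <- dplyr::bind_rows(cis)

  # trans hotspots: one SNP -> many distant proteins
  hot <- vector("list", cfg$n_trans_hotspots)
  non_cis <- setdiff(seq_len(p), cis_prot)
  if (cfg$n_trans_hotspots > 0 && cfg$hotspot_targets > 0) {
    hot_snps <- sample(which(snp_var > 0), cfg$n_trans_hotspots)
    for (h in seq_len(cfg$n_trans_hotspots)) {
      j <- hot_snps[h]
      gm <- genes[match(prot_gene[non_cis], genes$gene_id), ]
      d <- gene_snp_distance(meta$pos[j], meta$chrom[j], gm)
      trans_ok <- non_cis[d > cfg$cis_window_bp | is.infinite(d)]
      tgt <- sample(trans_ok, min(cfg$hotspot_targets, length(trans_ok)))
      betas <- numeric(length(tgt))
      for (k in seq_along(tgt)) {
        ve <- runif(1, cfg$hotspot_ve[1], cfg$hotspot_ve[2])
        betas[k] <- ve_to_beta(ve, dos[, j])
        genetic[, tgt[k]] <- genetic[, tgt[k]] + dos[, j] * betas[k]
      }
      hot[[h]] <- tibble(
        hotspot = h, snp_id = meta$snp_id[j],
        protein_id = prot_ids[tgt], beta = betas
      )
    }
  }
  hot <- dplyr::bind_rows(hot)

  # polygenic + residual strain effects
  eg <- eigen(unclass(K), symmetric = TRUE)
  sqrt_s <- sqrt(pmax(eg$values, 0))
  U <- eg$vectors
  u_mat <- sqrt(cfg$sigma_u2) * (U %*% (sqrt_s * matrix(rnorm(n * p), n, p)))
  e_mat <- matrix(rnorm(n * p, 0, sqrt(cfg$sigma_e2)), n, p)
  y_strain <- genetic + u_mat + e_mat

  h2_real <- vapply(seq_len(p), function(j) {
    vu <- var(u_mat[, j]); ve_ <- var(e_mat[, j])
    if (vu + ve_ <= 0) NA_real_ else vu / (vu + ve_)
  }, numeric(1))

  # replicate samples with i.i.d. log2-scale noise
  reps <- sample(seq(cfg$replicates[1], cfg$replicates[2]), n, replace = TRUE)
  sample_strain <- rep(strains, times = reps)
  sample_ids <- unlist(lapply(seq_len(n), function(i) sprintf("%s_r%d", strains[i], seq_len(reps[i]))))
  values <- y_strain[sample_strain, , drop = FALSE] +
    matrix(rnorm(length(sample_strain) * p, 0, cfg$replicate_sd), length(sample_strain), p)
  rownames(values) <- sample_ids
  colnames(values) <- prot_ids

  # strain-wise missingness per protein
  cov_frac <- runif(p, cfg$coverage[1], cfg$coverage[2])
  for (j in seq_len(p)) {
    keep_n <- round(cov_frac[j] * n)
    if (keep_n < n) {
      dropped <- sample(strains, n - keep_n)
      values[sample_strain %in% dropped, j] <- NA_real_
    }
  }

  ab <- abundance_matrix(values, tibble(sample_id = sample_ids, strain_id = sample_strain))
  truth <- structure(
    list(
      cis = cis, hotspots = hot,
      protein_genes = tibble(protein_id = prot_ids, gene_id = prot_gene),
      heritability = tibble(
        protein_id = prot_ids,
        h2_generative = if (tot_var > 0) cfg$sigma_u2 / tot_var else NA_real_,
        h2_realized = h2_real
      ),
      trait_weights = NULL
    ),
    class = "truth_ledger"
  )
  list(abundance = ab, truth = truth)
}

#' Simulate strain-level traits driven by proteins
#'
#' Each trait is a weighted sum of chosen strain-mean protein abundances plus
#' Gaussian noise. Contributions missing for a strain are omitted from the sum
#' (values are centred log2 ratios, so omission adds noise rather than bias).
#' With `causal_chain = TRUE` the first trait takes its unit-weight driver from
#' the planted cis protein with the largest variance explained, completing a
#' SNP -> protein -> trait chain recorded in the truth ledger.
#'
#' @param abundance An [abundance_matrix()] from [simulate_proteome()].
#' @param truth The matching `truth_ledger` (updated in the return value).
#' @param cfg The same [sim_config()].
#' @param weights Optional tibble `trait_id, protein_id, weight` overriding the
#'   random trait construction; unknown proteins raise an error.
#' @return List with `traits` (strain-level tibble) and the updated `truth`.
#' @export
simulate_traits <- function(abundance, truth, cfg, weights = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(abundance, "abundance_matrix"))
  set.seed(cfg$seed + 2)
  sm <- strain_aggregate(abundance, quantile_normalize = FALSE)
  prot_ids <- colnames(sm)
  strains <- rownames(sm)

  if (is.null(weights)) {
    k <- cfg$proteins_per_trait
    weights <- vector("list", cfg$n_traits)
    for (t in seq_len(cfg$n_traits)) {
      if (t == 1 && cfg$causal_chain && nrow(truth$cis) > 0) {
        driver <- truth$cis$protein_id[which.max(truth$cis$ve)]
        minors <- sample(setdiff(prot_ids, driver), max(0, k - 1))
        weights[[t]] <- tibble(
          trait_id = sprintf("trait_%02d", t),
          protein_id = c(driver, minors),
          weight = c(1, rep(0.3, length(minors)) * sample(c(-1, 1), length(minors), replace = TRUE))
        )
      } else {
        chosen <- sample(prot_ids, k)
        weights[[t]] <- tibble(
          trait_id = sprintf("trait_%02d", t),
          protein_id = chosen,
          weight = runif(k, 0.4, 1) * sample(c(-1, 1), k, replace = TRUE)
        )
      }
    }
    weights <- dplyr::bind_rows(weights)
  } else {
    weights <- as_tibble(weights)
    unknown <- setdiff(weights$protein_id, prot_ids)
    if (length(unknown) > 0) {
      abort(paste("trait weight on unknown protein:", paste(unknown, collapse = ", ")))
    }
  }

  traits <- tibble(strain_id = strains)
  for (tid in unique(weights$trait_id)) {
    w <- weights[weights$trait_id == tid, ]
    contrib <- sm[, w$protein_id, drop = FALSE] %*% diag(w$weight, nrow = nrow(w))
    signal <- rowSums(contrib, na.rm = TRUE)
    signal[rowSums(!is.na(contrib)) == 0] <- NA_real_
    noise_sd <- cfg$trait_noise * sd(signal, na.rm = TRUE)
    if (!is.finite(noise_sd)) noise_sd <- 0
    traits[[tid]] <- signal + rnorm(length(signal), 0, noise_sd)
  }
  truth$trait_weights <- weights
  list(traits = validate_traits(traits), truth = truth)
}

#' Run the full generator chain
#'
#' Convenience wrapper: genotypes + genes, proteome + truth, traits.
#'
#' @param cfg A [sim_config()].
#' @return List with `panel`, `genes`, `abundance`, `traits`, `truth`.
#' @export
simulate_panel <- function(cfg) {
  gen <- simulate_genotypes(cfg)
  pro <- simulate_proteome(gen$panel, gen$genes, cfg)
  tr <- simulate_traits(pro$abundance, pro$truth, cfg)
  list(
    panel = gen$panel, genes = gen$genes, abundance = pro$abundance,
    traits = tr$traits, truth = tr$truth
  )
}
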