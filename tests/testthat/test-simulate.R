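test_that("the generator chain is deterministic under a fixed seed", {
  a <- simulate_panel(small_sim(5))
  b <- simulate_panel(small_sim(5))
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$abundance$values, b$abundance$values)
  expect_identical(a$traits, b$traits)
  expect_identical(a$truth$cis, b$truth$cis)
})

test_that("within-block LD correlation hits its limit cases", {
  # rho = 1: all SNPs of a block identical across strains
  gen1 <- simulate_genotypes(small_sim(9, ld_rho = 1))
  block <- (gen1$panel$snp_meta$pos - 1) %/% 6e6
  key <- paste(gen1$panel$snp_meta$chrom, block)
  for (b in unique(key)) {
    cols <- which(key == b)
    if (length(cols) < 2) next
    ref <- gen1$panel$dosage[, cols[1]]
    for (j in cols[-1]) expect_identical(gen1$panel$dosage[, j], ref)
  }
  # rho = 0: mean absolute within-block dosage correlation near zero
  gen0 <- simulate_genotypes(sim_config(
    seed = 9, n_strains = 75, n_chromosomes = 2, chrom_length_bp = 6e7,
    n_snps = 200, ld_block_bp = 6e6, ld_rho = 0
  ))
  block0 <- (gen0$panel$snp_meta$pos - 1) %/% 6e6
  key0 <- paste(gen0$panel$snp_meta$chrom, block0)
  rs <- c()
  for (b in unique(key0)) {
    cols <- which(key0 == b)
    if (length(cols) < 2) next
    cc <- suppressWarnings(cor(gen0$panel$dosage[, cols]))
    rs <- c(rs, abs(cc[upper.tri(cc)]))
  }
  expect_lt(mean(rs, na.rm = TRUE), 0.1)
})

test_that("too few SNPs for the LD block grid is an error", {
  expect_error(
    simulate_genotypes(sim_config(
      seed = 1, n_chromosomes = 5, chrom_length_bp = 1.2e8,
      ld_block_bp = 2e6, n_snps = 100
    )),
    "LD blocks"
  )
})

test_that("a noise-free configuration yields a constant proteome", {
  cfg <- small_sim(3,
    sigma_u2 = 0, sigma_e2 = 0, replicate_sd = 0,
    cis_fraction = 0, n_trans_hotspots = 0, coverage = c(1, 1)
  )
  gen <- simulate_genotypes(cfg)
  pro <- simulate_proteome(gen$panel, gen$genes, cfg)
  expect_true(all(pro$abundance$values == 0))
})

test_that("planted architecture satisfies the truth-ledger geometry", {
  for (seed in c(2, 13)) {
    sim <- simulate_panel(small_sim(seed))
    meta <- sim$panel$snp_meta
    # cis SNPs within the window of their protein's gene
    for (i in seq_len(nrow(sim$truth$cis))) {
      g <- sim$genes[sim$genes$gene_id == sim$truth$cis$gene_id[i], ]
      j <- match(sim$truth$cis$snp_id[i], meta$snp_id)
      expect_equal(meta$chrom[j], g$chrom)
      d <- min(abs(meta$pos[j] - g$start), abs(meta$pos[j] - g$end))
      if (meta$pos[j] >= g$start && meta$pos[j] <= g$end) d <- 0
      expect_lte(d, 10e6)
    }
    # hotspot SNPs beyond the window of every target's gene
    pg <- sim$truth$protein_genes
    for (i in seq_len(nrow(sim$truth$hotspots))) {
      j <- match(sim$truth$hotspots$snp_id[i], meta$snp_id)
      gid <- pg$gene_id[pg$protein_id == sim$truth$hotspots$protein_id[i]]
      g <- sim$genes[sim$genes$gene_id == gid, ]
      if (meta$chrom[j] == g$chrom) {
        expect_gt(min(abs(meta$pos[j] - g$start), abs(meta$pos[j] - g$end)), 10e6)
      } else {
        succeed()
      }
    }
  }
})

test_that("genotypes are homozygous and respect the MAF floor", {
  gen <- simulate_genotypes(small_sim(21))
  expect_true(all(gen$panel$dosage %in% c(0, 2)))
  f <- colMeans(gen$panel$dosage) / 2
  # expected MAF >= floor; sampling noise allows modest undershoot at n = 40
  expect_gt(mean(pmin(f, 1 - f) >= 0.10), 0.9)
})

test_that("planted cis variance explained is realized on the strain means", {
  # effects planted at 50% VE should show squared dosage/abundance correlation
  # near 0.5 on average
  r2 <- c()
  for (seed in 1:20) {
    cfg <- sim_config(
      seed = 800 + seed, n_proteins = 40, cis_fraction = 0.5,
      cis_ve = c(0.5, 0.5), n_trans_hotspots = 0, coverage = c(1, 1)
    )
    gen <- simulate_genotypes(cfg)
    pro <- simulate_proteome(gen$panel, gen$genes, cfg)
    sm <- strain_aggregate(pro$abundance, quantile_normalize = FALSE)
    for (i in seq_len(nrow(pro$truth$cis))) {
      x <- gen$panel$dosage[, pro$truth$cis$snp_id[i]]
      y <- sm[, pro$truth$cis$protein_id[i]]
      r2 <- c(r2, cor(x, y)^2)
    }
  }
  expect_gt(length(r2), 100)
  expect_lt(abs(mean(r2) - 0.5), 0.1)
})

test_that("trait layer reproduces its generative weights", {
  cfg <- small_sim(31, coverage = c(1, 1))
  gen <- simulate_genotypes(cfg)
  pro <- simulate_proteome(gen$panel, gen$genes, cfg)
  sm <- strain_aggregate(pro$abundance, quantile_normalize = FALSE)

  # noise 0, single protein, weight 1 -> trait equals that protein's means
  cfg0 <- small_sim(31, trait_noise = 0, coverage = c(1, 1))
  w <- tibble::tibble(trait_id = "t", protein_id = colnames(sm)[4], weight = 1)
  tr <- simulate_traits(pro$abundance, pro$truth, cfg0, weights = w)
  expect_equal(
    setNames(tr$traits$t, tr$traits$strain_id),
    sm[tr$traits$strain_id, 4]
  )

  # unknown protein in the weights errors
  bad <- tibble::tibble(trait_id = "t", protein_id = "prot_9999", weight = 1)
  expect_error(simulate_traits(pro$abundance, pro$truth, cfg0, weights = bad), "unknown protein")

  # declared weight signs agree with the realized bicor signs
  tr2 <- simulate_traits(pro$abundance, pro$truth, cfg)
  ww <- tr2$truth$trait_weights
  agree <- vapply(seq_len(nrow(ww)), function(i) {
    y <- tr2$traits[[ww$trait_id[i]]]
    ok <- stats::complete.cases(sm[, ww$protein_id[i]], y)
    sign(bicor(sm[ok, ww$protein_id[i]], y[ok])) == sign(ww$weight[i])
  }, logical(1))
  expect_gt(mean(agree), 0.8)
})

test_that("excessive planted effect variance is rejected", {
  cfg <- small_sim(3, cis_ve = c(1, 1))
  gen <- simulate_genotypes(cfg)
  expect_error(simulate_proteome(gen$panel, gen$genes, cfg), "variance fraction")
})
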