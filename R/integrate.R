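# Three-step systems-genetics integration nominating candidate causal
# proteins for a trait:
#   step 1 — SNPs shared between the protein's cis-QTL set and the trait's
#            significant QTL set;
#   step 2 — biweight-midcorrelation protein-trait association passing the
#            magnitude-plus-p filter;
#   step 3 — allelic-contrast t-tests: strains split by homozygous genotype at
#            the lead shared SNP must differ in both protein abundance and
#            trait, with concordant directions.

#' Shared significant SNPs between a protein and a trait scan
#'
#' Exact id intersection of the two significant SNP sets, with an optional
#' LD-window slack: when `window_bp > 0`, a protein SNP also matches any trait
#' SNP within `window_bp` on the same chromosome. The lead shared SNP
#' minimizes the larger of the two p-values.
#'
#' @param protein_snps Tibble of the protein's significant SNPs (`snp_id, p`,
#'   and `chrom, pos` if `window_bp > 0`).
#' @param trait_snps Tibble of the trait's significant SNPs (same columns).
#' @param window_bp Matching slack in bp (0 = exact id intersection).
#' @return List with `snps` (character vector) and `lead` (one-row tibble
#'   `snp_id, p_protein, p_trait` or `NULL` when the intersection is empty).
#' @export
shared_snps <- function(protein_snps, trait_snps, window_bp = 0) {
  protein_snps <- as_tibble(protein_snps)
  trait_snps <- as_tibble(trait_snps)
  if (window_bp > 0) {
    hit <- purrr::map_lgl(seq_len(nrow(protein_snps)), function(i) {
      any(trait_snps$chrom == protein_snps$chrom[i] &
        abs(trait_snps$pos - protein_snps$pos[i]) <= window_bp)
    })
    shared <- protein_snps$snp_id[hit]
  } else {
    shared <- intersect(protein_snps$snp_id, trait_snps$snp_id)
  }
  if (length(shared) == 0) {
    return(list(snps = character(0), lead = NULL))
  }
  pp <- protein_snps$p[match(shared, protein_snps$snp_id)]
  pt_ <- trait_snps$p[match(shared, trait_snps$snp_id)]
  if (window_bp > 0 && anyNA(pt_)) {
    # windowed match: use the best trait p within the window
    pt_ <- purrr::map_dbl(shared, function(s) {
      i <- match(s, protein_snps$snp_id)
      min(trait_snps$p[trait_snps$chrom == protein_snps$chrom[i] &
        abs(trait_snps$pos - protein_snps$pos[i]) <= window_bp])
    })
  }
  worst <- pmax(pp, pt_)
  lead_i <- order(worst, pp + pt_, shared)[1]
  list(
    snps = shared,
    lead = tibble(snp_id = shared[lead_i], p_protein = pp[lead_i], p_trait = pt_[lead_i])
  )
}

#' Allelic-contrast t-tests at a SNP
#'
#' Splits strains into the two homozygous dosage groups (heterozygous strains
#' are excluded) and runs two-sided pooled-variance Student t-tests on the
#' strain-level protein abundance and on the trait. Groups smaller than
#' `min_group` strains make the record untestable.
#'
#' @param snp_id SNP to test.
#' @param panel A [genotype_panel()].
#' @param protein_y,trait_y Named strain-level vectors.
#' @param min_group Minimum strains per homozygous group.
#' @return One-row tibble: group sizes, protein/trait mean differences
#'   (`alt - ref` homozygotes), t statistics, p-values and a `testable` flag.
#' @export
allelic_contrast <- function(snp_id, panel, protein_y, trait_y, min_group = 3) {
  j <- match(snp_id, colnames(panel$dosage))
  if (is.na(j)) abort(paste("unknown SNP:", snp_id))
  g <- panel$dosage[, j]
  res <- tibble(
    snp_id = snp_id, n_ref = NA_integer_, n_alt = NA_integer_,
    protein_diff = NA_real_, protein_t = NA_real_, protein_p = NA_real_,
    trait_diff = NA_real_, trait_t = NA_real_, trait_p = NA_real_,
    testable = FALSE
  )
  one <- function(y) {
    y <- y[names(g)]
    ref <- y[!is.na(g) & g == 0 & !is.na(y)]
    alt <- y[!is.na(g) & g == 2 & !is.na(y)]
    if (length(ref) < min_group || length(alt) < min_group) return(NULL)
    if (sd(ref) == 0 && sd(alt) == 0) {
      d <- mean(alt) - mean(ref)
      if (d == 0) return(list(diff = 0, t = 0, p = 1, n_ref = length(ref), n_alt = length(alt)))
      return(NULL)
    }
    tt <- stats::t.test(alt, ref, var.equal = TRUE)
    list(
      diff = mean(alt) - mean(ref), t = unname(tt$statistic), p = tt$p.value,
      n_ref = length(ref), n_alt = length(alt)
    )
  }
  pr <- one(protein_y)
  tr <- one(trait_y)
  if (is.null(pr) || is.null(tr)) return(res)
  res$n_ref <- pr$n_ref; res$n_alt <- pr$n_alt
  res$protein_diff <- pr$diff; res$protein_t <- pr$t; res$protein_p <- pr$p
  res$trait_diff <- tr$diff; res$trait_t <- tr$t; res$trait_p <- tr$p
  res$testable <- TRUE
  res
}

#' Per-protein cis-qualifying SNP sets
#'
#' Applies the cis classification rule to every feature of an association
#' table and returns the full qualifying set per feature (not just the lead),
#' as consumed by the shared-SNP step of the integration.
#'
#' @param assoc Association tibble from [map_qtl()].
#' @param genes,feature_genes Gene models and feature-to-gene map.
#' @param cfg A [run_config()].
#' @return Named list (by feature id) of tibbles `snp_id, chrom, pos, p`.
#' @export
cis_candidate_snps <- function(assoc, genes, feature_genes, cfg = run_config()) {
  genes <- validate_genes(genes)
  feature_genes <- as_tibble(feature_genes)
  split_assoc <- split.data.frame(assoc, assoc$feature_id)
  lapply(split_assoc, function(pa) {
    pa <- pa[!is.na(pa$p), ]
    gid <- feature_genes$gene_id[match(pa$feature_id[1], feature_genes$feature_id)]
    gene <- if (length(gid) == 1 && !is.na(gid) && gid %in% genes$gene_id) {
      genes[genes$gene_id == gid, ]
    } else {
      NULL
    }
    qualify_sets(pa, gene, cfg)$cis[c("snp_id", "chrom", "pos", "p")]
  })
}

#' Three-step integration of pQTLs with a trait
#'
#' Evaluates, per protein, (1) shared significant SNPs between the protein's
#' cis-qualifying set and the trait's significant scan, (2) the
#' biweight-midcorrelation association under the magnitude-plus-p filter, and
#' (3) allelic-contrast t-tests at the lead shared SNP, requiring both tests
#' below `p_cut` with allelic directions concordant with the correlation sign
#' (toggleable). The verdict is `prioritized` when all three steps pass,
#' `none` when none does, otherwise `partial` with the passing-step pattern.
#'
#' @param protein_assoc Association tibble from [map_qtl()] on the proteome.
#' @param trait_assoc Association tibble from [map_qtl()] on the traits
#'   (filtered internally to `trait_id` rows, significant at `q < q_cut`).
#' @param trait_id Trait to integrate.
#' @param strain_mat Strain-level protein matrix ([strain_aggregate()]).
#' @param traits Trait tibble.
#' @param panel The [genotype_panel()].
#' @param genes,feature_genes Gene models and protein-to-gene map (cis rule).
#' @param corr Optional precomputed [correlate_features()] table against
#'   `traits`; computed when `NULL`.
#' @param cis_sets Optional precomputed [cis_candidate_snps()] list (shared
#'   across traits); computed when `NULL`.
#' @param cfg A [run_config()].
#' @param proteins Protein subset to evaluate (default: all proteins with at
#'   least one association row).
#' @param require_concordance Require the sign of the allelic effect product
#'   to match the correlation sign in step 3.
#' @param min_group Minimum strains per homozygous group in step 3.
#' @return Tibble with one row per protein: step fields, verdict, and the step
#'   pattern, sorted by lead shared-SNP strength.
#' @export
integrate_qtl <- function(protein_assoc, trait_assoc, trait_id, strain_mat, traits,
                          panel, genes, feature_genes, corr = NULL,
                          cis_sets = NULL, cfg = run_config(), proteins = NULL,
                          require_concordance = TRUE, min_group = 3) {
  traits <- validate_traits(traits)
  if (!trait_id %in% names(traits)) abort(paste("unknown trait:", trait_id))
  bad <- setdiff(rownames(strain_mat), rownames(panel$dosage))
  if (length(bad) > 0) {
    abort(paste("strains absent from the genotype panel:", paste(head(bad, 5), collapse = ", ")))
  }
  proteins <- proteins %||% unique(protein_assoc$feature_id)
  if (is.null(cis_sets)) {
    cis_sets <- cis_candidate_snps(protein_assoc, genes, feature_genes, cfg)
  }
  if (is.null(corr)) {
    corr <- correlate_features(strain_mat, traits,
      trait_ids = trait_id,
      r_low = cfg$r_low, r_high = cfg$r_high, p_cut = cfg$p_cut
    )
  }
  corr <- corr[corr$feature_b == trait_id, ]

  ta <- trait_assoc[trait_assoc$feature_id == trait_id & !is.na(trait_assoc$p), ]
  ta_sig <- ta[!is.na(ta$q) & ta$q < cfg$q_cut, ]

  trait_y <- setNames(traits[[trait_id]], traits$strain_id)
  genes <- validate_genes(genes)

  rows <- purrr::map(proteins, function(pid) {
    cis_set <- cis_sets[[pid]]
    if (is.null(cis_set)) cis_set <- tibble(snp_id = character(), chrom = character(), pos = numeric(), p = numeric())
    sh <- shared_snps(cis_set, ta_sig[c("snp_id", "p")])
    step1 <- length(sh$snps) > 0

    cr <- corr[corr$feature_a == pid, ]
    step2 <- nrow(cr) == 1 && isTRUE(cr$selected)
    r_val <- if (nrow(cr) == 1) cr$r else NA_real_
    p_val <- if (nrow(cr) == 1) cr$p else NA_real_

    step3 <- FALSE
    contrast <- NULL
    if (step1) {
      py <- setNames(strain_mat[, pid], rownames(strain_mat))
      contrast <- allelic_contrast(sh$lead$snp_id, panel, py, trait_y, min_group = min_group)
      if (isTRUE(contrast$testable) &&
        !is.na(contrast$protein_p) && contrast$protein_p < cfg$p_cut &&
        !is.na(contrast$trait_p) && contrast$trait_p < cfg$p_cut) {
        if (require_concordance) {
          step3 <- !is.na(r_val) &&
            sign(contrast$protein_diff * contrast$trait_diff) == sign(r_val)
        } else {
          step3 <- TRUE
        }
      }
    }
    pattern <- paste(which(c(step1, step2, step3)), collapse = ",")
    verdict <- if (step1 && step2 && step3) {
      "prioritized"
    } else if (pattern == "") {
      "none"
    } else {
      "partial"
    }
    tibble(
      protein_id = pid, trait_id = trait_id,
      n_shared_snps = length(sh$snps),
      lead_snp = if (step1) sh$lead$snp_id else NA_character_,
      lead_p_protein = if (step1) sh$lead$p_protein else NA_real_,
      lead_p_trait = if (step1) sh$lead$p_trait else NA_real_,
      r = r_val, cor_p = p_val,
      protein_t = if (!is.null(contrast)) contrast$protein_t else NA_real_,
      protein_p = if (!is.null(contrast)) contrast$protein_p else NA_real_,
      trait_t = if (!is.null(contrast)) contrast$trait_t else NA_real_,
      trait_p = if (!is.null(contrast)) contrast$trait_p else NA_real_,
      step1 = step1, step2 = step2, step3 = step3,
      pattern = pattern, verdict = verdict
    )
  })
  out <- dplyr::bind_rows(rows)
  strength <- pmax(out$lead_p_protein, out$lead_p_trait)
  out[order(out$verdict != "prioritized", strength, out$cor_p, out$protein_id), ]
}
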