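# S3 containers for the matrix-shaped inputs. Result tables everywhere else are
# plain tibbles so they compose with dplyr; these three stay matrices because the
# kinship/mixed-model algebra is matrix algebra.

#' Construct a genotype panel
#'
#' Bundles a strain-by-SNP dosage matrix with per-SNP metadata. Dosages code the
#' number of alternate alleles (0/1/2); inbred panels are expected to be mostly
#' homozygous (0/2) but residual heterozygous calls are kept as-is. Missing
#' calls are `NA`.
#'
#' @param dosage Numeric matrix, strains in rows (rownames = strain ids), SNPs
#'   in columns (colnames = SNP ids). Values in `{0, 1, 2, NA}`.
#' @param snp_meta Data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based bp), `ref`, `alt`, `consequence`, `host_gene`. Extra columns are
#'   kept.
#' @return An object of class `genotype_panel` with elements `dosage` and
#'   `snp_meta` (a tibble gaining a `miss_frac` column, the per-SNP fraction of
#'   missing calls).
#' @export
genotype_panel <- function(dosage, snp_meta) {
  dosage <- as.matrix(dosage)
  snp_meta <- as_tibble(snp_meta)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    abort("`dosage` needs strain rownames and SNP colnames")
  }
  if (anyDuplicated(rownames(dosage))) abort("duplicate strain ids in dosage")
  if (anyDuplicated(colnames(dosage))) abort("duplicate SNP ids in dosage")
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snp_meta))) {
    abort(paste("snp_meta must contain columns:", paste(need, collapse = ", ")))
  }
  for (col in c("ref", "alt", "consequence", "host_gene")) {
    if (!col %in% names(snp_meta)) snp_meta[[col]] <- NA_character_
  }
  # text columns stay text regardless of how a reader guessed them
  for (col in c("snp_id", "chrom", "ref", "alt", "consequence", "host_gene")) {
    snp_meta[[col]] <- as.character(snp_meta[[col]])
  }
  snp_meta$pos <- as.numeric(snp_meta$pos)
  if (anyDuplicated(snp_meta$snp_id)) abort("duplicate snp_id in snp_meta")
  if (!identical(colnames(dosage), as.character(snp_meta$snp_id))) {
    abort("snp_meta$snp_id must match dosage colnames (same order)")
  }
  if (any(snp_meta$pos < 1, na.rm = TRUE)) abort("SNP positions must be >= 1")
  bad <- which(!(dosage %in% c(0, 1, 2)) & !is.na(dosage), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "dosage out of {0,1,2} at strain '%s', SNP '%s' (value %s)",
      rownames(dosage)[bad[1, 1]], colnames(dosage)[bad[1, 2]],
      format(dosage[bad[1, , drop = FALSE]])
    ))
  }
  snp_meta$miss_frac <- colMeans(is.na(dosage))
  structure(list(dosage = dosage, snp_meta = snp_meta), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d strains x %d SNPs on %d chromosome(s)\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$snp_meta$chrom))
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Strain identifiers of a panel or kinship matrix
#' @param x A `genotype_panel`, `kinship_matrix`, or `abundance_matrix`.
#' @return Character vector of strain ids.
#' @export
strain_ids <- function(x) UseMethod("strain_ids")

#' @export
strain_ids.genotype_panel <- function(x) rownames(x$dosage)

#' @export
strain_ids.kinship_matrix <- function(x) rownames(unclass(x))

#' @export
strain_ids.abundance_matrix <- function(x) unique(x$sample_to_strain$strain_id)

#' Tidy a genotype panel into long format
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return Tibble with `strain_id`, `snp_id`, `dosage`.
#' @method tidy genotype_panel
#' @export
tidy.genotype_panel <- function(x, ...) {
  tibble(
    strain_id = rep(rownames(x$dosage), times = ncol(x$dosage)),
    snp_id = rep(colnames(x$dosage), each = nrow(x$dosage)),
    dosage = as.vector(x$dosage)
  )
}

#' Construct a protein abundance matrix
#'
#' Samples-by-features matrix of log2 ratio-to-reference protein abundances with
#' a sample-to-strain map. Proteins are typically quantified in a subset of
#' samples; missing cells are `NA`, never zero.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   features (protein accessions) in columns.
#' @param sample_to_strain Data frame with columns `sample_id`, `strain_id`
#'   covering every row of `values`.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, sample_to_strain) {
  values <- as.matrix(values)
  sample_to_strain <- as_tibble(sample_to_strain)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs sample rownames and feature colnames")
  }
  if (!all(c("sample_id", "strain_id") %in% names(sample_to_strain))) {
    abort("sample_to_strain needs columns sample_id, strain_id")
  }
  if (anyDuplicated(sample_to_strain$sample_id)) abort("duplicate sample_id")
  missing_map <- setdiff(rownames(values), sample_to_strain$sample_id)
  if (length(missing_map) > 0) {
    abort(paste("samples missing from sample_to_strain:", paste(head(missing_map, 5), collapse = ", ")))
  }
  sample_to_strain <- sample_to_strain[match(rownames(values), sample_to_strain$sample_id), ]
  structure(
    list(values = values, sample_to_strain = sample_to_strain),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "<abundance_matrix> %d samples (%d strains) x %d features; %.1f%% missing\n",
    nrow(x$values), length(unique(x$sample_to_strain$strain_id)), ncol(x$values),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Tidy an abundance matrix into long format
#' @param x An `abundance_matrix`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `strain_id`, `feature_id`, `value`.
#' @method tidy abundance_matrix
#' @export
tidy.abundance_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    strain_id = rep(x$sample_to_strain$strain_id, times = ncol(x$values)),
    feature_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

validate_traits <- function(traits) {
  traits <- as_tibble(traits)
  if (!"strain_id" %in% names(traits)) abort("trait table needs a strain_id column")
  if (anyDuplicated(traits$strain_id)) abort("trait table must have one row per strain")
  if (anyDuplicated(names(traits))) abort("trait ids must be unique")
  traits
}

validate_genes <- function(genes) {
  genes <- as_tibble(genes)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    abort(paste("gene table must contain columns:", paste(need, collapse = ", ")))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  bad <- which(genes$start > genes$end)
  if (length(bad) > 0) {
    abort(sprintf("gene '%s' has start > end", genes$gene_id[bad[1]]))
  }
  genes
}

#' Analysis thresholds and options
#'
#' Central configuration for the mapping/classification/correlation stages.
#' Defaults follow the conventions of mouse-panel pQTL studies: a cis window of
#' +/- 10 Mb around the gene, a window-local adjusted p cut of 1e-4 for cis
#' calls, a genome-wide adjusted p cut of 5e-8 for trans calls, and q < 0.1
#' overall significance.
#'
#' @param cis_window_bp Half-width of the cis window in bp.
#' @param local_p Cut on the window-local adjusted p for cis calls.
#' @param global_p Cut on the genome-wide adjusted p for trans calls.
#' @param q_cut Overall q-value significance cut.
#' @param maf_min Minor-allele-frequency floor among the strains used in a test.
#' @param min_strains Minimum non-missing strains for a feature to be mapped.
#'   `NULL` scales the conventional 50-of-73 coverage floor to the panel size.
#' @param qvalue_method `"storey"` or `"bh"`.
#' @param r_low,r_high Correlation-filter bounds: selected pairs satisfy
#'   `r <= r_low` or `r >= r_high`.
#' @param p_cut Correlation p cut for the selection filter.
#' @param hotspot_bin_bp Genome bin width for trans-hotspot counting.
#' @param hotspot_alpha BH-adjusted Poisson tail cut for flagging a bin.
#' @param edge_r Absolute-correlation cutoff for network edges.
#' @param edge_q q cut for network edges.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(cis_window_bp = 10e6,
                       local_p = 1e-4,
                       global_p = 5e-8,
                       q_cut = 0.1,
                       maf_min = 0.05,
                       min_strains = NULL,
                       qvalue_method = c("storey", "bh"),
                       r_low = -0.3,
                       r_high = 0.6,
                       p_cut = 0.05,
                       hotspot_bin_bp = 4e6,
                       hotspot_alpha = 1e-3,
                       edge_r = 0.6,
                       edge_q = 0.05) {
  qvalue_method <- match.arg(qvalue_method)
  cfg <- list(
    cis_window_bp = cis_window_bp, local_p = local_p, global_p = global_p,
    q_cut = q_cut, maf_min = maf_min, min_strains = min_strains,
    qvalue_method = qvalue_method, r_low = r_low, r_high = r_high,
    p_cut = p_cut, hotspot_bin_bp = hotspot_bin_bp,
    hotspot_alpha = hotspot_alpha, edge_r = edge_r, edge_q = edge_q
  )
  num <- cfg[!vapply(cfg, is.null, logical(1))]
  num <- num[vapply(num, is.numeric, logical(1))]
  if (any(unlist(num[c("cis_window_bp", "local_p", "global_p", "q_cut", "maf_min",
                       "p_cut", "hotspot_bin_bp", "hotspot_alpha")]) <= 0)) {
    abort("thresholds must be positive")
  }
  structure(cfg, class = "run_config")
}

# conventional 50-of-73 coverage floor, rescaled to the panel at hand
min_strains_default <- function(cfg, n_strains) {
  cfg$min_strains %||% max(8L, round(50 / 73 * n_strains))
}

#' Natural chromosome ordering (1..19, X, Y, ...)
#'
#' @param chrom Character vector of chromosome labels (with or without a
#'   `"chr"` prefix).
#' @return A factor ordered numerically first, then alphabetically.
#' @export
chrom_order <- function(chrom) {
  stripped <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(stripped))
  lev <- unique(stripped[order(is.na(num), num, stripped)])
  factor(stripped, levels = lev)
}
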