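# cis/trans classification, variant annotation, and trans-hotspot detection.
#
# A cis call requires the SNP within +/- cis_window_bp of the feature's gene
# (distance to the nearer gene boundary, 0 if inside the gene), a window-local
# adjusted p below local_p, and q below q_cut. A trans call requires the SNP
# beyond the window (or on another chromosome), a genome-wide adjusted p below
# global_p, and q below q_cut. "Local adjustment" is the q-value computed over
# the SNPs inside the window only; "global adjustment" is over all SNPs tested
# for the feature.

feature_distance <- function(meta, gene) {
  gene_snp_distance(meta$pos, meta$chrom, gene)
}

# per-feature cis/trans qualifying sets under the classification rule
qualify_sets <- function(af, gene, cfg) {
  ok <- !is.na(af$p)
  af <- af[ok, , drop = FALSE]
  if (nrow(af) == 0) {
    return(list(cis = af[0, ], trans = af[0, ]))
  }
  af$global_q <- qvalues(af$p, method = cfg$qvalue_method)
  if (!"q" %in% names(af)) af$q <- af$global_q
  if (is.null(gene)) {
    af$distance <- Inf
    af$local_q <- NA_real_
  } else {
    af$distance <- feature_distance(af, gene)
    af$local_q <- NA_real_
    loc <- which(af$distance <= cfg$cis_window_bp)
    if (length(loc) > 0) af$local_q[loc] <- qvalues(af$p[loc], method = cfg$qvalue_method)
  }
  cis <- af[!is.na(af$local_q) & af$distance <= cfg$cis_window_bp &
    af$local_q < cfg$local_p & af$global_q < cfg$q_cut, , drop = FALSE]
  trans <- af[af$distance > cfg$cis_window_bp & af$global_q < cfg$global_p &
    af$global_q < cfg$q_cut, , drop = FALSE]
  list(cis = cis, trans = trans, all = af)
}

lead_row <- function(x) {
  x[order(x$p, x$pos, x$snp_id), ][1, , drop = FALSE]
}

#' Classify associations into cis and trans QTL calls
#'
#' Applies the cis/trans decision rule per feature and reports at most one
#' lead cis call and one lead trans call per feature (lead SNP = minimal p in
#' the qualifying set, ties broken by smallest genomic position). Calls are
#' annotated for intragenic position and variant consequence via
#' [annotate_variant()].
#'
#' @param assoc Association tibble from [map_qtl()] (columns `feature_id,
#'   snp_id, chrom, pos, p`, ...).
#' @param panel The [genotype_panel()] that produced the scan (for SNP
#'   metadata).
#' @param genes Gene model tibble.
#' @param feature_genes Tibble `feature_id, gene_id` mapping features to their
#'   host gene. Features without a gene are eligible for trans calls only (a
#'   warning reports how many).
#' @param cfg A [run_config()].
#' @return Tibble of QTL calls: `feature_id, snp_id, chrom, pos, call, p, q,
#'   local_q, global_q, distance, intragenic, consequence`.
#' @export
classify_qtl <- function(assoc, panel, genes, feature_genes, cfg = run_config()) {
  genes <- validate_genes(genes)
  feature_genes <- as_tibble(feature_genes)
  feats <- unique(assoc$feature_id)
  no_gene <- 0L
  calls <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    af <- assoc[assoc$feature_id == feats[i], , drop = FALSE]
    gid <- feature_genes$gene_id[match(feats[i], feature_genes$feature_id)]
    gene <- NULL
    if (!is.na(gid) && length(gid) == 1 && gid %in% genes$gene_id) {
      gene <- genes[genes$gene_id == gid, ]
    } else {
      no_gene <- no_gene + 1L
    }
    qs <- qualify_sets(af, gene, cfg)
    out <- list()
    if (nrow(qs$cis) > 0) {
      lead <- lead_row(qs$cis)
      lead$call <- "cis"
      out <- c(out, list(lead))
    }
    if (nrow(qs$trans) > 0) {
      lead <- lead_row(qs$trans)
      lead$call <- "trans"
      out <- c(out, list(lead))
    }
    if (length(out) > 0) calls[[i]] <- dplyr::bind_rows(out)
  }
  if (no_gene > 0) {
    warn(sprintf("classify_qtl: %d feature(s) without a gene model; cis classification skipped for them", no_gene))
  }
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0) {
    return(tibble(
      feature_id = character(), snp_id = character(), chrom = character(),
      pos = numeric(), call = character(), p = numeric(), q = numeric(),
      local_q = numeric(), global_q = numeric(), distance = numeric(),
      intragenic = logical(), consequence = character()
    ))
  }
  calls <- calls[c("feature_id", "snp_id", "chrom", "pos", "call", "p", "q",
                   "local_q", "global_q", "distance")]
  annotate_variant(calls, panel$snp_meta, genes)
}

#' Annotate QTL calls with variant position and consequence
#'
#' A call is intragenic when its SNP lies within any gene interval on its
#' chromosome. The consequence label is copied verbatim from the SNP
#' annotation (e.g. `"missense_variant"`); absent annotation yields
#' `"unannotated"`.
#'
#' @param calls Tibble of calls with `snp_id, chrom, pos`.
#' @param snp_meta SNP metadata tibble (from a [genotype_panel()]).
#' @param genes Gene model tibble.
#' @return `calls` with `intragenic` and `consequence` columns
#'   added/overwritten.
#' @export
annotate_variant <- function(calls, snp_meta, genes) {
  genes <- validate_genes(genes)
  calls$intragenic <- vapply(seq_len(nrow(calls)), function(i) {
    g <- genes[genes$chrom == calls$chrom[i], ]
    any(g$start <= calls$pos[i] & calls$pos[i] <= g$end)
  }, logical(1))
  cons <- snp_meta$consequence[match(calls$snp_id, snp_meta$snp_id)]
  calls$consequence <- ifelse(is.na(cons), "unannotated", cons)
  calls
}

#' Detect trans-regulation hotspots
#'
#' Tiles the genome in fixed bins and counts, per bin, the distinct features
#' whose lead trans SNP falls in it. A bin is flagged when its Poisson
#' upper-tail p-value (rate = genome-wide mean count per bin) survives BH
#' adjustment across bins at `alpha`. This operationalizes the vertical
#' "streaks" visible on trans-QTL Manhattan plots.
#'
#' @param calls QTL call tibble from [classify_qtl()]; only `call == "trans"`
#'   rows are used.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp). When
#'   `NULL`, inferred as the maximum SNP position per chromosome seen in
#'   `calls` (fine for flagging, but pass true lengths for calibrated rates).
#' @param bin_bp Bin width in bp.
#' @param alpha BH-adjusted significance cut for flagging.
#' @return Tibble of bins: `chrom, start, end, n_features, p, q, flagged`.
#'   Zero trans calls give an empty tibble.
#' @export
detect_hotspots <- function(calls, chrom_lengths = NULL, bin_bp = 4e6, alpha = 1e-3) {
  trans <- calls[calls$call == "trans", , drop = FALSE]
  empty <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    n_features = integer(), p = numeric(), q = numeric(), flagged = logical()
  )
  if (nrow(trans) == 0) return(empty)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(trans$pos, trans$chrom, max)
  }
  bins <- dplyr::bind_rows(lapply(names(chrom_lengths), function(ch) {
    nb <- max(1, ceiling(chrom_lengths[[ch]] / bin_bp))
    tibble(
      chrom = ch,
      start = (seq_len(nb) - 1) * bin_bp + 1,
      end = pmin(seq_len(nb) * bin_bp, chrom_lengths[[ch]])
    )
  }))
  trans$bin <- paste0(trans$chrom, ":", (trans$pos - 1) %/% bin_bp)
  bins$bin <- paste0(bins$chrom, ":", (bins$start - 1) %/% bin_bp)
  counts <- tapply(trans$feature_id, trans$bin, function(f) length(unique(f)))
  bins$n_features <- as.integer(counts[bins$bin])
  bins$n_features[is.na(bins$n_features)] <- 0L
  lambda <- sum(bins$n_features) / nrow(bins)
  bins$p <- ppois(bins$n_features - 1, lambda, lower.tail = FALSE)
  bins$q <- p.adjust(bins$p, method = "BH")
  bins$flagged <- bins$q < alpha
  bins$bin <- NULL
  bins
}
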