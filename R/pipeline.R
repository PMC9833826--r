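# End-to-end orchestration over a synthetic panel:
# simulate -> kinship -> map (proteins, traits) -> classify -> hotspots ->
# correlate -> OPLS -> integrate, with a run manifest.

#' Run the full systems-genetics pipeline on a synthetic panel
#'
#' Executes every stage in dependency order and returns all intermediate
#' objects plus a manifest (seed, configs, per-stage timings, counts).
#' When `out_dir` is given, the main tables are written as TSV with a JSON
#' manifest sidecar.
#'
#' @param sim_cfg A [sim_config()] (carries the master seed).
#' @param cfg A [run_config()].
#' @param integrate_traits Trait ids to integrate (default: all simulated
#'   traits).
#' @param opls_traits Trait ids to model with OPLS (default: the first trait).
#' @param out_dir Optional output directory.
#' @return List of class `qtl_pipeline`: `panel, genes, abundance, traits,
#'   truth, kinship, protein_scan, trait_scan, calls, hotspots, strain_mat,
#'   corr, opls, integration, manifest`.
#' @export
run_pipeline <- function(sim_cfg, cfg = run_config(), integrate_traits = NULL,
                         opls_traits = NULL, out_dir = NULL) {
  stopifnot(inherits(sim_cfg, "sim_config"))
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  sim <- tick("simulate", simulate_panel(sim_cfg))
  K <- tick("kinship", ibs_kinship(sim$panel))
  pscan <- tick("map_proteins", suppressMessages(
    map_qtl(sim$abundance, sim$panel, K, cfg)
  ))
  tscan <- tick("map_traits", suppressMessages(
    map_qtl(sim$traits, sim$panel, K, cfg)
  ))
  feature_genes <- dplyr::rename(sim$truth$protein_genes, feature_id = "protein_id")
  calls <- tick("classify", suppressWarnings(
    classify_qtl(pscan$assoc, sim$panel, sim$genes, feature_genes, cfg)
  ))
  chrom_lengths <- setNames(
    rep(sim_cfg$chrom_length_bp, sim_cfg$n_chromosomes),
    as.character(seq_len(sim_cfg$n_chromosomes))
  )
  hotspots <- tick("hotspots", detect_hotspots(
    calls, chrom_lengths, bin_bp = cfg$hotspot_bin_bp, alpha = cfg$hotspot_alpha
  ))
  strain_mat <- tick("aggregate", strain_aggregate(sim$abundance, quantile_normalize = TRUE))
  corr <- tick("correlate", correlate_features(
    strain_mat, sim$traits,
    r_low = cfg$r_low, r_high = cfg$r_high, p_cut = cfg$p_cut
  ))

  trait_ids <- setdiff(names(sim$traits), "strain_id")
  opls_traits <- opls_traits %||% trait_ids[1]
  opls <- tick("opls", {
    fits <- lapply(opls_traits, function(tid) {
      y <- setNames(sim$traits[[tid]], sim$traits$strain_id)
      suppressMessages(fit_opls(strain_mat, y))
    })
    setNames(fits, opls_traits)
  })

  integrate_traits <- integrate_traits %||% trait_ids
  integration <- tick("integrate", {
    cis_sets <- cis_candidate_snps(pscan$assoc, sim$genes, feature_genes, cfg)
    dplyr::bind_rows(lapply(integrate_traits, function(tid) {
      integrate_qtl(
        pscan$assoc, tscan$assoc, tid, strain_mat, sim$traits,
        sim$panel, sim$genes, feature_genes,
        corr = corr, cis_sets = cis_sets, cfg = cfg
      )
    }))
  })

  counts <- tibble(
    n_proteins_mapped = length(unique(pscan$assoc$feature_id)),
    n_cis = sum(calls$call == "cis"),
    n_trans = sum(calls$call == "trans"),
    n_hotspot_bins = sum(hotspots$flagged),
    n_selected_pairs = sum(corr$selected, na.rm = TRUE),
    n_prioritized = sum(integration$verdict == "prioritized")
  )
  manifest <- list(
    seed = sim_cfg$seed,
    sim_config = unclass(sim_cfg),
    run_config = unclass(cfg),
    config_hash = rlang::hash(list(unclass(sim_cfg), unclass(cfg))),
    timings = as.list(timings),
    counts = as.list(counts)
  )

  res <- structure(
    list(
      panel = sim$panel, genes = sim$genes, abundance = sim$abundance,
      traits = sim$traits, truth = sim$truth, kinship = K,
      protein_scan = pscan, trait_scan = tscan, calls = calls,
      hotspots = hotspots, strain_mat = strain_mat, corr = corr,
      opls = opls, integration = integration, counts = counts,
      manifest = manifest
    ),
    class = "qtl_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.qtl_pipeline <- function(x, ...) {
  cat("<qtl_pipeline>\n")
  print(x$counts)
  invisible(x)
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_genotypes(res$panel, fp("genotypes.tsv"))
  write_genes(res$genes, fp("genes.tsv"))
  write_abundance(res$abundance, fp("abundance.tsv"))
  write_traits(res$traits, fp("traits.tsv"))
  readr::write_tsv(res$protein_scan$assoc, fp("protein_assoc.tsv"), progress = FALSE)
  readr::write_tsv(res$protein_scan$fits, fp("protein_fits.tsv"), progress = FALSE)
  readr::write_tsv(res$trait_scan$assoc, fp("trait_assoc.tsv"), progress = FALSE)
  readr::write_tsv(res$calls, fp("qtl_calls.tsv"), progress = FALSE)
  readr::write_tsv(res$hotspots, fp("hotspots.tsv"), progress = FALSE)
  readr::write_tsv(res$corr, fp("correlations.tsv"), progress = FALSE)
  readr::write_tsv(res$integration, fp("integration.tsv"), progress = FALSE)
  truth <- res$truth
  jsonlite::write_json(
    lapply(truth[c("cis", "hotspots", "protein_genes", "heritability", "trait_weights")], as.data.frame),
    fp("truth_ledger.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  write_manifest(fp("manifest.json"),
    config = res$manifest$run_config,
    seed = res$manifest$seed,
    inputs = NULL,
    extra = list(
      sim_config = res$manifest$sim_config,
      timings = res$manifest$timings, counts = res$manifest$counts
    )
  )
  invisible(out_dir)
}

#' Summary report of a pipeline run
#'
#' Counts table plus, when a truth ledger is present, a confusion table of cis
#' calls against the planted architecture.
#'
#' @param res A `qtl_pipeline` from [run_pipeline()].
#' @return List with `counts` and (if truth is available) `cis_confusion`
#'   (`tp, fn, fp, recall, false_call_rate` over proteins).
#' @export
qtl_report <- function(res) {
  stopifnot(inherits(res, "qtl_pipeline"))
  out <- list(counts = res$counts)
  if (!is.null(res$truth)) {
    planted <- unique(res$truth$cis$protein_id)
    called <- unique(res$calls$feature_id[res$calls$call == "cis"])
    all_prot <- res$truth$protein_genes$protein_id
    tp <- length(intersect(planted, called))
    fp <- length(setdiff(called, planted))
    out$cis_confusion <- tibble(
      tp = tp, fn = length(setdiff(planted, called)), fp = fp,
      recall = if (length(planted) > 0) tp / length(planted) else NA_real_,
      false_call_rate = fp / max(1, length(all_prot) - length(planted))
    )
  }
  out
}
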