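# Readers/writers for the tabular interchange formats. Everything is UTF-8 TSV
# with a header row and "NA" for missing; coordinates are 1-based inclusive
# everywhere after ingestion (BED is converted on read).

geno_meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt", "consequence", "host_gene")

#' Read a genotype panel
#'
#' TSV layout: columns `snp_id, chrom, pos, ref, alt, consequence, host_gene`
#' followed by one dosage column per strain. VCF input collapses per-strain GT
#' calls to alternate-allele dosage (`0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`,
#' missing -> `NA`).
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (format == "vcf") return(read_genotypes_vcf(path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = "NA", progress = FALSE)
  if (!all(geno_meta_cols %in% names(tab))) {
    abort(paste("genotype TSV must start with columns:", paste(geno_meta_cols, collapse = ", ")))
  }
  strain_cols <- setdiff(names(tab), geno_meta_cols)
  if (length(strain_cols) == 0) abort("genotype TSV has no strain columns")
  dosage <- as.matrix(tab[strain_cols])
  if (!is.numeric(dosage)) abort("strain dosage columns must be numeric")
  dosage <- t(dosage)
  rownames(dosage) <- strain_cols
  colnames(dosage) <- tab$snp_id
  genotype_panel(dosage, tab[geno_meta_cols])
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
    paste0(fix$CHROM, "_", fix$POS), fix$ID
  )
  dose <- apply(gt, 2, function(col) {
    alleles <- strsplit(gsub("\\|", "/", col), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) == 0 || any(a == "." | is.na(a))) return(NA_real_)
      sum(a != "0")
    }, numeric(1))
  })
  dose <- t(matrix(dose, nrow = nrow(gt), dimnames = list(ids, colnames(gt))))
  meta <- tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    consequence = NA_character_, host_gene = NA_character_
  )
  genotype_panel(dose, meta)
}

#' Write a genotype panel to TSV
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  meta <- panel$snp_meta[geno_meta_cols]
  tab <- dplyr::bind_cols(meta, as_tibble(t(panel$dosage)))
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a protein abundance table
#'
#' TSV layout: `sample_id`, `strain_id`, then one column per protein holding
#' log2 ratio-to-reference values. Empty cells and `NA` read as missing (never
#' coerced to zero).
#'
#' @param path File path.
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = c("NA", ""), progress = FALSE)
  if (!all(c("sample_id", "strain_id") %in% names(tab))) {
    abort("abundance TSV needs sample_id and strain_id columns")
  }
  feats <- setdiff(names(tab), c("sample_id", "strain_id"))
  values <- as.matrix(tab[feats])
  rownames(values) <- tab$sample_id
  abundance_matrix(values, tab[c("sample_id", "strain_id")])
}

#' @rdname read_abundance
#' @param ab An [abundance_matrix()].
#' @export
write_abundance <- function(ab, path) {
  tab <- dplyr::bind_cols(ab$sample_to_strain, as_tibble(ab$values))
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a strain-level trait table
#'
#' TSV layout: `strain_id` then one numeric column per trait, one row per
#' strain.
#'
#' @param path File path.
#' @return A tibble with a `strain_id` column and one column per trait.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  validate_traits(readr::read_tsv(path, show_col_types = FALSE, na = c("NA", ""), progress = FALSE))
}

#' @rdname read_traits
#' @param traits Trait tibble as returned by [read_traits()].
#' @export
write_traits <- function(traits, path) {
  readr::write_tsv(validate_traits(traits), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Accepts a TSV (`gene_id, chrom, start, end, strand`; 1-based inclusive), a
#' BED file (0-based half-open, converted to 1-based inclusive on read), or a
#' GFF3 (gene-type records). BED/GFF3 parsing uses rtracklayer.
#'
#' @param path File path.
#' @param format `"tsv"`, `"bed"`, or `"gff3"`.
#' @return Tibble of gene models: `gene_id, chrom, start, end, strand`.
#' @export
read_genes <- function(path, format = c("tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (format == "tsv") {
    return(validate_genes(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("BED/GFF3 input needs the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3" && "type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", ]
  }
  id <- if ("name" %in% names(df) && !all(is.na(df$name))) {
    df$name
  } else if ("ID" %in% names(df)) {
    df$ID
  } else if ("gene_id" %in% names(df)) {
    df$gene_id
  } else {
    paste0("gene_", seq_len(nrow(df)))
  }
  validate_genes(tibble(
    gene_id = as.character(id),
    chrom = as.character(df$seqnames),
    start = df$start, # rtracklayer already yields 1-based inclusive
    end = df$end,
    strand = ifelse(as.character(df$strand) %in% c("+", "-"), as.character(df$strand), "+")
  ))
}

#' @rdname read_genes
#' @param genes Gene tibble.
#' @export
write_genes <- function(genes, path) {
  readr::write_tsv(validate_genes(genes)[c("gene_id", "chrom", "start", "end", "strand")],
    path,
    na = "NA", progress = FALSE
  )
  invisible(path)
}

#' Write a JSON run-metadata sidecar
#'
#' Records inputs, configuration, seed and package version next to a result
#' file so that any table can be traced back to the run that produced it.
#'
#' @param path Output path of the `.json` sidecar.
#' @param config A [run_config()] or [sim_config()] (or plain list).
#' @param seed Integer seed used for the run.
#' @param inputs Named character vector/list of input paths; files that exist
#'   are content-hashed.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seed = NULL, inputs = NULL, extra = NULL) {
  hashes <- NULL
  if (!is.null(inputs)) {
    inputs <- unlist(inputs)
    hashes <- vapply(inputs, function(f) {
      if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
    }, character(1))
  }
  manifest <- c(
    list(
      package = "strainqtl",
      version = as.character(utils::packageVersion("strainqtl")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      config = unclass(config),
      config_hash = if (!is.null(config)) rlang::hash(unclass(config)),
      inputs = as.list(hashes)
    ),
    extra
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(manifest)
}
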