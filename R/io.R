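#' Write / read a genotype matrix as TSV
#'
#' Layout: snp_id, chrom, pos_bp, then one column per strain with calls in
#' \{0, 1, NA\}. All coordinates 1-based.
#'
#' @param geno a `geno_matrix`.
#' @param path file path.
#' @return `read_genotypes` returns a `geno_matrix`; `write_genotypes`
#'   returns `path` invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  df <- data.frame(snp_id = geno$snp_ids, chrom = geno$chrom,
                   pos_bp = geno$pos_bp, t(geno$calls), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("genotype file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id in genotype file")
  strain_cols <- setdiff(names(df), need)
  calls <- t(as.matrix(df[, strain_cols, drop = FALSE]))
  storage.mode(calls) <- "double"
  bad <- which(!(calls %in% c(0, 1) | is.na(calls)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(calls))
    stop(sprintf("invalid genotype call (not 0/1/NA) for strain '%s', SNP '%s'",
                 strain_cols[rc[1L]], df$snp_id[rc[2L]]))
  }
  colnames(calls) <- df$snp_id
  geno_matrix(calls, df$chrom, df$pos_bp)
}

#' Write / read a phenotype matrix as TSV
#'
#' Layout: feature_id, then one column per sample named `strain` or
#' `strain:replicate`.
#'
#' @param pheno a `pheno_matrix`.
#' @param path file path.
#' @param kind phenotype kind used when reading.
#' @return `read_phenotypes` returns a `pheno_matrix`; `write_phenotypes`
#'   returns `path` invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  stopifnot(inherits(pheno, "pheno_matrix"))
  cols <- ifelse(pheno$replicate == 1L & !duplicated(pheno$strain) &
                   !pheno$strain %in% pheno$strain[duplicated(pheno$strain)],
                 pheno$strain,
                 paste(pheno$strain, pheno$replicate, sep = ":"))
  df <- data.frame(feature_id = rownames(pheno$values), pheno$values,
                   check.names = FALSE)
  names(df)[-1] <- cols
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path, kind = c("transcript", "peptide", "trait")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "feature_id") stop("first column must be feature_id")
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id in phenotype file")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature_id
  cols <- colnames(vals)
  has_rep <- grepl(":", cols, fixed = TRUE)
  strain <- ifelse(has_rep, sub(":.*$", "", cols), cols)
  replicate <- ifelse(has_rep, as.integer(sub("^.*:", "", cols)), 1L)
  pheno_matrix(vals, strain = strain, replicate = replicate, kind = kind)
}

#' Write an annotation set as a directory of TSV files
#'
#' Genes are written BED-like (chrom, start, end, id, strand; 1-based
#' inclusive) plus mapping tables for probesets, probes, peptides, isoforms
#' and groups.
#'
#' @param ann an `annotation_set`.
#' @param dir output directory (created if needed).
#' @return `read_annotations` returns an `annotation_set`;
#'   `write_annotations` returns `dir` invisibly.
#' @export
write_annotations <- function(ann, dir) {
  stopifnot(inherits(ann, "annotation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  genes_bed <- ann$genes[, c("chrom", "tss_bp", "tes_bp", "gene_id", "strand")]
  names(genes_bed) <- c("chrom", "start_bp", "end_bp", "id", "strand")
  w(genes_bed, "genes")
  w(ann$probeset_genes, "probeset_genes")
  w(ann$probes, "probes")
  w(ann$peptides, "peptides")
  w(ann$peptide_genes, "peptide_genes")
  w(ann$peptide_isoforms, "peptide_isoforms")
  w(ann$groups, "groups")
  invisible(dir)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(dir) {
  r <- function(name) utils::read.delim(file.path(dir, paste0(name, ".tsv")),
                                        check.names = FALSE,
                                        colClasses = NA)
  genes_bed <- r("genes")
  if (any(genes_bed$start_bp > genes_bed$end_bp))
    stop("gene annotation with start > end")
  genes <- data.frame(gene_id = genes_bed$id, chrom = as.character(genes_bed$chrom),
                      tss_bp = genes_bed$start_bp, tes_bp = genes_bed$end_bp,
                      strand = genes_bed$strand)
  probes <- r("probes"); probes$chrom <- as.character(probes$chrom)
  peptides <- r("peptides")
  if ("chrom" %in% names(peptides)) peptides$chrom <- as.character(peptides$chrom)
  annotation_set(genes = genes,
                 probeset_genes = r("probeset_genes"),
                 probes = probes,
                 peptides = peptides,
                 peptide_genes = r("peptide_genes"),
                 peptide_isoforms = r("peptide_isoforms"),
                 groups = r("groups"))
}

#' Default pipeline configuration
#'
#' Collects every analysis threshold with its standard default: peptide
#' missingness 0.5, signal-to-noise cutoff 2, heritability p 0.05,
#' probe-mask exclusion at 8 probes, MAF floor 0.10, LD r-squared 0.5,
#' local-QTL flank 2 Mb, hotspot window 2 Mb with 50 kb step, FDR levels
#' \{0.05, 0.01, 0.001\}, and 100000 bootstrap draws.
#'
#' @param ... overrides for individual entries (unknown names are rejected).
#' @param sim a [sim_config()] for the simulate stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(..., sim = sim_config()) {
  cfg <- list(max_missing = 0.5, snr_cutoff = 2, herit_p = 0.05,
              probe_mask_exclude = 8, maf_min = 0.10, miss_max = 0.10,
              r2_cut = 0.5, flank_bp = 2e6, window_bp = 2e6, step_bp = 5e4,
              fdr_levels = c(0.05, 0.01, 0.001), n_boot = 100000,
              eigen_trends = 0, seed = sim$seed)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$sim <- sim
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic-panel analysis pipeline
#'
#' Chains simulate, qc, concordance, gwas and qtl stages, writing each
#' stage's outputs as TSV under `out_dir` together with a provenance manifest
#' (config hash, per-stage row counts). With `resume = TRUE`, stages whose
#' outputs already exist are skipped and their outputs re-read.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @param resume skip stages whose outputs exist (default FALSE).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(cfg, out_dir, resume = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(cfg), stages = list())
  done <- function(...) all(file.exists(file.path(out_dir, c(...))))

  ## simulate
  if (resume && done("genotypes.tsv", "transcripts.tsv", "peptides.tsv",
                     "tech_reps.tsv", "traits.tsv", "annotations/genes.tsv")) {
    geno <- read_genotypes(file.path(out_dir, "genotypes.tsv"))
    ann <- read_annotations(file.path(out_dir, "annotations"))
    transcripts <- read_phenotypes(file.path(out_dir, "transcripts.tsv"), "transcript")
    peptides <- read_phenotypes(file.path(out_dir, "peptides.tsv"), "peptide")
    traits <- read_phenotypes(file.path(out_dir, "traits.tsv"), "trait")
    tech <- as.matrix(utils::read.delim(file.path(out_dir, "tech_reps.tsv"),
                                        row.names = 1, check.names = FALSE))
    manifest$stages$simulate <- "resumed"
  } else {
    panel <- simulate_panel(cfg$sim)
    geno <- panel$geno; ann <- panel$ann
    transcripts <- panel$transcripts; peptides <- panel$peptides
    traits <- panel$traits; tech <- panel$tech_reps
    write_genotypes(geno, file.path(out_dir, "genotypes.tsv"))
    write_annotations(ann, file.path(out_dir, "annotations"))
    write_phenotypes(transcripts, file.path(out_dir, "transcripts.tsv"))
    write_phenotypes(peptides, file.path(out_dir, "peptides.tsv"))
    write_phenotypes(traits, file.path(out_dir, "traits.tsv"))
    utils::write.table(data.frame(peptide_id = rownames(tech), tech,
                                  check.names = FALSE),
                       file.path(out_dir, "tech_reps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tech <- as.matrix(as.data.frame(tech))
    manifest$stages$simulate <- list(n_snps = ncol(geno$calls),
                                     n_transcripts = nrow(transcripts$values),
                                     n_peptides = nrow(peptides$values))
  }

  ## qc
  basic <- peptide_basic_filter(peptides, ann, max_missing = cfg$max_missing)
  snr <- signal_to_noise(subset_features(peptides, basic$retained),
                         tech[basic$retained, , drop = FALSE],
                         cutoff = cfg$snr_cutoff)
  pep_keep <- snr$peptide_id[snr$pass]
  her <- heritability_anova(transcripts)
  masked <- mask_probes(ann, geno$chrom, geno$pos_bp,
                        exclude_at = cfg$probe_mask_exclude)
  tr_keep <- setdiff(filter_transcripts(her, ann, peptide_ids = pep_keep,
                                        p_cutoff = cfg$herit_p),
                     masked$excluded_probesets)
  pep_f <- subset_features(peptides, pep_keep)
  if (cfg$eigen_trends > 0) pep_f <- eigen_normalize(pep_f, cfg$eigen_trends)
  tr_f <- subset_features(transcripts, tr_keep)
  utils::write.table(rbind(basic$log,
                           data.frame(peptide_id = snr$peptide_id[!snr$pass],
                                      rule = "signal_to_noise")),
                     file.path(out_dir, "peptide_rejections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(snr, file.path(out_dir, "snr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(her, file.path(out_dir, "heritability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$qc <- list(peptides_retained = length(pep_keep),
                             transcripts_retained = length(tr_keep))

  ## concordance
  pairs <- build_gene_pairs(pep_f, tr_f, ann)
  utils::write.table(pairs, file.path(out_dir, "gene_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  strata <- snr_strata_summary(pairs, snr[snr$peptide_id %in% pep_keep, ])
  utils::write.table(strata, file.path(out_dir, "snr_strata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$concordance <- list(n_pairs = nrow(pairs))

  ## gwas
  K <- ibs_kinship(geno)
  scan_t <- gwas_scan(tr_f, geno, K, maf_min = cfg$maf_min,
                      miss_max = cfg$miss_max)
  scan_p <- gwas_scan(pep_f, geno, K, maf_min = cfg$maf_min,
                      miss_max = cfg$miss_max)
  utils::write.table(scan_t, file.path(out_dir, "assoc_transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan_p, file.path(out_dir, "assoc_peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$gwas <- list(n_tests_transcript = nrow(scan_t),
                               n_tests_peptide = nrow(scan_p))

  ## qtl
  fdr <- cfg$fdr_levels[1]
  sig_t <- scan_t[scan_t$q < fdr, , drop = FALSE]
  sig_p <- scan_p[scan_p$q < fdr, , drop = FALSE]
  calls <- list()
  if (nrow(sig_t)) {
    pr <- ld_prune(sig_t, geno, r2_cut = cfg$r2_cut)
    calls$e <- classify_qtl(pr[pr$is_peak, ], ann, flank_bp = cfg$flank_bp,
                            dataset = "transcript")
  }
  if (nrow(sig_p)) {
    pr <- ld_prune(sig_p, geno, r2_cut = cfg$r2_cut)
    calls$p <- classify_qtl(pr[pr$is_peak, ], ann, flank_bp = cfg$flank_bp,
                            dataset = "protein")
  }
  all_calls <- do.call(rbind, calls)
  if (!is.null(all_calls)) {
    utils::write.table(all_calls, file.path(out_dir, "qtl_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hot <- hotspot_scan(all_calls, window_bp = cfg$window_bp,
                        step_bp = cfg$step_bp)
    utils::write.table(hot, file.path(out_dir, "hotspots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$qtl <- list(n_calls = nrow(all_calls))
  } else {
    manifest$stages$qtl <- list(n_calls = 0L)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(geno = geno, ann = ann, peptides = pep_f, transcripts = tr_f,
                 snr = snr, heritability = her, pairs = pairs,
                 scan_transcripts = scan_t, scan_peptides = scan_p,
                 calls = all_calls, manifest = manifest))
}

#' Subset a phenotype matrix to a set of features
#'
#' @param pheno a `pheno_matrix`.
#' @param ids feature ids to keep.
#' @return a `pheno_matrix`.
#' @export
subset_features <- function(pheno, ids) {
  out <- pheno
  out$values <- pheno$values[intersect(ids, rownames(pheno$values)), ,
                             drop = FALSE]
  out$feature_ids <- rownames(out$values)
  out
}

## stable hash of a configuration (serialize to yaml, md5 the file)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_recursive(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}
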