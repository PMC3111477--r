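# Small-panel configurations and hand-built fixtures shared across tests.

tiny_cfg <- function(...) {
  defaults <- list(n_strains = 40, n_chromosomes = 2, chrom_length_bp = 20e6,
                   n_snps = 120, ld_block_mean_bp = 2e6, n_transcripts = 20,
                   n_peptides = 30, n_traits = 4, missing_rate_peptide = 0.1,
                   seed = 101)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

## a pheno_matrix from a plain matrix; strain names default to column names
make_pheno <- function(values, strain = colnames(values), replicate = NULL,
                       kind = "peptide") {
  pheno_matrix(values, strain = strain, replicate = replicate, kind = kind)
}

## minimal annotation set with one gene spanning [tss, tes] on chrom "1"
one_gene_ann <- function(peptide_ids = character(0), sequences = character(0),
                         tss = 1e6, tes = 1.5e6, extra_genes = NULL) {
  genes <- data.frame(gene_id = "g1", chrom = "1", tss_bp = tss, tes_bp = tes,
                      strand = "+")
  if (!is.null(extra_genes)) genes <- rbind(genes, extra_genes)
  pep <- if (length(peptide_ids))
    data.frame(peptide_id = peptide_ids, sequence = sequences) else NULL
  pg <- if (length(peptide_ids))
    data.frame(peptide_id = peptide_ids, gene_id = "g1") else NULL
  annotation_set(genes = genes, peptides = pep, peptide_genes = pg)
}

## deterministic toy genotype matrix from explicit SNP columns
toy_geno <- function(cols, chrom = NULL, pos = NULL) {
  X <- do.call(cbind, cols)
  rownames(X) <- sprintf("s%02d", seq_len(nrow(X)))
  colnames(X) <- names(cols)
  if (is.null(chrom)) chrom <- rep("1", ncol(X))
  if (is.null(pos)) pos <- seq_len(ncol(X)) * 1000
  geno_matrix(X, chrom, pos)
}
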