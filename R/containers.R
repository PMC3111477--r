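#' Construct a genotype matrix for an inbred panel
#'
#' Homozygous inbred genotypes are coded \{0, 1\} (the two homozygous states;
#' heterozygotes do not occur in fully inbred strains). SNPs are ordered by
#' chromosome and position; positions must be strictly increasing within a
#' chromosome.
#'
#' @param calls numeric matrix, strains x SNPs, entries in \{0, 1, NA\}.
#'   Row names are strain identifiers, column names SNP identifiers.
#' @param chrom character vector of per-SNP chromosome labels.
#' @param pos_bp numeric vector of per-SNP 1-based positions.
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `chrom`, `pos_bp`, `strain_ids`, `snp_ids`.
#' @export
geno_matrix <- function(calls, chrom, pos_bp) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix (strains x SNPs)")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("`calls` must have strain row names and SNP column names")
  if (length(chrom) != ncol(calls) || length(pos_bp) != ncol(calls))
    stop("`chrom` and `pos_bp` must have one entry per SNP")
  bad <- !(calls %in% c(0, 1) | is.na(calls))
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(calls))
    stop(sprintf("genotype call at strain '%s', SNP '%s' is not in {0, 1, NA}",
                 rownames(calls)[rc[1L]], colnames(calls)[rc[2L]]))
  }
  for (ch in unique(chrom)) {
    p <- pos_bp[chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  structure(list(calls = calls, chrom = as.character(chrom),
                 pos_bp = as.numeric(pos_bp),
                 strain_ids = rownames(calls), snp_ids = colnames(calls)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d strains x %d SNPs on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$chrom))))
  invisible(x)
}

#' Construct a phenotype matrix (features x samples)
#'
#' Holds molecular or clinical phenotypes on the log2 scale, one row per
#' feature. Samples are strain measurements; a strain may appear in several
#' columns (biological replicates), tracked through `strain` and `replicate`.
#'
#' @param values numeric matrix, features x samples, with row names
#'   (feature ids) and column names (sample ids). `NA` marks missing values.
#' @param strain character vector mapping each column to a strain id.
#' @param replicate integer replicate index per column (default all 1).
#' @param kind one of "transcript", "peptide", "trait".
#' @return An object of class `pheno_matrix`.
#' @export
pheno_matrix <- function(values, strain, replicate = NULL,
                         kind = c("transcript", "peptide", "trait")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature row names and sample column names")
  if (length(strain) != ncol(values))
    stop("`strain` must have one entry per sample column")
  if (is.null(replicate)) replicate <- rep(1L, ncol(values))
  if (any(!is.finite(values) & !is.na(values)))
    stop("phenotype values must be finite or NA")
  structure(list(values = values, strain = as.character(strain),
                 replicate = as.integer(replicate), kind = kind,
                 feature_ids = rownames(values)),
            class = "pheno_matrix")
}

#' @export
print.pheno_matrix <- function(x, ...) {
  cat(sprintf("pheno_matrix (%s): %d features x %d samples (%d strains)\n",
              x$kind, nrow(x$values), ncol(x$values), length(unique(x$strain))))
  invisible(x)
}

#' Average replicate measurements to one column per strain
#'
#' @param pheno a `pheno_matrix`.
#' @return numeric matrix, features x strains, strain means over non-missing
#'   replicates.
#' @export
strain_means <- function(pheno) {
  stopifnot(inherits(pheno, "pheno_matrix"))
  f <- factor(pheno$strain, levels = unique(pheno$strain))
  X <- pheno$values
  obs <- !is.na(X)
  Xz <- ifelse(obs, X, 0)
  ind <- level_indicator(f)
  sums <- Xz %*% ind
  cnts <- obs %*% ind
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  colnames(out) <- levels(f)
  out
}

#' Construct an annotation set
#'
#' Bundles gene models, probeset probe intervals, peptide records and group
#' (GO / pathway) memberships. All coordinates are 1-based inclusive.
#'
#' @param genes data.frame with columns gene_id, chrom, tss_bp, tes_bp, strand.
#' @param probeset_genes data.frame (probeset_id, gene_id); a probeset mapped
#'   to several genes has several rows.
#' @param probes data.frame (probeset_id, chrom, start_bp, end_bp), one row
#'   per 25-mer probe.
#' @param peptides data.frame (peptide_id, sequence); tryptic peptides ending
#'   in K or R, with optional exon columns chrom, exon_start, exon_end.
#' @param peptide_genes data.frame (peptide_id, gene_id), multi-row for
#'   ambiguous peptides.
#' @param peptide_isoforms data.frame (peptide_id, isoform_id).
#' @param groups data.frame (term_id, namespace, gene_id) with namespace in
#'   CC, MF, BP, pathway.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes, probeset_genes = NULL, probes = NULL,
                           peptides = NULL, peptide_genes = NULL,
                           peptide_isoforms = NULL, groups = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "tss_bp", "tes_bp") %in% names(genes)))
  if (any(genes$tss_bp > genes$tes_bp))
    stop("gene with tss_bp > tes_bp; coordinates must satisfy tss <= tes")
  empty <- function(...) {
    cols <- c(...)
    stats::setNames(as.data.frame(replicate(length(cols), character(0),
                                            simplify = FALSE)), cols)
  }
  if (is.null(probeset_genes)) probeset_genes <- empty("probeset_id", "gene_id")
  if (is.null(probes))
    probes <- data.frame(probeset_id = character(0), chrom = character(0),
                         start_bp = numeric(0), end_bp = numeric(0))
  if (is.null(peptides)) peptides <- empty("peptide_id", "sequence")
  if (is.null(peptide_genes)) peptide_genes <- empty("peptide_id", "gene_id")
  if (is.null(peptide_isoforms)) peptide_isoforms <- empty("peptide_id", "isoform_id")
  if (is.null(groups)) groups <- empty("term_id", "namespace", "gene_id")
  if (nrow(probes) && any(probes$end_bp - probes$start_bp + 1 != 25))
    stop("every probe interval must have length 25")
  known <- genes$gene_id
  for (nm in c("probeset_genes", "peptide_genes", "groups")) {
    df <- get(nm)
    if (nrow(df) && !all(df$gene_id %in% known))
      stop(sprintf("%s refers to gene ids absent from `genes`", nm))
  }
  if (nrow(peptides)) {
    if (any(is.na(peptides$sequence) | peptides$sequence == ""))
      stop("peptide without sequence")
    if (any(grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                  peptides$sequence)))
      stop("peptide sequence with characters outside the 20-letter amino-acid alphabet")
  }
  structure(list(genes = genes, probeset_genes = probeset_genes,
                 probes = probes, peptides = peptides,
                 peptide_genes = peptide_genes,
                 peptide_isoforms = peptide_isoforms, groups = groups),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(paste0("annotation_set: %d genes, %d probesets (%d probes), ",
                     "%d peptides, %d group terms\n"),
              nrow(x$genes), length(unique(x$probeset_genes$probeset_id)),
              nrow(x$probes), nrow(x$peptides),
              length(unique(x$groups$term_id))))
  invisible(x)
}

## 20-letter amino-acid alphabet
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## 0/1 indicator matrix of factor levels (columns), robust to single-level f
level_indicator <- function(f) {
  ind <- vapply(levels(f), function(l) as.numeric(f == l),
                numeric(length(f)))
  matrix(ind, nrow = length(f), dimnames = list(NULL, levels(f)))
}

## row variance with NA handling (n-1 denominator)
row_vars <- function(X) {
  obs <- !is.na(X)
  n <- rowSums(obs)
  Xz <- ifelse(obs, X, 0)
  mu <- rowSums(Xz) / n
  ss <- rowSums((Xz - mu * obs)^2)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}

## fan a global seed out into deterministic per-stage child seeds (< 2^31)
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("genotypes", "annotations", "truth", "molecular",
                        "traits", "analysis"))
  if (is.na(idx)) idx <- 7L + (sum(utf8ToInt(stage)) %% 100L)
  as.integer((as.numeric(seed) %% 1e6) * 1009 + idx * 104729) %% 2147483647L
}
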