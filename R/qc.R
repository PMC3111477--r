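#' Log2-transform (optionally) and zero-center a phenotype matrix
#'
#' Each feature row is centered to mean zero over its non-missing entries,
#' matching the convention of reporting log2 abundances relative to the
#' feature's panel mean.
#'
#' @param pheno a `pheno_matrix`.
#' @param log2_transform if `TRUE`, values are log2-transformed first; they
#'   must then be strictly positive.
#' @return A `pheno_matrix` with zero-mean feature rows.
#' @export
log2_center <- function(pheno, log2_transform = FALSE) {
  stopifnot(inherits(pheno, "pheno_matrix"))
  X <- pheno$values
  if (log2_transform) {
    bad <- rowSums(X <= 0, na.rm = TRUE) > 0
    if (any(bad))
      stop("non-positive value(s) in feature(s) ",
           paste(utils::head(rownames(X)[bad], 3), collapse = ", "),
           "; cannot log2-transform")
    X <- log2(X)
  }
  X <- X - rowMeans(X, na.rm = TRUE)
  out <- pheno
  out$values <- X
  out
}

#' Basic peptide filters: missingness, internal K/R, unique gene
#'
#' Retains peptides that (a) are missing in fewer than half of the strains,
#' (b) carry no internal lysine or arginine (the tryptic C-terminal residue
#' is exempt), and (c) map uniquely to a single gene. A rejection log states
#' which rule(s) each dropped peptide failed.
#'
#' @param peptides a `pheno_matrix` of kind "peptide" (columns = strains).
#' @param ann an `annotation_set` with sequences and gene mappings.
#' @param max_missing missingness threshold; peptides with a missing fraction
#'   `>= max_missing` are rejected (default 0.5, i.e. "less than 50\% missing"
#'   is required, strictly).
#' @return list with `retained` (character vector of peptide ids) and
#'   `log` (data.frame peptide_id, rule for every rejection).
#' @export
peptide_basic_filter <- function(peptides, ann, max_missing = 0.5) {
  stopifnot(inherits(peptides, "pheno_matrix"), inherits(ann, "annotation_set"))
  ids <- rownames(peptides$values)
  seqs <- ann$peptides$sequence[match(ids, ann$peptides$peptide_id)]
  if (any(is.na(seqs) | seqs == ""))
    stop("peptide without sequence: ",
         paste(utils::head(ids[is.na(seqs) | seqs == ""], 3), collapse = ", "))
  n_strain <- length(unique(peptides$strain))
  miss <- rowSums(is.na(peptides$values)) / n_strain
  internal <- substr(seqs, 1L, nchar(seqs) - 1L)
  has_kr <- grepl("[KR]", internal)
  n_genes <- table(factor(ann$peptide_genes$peptide_id, levels = ids))
  n_genes <- as.integer(n_genes[ids])

  fail <- list(missingness = miss >= max_missing,
               internal_kr = has_kr,
               gene_mapping = n_genes != 1L)
  log <- do.call(rbind, lapply(names(fail), function(rule) {
    i <- which(fail[[rule]])
    if (!length(i)) return(NULL)
    data.frame(peptide_id = ids[i], rule = rule)
  }))
  if (is.null(log)) log <- data.frame(peptide_id = character(0), rule = character(0))
  retained <- ids[!Reduce(`|`, fail)]
  list(retained = retained, log = log)
}

#' Per-peptide signal-to-noise ratio against technical replicates
#'
#' The signal-to-noise ratio S of a peptide is the ratio of its variance
#' across the strain panel (genetic + biological + technical) to its variance
#' over repeated technical runs of one reference strain (noise). Peptides
#' pass when S exceeds the cutoff (default 2). A peptide whose technical
#' variance is exactly zero is flagged as passing with an infinite S rather
#' than divided.
#'
#' @param peptides a `pheno_matrix` of kind "peptide".
#' @param tech_reps numeric matrix, peptides x technical runs.
#' @param cutoff pass threshold on S (default 2; pass is strict, S > cutoff).
#' @return data.frame (peptide_id, var_population, var_technical, snr, pass).
#' @export
signal_to_noise <- function(peptides, tech_reps, cutoff = 2) {
  stopifnot(inherits(peptides, "pheno_matrix"), is.matrix(tech_reps))
  if (ncol(tech_reps) < 2) stop("at least 2 technical replicates required")
  ids <- rownames(peptides$values)
  missing_tech <- setdiff(ids, rownames(tech_reps))
  if (length(missing_tech))
    stop("peptide(s) absent from technical replicates: ",
         paste(utils::head(missing_tech, 3), collapse = ", "))
  n_obs <- rowSums(!is.na(peptides$values))
  if (any(n_obs < 3))
    stop("peptide(s) with fewer than 3 population values: ",
         paste(utils::head(ids[n_obs < 3], 3), collapse = ", "))
  v_pop <- row_vars(peptides$values)
  v_tec <- row_vars(tech_reps[ids, , drop = FALSE])
  snr <- ifelse(v_tec > 0, v_pop / v_tec, Inf)
  pass <- ifelse(v_tec > 0, snr > cutoff, v_pop > 0)
  data.frame(peptide_id = ids, var_population = v_pop, var_technical = v_tec,
             snr = snr, pass = pass, row.names = NULL)
}

#' Broad-sense heritability by one-way strain ANOVA
#'
#' For each feature, a fixed-effect one-way ANOVA with strain as the grouping
#' factor is computed over the non-missing replicate measurements. The
#' heritability estimate is the strain sum of squares over the total sum of
#' squares, and the p-value comes from the F statistic of the strain term.
#' Unbalanced designs (1-3 replicates per strain) are supported. Features
#' with all-identical values get h2 = 0 and p = 1.
#'
#' @param pheno a `pheno_matrix` with replicate columns.
#' @return data.frame (feature_id, h2, f_stat, p_strain, df_strain, df_within).
#' @export
heritability_anova <- function(pheno) {
  stopifnot(inherits(pheno, "pheno_matrix"))
  Y <- pheno$values
  f <- factor(pheno$strain, levels = unique(pheno$strain))
  ind <- level_indicator(f)
  obs <- !is.na(Y)
  Yz <- ifelse(obs, Y, 0)
  cnt <- obs %*% ind                       # features x strains: replicates seen
  k <- rowSums(cnt > 0)                    # strains observed per feature
  if (any(k < 2))
    stop("feature(s) observed in fewer than 2 strains: ",
         paste(utils::head(rownames(Y)[k < 2], 3), collapse = ", "))
  n <- rowSums(obs)
  gsum <- Yz %*% ind
  gmean <- ifelse(cnt > 0, gsum / pmax(cnt, 1), 0)
  grand <- rowSums(Yz) / n
  ss_total <- rowSums((Yz - grand * obs)^2 * obs)
  ss_strain <- rowSums(cnt * (gmean - grand)^2 * (cnt > 0))
  ss_within <- pmax(ss_total - ss_strain, 0)
  df_s <- k - 1
  df_w <- n - k
  Fs <- (ss_strain / df_s) / (ss_within / pmax(df_w, 1))
  p <- stats::pf(Fs, df_s, df_w, lower.tail = FALSE)
  h2 <- ifelse(ss_total > 0, ss_strain / ss_total, 0)
  const <- ss_total <= .Machine$double.eps * pmax(abs(grand), 1)^2 * n
  h2[const] <- 0; p[const] <- 1; Fs[const] <- 0
  zero_within <- !const & ss_within <= 0
  p[zero_within] <- 0; Fs[zero_within] <- Inf
  p[df_w < 1] <- NA_real_
  data.frame(feature_id = rownames(Y), h2 = h2, f_stat = Fs, p_strain = p,
             df_strain = df_s, df_within = df_w, row.names = NULL)
}

#' Retain probesets by heritability significance and unambiguous annotation
#'
#' A probeset is retained if its strain-heritability p-value is below
#' `p_cutoff` and it maps to exactly one gene; probesets that map uniquely to
#' a gene represented in the retained peptide set are force-included
#' regardless of their heritability, so every protein has its matching
#' transcript available for comparison.
#'
#' @param her data.frame from [heritability_anova()] on the transcript matrix.
#' @param ann an `annotation_set`.
#' @param peptide_ids peptide ids retained by the peptide filters; their genes
#'   drive the forced inclusion (default none).
#' @param p_cutoff heritability significance threshold (default 0.05, strict
#'   p < 0.05).
#' @return character vector of retained probeset ids.
#' @export
filter_transcripts <- function(her, ann, peptide_ids = character(0),
                               p_cutoff = 0.05) {
  stopifnot(inherits(ann, "annotation_set"),
            all(c("feature_id", "p_strain") %in% names(her)))
  ids <- her$feature_id
  n_genes <- table(factor(ann$probeset_genes$probeset_id, levels = ids))
  unique_gene <- as.integer(n_genes[ids]) == 1L
  gene_of <- ann$probeset_genes$gene_id[match(ids, ann$probeset_genes$probeset_id)]
  pep_genes <- unique(ann$peptide_genes$gene_id[
    ann$peptide_genes$peptide_id %in% peptide_ids])
  keep <- (her$p_strain < p_cutoff & unique_gene) |
    (unique_gene & gene_of %in% pep_genes)
  ids[keep]
}

#' Mask probes containing SNPs and exclude heavily masked probesets
#'
#' A probe is masked if at least one SNP position falls within its 25-mer
#' interval (1-based inclusive). A probeset is excluded when `exclude_at` or
#' more of its probes are masked.
#'
#' @param ann an `annotation_set` with a `probes` table.
#' @param snp_chrom,snp_pos chromosome labels and positions of the SNPs.
#' @param exclude_at masked-probe count at which a probeset is excluded
#'   (default 8).
#' @return list with `probes` (the probes table plus a `masked` flag) and
#'   `excluded_probesets` (ids with >= `exclude_at` masked probes).
#' @export
mask_probes <- function(ann, snp_chrom, snp_pos, exclude_at = 8) {
  stopifnot(inherits(ann, "annotation_set"), length(snp_chrom) == length(snp_pos))
  pr <- ann$probes
  unknown <- setdiff(unique(pr$chrom), unique(as.character(snp_chrom)))
  if (length(unknown))
    stop("probe interval(s) on unknown chromosome: ",
         paste(unknown, collapse = ", "))
  pr$masked <- FALSE
  for (ch in unique(pr$chrom)) {
    pos <- sort(snp_pos[as.character(snp_chrom) == ch])
    i <- pr$chrom == ch
    ## a SNP lies in [start, end] iff count(pos <= end) > count(pos < start)
    pr$masked[i] <- findInterval(pr$end_bp[i], pos) >
      findInterval(pr$start_bp[i] - 1, pos)
  }
  n_masked <- tapply(pr$masked, pr$probeset_id, sum)
  excluded <- names(n_masked)[n_masked >= exclude_at]
  list(probes = pr, excluded_probesets = excluded)
}

#' Remove systematic trends by singular value decomposition
#'
#' Discovers the dominant systematic trends across samples (the leading right
#' singular vectors of the centered feature-by-sample matrix, often called
#' eigenpeptides in LC-MS normalization) and removes their contribution from
#' every feature. Missing cells are imputed to the feature mean for the
#' decomposition only and restored afterwards.
#'
#' @param pheno a `pheno_matrix`.
#' @param n_trends number of leading trends to remove; 0 returns the input
#'   (centered) unchanged.
#' @return A `pheno_matrix` of residuals, feature rows still zero-mean.
#' @export
eigen_normalize <- function(pheno, n_trends) {
  stopifnot(inherits(pheno, "pheno_matrix"))
  X <- pheno$values
  if (n_trends >= min(dim(X)))
    stop("n_trends must be smaller than both matrix dimensions")
  na_mask <- is.na(X)
  Xc <- X - rowMeans(X, na.rm = TRUE)
  Xi <- ifelse(na_mask, 0, Xc)             # feature means are 0 after centering
  if (n_trends > 0) {
    sv <- svd(Xi, nu = 0, nv = n_trends)
    V <- sv$v[, seq_len(n_trends), drop = FALSE]
    Xi <- Xi - (Xi %*% V) %*% t(V)
  }
  Xi[na_mask] <- NA_real_
  Xi <- Xi - rowMeans(Xi, na.rm = TRUE)
  out <- pheno
  out$values <- Xi
  out
}
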