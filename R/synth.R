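#' Simulation configuration for a synthetic inbred-panel study
#'
#' Defaults reproduce the scale and design of a hybrid mouse diversity panel
#' liver study: 97 inbred strains, block-structured genotypes at minor allele
#' frequency >= 10\%, transcripts profiled in three biological replicates per
#' strain, peptides measured once per strain as log2 sample/reference ratios
#' plus ten technical replicates of one reference strain, and 42 clinical
#' traits driven by subsets of the molecular phenotypes.
#'
#' @param n_strains number of inbred strains (default 97).
#' @param n_chromosomes number of autosomes (default 19).
#' @param chrom_length_bp chromosome length in bp (default 150 Mb).
#' @param n_snps total number of SNPs across the genome.
#' @param ld_block_mean_bp mean haplotype-block length in bp (default 750 kb;
#'   blocks average ~0.73 Mb in dense inbred-strain maps).
#' @param maf_min minor-allele-frequency floor in [0, 0.5) (default 0.10).
#' @param n_transcripts,n_peptides,n_traits feature counts.
#' @param n_bio_replicates_transcript biological replicates per strain for the
#'   transcript assay (default 3).
#' @param n_tech_replicates_peptide technical replicate runs of the reference
#'   strain in the peptide assay (default 10).
#' @param heritability_range range the per-feature broad-sense heritability
#'   targets are drawn from (default c(0.07, 0.95)).
#' @param frac_local_qtl,frac_distant_qtl probability that a gene carries a
#'   local / distant QTL.
#' @param effect_size_range range of QTL effect sizes, expressed as fractions
#'   of the strain-level (genetic) variance of the feature.
#' @param tech_noise_sd replicate-level technical noise standard deviation on
#'   the log2 scale (default 0.25).
#' @param missing_rate_peptide missing-at-random rate injected into the
#'   peptide matrix (default 0.2).
#' @param n_subpops number of founder subpopulations used to endow the panel
#'   with family structure (default 4).
#' @param seed global seed; per-stage child seeds are derived from it so
#'   stages can be regenerated independently.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 97, n_chromosomes = 19,
                       chrom_length_bp = 150e6, n_snps = 95854,
                       ld_block_mean_bp = 750e3, maf_min = 0.10,
                       n_transcripts = 22700, n_peptides = 5000,
                       n_traits = 42, n_bio_replicates_transcript = 3,
                       n_tech_replicates_peptide = 10,
                       heritability_range = c(0.07, 0.95),
                       frac_local_qtl = 0.3, frac_distant_qtl = 0.3,
                       effect_size_range = c(0.2, 0.8),
                       tech_noise_sd = 0.25, missing_rate_peptide = 0.2,
                       n_subpops = 4, seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_snps = as.integer(n_snps),
              ld_block_mean_bp = as.numeric(ld_block_mean_bp),
              maf_min = maf_min,
              n_transcripts = as.integer(n_transcripts),
              n_peptides = as.integer(n_peptides),
              n_traits = as.integer(n_traits),
              n_bio_replicates_transcript = as.integer(n_bio_replicates_transcript),
              n_tech_replicates_peptide = as.integer(n_tech_replicates_peptide),
              heritability_range = as.numeric(heritability_range),
              frac_local_qtl = frac_local_qtl,
              frac_distant_qtl = frac_distant_qtl,
              effect_size_range = as.numeric(effect_size_range),
              tech_noise_sd = tech_noise_sd,
              missing_rate_peptide = missing_rate_peptide,
              n_subpops = as.integer(n_subpops),
              seed = as.integer(seed))
  fr <- c(maf_min = cfg$maf_min, frac_local_qtl = cfg$frac_local_qtl,
          frac_distant_qtl = cfg$frac_distant_qtl,
          missing_rate_peptide = cfg$missing_rate_peptide)
  bad <- fr < 0 | fr > 1
  if (any(bad)) stop("fractions out of [0, 1]: ", paste(names(fr)[bad], collapse = ", "))
  if (cfg$maf_min >= 0.5) stop("maf_min must be below 0.5")
  if (cfg$n_strains < 3) stop("n_strains must be at least 3")
  hr <- cfg$heritability_range
  if (length(hr) != 2 || any(hr < 0) || any(hr > 1) || hr[1] > hr[2])
    stop("heritability_range must be an ordered pair within [0, 1]")
  if (cfg$tech_noise_sd <= 0) stop("tech_noise_sd must be positive")
  if (any(cfg$effect_size_range < 0) || any(cfg$effect_size_range > 1) ||
      diff(cfg$effect_size_range) < 0)
    stop("effect_size_range must be an ordered pair within [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate block-structured inbred genotypes
#'
#' SNPs are partitioned into contiguous blocks whose bp lengths are drawn
#' from an exponential distribution with mean `ld_block_mean_bp`. Within a
#' block every SNP is a noisy copy (per-strain flip probability 0.03) of a
#' block founder column; founders are drawn independently across blocks from
#' subpopulation-specific allele frequencies (Balding-Nichols, F = 0.2), so
#' the panel carries both linkage disequilibrium and population structure.
#' SNPs failing the minor-allele-frequency floor are redrawn; stubborn
#' failures are repaired by flipping the minimum number of majority-allele
#' strains.
#'
#' @param cfg a [sim_config()].
#' @return A [geno_matrix()] with attributes `blocks` (data.frame of true
#'   block boundaries: chrom, start_bp, end_bp, first/last SNP index) and
#'   `subpop` (per-strain subpopulation index).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_snps < cfg$n_chromosomes)
    stop("invalid config: n_snps must be at least n_chromosomes")
  set.seed(stage_seed(cfg$seed, "genotypes"))
  n <- cfg$n_strains
  flip_p <- 0.03
  subpop <- rep(seq_len(cfg$n_subpops), length.out = n)
  strain_ids <- sprintf("strain%03d", seq_len(n))

  ## spread SNPs over chromosomes as evenly as possible
  per_chr <- diff(round(seq(0, cfg$n_snps, length.out = cfg$n_chromosomes + 1)))
  calls <- matrix(NA_real_, n, cfg$n_snps)
  chrom <- character(cfg$n_snps)
  pos <- numeric(cfg$n_snps)
  blocks <- list()
  off <- 0L
  for (ch in seq_len(cfg$n_chromosomes)) {
    m <- per_chr[ch]
    if (m == 0L) next
    p_chr <- sort(sample.int(cfg$chrom_length_bp, m))
    ## block boundaries along the chromosome
    brk <- cumsum(stats::rexp(ceiling(cfg$chrom_length_bp /
                                        cfg$ld_block_mean_bp) + 25,
                              rate = 1 / cfg$ld_block_mean_bp))
    blk <- findInterval(p_chr, brk) + 1L
    for (b in unique(blk)) {
      idx <- which(blk == b)
      ## Balding-Nichols founder frequencies per subpopulation
      p_anc <- stats::runif(1, 0.25, 0.75)
      Fst <- 0.2
      p_sub <- stats::rbeta(cfg$n_subpops, p_anc * (1 - Fst) / Fst,
                            (1 - p_anc) * (1 - Fst) / Fst)
      p_sub <- pmin(pmax(p_sub, 0.05), 0.95)
      founder <- stats::rbinom(n, 1, p_sub[subpop])
      for (j in idx) {
        x <- draw_snp(founder, flip_p, cfg$maf_min)
        calls[, off + j] <- x
      }
      blocks[[length(blocks) + 1L]] <-
        data.frame(chrom = as.character(ch), start_bp = p_chr[idx[1L]],
                   end_bp = p_chr[idx[length(idx)]],
                   first_snp = off + idx[1L], last_snp = off + idx[length(idx)])
    }
    chrom[off + seq_len(m)] <- as.character(ch)
    pos[off + seq_len(m)] <- p_chr
    off <- off + m
  }
  rownames(calls) <- strain_ids
  colnames(calls) <- sprintf("snp%06d", seq_len(cfg$n_snps))
  g <- geno_matrix(calls, chrom, pos)
  attr(g, "blocks") <- do.call(rbind, blocks)
  attr(g, "subpop") <- subpop
  g
}

## one SNP column: noisy founder copy, redrawn/repaired to meet the MAF floor
draw_snp <- function(founder, flip_p, maf_min) {
  n <- length(founder)
  need <- ceiling(maf_min * n)
  for (attempt in 1:3) {
    x <- abs(founder - stats::rbinom(n, 1, flip_p))
    k <- sum(x)
    if (min(k, n - k) >= need) return(x)
  }
  ## repair: flip majority-allele strains chosen at random until the floor holds
  k <- sum(x)
  minority <- if (k <= n - k) 1 else 0
  deficit <- need - min(k, n - k)
  maj_idx <- which(x != minority)
  flip_idx <- maj_idx[sample.int(length(maj_idx), deficit)]
  x[flip_idx] <- minority
  x
}

#' Simulate gene, probeset, peptide, and group annotations
#'
#' Genes are placed uniformly on the genome; each probeset receives 11
#' 25-mer probes inside its gene body; peptides receive tryptic-style
#' sequences (C-terminal K/R) with a configurable fraction carrying an
#' internal K/R; each gene's peptides are assigned to one of its isoform
#' clusters; group terms (GO slim namespaces and pathways) draw gene
#' memberships of configurable size.
#'
#' @param cfg a [sim_config()].
#' @param n_genes number of genes (default scales with `n_transcripts`).
#' @param frac_internal_kr fraction of peptides given an internal lysine or
#'   arginine (missed-cleavage products; rejected by the basic filter).
#' @param frac_multi_gene_peptide fraction of peptides mapped ambiguously to
#'   a second gene.
#' @param frac_multi_gene_probeset fraction of probesets mapped ambiguously
#'   to a second gene.
#' @param frac_multi_isoform fraction of peptides assigned to two isoform
#'   clusters of their gene.
#' @param n_terms number of group terms.
#' @param term_size_range range of genes per term.
#' @param n_probes_per_probeset probes per probeset (default 11).
#' @return An [annotation_set()].
#' @export
simulate_annotations <- function(cfg, n_genes = NULL, frac_internal_kr = 0.1,
                                 frac_multi_gene_peptide = 0.05,
                                 frac_multi_gene_probeset = 0.05,
                                 frac_multi_isoform = 0.05, n_terms = 40,
                                 term_size_range = c(3, 30),
                                 n_probes_per_probeset = 11) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "annotations"))
  if (is.null(n_genes))
    n_genes <- max(20L, round(0.8 * max(cfg$n_transcripts, cfg$n_peptides)))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  glen <- round(stats::runif(n_genes, 5e3, 1e5))
  gchr <- as.character(sample.int(cfg$n_chromosomes, n_genes, replace = TRUE))
  gstart <- floor(stats::runif(n_genes, 1, cfg$chrom_length_bp - glen))
  genes <- data.frame(gene_id = gene_ids, chrom = gchr, tss_bp = gstart,
                      tes_bp = gstart + glen - 1,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE))

  ## probesets: random gene assignment, 11 probes of length 25 in the gene body
  ps_ids <- sprintf("ps%05d_at", seq_len(cfg$n_transcripts))
  ps_gene <- sample.int(n_genes, cfg$n_transcripts, replace = TRUE)
  probeset_genes <- data.frame(probeset_id = ps_ids, gene_id = gene_ids[ps_gene])
  multi_ps <- which(stats::runif(cfg$n_transcripts) < frac_multi_gene_probeset)
  if (length(multi_ps)) {
    extra <- sapply(multi_ps, function(i)
      gene_ids[sample(setdiff(seq_len(n_genes), ps_gene[i]), 1)])
    probeset_genes <- rbind(probeset_genes,
                            data.frame(probeset_id = ps_ids[multi_ps],
                                       gene_id = extra))
  }
  k <- n_probes_per_probeset
  pstart <- floor(stats::runif(cfg$n_transcripts * k,
                               rep(genes$tss_bp[ps_gene], each = k),
                               rep(genes$tes_bp[ps_gene] - 24, each = k)))
  probes <- data.frame(probeset_id = rep(ps_ids, each = k),
                       chrom = rep(genes$chrom[ps_gene], each = k),
                       start_bp = pstart, end_bp = pstart + 24)

  ## peptides: tryptic-style sequences ending in K/R
  pep_ids <- sprintf("pep%05d", seq_len(cfg$n_peptides))
  pep_gene <- sample.int(n_genes, cfg$n_peptides, replace = TRUE)
  inner_aa <- setdiff(AA_ALPHABET, c("K", "R"))
  seqs <- vapply(seq_len(cfg$n_peptides), function(i) {
    len <- sample(7:24, 1)
    body <- sample(inner_aa, len - 1, replace = TRUE)
    if (stats::runif(1) < frac_internal_kr)
      body[sample.int(len - 1, 1)] <- sample(c("K", "R"), 1)
    paste(c(body, sample(c("K", "R"), 1)), collapse = "")
  }, character(1))
  exon_start <- floor(stats::runif(cfg$n_peptides, genes$tss_bp[pep_gene],
                                   genes$tes_bp[pep_gene] - 100))
  peptides <- data.frame(peptide_id = pep_ids, sequence = seqs,
                         chrom = genes$chrom[pep_gene],
                         exon_start = exon_start, exon_end = exon_start + 100)
  peptide_genes <- data.frame(peptide_id = pep_ids, gene_id = gene_ids[pep_gene])
  multi_pep <- which(stats::runif(cfg$n_peptides) < frac_multi_gene_peptide)
  if (length(multi_pep)) {
    extra <- sapply(multi_pep, function(i)
      gene_ids[sample(setdiff(seq_len(n_genes), pep_gene[i]), 1)])
    peptide_genes <- rbind(peptide_genes,
                           data.frame(peptide_id = pep_ids[multi_pep],
                                      gene_id = extra))
  }

  ## isoform clusters: one or two per gene, peptides assigned to one
  n_iso <- sample(1:2, n_genes, replace = TRUE)
  iso_of <- vapply(seq_len(cfg$n_peptides), function(i)
    sprintf("%s.iso%d", gene_ids[pep_gene[i]], sample.int(n_iso[pep_gene[i]], 1)),
    character(1))
  peptide_isoforms <- data.frame(peptide_id = pep_ids, isoform_id = iso_of)
  multi_iso <- which(stats::runif(cfg$n_peptides) < frac_multi_isoform &
                       n_iso[pep_gene] > 1)
  if (length(multi_iso)) {
    other <- vapply(multi_iso, function(i) {
      cur <- as.integer(sub(".*iso", "", iso_of[i]))
      sprintf("%s.iso%d", gene_ids[pep_gene[i]],
              setdiff(seq_len(n_iso[pep_gene[i]]), cur)[1])
    }, character(1))
    peptide_isoforms <- rbind(peptide_isoforms,
                              data.frame(peptide_id = pep_ids[multi_iso],
                                         isoform_id = other))
  }

  ## group memberships
  ns <- rep(c("CC", "MF", "BP", "pathway"), length.out = n_terms)
  groups <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
    size <- sample(term_size_range[1]:term_size_range[2], 1)
    data.frame(term_id = sprintf("term%03d", t), namespace = ns[t],
               gene_id = sample(gene_ids, min(size, n_genes)))
  }))

  annotation_set(genes = genes, probeset_genes = probeset_genes,
                 probes = probes, peptides = peptides,
                 peptide_genes = peptide_genes,
                 peptide_isoforms = peptide_isoforms, groups = groups)
}

#' Construct a ground-truth object for the simulator
#'
#' @param features data.frame (feature_id, kind, gene_id, h2_target).
#' @param effects data.frame (feature_id, snp_id, frac, locality); `frac` is
#'   the fraction of the feature's strain-level variance explained by the SNP.
#' @param drivers data.frame (trait_id, feature_id, coef).
#' @param seed seed recorded with the truth.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(features, effects = NULL, drivers = NULL, seed = NA_integer_) {
  stopifnot(is.data.frame(features),
            all(c("feature_id", "kind", "gene_id", "h2_target") %in% names(features)))
  if (is.null(effects))
    effects <- data.frame(feature_id = character(0), snp_id = character(0),
                          frac = numeric(0), locality = character(0))
  if (is.null(drivers))
    drivers <- data.frame(trait_id = character(0), feature_id = character(0),
                          coef = numeric(0))
  if (any(features$h2_target < 0 | features$h2_target > 1))
    stop("h2_target must lie in [0, 1]")
  if (nrow(effects)) {
    tot <- tapply(effects$frac, effects$feature_id, sum)
    if (any(tot > 1 + 1e-12))
      stop("per-feature QTL effect fractions must sum to at most 1")
  }
  structure(list(features = features, effects = effects, drivers = drivers,
                 seed = seed), class = "sim_truth")
}

#' Draw a random genetic architecture for the annotated features
#'
#' Genes receive local and/or distant QTLs with the configured probabilities;
#' all features (probesets and peptides) of a gene inherit its QTLs, which is
#' what couples transcript and protein levels of the same gene. Traits are
#' assigned one to three molecular driver features each.
#'
#' @param geno a [geno_matrix()].
#' @param ann an [annotation_set()].
#' @param cfg a [sim_config()].
#' @return A [sim_truth()].
#' @export
simulate_truth <- function(geno, ann, cfg) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(ann, "annotation_set"),
            inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "truth"))
  first_gene <- function(df, id_col) df[!duplicated(df[[id_col]]), ]
  ps <- first_gene(ann$probeset_genes, "probeset_id")
  pep <- first_gene(ann$peptide_genes, "peptide_id")
  features <- rbind(
    data.frame(feature_id = ps$probeset_id,
               kind = rep("transcript", nrow(ps)), gene_id = ps$gene_id),
    data.frame(feature_id = pep$peptide_id,
               kind = rep("peptide", nrow(pep)), gene_id = pep$gene_id))
  features$h2_target <- stats::runif(nrow(features), cfg$heritability_range[1],
                                     cfg$heritability_range[2])

  ## per-gene QTL architecture
  used_genes <- unique(features$gene_id)
  gi <- match(used_genes, ann$genes$gene_id)
  eff <- list()
  for (k in seq_along(used_genes)) {
    g <- ann$genes[gi[k], ]
    fr <- numeric(0); snp <- character(0); loc <- character(0)
    if (stats::runif(1) < cfg$frac_local_qtl) {
      cand <- which(geno$chrom == g$chrom &
                      geno$pos_bp >= g$tss_bp - 2e6 & geno$pos_bp <= g$tes_bp + 2e6)
      if (length(cand)) {
        snp <- c(snp, geno$snp_ids[cand[sample.int(length(cand), 1)]])
        fr <- c(fr, stats::runif(1, cfg$effect_size_range[1], cfg$effect_size_range[2]))
        loc <- c(loc, "local")
      }
    }
    if (stats::runif(1) < cfg$frac_distant_qtl) {
      cand <- which(geno$chrom != g$chrom)
      if (length(cand)) {
        snp <- c(snp, geno$snp_ids[cand[sample.int(length(cand), 1)]])
        fr <- c(fr, stats::runif(1, cfg$effect_size_range[1], cfg$effect_size_range[2]))
        loc <- c(loc, "distant")
      }
    }
    if (length(fr) && sum(fr) > 0.95) fr <- fr * 0.95 / sum(fr)
    if (length(fr))
      eff[[length(eff) + 1L]] <- data.frame(gene_id = used_genes[k],
                                            snp_id = snp, frac = fr,
                                            locality = loc)
  }
  eff <- if (length(eff)) do.call(rbind, eff) else
    data.frame(gene_id = character(0), snp_id = character(0),
               frac = numeric(0), locality = character(0))
  effects <- merge(features[, c("feature_id", "gene_id")], eff, by = "gene_id")
  effects <- effects[, c("feature_id", "snp_id", "frac", "locality")]

  ## trait drivers
  drivers <- do.call(rbind, lapply(seq_len(cfg$n_traits), function(t) {
    nd <- sample(1:3, 1)
    data.frame(trait_id = sprintf("trait%02d", t),
               feature_id = sample(features$feature_id, nd),
               coef = sample(c(-1, 1), nd, replace = TRUE) *
                 stats::runif(nd, 0.5, 1.5))
  }))
  sim_truth(features, effects, drivers, seed = cfg$seed)
}

## strain/replicate variance ratio that calibrates the one-way-ANOVA
## heritability estimator (SS_strain/SS_total) to a target expectation h,
## given s strains and r replicates. For r = 1 the target is interpreted as
## the strain-level fraction of single-measurement variance. Infeasible
## targets (below the estimator's design floor (s-1)/(sr-1)) are clamped to 0.
h2_variance_ratio <- function(h, s, r) {
  h <- pmin(h, 0.99)
  if (r == 1) return(h / (1 - h))
  rho <- (h * s * (r - 1) / ((1 - h) * (s - 1)) - 1) / r
  pmax(rho, 0)
}

## expectation floor of the SS-ratio heritability estimator for a design
h2_design_floor <- function(s, r) (s - 1) / (s * r - 1)

#' Simulate transcript and peptide measurements from a genetic ground truth
#'
#' Each feature's strain-level value is the sum of its QTL effects (on
#' standardized genotypes), a polygenic/biological strain component, all
#' scaled so that the heritability target is met, plus replicate-level
#' technical noise. The strain/replicate variance ratio is calibrated so that
#' the one-way-ANOVA heritability estimator recovers the target in
#' expectation under the replicate design (for single-measurement designs the
#' target is the strain-level fraction of total variance). Transcripts
#' receive `n_bio_replicates_transcript` replicate columns per strain;
#' peptides receive one biological sample per strain plus technical-replicate
#' runs of the first (reference) strain, and missing values injected at
#' `missing_rate_peptide`. Values are zero-centered per feature.
#'
#' @param geno a [geno_matrix()].
#' @param ann an [annotation_set()] (used only for feature/gene bookkeeping).
#' @param truth a [sim_truth()].
#' @param cfg a [sim_config()].
#' @return list with elements `transcripts` (pheno_matrix with replicates),
#'   `peptides` (pheno_matrix, one column per strain), `tech_reps` (matrix
#'   peptides x technical runs, attribute `strain` naming the reference
#'   strain).
#' @export
simulate_molecular_data <- function(geno, ann, truth, cfg) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(truth, "sim_truth"),
            inherits(cfg, "sim_config"))
  unknown <- setdiff(truth$effects$snp_id, geno$snp_ids)
  if (length(unknown))
    stop("truth references unknown SNP(s): ", paste(unknown[1:min(3, length(unknown))],
                                                    collapse = ", "))
  set.seed(stage_seed(cfg$seed, "molecular"))
  n <- nrow(geno$calls)
  strains <- geno$strain_ids
  Gstd <- standardize_genotypes(geno$calls)
  s_t <- cfg$tech_noise_sd

  strain_signal <- function(ids, h2, r_design) {
    S <- matrix(0, length(ids), n, dimnames = list(ids, strains))
    for (i in seq_along(ids)) {
      fid <- ids[i]
      ef <- truth$effects[truth$effects$feature_id == fid, , drop = FALSE]
      sigma_s2 <- h2_variance_ratio(h2[i], n, r_design) * s_t^2
      qtl <- rep(0, n); fsum <- 0
      if (nrow(ef)) {
        X <- Gstd[, ef$snp_id, drop = FALSE]
        qtl_raw <- as.vector(X %*% sqrt(ef$frac))
        if (stats::sd(qtl_raw) > 0) {
          fsum <- min(sum(ef$frac), 1)
          qtl <- (qtl_raw - mean(qtl_raw)) / stats::sd(qtl_raw) * sqrt(fsum)
        }
      }
      v <- stats::rnorm(n)
      if (fsum > 0) v <- stats::residuals(stats::lm(v ~ qtl))
      v <- (v - mean(v)) / stats::sd(v)
      S[i, ] <- sqrt(sigma_s2) * (qtl + sqrt(max(0, 1 - fsum)) * v)
    }
    S
  }

  tf <- truth$features
  tr <- tf[tf$kind == "transcript", , drop = FALSE]
  pp <- tf[tf$kind == "peptide", , drop = FALSE]

  transcripts <- NULL
  if (nrow(tr)) {
    r <- cfg$n_bio_replicates_transcript
    S <- strain_signal(tr$feature_id, tr$h2_target, r)
    reps <- matrix(stats::rnorm(nrow(S) * n * r, sd = s_t), nrow(S), n * r)
    Y <- S[, rep(seq_len(n), each = r), drop = FALSE] + reps
    colnames(Y) <- paste(rep(strains, each = r), rep(seq_len(r), n), sep = ":")
    Y <- Y - rowMeans(Y)
    transcripts <- pheno_matrix(Y, strain = rep(strains, each = r),
                                replicate = rep(seq_len(r), n),
                                kind = "transcript")
  }

  peptides <- NULL; tech <- NULL
  if (nrow(pp)) {
    S <- strain_signal(pp$feature_id, pp$h2_target, 1L)
    Y <- S + matrix(stats::rnorm(nrow(S) * n, sd = s_t), nrow(S), n)
    colnames(Y) <- strains
    ref <- strains[1L]
    nt <- cfg$n_tech_replicates_peptide
    tech <- S[, rep(1L, nt), drop = FALSE] +
      matrix(stats::rnorm(nrow(S) * nt, sd = s_t), nrow(S), nt)
    colnames(tech) <- sprintf("%s_run%02d", ref, seq_len(nt))
    if (cfg$missing_rate_peptide > 0) {
      drop <- matrix(stats::runif(length(Y)) < cfg$missing_rate_peptide,
                     nrow(Y), ncol(Y))
      ## keep at least 3 observed values per peptide so variances exist
      keep_n <- rowSums(!drop)
      for (i in which(keep_n < 3)) drop[i, sample.int(n, 3)] <- FALSE
      Y[drop] <- NA_real_
    }
    mu <- rowMeans(Y, na.rm = TRUE)
    Y <- Y - mu
    tech <- tech - mu
    attr(tech, "strain") <- ref
    peptides <- pheno_matrix(Y, strain = strains, kind = "peptide")
  }

  list(transcripts = transcripts, peptides = peptides, tech_reps = tech)
}

#' Simulate clinical traits driven by molecular phenotypes
#'
#' Each trait is a linear combination of the strain means of its driver
#' features plus independent strain-level noise.
#'
#' @param molecular list with `transcripts` and/or `peptides` pheno matrices
#'   (as returned by [simulate_molecular_data()]), or a single pheno_matrix.
#' @param truth a [sim_truth()] carrying the trait drivers.
#' @param cfg a [sim_config()].
#' @param noise_sd standard deviation of the trait noise (default 1).
#' @return A `pheno_matrix` of kind "trait", traits x strains.
#' @export
simulate_traits <- function(molecular, truth, cfg, noise_sd = 1) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  if (inherits(molecular, "pheno_matrix")) molecular <- list(molecular)
  mats <- lapply(Filter(Negate(is.null),
                        molecular[intersect(names(molecular),
                                            c("transcripts", "peptides"))]),
                 strain_means)
  if (!length(mats))
    mats <- lapply(Filter(function(m) inherits(m, "pheno_matrix"), molecular),
                   strain_means)
  M <- do.call(rbind, mats)
  unknown <- setdiff(truth$drivers$feature_id, rownames(M))
  if (length(unknown))
    stop("trait driver references unknown feature(s): ",
         paste(unknown[1:min(3, length(unknown))], collapse = ", "))
  set.seed(stage_seed(cfg$seed, "traits"))
  strains <- colnames(M)
  trait_ids <- unique(truth$drivers$trait_id)
  Y <- matrix(0, length(trait_ids), length(strains),
              dimnames = list(trait_ids, strains))
  for (t in seq_along(trait_ids)) {
    d <- truth$drivers[truth$drivers$trait_id == trait_ids[t], , drop = FALSE]
    sig <- colSums(d$coef * M[d$feature_id, , drop = FALSE], na.rm = TRUE)
    Y[t, ] <- sig + stats::rnorm(length(strains), sd = noise_sd)
  }
  pheno_matrix(Y, strain = strains, kind = "trait")
}

#' Simulate a complete synthetic panel
#'
#' Convenience wrapper chaining genotypes, annotations, truth, molecular data
#' and traits with the per-stage child seeds of `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param ... passed to [simulate_annotations()].
#' @return list(geno, ann, truth, transcripts, peptides, tech_reps, traits).
#' @export
simulate_panel <- function(cfg, ...) {
  geno <- simulate_genotypes(cfg)
  ann <- simulate_annotations(cfg, ...)
  truth <- simulate_truth(geno, ann, cfg)
  mol <- simulate_molecular_data(geno, ann, truth, cfg)
  traits <- simulate_traits(mol, truth, cfg)
  list(geno = geno, ann = ann, truth = truth,
       transcripts = mol$transcripts, peptides = mol$peptides,
       tech_reps = mol$tech_reps, traits = traits)
}

## center genotype columns by allele frequency and scale to unit variance;
## missing calls are mean-imputed first
standardize_genotypes <- function(calls) {
  X <- calls
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  X[is.nan(X)] <- 0
  X
}
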