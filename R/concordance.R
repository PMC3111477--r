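#' Biweight midcorrelation
#'
#' Robust correlation using median/MAD-based weights with tuning constant 9:
#' for each variable, `u_i = (x_i - median(x)) / (9 * mad(x))` with the raw
#' (consistency-constant 1) median absolute deviation, weights
#' `w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]`, and the correlation is the inner
#' product of the weighted deviations normalized by the two weighted norms.
#' A variable whose MAD is zero falls back to Pearson-style mean/no-weight
#' deviations. Missing values are removed pairwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in [-1, 1].
#' @export
bicor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  ax <- bicor_deviations(x)
  ay <- bicor_deviations(y)
  nx <- sqrt(sum(ax^2)); ny <- sqrt(sum(ay^2))
  if (nx == 0 && ny == 0) stop("undefined correlation: both variables have zero variance")
  if (nx == 0 || ny == 0) stop("undefined correlation: a variable has zero variance")
  r <- sum(ax * ay) / (nx * ny)
  min(1, max(-1, r))
}

## weighted deviations of the biweight midcovariance; Pearson fallback at MAD 0
bicor_deviations <- function(x) {
  med <- stats::median(x)
  madx <- stats::median(abs(x - med))        # raw MAD, consistency constant 1
  if (madx == 0) return(x - mean(x))
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Two-sided p-value for a correlation coefficient
#'
#' Student-t transform: `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Correlations of exactly +/-1 give p = 0.
#'
#' @param r correlation in [-1, 1].
#' @param n number of complete pairs (>= 3).
#' @return Two-sided p-value.
#' @export
cor_test <- function(r, n) {
  if (any(n < 3)) stop("n must be at least 3")
  if (any(abs(r) > 1)) stop("r must lie in [-1, 1]")
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2,
                            lower.tail = FALSE))
  pmin(p, 1)
}

## bicor + t-test p on two strain-mean vectors, pairwise complete
bicor_record <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(list(n = n, r = NA_real_, p = NA_real_))
  r <- bicor(x[ok], y[ok])
  list(n = n, r = r, p = cor_test(r, n))
}

#' Gene-level peptide x probeset correlation pairs
#'
#' For every gene with at least one peptide and one probeset among the
#' supplied (filtered) matrices, emits the full peptide x probeset cross
#' product with biweight midcorrelations over strain means.
#'
#' @param peptides a `pheno_matrix` of kind "peptide".
#' @param transcripts a `pheno_matrix` of kind "transcript".
#' @param ann an `annotation_set`; only features mapping uniquely to a gene
#'   are paired.
#' @return data.frame (gene_id, peptide_id, probeset_id, n, r, p), one row
#'   per pair.
#' @export
build_gene_pairs <- function(peptides, transcripts, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  Mp <- strain_means(peptides)
  Mt <- strain_means(transcripts)
  shared <- intersect(colnames(Mp), colnames(Mt))
  if (length(shared) < 3) stop("fewer than 3 shared strains")
  Mp <- Mp[, shared, drop = FALSE]; Mt <- Mt[, shared, drop = FALSE]
  pg <- unique_gene_map(ann$peptide_genes, "peptide_id")
  tg <- unique_gene_map(ann$probeset_genes, "probeset_id")
  pg <- pg[pg$peptide_id %in% rownames(Mp), ]
  tg <- tg[tg$probeset_id %in% rownames(Mt), ]
  genes <- intersect(pg$gene_id, tg$gene_id)
  out <- lapply(genes, function(g) {
    peps <- pg$peptide_id[pg$gene_id == g]
    pss <- tg$probeset_id[tg$gene_id == g]
    grid <- expand.grid(peptide_id = peps, probeset_id = pss,
                        stringsAsFactors = FALSE)
    rec <- mapply(function(a, b) bicor_record(Mp[a, ], Mt[b, ]),
                  grid$peptide_id, grid$probeset_id, SIMPLIFY = FALSE)
    data.frame(gene_id = g, grid,
               n = vapply(rec, `[[`, 0, "n"),
               r = vapply(rec, `[[`, 0, "r"),
               p = vapply(rec, `[[`, 0, "p"))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), peptide_id = character(0),
                      probeset_id = character(0), n = integer(0),
                      r = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}

## features mapping to exactly one gene
unique_gene_map <- function(df, id_col) {
  tab <- table(df[[id_col]])
  df[df[[id_col]] %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Median transcript-protein correlation by peptide signal-to-noise stratum
#'
#' Pairs are binned by the percentile rank (or raw value) of their peptide's
#' signal-to-noise ratio, and the median correlation is reported per stratum.
#'
#' @param pairs data.frame from [build_gene_pairs()].
#' @param snr data.frame from [signal_to_noise()].
#' @param strata_edges increasing bin edges; with `mode = "percentile"` these
#'   are percentile cut points in [0, 100] (default quartiles).
#' @param mode bin by SNR "percentile" rank (default) or raw "value".
#' @return data.frame (stratum, lower, upper, n_pairs, median_r); empty
#'   strata carry NA medians.
#' @export
snr_strata_summary <- function(pairs, snr, strata_edges = c(0, 25, 50, 75, 100),
                               mode = c("percentile", "value")) {
  mode <- match.arg(mode)
  missing_snr <- setdiff(pairs$peptide_id, snr$peptide_id)
  if (length(missing_snr))
    stop("peptide(s) in pairs without an SNR: ",
         paste(utils::head(missing_snr, 3), collapse = ", "))
  s <- snr$snr[match(pairs$peptide_id, snr$peptide_id)]
  if (mode == "percentile") {
    pct <- 100 * rank(snr$snr, ties.method = "average") / nrow(snr)
    s <- pct[match(pairs$peptide_id, snr$peptide_id)]
  }
  bin <- cut(s, breaks = strata_edges, include.lowest = TRUE, right = TRUE)
  med <- tapply(pairs$r, bin, stats::median, na.rm = TRUE)
  cnt <- tapply(pairs$r, bin, length)
  data.frame(stratum = levels(bin),
             lower = strata_edges[-length(strata_edges)],
             upper = strata_edges[-1],
             n_pairs = ifelse(is.na(cnt[levels(bin)]), 0L, cnt[levels(bin)]),
             median_r = as.numeric(med[levels(bin)]), row.names = NULL)
}

#' Compare trait correlations of two molecular datasets at matched FDR
#'
#' Computes all feature x trait biweight midcorrelations for both datasets
#' over shared strains, converts p-values to Storey q-values separately per
#' dataset, and at each FDR level builds gene-level trait-relation sets (a
#' gene relates to a trait iff any of its features passes) and counts
#' relations shared between the datasets and unique to each.
#'
#' @param features_a,features_b `pheno_matrix` objects (e.g. peptides and
#'   transcripts); dataset a is reported as "protein"-style, b as
#'   "transcript"-style, but any two datasets can be compared.
#' @param traits a `pheno_matrix` of kind "trait".
#' @param ann an `annotation_set` for the gene-level rollup.
#' @param fdr_levels FDR thresholds (default 0.05, 0.01, 0.001).
#' @return list with `cor_a`, `cor_b` (long data.frames feature_id, trait_id,
#'   n, r, p, q) and `summary`, one row per FDR level: significant pair
#'   counts, features with >= 1 significant trait, gene-level shared and
#'   unique relation counts, genes with >= 1 relation.
#' @export
trait_correlation_compare <- function(features_a, features_b, traits, ann,
                                      fdr_levels = c(0.05, 0.01, 0.001)) {
  Ma <- strain_means(features_a); Mb <- strain_means(features_b)
  Mt <- strain_means(traits)
  shared <- Reduce(intersect, list(colnames(Ma), colnames(Mb), colnames(Mt)))
  if (length(shared) < 3) stop("no shared strain set across the matrices")
  corr_tab <- function(M) {
    M <- M[, shared, drop = FALSE]
    grid <- expand.grid(feature_id = rownames(M), trait_id = rownames(Mt),
                        stringsAsFactors = FALSE)
    rec <- mapply(function(f, t) bicor_record(M[f, ], Mt[t, shared]),
                  grid$feature_id, grid$trait_id, SIMPLIFY = FALSE)
    grid$n <- vapply(rec, `[[`, 0, "n")
    grid$r <- vapply(rec, `[[`, 0, "r")
    grid$p <- vapply(rec, `[[`, 0, "p")
    grid$q <- qvalues(grid$p)
    grid
  }
  ca <- corr_tab(Ma); cb <- corr_tab(Mb)
  gene_of <- function(ids) {
    maps <- rbind(stats::setNames(ann$peptide_genes, c("id", "gene_id")),
                  stats::setNames(ann$probeset_genes, c("id", "gene_id")))
    maps <- maps[!duplicated(maps$id), ]
    maps$gene_id[match(ids, maps$id)]
  }
  summ <- do.call(rbind, lapply(fdr_levels, function(a) {
    sa <- ca[!is.na(ca$q) & ca$q < a, ]
    sb <- cb[!is.na(cb$q) & cb$q < a, ]
    rel_a <- unique(data.frame(gene_id = gene_of(sa$feature_id),
                               trait_id = sa$trait_id))
    rel_b <- unique(data.frame(gene_id = gene_of(sb$feature_id),
                               trait_id = sb$trait_id))
    key <- function(d) paste(d$gene_id, d$trait_id)
    shared_n <- length(intersect(key(rel_a), key(rel_b)))
    data.frame(fdr = a,
               sig_pairs_a = nrow(sa), sig_pairs_b = nrow(sb),
               features_with_hit_a = length(unique(sa$feature_id)),
               features_with_hit_b = length(unique(sb$feature_id)),
               gene_relations_a = nrow(rel_a), gene_relations_b = nrow(rel_b),
               shared_relations = shared_n,
               unique_to_a = nrow(rel_a) - shared_n,
               unique_to_b = nrow(rel_b) - shared_n,
               genes_with_hit_a = length(unique(rel_a$gene_id)),
               genes_with_hit_b = length(unique(rel_b$gene_id)))
  }))
  list(cor_a = ca, cor_b = cb, summary = summ)
}

#' Bootstrap group-concordance test on a pool of correlation p-values
#'
#' For each group, the observed statistic is the mean correlation p-value of
#' its members. The null distribution is built from `n_boot` equal-size
#' subsets drawn randomly and without replacement from the whole pool, and
#' the empirical two-tailed p-value is
#' `(2 * min(#\{null <= obs\}, #\{null >= obs\}) + 1) / (n_boot + 1)`, capped
#' at 1. Direction is "concordant" when the observed mean p lies below the
#' null median (the group correlates better than chance).
#'
#' @param pool named numeric vector of correlation p-values (names are member
#'   ids, e.g. gene ids).
#' @param groups list of character vectors (term -> member ids), or a
#'   data.frame with columns term_id and a member id column matching names
#'   of `pool`.
#' @param n_boot number of bootstrap draws (default 100000).
#' @param seed RNG seed for reproducibility.
#' @param exact enumerate every subset of the pool instead of sampling
#'   (only sensible for tiny pools; replaces the n_boot draws).
#' @return data.frame (term_id, n_members, mean_p, empirical_p, direction).
#' @export
go_bootstrap_test <- function(pool, groups, n_boot = 100000, seed = 1L,
                              exact = FALSE) {
  stopifnot(!is.null(names(pool)))
  if (is.data.frame(groups)) {
    idc <- setdiff(names(groups), "term_id")[1]
    groups <- split(groups[[idc]], groups$term_id)
  }
  set.seed(seed)
  out <- lapply(names(groups), function(term) {
    if (length(unique(groups[[term]])) > length(pool))
      stop(sprintf("group '%s' larger than the p-value pool", term))
    members <- intersect(groups[[term]], names(pool))
    m <- length(members)
    if (m < 2) return(NULL)
    obs <- mean(pool[members])
    if (exact) {
      null <- utils::combn(pool, m, mean)
      n_boot <- length(null)
    } else {
      null <- vapply(seq_len(n_boot),
                     function(i) mean(pool[sample.int(length(pool), m)]),
                     numeric(1))
    }
    lo <- sum(null <= obs); hi <- sum(null >= obs)
    p <- min(1, (2 * min(lo, hi) + 1) / (n_boot + 1))
    data.frame(term_id = term, n_members = m, mean_p = obs, empirical_p = p,
               direction = if (obs < stats::median(null)) "concordant"
                           else "discordant")
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(term_id = character(0), n_members = integer(0),
                      mean_p = numeric(0), empirical_p = numeric(0),
                      direction = character(0))
  rownames(out) <- NULL
  out
}

#' Within- and cross-dataset pathway concordance
#'
#' For each pathway with at least two peptides and two probesets, reports the
#' mean pairwise Spearman correlation (over strain means) within peptides,
#' within probesets, and across the two sets.
#'
#' @param peptides,transcripts `pheno_matrix` objects.
#' @param ann an `annotation_set`; pathway terms are the groups with
#'   namespace "pathway" unless `namespace` says otherwise.
#' @param namespace which group namespace to use (default "pathway").
#' @param min_features minimum peptides and probesets per pathway (default 2).
#' @return list with `summary` (term_id, n_peptides, n_probesets,
#'   mean_r_protein, mean_r_transcript, mean_r_cross) and `skipped`
#'   (underpopulated terms).
#' @export
pathway_concordance <- function(peptides, transcripts, ann,
                                namespace = "pathway", min_features = 2) {
  Mp <- strain_means(peptides); Mt <- strain_means(transcripts)
  shared <- intersect(colnames(Mp), colnames(Mt))
  Mp <- Mp[, shared, drop = FALSE]; Mt <- Mt[, shared, drop = FALSE]
  pg <- ann$peptide_genes[ann$peptide_genes$peptide_id %in% rownames(Mp), ]
  tg <- ann$probeset_genes[ann$probeset_genes$probeset_id %in% rownames(Mt), ]
  grp <- ann$groups[ann$groups$namespace == namespace, ]
  terms <- unique(grp$term_id)
  mean_offdiag <- function(C) mean(C[upper.tri(C)], na.rm = TRUE)
  res <- list(); skipped <- character(0)
  for (term in terms) {
    genes <- grp$gene_id[grp$term_id == term]
    peps <- unique(pg$peptide_id[pg$gene_id %in% genes])
    pss <- unique(tg$probeset_id[tg$gene_id %in% genes])
    if (length(peps) < min_features || length(pss) < min_features) {
      skipped <- c(skipped, term)
      next
    }
    Cp <- stats::cor(t(Mp[peps, , drop = FALSE]), method = "spearman",
                     use = "pairwise.complete.obs")
    Ct <- stats::cor(t(Mt[pss, , drop = FALSE]), method = "spearman",
                     use = "pairwise.complete.obs")
    Cx <- stats::cor(t(Mp[peps, , drop = FALSE]), t(Mt[pss, , drop = FALSE]),
                     method = "spearman", use = "pairwise.complete.obs")
    res[[length(res) + 1L]] <-
      data.frame(term_id = term, n_peptides = length(peps),
                 n_probesets = length(pss),
                 mean_r_protein = mean_offdiag(Cp),
                 mean_r_transcript = mean_offdiag(Ct),
                 mean_r_cross = mean(Cx, na.rm = TRUE))
  }
  summary <- do.call(rbind, res)
  if (is.null(summary))
    summary <- data.frame(term_id = character(0), n_peptides = integer(0),
                          n_probesets = integer(0), mean_r_protein = numeric(0),
                          mean_r_transcript = numeric(0),
                          mean_r_cross = numeric(0))
  list(summary = summary, skipped = skipped)
}

#' Within-gene versus within-isoform-cluster peptide concordance
#'
#' Peptides assigned to more than one isoform cluster are excluded. Genes
#' (resp. clusters) with at least two remaining peptides contribute their
#' pairwise biweight midcorrelations; the function returns the average over
#' all within-gene pairs and over all within-cluster pairs, for comparison.
#'
#' @param peptides a `pheno_matrix` of kind "peptide".
#' @param ann an `annotation_set` with peptide isoform memberships.
#' @return list with `gene_mean`, `cluster_mean`, and per-gene / per-cluster
#'   data.frames (id, n_peptides, mean_r).
#' @export
isoform_cluster_concordance <- function(peptides, ann) {
  M <- strain_means(peptides)
  iso <- ann$peptide_isoforms[ann$peptide_isoforms$peptide_id %in% rownames(M), ]
  multi <- names(which(table(iso$peptide_id) > 1))
  iso <- iso[!iso$peptide_id %in% multi, ]
  pg <- ann$peptide_genes[!duplicated(ann$peptide_genes$peptide_id), ]
  iso$gene_id <- pg$gene_id[match(iso$peptide_id, pg$peptide_id)]

  pair_mean <- function(ids) {
    prs <- utils::combn(ids, 2)
    mean(apply(prs, 2, function(pr) {
      rec <- bicor_record(M[pr[1], ], M[pr[2], ])
      rec$r
    }), na.rm = TRUE)
  }
  level_summary <- function(key) {
    grps <- split(iso$peptide_id, iso[[key]])
    grps <- grps[vapply(grps, length, 0L) >= 2]
    if (!length(grps))
      return(data.frame(id = character(0), n_peptides = integer(0),
                        mean_r = numeric(0)))
    data.frame(id = names(grps),
               n_peptides = vapply(grps, length, 0L),
               mean_r = vapply(grps, pair_mean, numeric(1)), row.names = NULL)
  }
  per_gene <- level_summary("gene_id")
  per_cluster <- level_summary("isoform_id")
  wmean <- function(d) {
    np <- choose(d$n_peptides, 2)
    if (!nrow(d)) return(NA_real_)
    sum(d$mean_r * np) / sum(np)       # average over all pairs
  }
  list(gene_mean = wmean(per_gene), cluster_mean = wmean(per_cluster),
       per_gene = per_gene, per_cluster = per_cluster)
}
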