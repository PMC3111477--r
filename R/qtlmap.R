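#' Haplotype blocks from adjacent-SNP linkage disequilibrium
#'
#' Greedy left-to-right scan within each chromosome: a block is extended
#' while the next SNP's genotype r-squared with the previous SNP is strictly
#' above `r2_cut` (a "continuous stretch" of correlated SNPs); otherwise a
#' new block starts.
#'
#' @param geno a `geno_matrix` (SNPs sorted by position within chromosome).
#' @param r2_cut adjacency threshold (default 0.5, strict: r2 > 0.5 extends).
#' @return list with `blocks` (data.frame chrom, first_snp, last_snp,
#'   first_pos, last_pos, n_snps, length_bp) and `summary`
#'   (mean/median/max block length in bp).
#' @export
haplotype_blocks <- function(geno, r2_cut = 0.5) {
  stopifnot(inherits(geno, "geno_matrix"))
  G <- standardize_raw(geno$calls)
  blocks <- list()
  for (ch in unique(geno$chrom)) {
    idx <- which(geno$chrom == ch)
    if (any(diff(geno$pos_bp[idx]) <= 0))
      stop("positions not sorted on chromosome ", ch)
    m <- length(idx)
    if (m == 1) {
      adj <- logical(0)
    } else {
      x <- G[, idx, drop = FALSE]
      r <- vapply(seq_len(m - 1), function(j)
        suppressWarnings(stats::cor(x[, j], x[, j + 1])), numeric(1))
      r[is.na(r)] <- 0
      adj <- r^2 > r2_cut
    }
    start <- idx[c(1L, which(!adj) + 1L)]
    end <- idx[c(which(!adj), m)]
    blocks[[ch]] <- data.frame(
      chrom = ch,
      first_snp = geno$snp_ids[start], last_snp = geno$snp_ids[end],
      first_pos = geno$pos_bp[start], last_pos = geno$pos_bp[end],
      n_snps = end - start + 1L,
      length_bp = geno$pos_bp[end] - geno$pos_bp[start] + 1)
  }
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL
  list(blocks = blocks,
       summary = c(mean_bp = mean(blocks$length_bp),
                   median_bp = stats::median(blocks$length_bp),
                   max_bp = max(blocks$length_bp),
                   n_blocks = nrow(blocks)))
}

#' Classify peak associations as local or distant QTLs
#'
#' A QTL is local when its peak SNP lies on the gene's chromosome within the
#' window reaching `flank_bp` beyond the transcription start and termination
#' sites (inclusive boundaries; 2 Mb on either side gives the 4 Mb rule);
#' otherwise it is distant.
#'
#' @param records peak association data.frame (phenotype_id, snp_id, chrom,
#'   pos_bp, p, and optionally q).
#' @param ann an `annotation_set` mapping phenotypes to genes.
#' @param flank_bp flanking distance (default 2e6).
#' @param dataset label recorded on each call ("transcript" or "protein").
#' @return data.frame of QTL calls: phenotype_id, gene_id, snp_id, chrom,
#'   pos_bp, p (and q if present), locality, dataset.
#' @export
classify_qtl <- function(records, ann, flank_bp = 2e6,
                         dataset = c("transcript", "protein")) {
  dataset <- match.arg(dataset)
  stopifnot(inherits(ann, "annotation_set"))
  maps <- rbind(stats::setNames(ann$probeset_genes, c("id", "gene_id")),
                stats::setNames(ann$peptide_genes, c("id", "gene_id")))
  maps <- maps[!duplicated(maps$id), ]
  gene_id <- maps$gene_id[match(records$phenotype_id, maps$id)]
  if (anyNA(gene_id))
    stop("phenotype(s) without gene annotation: ",
         paste(utils::head(unique(records$phenotype_id[is.na(gene_id)]), 3),
               collapse = ", "))
  g <- ann$genes[match(gene_id, ann$genes$gene_id), ]
  lo <- pmin(g$tss_bp, g$tes_bp) - flank_bp
  hi <- pmax(g$tss_bp, g$tes_bp) + flank_bp
  local <- records$chrom == g$chrom & records$pos_bp >= lo & records$pos_bp <= hi
  out <- data.frame(phenotype_id = records$phenotype_id, gene_id = gene_id,
                    snp_id = records$snp_id, chrom = records$chrom,
                    pos_bp = records$pos_bp, p = records$p)
  if ("q" %in% names(records)) out$q <- records$q
  out$locality <- ifelse(local, "local", "distant")
  out$dataset <- dataset
  out
}

#' Sliding-window QTL hotspot profile
#'
#' The genome is divided into windows of `window_bp` slid every `step_bp`;
#' within each window the QTL calls of each dataset are counted (peak
#' positions, half-open [start, end) windows so a call is never counted
#' twice by adjacent non-overlapping windows) and expressed as a fraction of
#' that dataset's total calls.
#'
#' @param calls QTL call data.frame from [classify_qtl()] (datasets may be
#'   mixed; they are counted separately via the `dataset` column).
#' @param window_bp window length (default 2e6).
#' @param step_bp slide step (default 5e4).
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the maximum call position per chromosome.
#' @return data.frame (chrom, start_bp, end_bp, one count and one fraction
#'   column per dataset).
#' @export
hotspot_scan <- function(calls, window_bp = 2e6, step_bp = 5e4,
                         chrom_lengths = NULL) {
  datasets <- unique(calls$dataset)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(calls$pos_bp, calls$chrom, max)
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, max(1, len), by = step_bp)
    ends <- pmin(starts + window_bp, len + 1)   # half-open [start, end)
    w <- data.frame(chrom = ch, start_bp = starts, end_bp = ends)
    for (ds in datasets) {
      pos <- calls$pos_bp[calls$chrom == ch & calls$dataset == ds]
      cnt <- vapply(seq_along(starts), function(i)
        sum(pos >= starts[i] & pos < ends[i]), integer(1))
      total <- sum(calls$dataset == ds)
      w[[paste0("n_", ds)]] <- cnt
      w[[paste0("frac_", ds)]] <- if (total > 0) cnt / total else 0
    }
    out[[ch]] <- w
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Overlap between eQTL and pQTL calls
#'
#' Local QTLs are matched within genes: a local eQTL and local pQTL of the
#' same gene are shared when their peak SNPs map within `match_bp` of each
#' other. Distant QTLs are matched across datasets on the same chromosome by
#' peak distance at most `match_bp`. Matching is one-to-one, nearest pair
#' first. Shared pairs whose peak SNP is identical are counted separately,
#' and peak-to-peak distances reported for the rest.
#'
#' @param eqtls,pqtls QTL call data.frames from [classify_qtl()].
#' @param match_bp matching distance (default 2e6, inclusive).
#' @return list with counts (`shared_local`, `same_peak_local`,
#'   `shared_distant`, `same_peak_distant`, per-dataset totals) and the
#'   matched pair tables with distances.
#' @export
overlap_analysis <- function(eqtls, pqtls, match_bp = 2e6) {
  match_calls <- function(a, b, same_gene) {
    if (!nrow(a) || !nrow(b)) return(NULL)
    cand <- merge(
      cbind(a[, c("gene_id", "snp_id", "chrom", "pos_bp")], .ia = seq_len(nrow(a))),
      cbind(b[, c("gene_id", "snp_id", "chrom", "pos_bp")], .ib = seq_len(nrow(b))),
      by = if (same_gene) c("gene_id", "chrom") else "chrom",
      suffixes = c("_a", "_b"))
    if (!nrow(cand)) return(NULL)
    cand$dist <- abs(cand$pos_bp_a - cand$pos_bp_b)
    cand <- cand[cand$dist <= match_bp, , drop = FALSE]
    cand <- cand[order(cand$dist), , drop = FALSE]
    used_a <- used_b <- logical(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!cand$.ia[i] %in% used_a && !cand$.ib[i] %in% used_b) {
        keep[i] <- TRUE
        used_a <- c(used_a, cand$.ia[i])
        used_b <- c(used_b, cand$.ib[i])
      }
    }
    cand[keep, , drop = FALSE]
  }
  e_loc <- eqtls[eqtls$locality == "local", , drop = FALSE]
  p_loc <- pqtls[pqtls$locality == "local", , drop = FALSE]
  e_dis <- eqtls[eqtls$locality == "distant", , drop = FALSE]
  p_dis <- pqtls[pqtls$locality == "distant", , drop = FALSE]
  m_loc <- match_calls(e_loc, p_loc, same_gene = TRUE)
  m_dis <- match_calls(e_dis, p_dis, same_gene = FALSE)
  same_peak <- function(m) if (is.null(m)) 0L else
    sum(m$snp_id_a == m$snp_id_b)
  nshared <- function(m) if (is.null(m)) 0L else nrow(m)
  list(shared_local = nshared(m_loc), same_peak_local = same_peak(m_loc),
       shared_distant = nshared(m_dis), same_peak_distant = same_peak(m_dis),
       n_local_eqtl = nrow(e_loc), n_local_pqtl = nrow(p_loc),
       n_distant_eqtl = nrow(e_dis), n_distant_pqtl = nrow(p_dis),
       matched_local = m_loc, matched_distant = m_dis)
}

#' Per-dataset QTL bookkeeping summary
#'
#' For each dataset tag in the calls: total significant associations,
#' phenotypes with at least one association, local and distant association
#' counts, and phenotypes with more than one association.
#'
#' @param calls QTL call data.frame from [classify_qtl()].
#' @return data.frame, one row per dataset.
#' @export
summarize_counts <- function(calls) {
  if (!nrow(calls))
    return(data.frame(dataset = character(0), total_associations = integer(0),
                      phenotypes_with_hit = integer(0), n_local = integer(0),
                      n_distant = integer(0),
                      phenotypes_with_multiple = integer(0)))
  do.call(rbind, lapply(split(calls, calls$dataset), function(d) {
    per_ph <- table(d$phenotype_id)
    data.frame(dataset = d$dataset[1L],
               total_associations = nrow(d),
               phenotypes_with_hit = length(per_ph),
               n_local = sum(d$locality == "local"),
               n_distant = sum(d$locality == "distant"),
               phenotypes_with_multiple = sum(per_ph > 1),
               row.names = NULL)
  }))
}
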