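test_that("bicor handles exact linear relationships and bad input", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(bicor(x, 2 * x + 3), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  expect_error(bicor(1:2, 2:3), "fewer than 3")
  expect_error(bicor(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("bicor matches a direct evaluation of the biweight formula", {
  set.seed(3)
  x <- stats::rnorm(20); y <- x + stats::rnorm(20, sd = 0.3)
  y[7] <- 25   # one gross outlier
  # independent implementation straight from the definition
  dev <- function(v) {
    med <- stats::median(v)
    u <- (v - med) / (9 * stats::median(abs(v - med)))
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  ax <- dev(x); ay <- dev(y)
  want <- sum(ax * ay) / sqrt(sum(ax^2) * sum(ay^2))
  expect_equal(bicor(x, y), want, tolerance = 1e-12)
  # more robust than Pearson against the outlier
  expect_gt(bicor(x, y), stats::cor(x, y))
})

test_that("bicor is invariant under positive affine transforms", {
  set.seed(6)
  for (i in 1:20) {
    x <- stats::rnorm(30); y <- stats::rnorm(30)
    expect_equal(bicor(3 * x + 1, y), bicor(x, y), tolerance = 1e-12)
    expect_equal(bicor(x, 0.2 * y - 5), bicor(x, y), tolerance = 1e-12)
    expect_lte(abs(bicor(x, y)), 1)
  }
})

test_that("bicor approximates Pearson on clean Gaussian data", {
  set.seed(12)
  diffs <- replicate(20, {
    x <- stats::rnorm(200); y <- 0.5 * x + stats::rnorm(200)
    abs(bicor(x, y) - stats::cor(x, y))
  })
  expect_lt(mean(diffs), 0.02)
  expect_lt(max(diffs), 0.05)
  # both variables MAD-zero: exact Pearson fallback
  x <- c(rep(0, 15), 1, 2, 3)
  y <- c(rep(5, 15), stats::rnorm(3))
  expect_equal(bicor(x, y), stats::cor(x, y), tolerance = 1e-12)
})

test_that("cor_test applies the Student-t transform", {
  expect_equal(cor_test(0, 30), 1)
  expect_equal(cor_test(1, 10), 0)
  # magnitude anchor: r about 0.46 at n = 97 sits at the 1e-6 level
  p <- cor_test(0.46, 97)
  expect_lt(p, 5e-6); expect_gt(p, 1e-7)
  expect_lt(cor_test(0.47, 97), 1.5e-6)
  # oracle: direct t CDF evaluation
  r <- 0.5; n <- 10
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(cor_test(r, n), 2 * stats::pt(t, n - 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(cor_test(0.5, 2), "at least 3")
})

test_that("build_gene_pairs emits the full per-gene cross product", {
  set.seed(21)
  strains <- sprintf("s%02d", 1:30)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                      tss_bp = c(1e6, 5e6), tes_bp = c(1.2e6, 5.2e6),
                      strand = "+")
  ann <- annotation_set(
    genes = genes,
    probeset_genes = data.frame(probeset_id = c("t1", "t2"), gene_id = "gA"),
    peptides = data.frame(peptide_id = c("p1", "p2", "p3", "p4"),
                          sequence = rep("AAAK", 4)),
    peptide_genes = data.frame(peptide_id = c("p1", "p2", "p3", "p4"),
                               gene_id = c("gA", "gA", "gA", "gB")))
  pep <- make_pheno(matrix(stats::rnorm(4 * 30), 4, 30,
                           dimnames = list(c("p1", "p2", "p3", "p4"), strains)))
  tra <- make_pheno(matrix(stats::rnorm(2 * 30), 2, 30,
                           dimnames = list(c("t1", "t2"), strains)),
                    kind = "transcript")
  pairs <- build_gene_pairs(pep, tra, ann)
  # gene gA: 3 peptides x 2 probesets = 6 pairs; gB has no probeset
  expect_identical(nrow(pairs), 6L)
  expect_false("gB" %in% pairs$gene_id)
  expect_setequal(unique(pairs$peptide_id), c("p1", "p2", "p3"))
  # pair count equals the brute-force sum over genes
  expect_identical(nrow(pairs), sum(3L * 2L))
  expect_true(all(pairs$n == 30))
})

test_that("snr_strata_summary bins pairs and reports medians", {
  pairs <- data.frame(gene_id = "g", peptide_id = c("a", "b", "c", "d"),
                      probeset_id = "t", n = 20,
                      r = c(0.1, 0.2, 0.6, 0.8), p = 0.5)
  snr <- data.frame(peptide_id = c("a", "b", "c", "d"),
                    var_population = 1, var_technical = 1,
                    snr = c(1, 2, 5, 10), pass = TRUE)
  # one stratum covering everything: median = global median
  one <- snr_strata_summary(pairs, snr, strata_edges = c(0, 100))
  expect_equal(one$median_r, stats::median(pairs$r))
  # two strata by hand: low {a, b}, high {c, d}
  two <- snr_strata_summary(pairs, snr, strata_edges = c(0, 50, 100))
  expect_equal(two$median_r, c(0.15, 0.7))
  # raw value mode, empty stratum reported as NA
  val <- snr_strata_summary(pairs, snr, strata_edges = c(0, 3, 20, 50),
                            mode = "value")
  expect_equal(val$median_r, c(0.15, 0.7, NA))
  expect_identical(val$n_pairs, c(2L, 2L, 0L))
  expect_error(snr_strata_summary(pairs, snr[1:3, ]), "without an SNR")
})

test_that("trait_correlation_compare counts shared and unique relations", {
  set.seed(31)
  strains <- sprintf("s%02d", 1:40)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                      tss_bp = c(1e6, 2e6), tes_bp = c(1.1e6, 2.1e6), strand = "+")
  ann <- annotation_set(
    genes = genes,
    probeset_genes = data.frame(probeset_id = c("t1", "t2"),
                                gene_id = c("g1", "g2")),
    peptides = data.frame(peptide_id = c("p1", "p2"), sequence = "AAAK"),
    peptide_genes = data.frame(peptide_id = c("p1", "p2"),
                               gene_id = c("g1", "g2")))
  base <- matrix(stats::rnorm(2 * 40), 2, 40,
                 dimnames = list(c("t1", "t2"), strains))
  tra <- make_pheno(base, kind = "transcript")
  # identical datasets (renamed to the peptide ids): everything shared
  pepvals <- base; rownames(pepvals) <- c("p1", "p2")
  pep <- make_pheno(pepvals)
  drv <- matrix(base[1, ] * 2 + stats::rnorm(40, sd = 0.1), 1, 40,
                dimnames = list("tr1", strains))
  traits <- make_pheno(drv, kind = "trait")
  res <- trait_correlation_compare(pep, tra, traits, ann, fdr_levels = 0.05)
  s <- res$summary
  expect_identical(s$unique_to_a, 0L)
  expect_identical(s$unique_to_b, 0L)
  expect_identical(s$shared_relations, s$gene_relations_a)
  expect_gt(s$shared_relations, 0)
  # planted toy: trait follows t1/g1 only in dataset b
  pep0 <- make_pheno(matrix(stats::rnorm(2 * 40), 2, 40,
                            dimnames = list(c("p1", "p2"), strains)))
  res2 <- trait_correlation_compare(pep0, tra, traits, ann, fdr_levels = 0.05)
  s2 <- res2$summary
  expect_identical(s2$shared_relations, 0L)
  expect_gte(s2$gene_relations_b, 1L)
  expect_identical(s2$unique_to_b, s2$gene_relations_b)
  # disjoint strain sets error
  tra2 <- tra; tra2$strain <- paste0("x", tra2$strain)
  colnames(tra2$values) <- tra2$strain
  expect_error(trait_correlation_compare(pep, tra2, traits, ann),
               "shared strain")
})

test_that("go_bootstrap_test matches exhaustive enumeration on a tiny pool", {
  pool <- c(a = 0.01, b = 0.2, c = 0.5, d = 0.7, e = 0.9)
  groups <- list(low = c("a", "b"), mid = c("b", "c"), all = names(pool))
  got <- go_bootstrap_test(pool, groups, exact = TRUE)
  # independent enumeration of all C(5, 2) = 10 subsets
  for (term in c("low", "mid")) {
    obs <- mean(pool[groups[[term]]])
    nulls <- utils::combn(pool, 2, mean)
    p_want <- min(1, (2 * min(sum(nulls <= obs), sum(nulls >= obs)) + 1) /
                    (length(nulls) + 1))
    expect_equal(got$empirical_p[got$term_id == term], p_want)
  }
  # the whole pool has a degenerate null: empirical p = 1
  expect_equal(got$empirical_p[got$term_id == "all"], 1)
  # direction: the low group is concordant (small mean p)
  expect_identical(got$direction[got$term_id == "low"], "concordant")
  # fixed seed reproducibility of the sampling path
  r1 <- go_bootstrap_test(pool, groups["low"], n_boot = 500, seed = 9)
  r2 <- go_bootstrap_test(pool, groups["low"], n_boot = 500, seed = 9)
  expect_identical(r1, r2)
  expect_error(go_bootstrap_test(pool[1:3], list(g = c("a", "b", "c", "d"))),
               "larger than the p-value pool")
})

test_that("pathway_concordance equals brute-force pairwise enumeration", {
  set.seed(41)
  strains <- sprintf("s%02d", 1:25)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "1",
                      tss_bp = 1:3 * 1e6, tes_bp = 1:3 * 1e6 + 1e5, strand = "+")
  groups <- data.frame(term_id = "path1", namespace = "pathway",
                       gene_id = c("g1", "g2", "g3"))
  ann <- annotation_set(
    genes = genes,
    probeset_genes = data.frame(probeset_id = c("t1", "t2"),
                                gene_id = c("g1", "g2")),
    peptides = data.frame(peptide_id = c("p1", "p2", "p3"), sequence = "AAAK"),
    peptide_genes = data.frame(peptide_id = c("p1", "p2", "p3"),
                               gene_id = c("g1", "g2", "g3")),
    groups = groups)
  Mp <- matrix(stats::rnorm(3 * 25), 3, 25,
               dimnames = list(c("p1", "p2", "p3"), strains))
  Mt <- matrix(stats::rnorm(2 * 25), 2, 25,
               dimnames = list(c("t1", "t2"), strains))
  res <- pathway_concordance(make_pheno(Mp), make_pheno(Mt, kind = "transcript"),
                             ann)
  s <- res$summary
  within_p <- mean(c(stats::cor(Mp[1, ], Mp[2, ], method = "spearman"),
                     stats::cor(Mp[1, ], Mp[3, ], method = "spearman"),
                     stats::cor(Mp[2, ], Mp[3, ], method = "spearman")))
  within_t <- stats::cor(Mt[1, ], Mt[2, ], method = "spearman")
  cross <- mean(outer(1:3, 1:2, Vectorize(function(i, j)
    stats::cor(Mp[i, ], Mt[j, ], method = "spearman"))))
  expect_equal(s$mean_r_protein, within_p, tolerance = 1e-12)
  expect_equal(s$mean_r_transcript, within_t, tolerance = 1e-12)
  expect_equal(s$mean_r_cross, cross, tolerance = 1e-12)
  # copies of one vector: all three means are 1
  v <- stats::rnorm(25)
  Mp2 <- rbind(p1 = v, p2 = v, p3 = v); colnames(Mp2) <- strains
  Mt2 <- rbind(t1 = v, t2 = v); colnames(Mt2) <- strains
  res2 <- pathway_concordance(make_pheno(Mp2),
                              make_pheno(Mt2, kind = "transcript"), ann)
  expect_equal(unlist(res2$summary[, c("mean_r_protein", "mean_r_transcript",
                                       "mean_r_cross")]),
               c(mean_r_protein = 1, mean_r_transcript = 1, mean_r_cross = 1))
  # underpopulated pathway skipped with a log entry
  ann2 <- ann
  ann2$groups <- data.frame(term_id = "tiny", namespace = "pathway",
                            gene_id = "g3")
  res3 <- pathway_concordance(make_pheno(Mp), make_pheno(Mt, kind = "transcript"),
                              ann2)
  expect_identical(res3$skipped, "tiny")
  expect_identical(nrow(res3$summary), 0L)
})

test_that("independent noise features give near-zero pathway means", {
  set.seed(51)
  strains <- sprintf("s%03d", 1:100)
  genes <- data.frame(gene_id = sprintf("g%d", 1:12), chrom = "1",
                      tss_bp = 1:12 * 1e6, tes_bp = 1:12 * 1e6 + 1e5, strand = "+")
  ann <- annotation_set(
    genes = genes,
    probeset_genes = data.frame(probeset_id = sprintf("t%d", 1:12),
                                gene_id = genes$gene_id),
    peptides = data.frame(peptide_id = sprintf("p%d", 1:12), sequence = "AAAK"),
    peptide_genes = data.frame(peptide_id = sprintf("p%d", 1:12),
                               gene_id = genes$gene_id),
    groups = data.frame(term_id = "path", namespace = "pathway",
                        gene_id = genes$gene_id))
  Mp <- matrix(stats::rnorm(12 * 100), 12, 100,
               dimnames = list(sprintf("p%d", 1:12), strains))
  Mt <- matrix(stats::rnorm(12 * 100), 12, 100,
               dimnames = list(sprintf("t%d", 1:12), strains))
  s <- pathway_concordance(make_pheno(Mp), make_pheno(Mt, kind = "transcript"),
                           ann)$summary
  expect_lt(abs(s$mean_r_protein), 0.05)
  expect_lt(abs(s$mean_r_transcript), 0.05)
  expect_lt(abs(s$mean_r_cross), 0.05)
})

test_that("isoform clustering separates planted within-cluster structure", {
  set.seed(61)
  strains <- sprintf("s%02d", 1:50)
  n_per <- 4
  sigA <- stats::rnorm(50); sigB <- stats::rnorm(50)  # two isoform programs
  mk <- function(sig, ids) {
    m <- t(sapply(seq_len(n_per), function(i) sig + stats::rnorm(50, sd = 0.4)))
    rownames(m) <- ids; colnames(m) <- strains; m
  }
  ids_a <- sprintf("pa%d", 1:n_per); ids_b <- sprintf("pb%d", 1:n_per)
  vals <- rbind(mk(sigA, ids_a), mk(sigB, ids_b))
  genes <- data.frame(gene_id = "g", chrom = "1", tss_bp = 1e6, tes_bp = 1.2e6,
                      strand = "+")
  ann <- annotation_set(
    genes = genes,
    peptides = data.frame(peptide_id = c(ids_a, ids_b), sequence = "AAAK"),
    peptide_genes = data.frame(peptide_id = c(ids_a, ids_b), gene_id = "g"),
    peptide_isoforms = data.frame(peptide_id = c(ids_a, ids_b),
                                  isoform_id = rep(c("g.iso1", "g.iso2"),
                                                   each = n_per)))
  res <- isoform_cluster_concordance(make_pheno(vals), ann)
  expect_gt(res$cluster_mean, res$gene_mean)
  # all peptides of a gene in one cluster: the two averages coincide
  ann1 <- ann
  ann1$peptide_isoforms$isoform_id <- "g.iso1"
  res1 <- isoform_cluster_concordance(make_pheno(vals), ann1)
  expect_equal(res1$cluster_mean, res1$gene_mean, tolerance = 1e-12)
  # peptides matching two clusters are excluded; singleton clusters ignored
  ann2 <- ann
  ann2$peptide_isoforms <- rbind(ann2$peptide_isoforms,
                                 data.frame(peptide_id = "pa1",
                                            isoform_id = "g.iso2"))
  res2 <- isoform_cluster_concordance(make_pheno(vals), ann2)
  expect_identical(sum(res2$per_cluster$n_peptides), 7L)
})
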