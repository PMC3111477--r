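test_that("log2_center transforms and centers feature rows", {
  X <- matrix(c(1, 2, 4, 8, 8, 8), 2, 3, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  out <- log2_center(make_pheno(X), log2_transform = TRUE)
  expect_equal(unname(out$values["f1", ]), c(-1, 0, 1))
  expect_equal(unname(out$values["f2", ]), c(0, 0, 0))
  # idempotence on already-centered log input
  again <- log2_center(out)
  expect_equal(again$values, out$values)
  # a missing value: mean over remaining entries is zero
  X2 <- matrix(c(3, NA, 7), 1, 3, dimnames = list("f", c("a", "b", "c")))
  cen <- log2_center(make_pheno(X2))
  expect_equal(unname(cen$values[1, ]), c(-2, NA, 2))
  expect_equal(mean(cen$values[1, ], na.rm = TRUE), 0)
  # non-positive value with log requested names the feature
  X3 <- matrix(c(1, -1), 1, 2, dimnames = list("badfeat", c("a", "b")))
  expect_error(log2_center(make_pheno(X3), log2_transform = TRUE), "badfeat")
})

test_that("peptide_basic_filter applies the three rules with strict boundaries", {
  n <- 100
  strains <- sprintf("s%03d", 1:n)
  vals <- matrix(stats::rnorm(4 * n), 4, n,
                 dimnames = list(c("ok", "intk", "m49", "m51"), strains))
  vals["m49", 1:49] <- NA   # 49% missing: keep
  vals["m51", 1:51] <- NA   # 51% missing: reject
  ann <- one_gene_ann(peptide_ids = c("ok", "intk", "m49", "m51"),
                      sequences = c("AGLMNR", "AGKLMR", "AGLMNK", "AGLMNR"))
  res <- peptide_basic_filter(make_pheno(vals), ann)
  expect_setequal(res$retained, c("ok", "m49"))
  expect_true("intk" %in% res$log$peptide_id[res$log$rule == "internal_kr"])
  expect_true("m51" %in% res$log$peptide_id[res$log$rule == "missingness"])
})

test_that("peptide_basic_filter matches brute-force rule evaluation", {
  set.seed(5)
  cfg <- tiny_cfg(n_peptides = 300, missing_rate_peptide = 0.3, seed = 77)
  p <- simulate_panel(cfg)
  ann <- simulate_annotations(cfg, frac_internal_kr = 0.3,
                              frac_multi_gene_peptide = 0.2)
  res <- peptide_basic_filter(p$peptides, ann)
  # independent per-rule re-check
  ids <- rownames(p$peptides$values)
  expected <- character(0)
  for (id in ids) {
    s <- ann$peptides$sequence[ann$peptides$peptide_id == id]
    miss <- mean(is.na(p$peptides$values[id, ]))
    ng <- sum(ann$peptide_genes$peptide_id == id)
    inner <- substr(s, 1, nchar(s) - 1)
    if (miss < 0.5 && !grepl("K", inner) && !grepl("R", inner) && ng == 1)
      expected <- c(expected, id)
  }
  expect_setequal(res$retained, expected)
})

test_that("peptides without sequences are an error", {
  vals <- matrix(stats::rnorm(3), 1, 3,
                 dimnames = list("mystery", c("a", "b", "c")))
  ann <- one_gene_ann(peptide_ids = "other", sequences = "AAAK")
  expect_error(peptide_basic_filter(make_pheno(vals), ann), "without sequence")
})

test_that("signal_to_noise computes the variance ratio with edge handling", {
  strains <- sprintf("s%d", 1:11)
  pop <- matrix(stats::rnorm(3 * 11), 3, 11,
                dimnames = list(c("a", "b", "c"), strains))
  tech <- matrix(stats::rnorm(3 * 10, sd = 0.1), 3, 10,
                 dimnames = list(c("a", "b", "c"), NULL))
  # engineer exact variances through scaling
  pop["a", ] <- scale(pop["a", ]) * sqrt(0.4)   # var 0.4
  tech["a", ] <- scale(tech["a", ]) * sqrt(0.1) # var 0.1 -> S = 4
  pop["b", ] <- scale(pop["b", ]) * sqrt(0.3)
  tech["b", ] <- scale(tech["b", ]) * sqrt(0.3) # S = 1, fail at cutoff 2
  tech["c", ] <- 0                              # zero technical variance
  snr <- signal_to_noise(make_pheno(pop), tech)
  expect_equal(snr$snr[snr$peptide_id == "a"], 4, tolerance = 1e-12)
  expect_true(snr$pass[snr$peptide_id == "a"])
  expect_equal(snr$snr[snr$peptide_id == "b"], 1, tolerance = 1e-12)
  expect_false(snr$pass[snr$peptide_id == "b"])
  expect_identical(snr$snr[snr$peptide_id == "c"], Inf)
  expect_true(snr$pass[snr$peptide_id == "c"])
  # scale invariance: multiplying a peptide by c leaves S unchanged
  pop2 <- pop * 3.7; tech2 <- tech * 3.7
  snr2 <- signal_to_noise(make_pheno(pop2), tech2)
  expect_equal(snr2$snr[1:2], snr$snr[1:2], tolerance = 1e-10)
  # peptide absent from the technical replicates
  expect_error(signal_to_noise(make_pheno(pop), tech[1:2, ]), "absent")
})

test_that("heritability_anova matches an independent one-way ANOVA", {
  set.seed(11)
  strains <- rep(c("A", "B", "C"), each = 3)
  y <- c(1.2, 1.1, 1.4, 2.0, 2.2, 1.9, 0.6, 0.8, 0.5)
  vals <- matrix(y, 1, 9, dimnames = list("f", sprintf("c%d", 1:9)))
  her <- heritability_anova(make_pheno(vals, strain = strains,
                                       replicate = rep(1:3, 3)))
  fit <- stats::aov(y ~ factor(strains))
  tab <- summary(fit)[[1]]
  expect_equal(her$h2, tab["factor(strains)", "Sum Sq"] / sum(tab[, "Sum Sq"]),
               tolerance = 1e-10)
  expect_equal(her$p_strain, tab["factor(strains)", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(her$f_stat, tab["factor(strains)", "F value"], tolerance = 1e-10)
})

test_that("heritability handles degenerate and unbalanced designs", {
  # identical replicates within strain, different means across -> h2 = 1
  vals <- matrix(c(1, 1, 2, 2, 3, 3), 1, 6,
                 dimnames = list("f", sprintf("c%d", 1:6)))
  her <- heritability_anova(make_pheno(vals, strain = rep(c("A", "B", "C"), each = 2)))
  expect_equal(her$h2, 1)
  expect_equal(her$p_strain, 0)
  # all-identical values -> h2 = 0, p = 1
  flat <- matrix(5, 1, 6, dimnames = list("f", sprintf("c%d", 1:6)))
  her2 <- heritability_anova(make_pheno(flat, strain = rep(c("A", "B", "C"), each = 2)))
  expect_equal(her2$h2, 0); expect_equal(her2$p_strain, 1)
  # unbalanced design agrees with aov
  set.seed(2)
  strains <- c("A", "A", "A", "B", "B", "C")
  y <- stats::rnorm(6) + rep(c(0, 1, 2), c(3, 2, 1))
  vals3 <- matrix(y, 1, 6, dimnames = list("f", sprintf("c%d", 1:6)))
  her3 <- heritability_anova(make_pheno(vals3, strain = strains))
  tab <- summary(stats::aov(y ~ factor(strains)))[[1]]
  expect_equal(her3$p_strain, tab["factor(strains)", "Pr(>F)"], tolerance = 1e-10)
  # affine invariance of h2 and additivity of sums of squares
  her4 <- heritability_anova(make_pheno(vals3 * 7 - 3, strain = strains))
  expect_equal(her4$h2, her3$h2, tolerance = 1e-10)
  # fewer than 2 strains observed -> error
  one <- matrix(1:3, 1, 3, dimnames = list("f", c("a", "b", "c")))
  expect_error(heritability_anova(make_pheno(one, strain = rep("A", 3))),
               "fewer than 2 strains")
})

test_that("filter_transcripts combines heritability, annotation, and forcing", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "1",
                      tss_bp = c(1e6, 2e6, 3e6), tes_bp = c(1.1e6, 2.1e6, 3.1e6),
                      strand = "+")
  ann <- annotation_set(
    genes = genes,
    probeset_genes = data.frame(
      probeset_id = c("p1", "p2", "p3", "p4", "p4"),
      gene_id = c("gA", "gA", "gB", "gB", "gC")),  # p4 ambiguous
    peptides = data.frame(peptide_id = "pep1", sequence = "AAAK"),
    peptide_genes = data.frame(peptide_id = "pep1", gene_id = "gB"))
  her <- data.frame(feature_id = c("p1", "p2", "p3", "p4"),
                    p_strain = c(0.049, 0.051, 0.5, 0.001))
  kept <- filter_transcripts(her, ann, peptide_ids = "pep1")
  # p1 passes p<0.05; p2 fails (0.051, gene without peptide); p3 forced via gB;
  # p4 significant but ambiguous
  expect_setequal(kept, c("p1", "p3"))
  # brute-force set algebra on a random table
  set.seed(8)
  her2 <- data.frame(feature_id = c("p1", "p2", "p3", "p4"),
                     p_strain = stats::runif(4))
  kept2 <- filter_transcripts(her2, ann, peptide_ids = character(0))
  uniq <- c("p1", "p2", "p3")
  expect_setequal(kept2, intersect(her2$feature_id[her2$p_strain < 0.05], uniq))
})

test_that("mask_probes flags SNP-containing probes with inclusive bounds", {
  genes <- data.frame(gene_id = "g", chrom = "1", tss_bp = 1, tes_bp = 1e6,
                      strand = "+")
  mk_probes <- function(starts, id = "ps1")
    data.frame(probeset_id = id, chrom = "1", start_bp = starts,
               end_bp = starts + 24)
  ann <- annotation_set(genes = genes,
                        probeset_genes = data.frame(probeset_id = "ps1",
                                                    gene_id = "g"),
                        probes = mk_probes(100))
  hit <- mask_probes(ann, "1", 124)$probes$masked
  miss <- mask_probes(ann, "1", 125)$probes$masked
  at_start <- mask_probes(ann, "1", 100)$probes$masked
  expect_true(hit); expect_false(miss); expect_true(at_start)
  # 8-of-11 exclusion boundary
  starts <- seq(1000, by = 100, length.out = 11)
  ann2 <- annotation_set(genes = genes,
                         probeset_genes = data.frame(probeset_id = "ps1",
                                                     gene_id = "g"),
                         probes = mk_probes(starts))
  res8 <- mask_probes(ann2, rep("1", 8), starts[1:8] + 5)
  res7 <- mask_probes(ann2, rep("1", 7), starts[1:7] + 5)
  expect_identical(res8$excluded_probesets, "ps1")
  expect_identical(res7$excluded_probesets, character(0))
  # unknown chromosome errors
  expect_error(mask_probes(ann2, "2", 1000), "unknown chromosome")
})

test_that("mask_probes equals a brute-force interval scan on random layouts", {
  set.seed(9)
  genes <- data.frame(gene_id = "g", chrom = c("1"), tss_bp = 1, tes_bp = 1e5,
                      strand = "+")
  for (rep in 1:100) {
    nprobe <- sample(5:15, 1)
    starts <- sample.int(9e4, nprobe)
    probes <- data.frame(probeset_id = sprintf("ps%d", seq_len(nprobe) %% 3),
                         chrom = "1", start_bp = starts, end_bp = starts + 24)
    ann <- annotation_set(genes = genes,
                          probeset_genes = data.frame(
                            probeset_id = unique(probes$probeset_id),
                            gene_id = "g"),
                          probes = probes)
    snps <- sample.int(1e5, sample(3:40, 1))
    got <- mask_probes(ann, rep("1", length(snps)), snps)$probes$masked
    want <- vapply(seq_len(nprobe), function(i)
      any(snps >= probes$start_bp[i] & snps <= probes$end_bp[i]), logical(1))
    expect_identical(got, want)
  }
})

test_that("eigen_normalize removes a planted systematic trend", {
  set.seed(4)
  n_feat <- 60; n_samp <- 40
  trend <- stats::rnorm(n_samp)
  X <- matrix(stats::rnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("f%d", 1:n_feat), sprintf("s%d", 1:n_samp)))
  X <- X + outer(stats::runif(n_feat, 2, 4), trend)   # strong rank-1 batch trend
  ph <- make_pheno(X)
  out <- eigen_normalize(ph, 1)
  rs <- apply(out$values, 1, function(z) stats::cor(z, trend))
  expect_lt(max(abs(rs)), 0.05)
  # rows stay zero-mean
  expect_lt(max(abs(rowMeans(out$values))), 1e-10)
  # n_trends = 0 is the identity on centered data
  cen <- log2_center(ph)
  expect_equal(eigen_normalize(cen, 0)$values, cen$values, tolerance = 1e-12)
  # missing cells restored to missing
  X[3, 5] <- NA
  out2 <- eigen_normalize(make_pheno(X), 1)
  expect_true(is.na(out2$values[3, 5]))
  expect_error(eigen_normalize(ph, 40), "n_trends")
})
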