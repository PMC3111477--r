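#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the fraction of SNPs, non-missing in both strains, at which
#' strains i and j carry the same allele.
#'
#' @param geno a `geno_matrix`.
#' @return symmetric strains x strains matrix with unit diagonal.
#' @export
ibs_kinship <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  X <- geno$calls
  if (nrow(X) < 2) stop("at least 2 strains required")
  obs <- !is.na(X)
  X1 <- ifelse(obs, X, 0)          # carrier of allele 1
  X0 <- ifelse(obs, 1 - X, 0)      # carrier of allele 0
  matches <- X1 %*% t(X1) + X0 %*% t(X0)
  denom <- obs %*% t(obs)
  if (any(denom == 0))
    stop("strain pair(s) with zero jointly observed SNPs")
  K <- matches / denom
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' REML variance components for a kinship random effect
#'
#' Fits `y = X b + u + e` with `Var(u) = sigma_g^2 K`, `Var(e) = sigma_e^2 I`
#' by restricted maximum likelihood over the variance ratio
#' `delta = sigma_e^2 / sigma_g^2`, using the spectral decomposition of the
#' kinship projected off the fixed effects. The restricted likelihood is
#' profiled on a grid of 100 intervals in `ln(delta)` over [-10, 10]; each
#' sign change of its derivative is refined by root finding and the global
#' optimum returned.
#'
#' @param y numeric phenotype vector (complete).
#' @param K kinship matrix aligned to `y`.
#' @param X fixed-effect design matrix (default intercept only).
#' @return list of class `reml_fit`: sigma_g2, sigma_e2, delta, loglik, and
#'   the spectral pieces (lambda, etas, n, q) needed to re-evaluate the
#'   restricted likelihood.
#' @export
reml_fit <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (stats::var(y) == 0) stop("degenerate phenotype: y is constant")
  if (n < 10) stop("at least 10 strains required")
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    K <- K + diag(1e-6, n)
    ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8) stop("kinship matrix is not positive semidefinite")
  }
  q <- qr(X)$rank
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eig <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
  lambda <- eig$values[seq_len(n - q)] - 1
  lambda <- pmax(lambda, 0)                      # clip tiny negatives
  etas <- as.vector(crossprod(eig$vectors[, seq_len(n - q), drop = FALSE], y))

  ll <- function(delta) reml_loglik(delta, lambda, etas, n, q)
  dll <- function(delta) {
    num <- sum(etas^2 / (lambda + delta)^2)
    den <- sum(etas^2 / (lambda + delta))
    0.5 * ((n - q) * num / den - sum(1 / (lambda + delta)))
  }
  grid <- exp(seq(-10, 10, length.out = 101))
  dv <- vapply(grid, dll, numeric(1))
  cand <- c(grid[1], grid[length(grid)])
  for (i in seq_len(length(grid) - 1)) {
    if (dv[i] > 0 && dv[i + 1] < 0)
      cand <- c(cand, stats::uniroot(dll, c(grid[i], grid[i + 1]))$root)
  }
  lls <- vapply(cand, ll, numeric(1))
  delta <- cand[which.max(lls)]
  sigma_g2 <- sum(etas^2 / (lambda + delta)) / (n - q)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
                 delta = delta, loglik = max(lls), lambda = lambda,
                 etas = etas, n = n, q = q),
            class = "reml_fit")
}

#' Restricted log-likelihood profile for [reml_fit()]
#'
#' @param delta variance ratio sigma_e2/sigma_g2.
#' @param lambda,etas,n,q spectral pieces from a `reml_fit`.
#' @return restricted log-likelihood at `delta`.
#' @export
reml_loglik <- function(delta, lambda, etas, n, q) {
  0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 -
                      log(sum(etas^2 / (lambda + delta)))) -
           sum(log(lambda + delta)))
}

#' Mixed-model genome-wide association scan
#'
#' Tests every passing SNP against every phenotype under the linear mixed
#' model `y = mu + x beta + u + e`, `Var(u) = sigma_g^2 K`. Variance
#' components are estimated once per phenotype under the null (no SNP) and
#' reused across SNPs: phenotype and design are rotated by the eigensystem of
#' K, whitened with the fitted variance ratio, and an F-test of `beta = 0`
#' performed on the whitened data (denominator degrees of freedom
#' `n - 2`). SNPs are filtered on minor allele frequency and missingness;
#' missing genotypes are mean-imputed per SNP for testing. `method = "naive"`
#' runs the same scan by ordinary least squares without the kinship term, and
#' `per_snp_reml = TRUE` re-estimates the variance components under each
#' SNP's alternative model (exact, much slower).
#'
#' @param pheno a `pheno_matrix`; replicates are averaged to strain means.
#' @param geno a `geno_matrix`.
#' @param K kinship matrix (default: computed by [ibs_kinship()]).
#' @param maf_min minimum minor allele frequency (default 0.10, inclusive).
#' @param miss_max maximum per-SNP missing fraction (default 0.10, strict).
#' @param method "emma" (mixed model, default) or "naive" (no kinship).
#' @param per_snp_reml re-fit variance components for each SNP (default FALSE).
#' @param min_strains phenotypes observed in fewer strains are skipped with a
#'   log entry (default 10).
#' @param compute_q attach Storey q-values over all reported p (default TRUE).
#' @return data.frame (phenotype_id, snp_id, chrom, pos_bp, beta, f_stat, p,
#'   var_explained[, q]) with attributes `vc` (per-phenotype variance
#'   components) and `skipped` (phenotype ids not scanned).
#' @export
gwas_scan <- function(pheno, geno, K = NULL, maf_min = 0.10, miss_max = 0.10,
                      method = c("emma", "naive"), per_snp_reml = FALSE,
                      min_strains = 10, compute_q = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(pheno, "pheno_matrix"), inherits(geno, "geno_matrix"))
  M <- strain_means(pheno)
  strains <- intersect(geno$strain_ids, colnames(M))
  if (length(strains) < min_strains) stop("too few strains shared with genotypes")
  M <- M[, strains, drop = FALSE]
  calls <- geno$calls[strains, , drop = FALSE]
  if (is.null(K) && method == "emma")
    K <- ibs_kinship(geno)
  if (!is.null(K)) K <- K[strains, strains]

  freq <- colMeans(calls, na.rm = TRUE)
  maf <- pmin(freq, 1 - freq)
  missfrac <- colMeans(is.na(calls))
  keep <- which(maf >= maf_min & missfrac < miss_max)
  if (!length(keep)) stop("no SNPs pass the MAF/missingness filters")
  Ximp <- standardize_raw(calls[, keep, drop = FALSE])
  snp_ids <- geno$snp_ids[keep]
  snp_chrom <- geno$chrom[keep]
  snp_pos <- geno$pos_bp[keep]

  patterns <- apply(!is.na(M), 1, function(z) paste(which(z), collapse = ","))
  res <- vector("list", nrow(M))
  vc <- list()
  skipped <- character(0)
  for (pat in unique(patterns)) {
    rows <- which(patterns == pat)
    sub <- as.integer(strsplit(pat, ",")[[1]])
    ns <- length(sub)
    if (ns < min_strains) {
      skipped <- c(skipped, rownames(M)[rows])
      next
    }
    Xs <- Ximp[sub, , drop = FALSE]
    if (method == "emma") {
      Ks <- K[sub, sub]
      eigK <- eigen(Ks, symmetric = TRUE)
      d <- pmax(eigK$values, 0)
      UX <- crossprod(eigK$vectors, Xs)          # rotate SNPs once per pattern
      U1 <- as.vector(crossprod(eigK$vectors, rep(1, ns)))
    }
    xc <- sweep(Xs, 2, colMeans(Xs))
    sxx_raw <- colSums(xc^2)
    for (i in rows) {
      y <- M[i, sub]
      if (stats::var(y) == 0) {
        skipped <- c(skipped, rownames(M)[i])
        next
      }
      if (method == "emma") {
        fit <- reml_fit(y, Ks)
        vc[[length(vc) + 1L]] <-
          data.frame(phenotype_id = rownames(M)[i], delta = fit$delta,
                     sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2)
        if (per_snp_reml) {
          stat <- per_snp_scan(y, Xs, Ks)
        } else {
          w <- 1 / sqrt(d + fit$delta)
          wy <- as.vector(crossprod(eigK$vectors, y)) * w
          w1 <- U1 * w
          WX <- UX * w
          s11 <- sum(w1^2)
          ytil <- wy - w1 * (sum(w1 * wy) / s11)
          Xtil <- WX - outer(w1, colSums(w1 * WX) / s11)
          stat <- whitened_ftest(ytil, Xtil, ns)
        }
      } else {
        ytil <- y - mean(y)
        stat <- whitened_ftest(ytil, xc, ns)
      }
      ## variance explained on the original phenotype scale
      covxy <- colSums(xc * (y - mean(y))) / (ns - 1)
      vy <- stats::var(y)
      ve <- (2 * stat$beta * covxy - stat$beta^2 * sxx_raw / (ns - 1)) / vy
      ve <- pmin(pmax(ve, 0), 1)
      res[[i]] <- data.frame(phenotype_id = rownames(M)[i], snp_id = snp_ids,
                             chrom = snp_chrom, pos_bp = snp_pos,
                             beta = stat$beta, f_stat = stat$f, p = stat$p,
                             var_explained = ve)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no phenotype could be scanned")
  rownames(out) <- NULL
  if (compute_q) out$q <- qvalues(out$p)
  attr(out, "vc") <- if (length(vc)) do.call(rbind, vc) else NULL
  attr(out, "skipped") <- skipped
  out
}

## F-test of beta = 0 for each (already whitened and intercept-projected)
## SNP column against the phenotype vector
whitened_ftest <- function(ytil, Xtil, n) {
  sxx <- colSums(Xtil^2)
  sxy <- colSums(Xtil * ytil)
  syy <- sum(ytil^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- syy - ifelse(sxx > 0, sxy^2 / sxx, 0)
  df2 <- n - 2
  f <- ifelse(sxx > 0, (sxy^2 / sxx) / (rss / df2), NA_real_)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  p[!is.na(f) & rss <= 0] <- 0
  list(beta = beta, f = f, p = p)
}

## exact per-SNP REML: refit variance components under each alternative model
per_snp_scan <- function(y, Xs, Ks) {
  m <- ncol(Xs)
  beta <- f <- p <- numeric(m)
  n <- length(y)
  for (j in seq_len(m)) {
    X <- cbind(1, Xs[, j])
    if (stats::var(Xs[, j]) == 0) { beta[j] <- NA; f[j] <- NA; p[j] <- NA; next }
    fit <- reml_fit(y, Ks, X)
    eigK <- eigen(Ks, symmetric = TRUE)
    w <- 1 / sqrt(pmax(eigK$values, 0) + fit$delta)
    Wy <- as.vector(crossprod(eigK$vectors, y)) * w
    WX <- crossprod(eigK$vectors, X) * w
    qrW <- qr(WX)
    bh <- qr.coef(qrW, Wy)
    rss1 <- sum(qr.resid(qrW, Wy)^2)
    W1 <- WX[, 1, drop = FALSE]
    rss0 <- sum(qr.resid(qr(W1), Wy)^2)
    beta[j] <- bh[2]
    f[j] <- (rss0 - rss1) / (rss1 / (n - 2))
    p[j] <- stats::pf(f[j], 1, n - 2, lower.tail = FALSE)
  }
  list(beta = beta, f = f, p = p)
}

## mean-impute missing genotype calls, keep the raw 0/1 scale
standardize_raw <- function(calls) {
  if (anyNA(calls)) {
    mu <- colMeans(calls, na.rm = TRUE)
    idx <- which(is.na(calls), arr.ind = TRUE)
    calls[idx] <- mu[idx[, 2]]
  }
  calls
}

#' Variance explained by a fitted SNP effect
#'
#' One minus the ratio of the residual variance after the SNP fit to the
#' variance of the original phenotype, clamped to [0, 1].
#'
#' @param y phenotype vector.
#' @param x genotype vector (same strains).
#' @param beta fitted SNP effect.
#' @param mu fitted intercept; defaults to `mean(y - x * beta)`.
#' @return fraction of variance explained.
#' @export
variance_explained <- function(y, x, beta, mu = NULL) {
  if (is.null(mu)) mu <- mean(y - x * beta)
  resid <- y - mu - x * beta
  min(1, max(0, 1 - stats::var(resid) / stats::var(y)))
}

#' Storey q-values
#'
#' The proportion of true nulls `pi0` is estimated by the smoother method:
#' `pi0(lambda) = #\{p > lambda\} / (n (1 - lambda))` over
#' `lambda = 0, 0.05, ..., 0.90`, smoothed with a cubic smoothing spline
#' (df = 3) and read off at the largest lambda. Q-values are
#' `pi0 * n * p_(i) / i`, monotonized from the largest p downward. Setting
#' `pi0 = 1` reproduces Benjamini-Hochberg adjusted p-values exactly. For
#' very large inputs the average-FDR subsampling approximation is available:
#' q-values are computed on `n_samples` random subsets of size `size` and
#' averaged through interpolation on the sorted p scale.
#'
#' @param p p-values in (0, 1].
#' @param pi0 optional fixed null proportion; estimated when NULL.
#' @param subsample optional list(n_samples, size) switching on the
#'   subsampling approximation (set the RNG seed beforehand for
#'   reproducibility).
#' @return q-values in the order of `p`.
#' @export
qvalues <- function(p, pi0 = NULL, subsample = NULL) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  if (!is.null(subsample)) {
    n_samples <- subsample$n_samples %||% 100
    size <- subsample$size
    acc <- rep(0, length(p)); cnt <- 0
    for (s in seq_len(n_samples)) {
      idx <- sample.int(length(p), min(size, length(p)))
      ps <- p[idx]
      qs <- qvalues(ps, pi0 = pi0)
      o <- order(ps)
      fun <- stats::approxfun(ps[o], qs[o], method = "constant", f = 1,
                              rule = 2, ties = "ordered")
      acc <- acc + fun(p)
      cnt <- cnt + 1
    }
    return(pmin(acc / cnt, 1))
  }
  pv <- p[ok]
  n <- length(pv)
  if (is.null(pi0)) {
    lambda <- seq(0, 0.90, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(sp, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(pv)
  q_sorted <- pi0 * n * pv[o] / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prune significant associations in linkage disequilibrium
#'
#' Greedy per-phenotype pruning: the most significant unpruned SNP becomes a
#' peak, every other significant SNP whose genotype r-squared with the peak
#' is `r2_cut` or larger is pruned, and the process repeats. Ties in p-value
#' are broken toward the smaller genomic coordinate, making the result
#' independent of input order.
#'
#' @param records association data.frame (phenotype_id, snp_id, p, ...),
#'   already restricted to significant hits.
#' @param geno a `geno_matrix` providing the genotypes for r-squared.
#' @param r2_cut pruning threshold (default 0.5, inclusive: "0.5 or larger").
#' @return `records` with added logical columns `pruned` and `is_peak`.
#' @export
ld_prune <- function(records, geno, r2_cut = 0.5) {
  stopifnot(inherits(geno, "geno_matrix"))
  unknown <- setdiff(records$snp_id, geno$snp_ids)
  if (length(unknown))
    stop("SNP(s) missing from genotype matrix: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  G <- standardize_raw(geno$calls)
  chrom_of <- geno$chrom[match(records$snp_id, geno$snp_ids)]
  pos_of <- geno$pos_bp[match(records$snp_id, geno$snp_ids)]
  records$pruned <- FALSE
  records$is_peak <- FALSE
  for (ph in unique(records$phenotype_id)) {
    rows <- which(records$phenotype_id == ph)
    ord <- rows[order(records$p[rows], suppressWarnings(as.numeric(chrom_of[rows])),
                      chrom_of[rows], pos_of[rows])]
    remaining <- ord
    while (length(remaining)) {
      peak <- remaining[1L]
      records$is_peak[peak] <- TRUE
      remaining <- remaining[-1L]
      if (!length(remaining)) break
      x <- G[, records$snp_id[peak]]
      r2 <- suppressWarnings(
        stats::cor(x, G[, records$snp_id[remaining], drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      drop <- r2 >= r2_cut
      records$pruned[remaining[drop]] <- TRUE
      remaining <- remaining[!drop]
    }
  }
  records
}
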