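#' Genotype-based kinship (genomic relationship matrix)
#'
#' Standardized cross-product of genotype dosages, averaged over non-missing
#' SNPs: entry (i,j) is the mean over SNPs of
#' (x_i - 2p)(x_j - 2p) / (2p(1-p)). Under this scaling the expectation is
#' 0 for unrelated outbred pairs and ~1 for an outbred individual with
#' itself, so half the value is comparable to the pedigree kinship phi.
#'
#' @param genotypes dosage matrix, SNPs in rows, samples in columns, values
#'   0/1/2 or `NA`
#' @param freqs per-SNP frequency of the counted allele, in (0,1); SNPs with
#'   frequency 0 or 1 are excluded with a warning
#' @return a `KinshipMatrix` on the GRM scale (diagonal ~1)
#' @export
genomic_kinship <- function(genotypes, freqs) {
  stopifnot(nrow(genotypes) == length(freqs))
  mono <- freqs <= 0 | freqs >= 1 | is.na(freqs)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from genomic kinship")
    genotypes <- genotypes[!mono, , drop = FALSE]
    freqs <- freqs[!mono]
  }
  if (!nrow(genotypes)) stop("no polymorphic SNPs left")
  z <- (genotypes - 2 * freqs) / sqrt(2 * freqs * (1 - freqs))
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- crossprod(z)                 # sum over observed SNPs of z_i z_j
  den <- crossprod(obs * 1)           # number of jointly observed SNPs
  k <- num / pmax(den, 1)
  dimnames(k) <- list(colnames(genotypes), colnames(genotypes))
  class(k) <- c("KinshipMatrix", class(k))
  k
}

#' Method-of-moments pairwise IBD estimation
#'
#' PLINK-style moment estimator of the probabilities that a pair of
#' individuals shares 0, 1 or 2 alleles identical by descent, from
#' identity-by-state counts at independent SNPs with known allele
#' frequencies. Estimates are clipped to [0,1] and renormalized;
#' pi-hat = P(IBD=1)/2 + P(IBD=2).
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) for the two individuals
#' @param freqs per-SNP allele frequency of the counted allele
#' @param min_snps minimum jointly non-missing SNPs for a reliable estimate
#' @return list with `p0`, `p1`, `p2`, `pihat`, `n_snps`, and `reliable`
#'   (FALSE when fewer than `min_snps` SNPs informed the estimate)
#' @export
pairwise_ibd_moments <- function(g1, g2, freqs, min_snps = 200L) {
  stopifnot(length(g1) == length(g2), length(g1) == length(freqs))
  ok <- !is.na(g1) & !is.na(g2) & freqs > 0 & freqs < 1
  g1 <- g1[ok]; g2 <- g2[ok]; p <- freqs[ok]; q <- 1 - p
  n <- length(g1)
  ibs <- 2L - abs(g1 - g2)
  ibs[g1 == 1 & g2 == 1] <- 2L   # both het: IBS 2
  # expected IBS-class probabilities given IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e2_ibd1 <- p^3 + q^3 + p^2 * q + p * q^2
  n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
  p0 <- n0 / sum(e0_ibd0)
  p1 <- (n1 - p0 * sum(e1_ibd0)) / sum(e1_ibd1)
  p2 <- (n2 - p0 * sum(e2_ibd0) - p1 * sum(e2_ibd1)) / n
  pr <- pmin(pmax(c(p0, p1, p2), 0), 1)
  pr <- pr / sum(pr)
  list(p0 = pr[1], p1 = pr[2], p2 = pr[3],
       pihat = pr[2] / 2 + pr[3], n_snps = n,
       reliable = n >= min_snps)
}
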