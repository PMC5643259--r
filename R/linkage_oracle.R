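# Brute-force single-point parametric LOD by full joint enumeration.
#
# Independent of the HMM implementation: inheritance patterns at the marker
# and at the disease locus are enumerated explicitly (no founder-symmetry
# reduction, no message passing), founder allele assignments are summed
# directly, and the marker-disease coupling uses the Hamming distance
# between the two inheritance vectors. Intended as a testing oracle for
# small pedigrees only.

# Trace the founder-allele origin of one allele of individual i under a
# full inheritance vector (bit list), by plain recursion.
.bf_origin <- function(ped, bits, fa, mo, meiosis_of, fidx, i, side) {
  if (is.na(fa[i]))
    return(2L * fidx[i] - (if (side == 1L) 1L else 0L))
  k <- meiosis_of[i]
  b <- bits[2L * k - (if (side == 1L) 1L else 0L)]
  par <- if (side == 1L) fa[i] else mo[i]
  .bf_origin(ped, bits, fa, mo, meiosis_of, fidx, par,
             if (b) 2L else 1L)
}

#' Brute-force single-point parametric LOD (testing oracle)
#'
#' Computes the LOD score for linkage between a single biallelic marker and
#' the disease locus at recombination fraction `theta` by exhaustive
#' enumeration of the joint likelihood over all founder marker-allele
#' assignments, all founder disease-allele assignments, and all pairs of
#' inheritance patterns at the two loci. Unaffected individuals are coded
#' unknown (affected-only). Refuses pedigrees with more than `max_meioses`
#' meioses.
#'
#' @param ped a `Pedigree`
#' @param genotypes named dosage vector (0/1/2/NA) for the marker, names
#'   matching pedigree ids; absent ids are treated as untyped
#' @param model a `DiseaseModel`
#' @param theta recombination fraction between marker and disease locus
#' @param marker_freq population frequency of the counted marker allele
#' @param max_meioses enumeration refusal threshold (default 12)
#' @return the LOD score, log10 L(theta) / L(1/2)
#' @export
single_point_lod_bruteforce <- function(ped, genotypes, model, theta,
                                        marker_freq, max_meioses = 12L) {
  stopifnot(inherits(ped, "Pedigree"), theta >= 0, theta <= 0.5)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  founder <- is.na(fa)
  fidx <- cumsum(founder)
  f <- sum(founder)
  nonf <- which(!founder)
  m <- 2L * length(nonf)
  if (m > max_meioses)
    stop("refusing enumeration: ", m, " meioses > ", max_meioses)
  meiosis_of <- match(seq_len(nrow(ped)), nonf)
  S <- 2^m
  nA <- 2^(2 * f)
  assign_mat <- matrix(0L, nA, 2 * f)
  for (b in seq_len(2 * f))
    assign_mat[, b] <- bitwAnd(0:(nA - 1), bitwShiftL(1L, b - 1L)) > 0L
  ka <- rowSums(assign_mat)
  p <- marker_freq
  Wm <- p^ka * (1 - p)^(2 * f - ka)
  Wq <- model$q^ka * (1 - model$q)^(2 * f - ka)

  g_obs <- rep(NA_integer_, nrow(ped))
  g_obs[match(names(genotypes), ped$id)] <- as.integer(genotypes)
  typed <- which(!is.na(g_obs))
  affected <- which(ped$affection == "affected")

  PG <- numeric(S)   # P(marker genotypes | inheritance pattern)
  PF <- numeric(S)   # P(phenotypes | inheritance pattern)
  for (s in seq_len(S)) {
    bits <- as.logical(bitwAnd(s - 1L, bitwShiftL(1L, seq_len(max(m, 1)) - 1L)))
    okm <- rep(TRUE, nA)
    for (i in typed) {
      o1 <- .bf_origin(ped, bits, fa, mo, meiosis_of, fidx, i, 1L)
      o2 <- .bf_origin(ped, bits, fa, mo, meiosis_of, fidx, i, 2L)
      okm <- okm & (assign_mat[, o1] + assign_mat[, o2] == g_obs[i])
    }
    PG[s] <- sum(Wm[okm])
    wq <- Wq
    for (i in affected) {
      o1 <- .bf_origin(ped, bits, fa, mo, meiosis_of, fidx, i, 1L)
      o2 <- .bf_origin(ped, bits, fa, mo, meiosis_of, fidx, i, 2L)
      wq <- wq * model$f[assign_mat[, o1] + assign_mat[, o2] + 1L]
    }
    PF[s] <- sum(wq)
  }

  # popcount table for Hamming distances between inheritance vectors
  pc <- rowSums(vapply(seq_len(max(m, 1)), function(b)
    bitwAnd(0:(S - 1), bitwShiftL(1L, b - 1L)) > 0, logical(S)))
  if (m == 0) pc <- rep(0, S)
  lnum <- 0
  if (theta == 0) {
    lnum <- sum(PG * PF) / S
  } else {
    lw <- log(theta) * 0:m + log(1 - theta) * (m - 0:m)
    for (s in seq_len(S)) {
      d <- pc[bitwXor(s - 1L, 0:(S - 1)) + 1L]
      lnum <- lnum + PG[s] * sum(exp(lw[d + 1L]) * PF)
    }
    lnum <- lnum / S   # uniform prior on the marker-locus vector; the
                       # theta kernel is already normalized over vd
  }
  lden <- (sum(PG) / S) * (sum(PF) / S)
  log10(lnum / lden)
}
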