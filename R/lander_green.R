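# Lander-Green inheritance-vector HMM.
#
# States are full inheritance vectors: one bit per meiosis (2 per
# non-founder), bit 0 = the transmitting parent passed its own paternal
# allele, 1 = its maternal allele. The state space has 2^(2n) elements, so
# pedigrees must be split (split_pedigree) before inference when large.
# Emissions are computed by summing founder-allele assignments (founder
# haplotypes are i.i.d. draws at each marker); transitions factorize over
# meioses with per-bit recombination fraction theta (Haldane).

# Precompute the state machinery for a pedigree.
lg_setup <- function(ped, max_states = 2^16) {
  stopifnot(inherits(ped, "Pedigree"))
  n_ind <- nrow(ped)
  founder <- is_founder(ped)
  f <- sum(founder)
  nonf <- which(!founder)
  m <- 2L * length(nonf)
  if (m > 0 && 2^m > max_states)
    stop("inheritance-vector space 2^", m, " exceeds max_states; ",
         "split the pedigree first (split_pedigree)")
  S <- 2^m
  states <- 0:(S - 1)
  bit_of <- function(b) bitwAnd(states, bitwShiftL(1L, b - 1L)) > 0L
  # founder allele indices: founder j -> alleles 2j-1 ("A"), 2j ("B")
  fidx <- cumsum(founder)
  O_pat <- matrix(0L, S, n_ind)
  O_mat <- matrix(0L, S, n_ind)
  meiosis_of <- match(seq_len(n_ind), nonf)   # NA for founders
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  for (i in seq_len(n_ind)) {
    if (founder[i]) {
      O_pat[, i] <- 2L * fidx[i] - 1L
      O_mat[, i] <- 2L * fidx[i]
    } else {
      k <- meiosis_of[i]
      bp <- bit_of(2L * k - 1L)
      bm <- bit_of(2L * k)
      O_pat[, i] <- ifelse(bp, O_mat[, fa[i]], O_pat[, fa[i]])
      O_mat[, i] <- ifelse(bm, O_mat[, mo[i]], O_pat[, mo[i]])
    }
  }
  flips <- lapply(seq_len(m), function(b)
    bitwXor(states, bitwShiftL(1L, b - 1L)) + 1L)
  # founder-allele assignment matrix for emission sums
  nA <- 2^(2 * f)
  A <- matrix(0L, nA, 2 * f)
  for (b in seq_len(2 * f))
    A[, b] <- bitwAnd(0:(nA - 1), bitwShiftL(1L, b - 1L)) > 0L
  list(ped = ped, n_ind = n_ind, founder = founder, f = f, m = m, S = S,
       O_pat = O_pat, O_mat = O_mat, flips = flips, A = A,
       k_assign = rowSums(A))
}

# Apply the meiosis transition kernel (prob theta per-bit flip) to a vector
# indexed by states. Valid for sum-product messages.
lg_transmit <- function(v, theta, setup) {
  if (theta <= 0) return(v)
  for (b in seq_len(setup$m))
    v <- (1 - theta) * v + theta * v[setup$flips[[b]]]
  v
}

# Max-product analogue (for Viterbi); the per-bit kernel factorization also
# distributes over max.
lg_transmit_max <- function(v, theta, setup) {
  if (theta <= 0) return(v)
  for (b in seq_len(setup$m))
    v <- pmax((1 - theta) * v, theta * v[setup$flips[[b]]])
  v
}

# Marker emission matrix P(G_l | state): S x L. G is an L x n_ind dosage
# matrix aligned to setup$ped order; freqs is the per-marker frequency of
# the counted (alt) allele among founder haplotypes. founder_values
# optionally fixes founder-allele contents (2f x L, NA = free): used when a
# chunk founder's phased haplotypes are already known from another chunk.
lg_emissions <- function(setup, G, freqs, founder_values = NULL) {
  L <- nrow(G)
  stopifnot(ncol(G) == setup$n_ind, length(freqs) == L)
  p <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)
  W <- exp(outer(setup$k_assign, log(p)) +
             outer(2 * setup$f - setup$k_assign, log(1 - p)))   # nA x L
  if (!is.null(founder_values)) {
    for (k in which(rowSums(!is.na(founder_values)) > 0)) {
      kn <- which(!is.na(founder_values[k, ]))
      eq <- outer(setup$A[, k], founder_values[k, kn], "==")
      W[, kn] <- W[, kn] * eq
    }
  }
  gi <- which(colSums(!is.na(G)) > 0)
  E <- matrix(0, setup$S, L)
  if (!length(gi)) return(E + 1)
  # outer loop over founder-allele assignments: for a fixed assignment the
  # implied dosage of each individual is a cheap per-state lookup, and the
  # genotype match is one S x L comparison per individual
  nA <- nrow(setup$A)
  for (a in seq_len(nA)) {
    arow <- setup$A[a, ]
    M <- matrix(W[a, ], setup$S, L, byrow = TRUE)
    for (i in gi) {
      D <- arow[setup$O_pat[, i]] + arow[setup$O_mat[, i]]   # length S
      eq <- outer(D, G[, i], "==")
      eq[, is.na(G[, i])] <- TRUE
      M <- M * eq
      if (!any(M > 0)) break
    }
    E <- E + M
  }
  E
}

# Phenotype likelihood P(phenotypes | state) under a parametric disease
# model, affected-only by default (unaffected coded unknown).
lg_phenotype_lik <- function(setup, model, affected_only = TRUE) {
  ped <- setup$ped
  q <- model$q
  Wq <- q^setup$k_assign * (1 - q)^(2 * setup$f - setup$k_assign)
  pen <- matrix(1, setup$n_ind, 3)
  aff <- ped$affection == "affected"
  pen[aff, ] <- rep(model$f, each = sum(aff))
  if (!affected_only) {
    un <- ped$affection == "unaffected"
    pen[un, ] <- rep(1 - model$f, each = sum(un))
  }
  inform <- which(rowSums(pen != 1) > 0)
  P <- numeric(setup$S)
  for (a in seq_len(nrow(setup$A))) {
    arow <- setup$A[a, ]
    v <- rep(Wq[a], setup$S)
    for (i in inform) {
      D <- arow[setup$O_pat[, i]] + arow[setup$O_mat[, i]]
      v <- v * pen[i, ][D + 1L]
    }
    P <- P + v
  }
  P
}

# Scaled forward-backward over markers. thetas: length L-1 recombination
# fractions between adjacent markers. Returns scaled column-stochastic
# forward/backward matrices, per-column log-scales, and the data log-lik.
lg_forward_backward <- function(setup, E, thetas) {
  S <- setup$S; L <- ncol(E)
  Fm <- matrix(0, S, L); Bm <- matrix(0, S, L)
  cf <- numeric(L); cb <- numeric(L)
  v <- E[, 1] / S
  cf[1] <- log(sum(v)); Fm[, 1] <- v / sum(v)
  if (L > 1) for (l in 2:L) {
    v <- E[, l] * lg_transmit(Fm[, l - 1], thetas[l - 1], setup)
    cf[l] <- cf[l - 1] + log(sum(v))
    Fm[, l] <- v / sum(v)
  }
  Bm[, L] <- 1; cb[L] <- 0
  if (L > 1) for (l in (L - 1):1) {
    v <- lg_transmit(E[, l + 1] * Bm[, l + 1], thetas[l], setup)
    cb[l] <- cb[l + 1] + log(sum(v))
    Bm[, l] <- v / sum(v)
  }
  list(f = Fm, b = Bm, log_cf = cf, log_cb = cb, loglik = cf[L])
}

#' Affected-only parametric LOD curve by the Lander-Green algorithm
#'
#' Multipoint parametric linkage: a forward-backward HMM over inheritance
#' vectors with Haldane transitions between markers, evaluating at each
#' requested position the likelihood ratio of the disease locus being there
#' versus unlinked (theta = 1/2). Unaffected individuals are coded unknown
#' (affected-only analysis) unless `affected_only = FALSE`.
#'
#' @param ped a `Pedigree` (must be small enough: 2 bits per non-founder;
#'   use [split_pedigree()] for large pedigrees)
#' @param gm a `GenotypeMatrix` of marker genotypes
#' @param map a `MarkerMap` aligned to `gm` variants by chrom+pos
#' @param model a `DiseaseModel` (default [disease_model()]: dominant,
#'   q = 0.001, penetrances 0.05/0.5/0.5, i.e. 5% phenocopy rate)
#' @param positions optional data.frame (chrom, cM) of evaluation
#'   positions; default is a grid every `grid_cM` across each chromosome
#' @param grid_cM default evaluation grid step in cM (default 0.5)
#' @param freqs optional per-marker alt-allele frequencies; default
#'   estimated from founders (with all samples as fallback)
#' @param affected_only treat unaffected individuals as unknown (default)
#' @param max_states refuse pedigrees with more inheritance vectors than
#'   this (default 2^16)
#' @return data.frame with columns `chrom`, `cM`, `lod`
#' @export
lander_green_lod <- function(ped, gm, map, model = disease_model(),
                             positions = NULL, grid_cM = 0.5, freqs = NULL,
                             affected_only = TRUE, max_states = 2^16) {
  setup <- lg_setup(ped, max_states = max_states)
  key_gm <- paste(gm$variants$chrom, gm$variants$pos)
  key_map <- paste(map$chrom, map$pos)
  midx <- match(key_gm, key_map)
  if (anyNA(midx)) stop("all genotype variants must appear in the map")
  cM_all <- map$cM[midx]
  if (is.null(freqs)) freqs <- .founder_freqs(gm, ped)
  Pphi <- lg_phenotype_lik(setup, model, affected_only)
  log_pphi <- log(mean(Pphi))
  out <- list()
  for (ch in unique(gm$variants$chrom)) {
    vi <- which(gm$variants$chrom == ch)
    vi <- vi[order(cM_all[vi])]
    cMs <- cM_all[vi]
    G <- .align_genotypes(gm, ped, vi)
    E <- lg_emissions(setup, G, freqs[vi])
    thetas <- haldane(diff(cMs))
    fb <- lg_forward_backward(setup, E, thetas)
    pos_ch <- if (is.null(positions)) {
      seq(min(cMs), max(cMs), by = grid_cM)
    } else positions$cM[positions$chrom == ch]
    lods <- vapply(pos_ch, function(x)
      .lod_at(setup, E, fb, cMs, x, Pphi, log_pphi), numeric(1))
    out[[ch]] <- data.frame(chrom = ch, cM = pos_ch, lod = lods,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# L x n dosage matrix aligned to pedigree order (NA for unsampled).
.align_genotypes <- function(gm, ped, variant_idx) {
  G <- matrix(NA_integer_, length(variant_idx), nrow(ped))
  present <- ped$id %in% gm$samples & ped$genotyped
  G[, present] <- gm$dosage[variant_idx, ped$id[present], drop = FALSE]
  G
}

.founder_freqs <- function(gm, ped) {
  founders <- intersect(ped$id[is_founder(ped)], gm$samples)
  src <- if (length(founders) >= 4) gm$dosage[, founders, drop = FALSE] else
    gm$dosage
  n_called <- rowSums(!is.na(src))
  # Laplace-smoothed so no observed allele gets probability zero
  (rowSums(src, na.rm = TRUE) + 1) / (2 * pmax(n_called, 1) + 2)
}

# LOD at position x (cM) on one chromosome given precomputed messages.
.lod_at <- function(setup, E, fb, cMs, x, Pphi, log_pphi) {
  S <- setup$S
  left <- if (any(cMs <= x)) max(which(cMs <= x)) else 0L
  right <- if (any(cMs > x)) min(which(cMs > x)) else 0L
  if (left > 0) {
    fmsg <- lg_transmit(fb$f[, left], haldane(x - cMs[left]), setup)
    lf <- fb$log_cf[left]
  } else {
    fmsg <- rep(1 / S, S); lf <- 0
  }
  if (right > 0) {
    bmsg <- lg_transmit(E[, right] * fb$b[, right],
                        haldane(cMs[right] - x), setup)
    lb <- fb$log_cb[right]
  } else {
    bmsg <- rep(1, S); lb <- 0
  }
  num <- log(sum(fmsg * Pphi * bmsg)) + lf + lb
  den <- fb$loglik + log_pphi
  (num - den) / log(10)
}

# Viterbi decoding of the inheritance-vector path. Returns the state path
# (1-based indices into 0:(S-1)) and the posterior probability of the
# chosen state at each marker.
lg_viterbi <- function(setup, E, thetas) {
  S <- setup$S; L <- ncol(E)
  V <- matrix(0, S, L)
  v <- E[, 1] / S
  V[, 1] <- v / max(v)
  if (L > 1) for (l in 2:L) {
    v <- E[, l] * lg_transmit_max(V[, l - 1], thetas[l - 1], setup)
    V[, l] <- v / max(v)
  }
  pc <- rowSums(vapply(seq_len(setup$m), function(b)
    bitwAnd(0:(S - 1), bitwShiftL(1L, b - 1L)) > 0, logical(S)))
  if (setup$m == 0) pc <- 0
  path <- integer(L)
  path[L] <- which.max(V[, L])
  if (L > 1) for (l in (L - 1):1) {
    th <- thetas[l]
    if (th <= 0) { path[l] <- path[l + 1]; next }
    d <- pc[bitwXor(0:(S - 1), path[l + 1] - 1L) + 1L]
    path[l] <- which.max(log(V[, l]) + d * log(th) +
                           (setup$m - d) * log(1 - th))
  }
  fb <- lg_forward_backward(setup, E, thetas)
  post <- fb$f * fb$b
  post <- sweep(post, 2, colSums(post), "/")
  conf <- post[cbind(path, seq_len(L))]
  list(path = path, confidence = conf)
}
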