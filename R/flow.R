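# Haplotype-flow reconstruction: Viterbi inheritance vectors per pedigree
# chunk, founder-haplotype labeling, and reassembly of chunk-local labels
# into globally labeled founder haplotypes via connector individuals.

# Solve founder-allele contents at each locus given the decoded origins.
# Constraint propagation: a homozygote pins both of its origin alleles; a
# heterozygote with one pinned origin pins the other to the complement.
# Unresolved alleles stay NA.
.solve_founder_alleles <- function(OPl, OMl, g, n_alleles,
                                   seed = rep(NA_integer_, n_alleles)) {
  val <- seed
  typed <- which(!is.na(g))
  hom <- typed[g[typed] != 1L]
  val[OPl[hom]] <- as.integer(g[hom] / 2L)
  val[OMl[hom]] <- as.integer(g[hom] / 2L)
  het <- typed[g[typed] == 1L]
  repeat {
    changed <- FALSE
    for (i in het) {
      a <- OPl[i]; b <- OMl[i]
      if (!is.na(val[a]) && is.na(val[b])) {
        val[b] <- 1L - val[a]; changed <- TRUE
      } else if (is.na(val[a]) && !is.na(val[b])) {
        val[a] <- 1L - val[b]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  val
}

# Run Viterbi flow decoding for one chunk on one chromosome.
# founder_values (2f x L, NA = free) pins the phased allele content of
# chunk founders already resolved in other chunks; loci where the pinned
# content contradicts the chunk's own genotypes fall back to the
# unconstrained emission.
.chunk_flow <- function(chunk, gm, vi, cMs, freqs, max_states,
                        founder_values = NULL) {
  setup <- lg_setup(chunk, max_states = max_states)
  G <- .align_genotypes(gm, chunk, vi)
  E <- lg_emissions(setup, G, freqs, founder_values)
  dead <- which(colSums(E) <= 0)
  if (length(dead)) {
    E0 <- lg_emissions(setup, G[dead, , drop = FALSE], freqs[dead])
    E[, dead] <- E0
  }
  thetas <- haldane(diff(cMs))
  vit <- lg_viterbi(setup, E, thetas)
  L <- length(vi)
  n <- nrow(chunk)
  OP <- matrix(0L, n, L); OM <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    OP[, l] <- setup$O_pat[vit$path[l], ]
    OM[, l] <- setup$O_mat[vit$path[l], ]
  }
  n_alleles <- 2L * setup$f
  val <- matrix(NA_integer_, n_alleles, L)
  for (l in seq_len(L)) {
    seed <- if (is.null(founder_values)) rep(NA_integer_, n_alleles) else
      founder_values[, l]
    val[, l] <- .solve_founder_alleles(OP[, l], OM[, l], G[l, ], n_alleles,
                                       seed)
  }
  list(ids = chunk$id, founder_ids = chunk$id[is_founder(chunk)],
       OP = OP, OM = OM, val = val, conf = vit$confidence)
}

# Topological order of chunks: chunk c depends on the chunk where each of
# its chunk-founders is a non-founder of the full pedigree.
.chunk_order <- function(chunks, ped) {
  k <- length(chunks)
  natal <- vapply(ped$id, function(x) {
    hit <- which(vapply(chunks, function(ch)
      x %in% ch$id && !is.na(ch$father[ch$id == x]), logical(1)))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  deps <- lapply(seq_len(k), function(c) {
    fo <- chunks[[c]]$id[is_founder(chunks[[c]])]
    setdiff(unique(stats::na.omit(natal[fo])), c)
  })
  order <- integer(0)
  done <- logical(k)
  while (length(order) < k) {
    ready <- which(!done & vapply(deps, function(d) all(done[d]), logical(1)))
    if (!length(ready)) { ready <- which(!done)[1] }   # safety, never expected
    order <- c(order, ready)
    done[ready] <- TRUE
  }
  order
}

#' Reconstruct the haplotype flow of a pedigree
#'
#' Divide-and-conquer reconstruction of which globally labeled founder
#' haplotype each individual carries at each marker. Large pedigrees are
#' split ([split_pedigree()]); within each chunk the single most probable
#' inheritance path is decoded by Viterbi over the Lander-Green HMM, and
#' chunk-local founder labels are merged across chunks at the connector
#' individuals (orientation chosen by majority agreement of the phased
#' allele contents; unresolved connectors fall back to the first
#' orientation). Founder haplotypes are labeled `"<id>|A"` and `"<id>|B"`,
#' identifiable up to swapping a founder's two labels.
#'
#' @param ped a `Pedigree`
#' @param gm a `GenotypeMatrix` of phase-informative markers
#' @param map a `MarkerMap` aligned to `gm` by chrom+pos
#' @param max_bits chunk size limit for [split_pedigree()] (default 12)
#' @param max_meioses per-chunk cap on meioses: exact inference enumerates
#'   `2^(2n)` inheritance vectors (default 12, i.e. at most 4096 states)
#' @param max_founders per-chunk cap on founders: emissions sum over
#'   `4^f` founder-allele assignments (default 6)
#' @param freqs optional per-marker allele frequencies (default founder
#'   estimate)
#' @param max_states refusal threshold for the per-chunk state space
#' @return a `HaplotypeFlow`: list with `ids`, `loci` (chrom, pos, cM),
#'   character label matrices `pat` and `mat` (individuals x loci), allele
#'   content matrices `pat_allele`/`mat_allele`, and `confidence`
#'   (posterior probability of the decoded inheritance state).
#' @export
reconstruct_flow <- function(ped, gm, map, max_bits = 12L,
                             max_meioses = 12L, max_founders = 6L,
                             freqs = NULL, max_states = 2^16) {
  sp <- split_pedigree(ped, max_bits = max_bits, max_meioses = max_meioses,
                       max_founders = max_founders)
  chunks <- sp$chunks
  key_gm <- paste(gm$variants$chrom, gm$variants$pos)
  key_map <- paste(map$chrom, map$pos)
  midx <- match(key_gm, key_map)
  if (anyNA(midx)) stop("all genotype variants must appear in the map")
  cM_all <- map$cM[midx]
  if (is.null(freqs)) freqs <- .founder_freqs(gm, ped)

  N <- nrow(ped)
  ord <- .chunk_order(chunks, ped)
  loci_list <- list(); pat_list <- list(); mat_list <- list()
  pa_list <- list(); ma_list <- list(); cf_list <- list()
  for (ch in unique(gm$variants$chrom)) {
    vi <- which(gm$variants$chrom == ch)
    vi <- vi[order(cM_all[vi])]
    cMs <- cM_all[vi]
    L <- length(vi)
    Gpat <- matrix(NA_character_, N, L, dimnames = list(ped$id, NULL))
    Gmat <- matrix(NA_character_, N, L, dimnames = list(ped$id, NULL))
    APat <- matrix(NA_integer_, N, L, dimnames = list(ped$id, NULL))
    AMat <- matrix(NA_integer_, N, L, dimnames = list(ped$id, NULL))
    Conf <- matrix(NA_real_, N, L, dimnames = list(ped$id, NULL))
    for (c in ord) {
      chunk <- chunks[[c]]
      fo <- chunk$id[is_founder(chunk)]
      n_alleles <- 2L * length(fo)
      # connectors already resolved elsewhere constrain this chunk: their
      # phased allele content is pinned, with chunk-haplotype A mapped to
      # the resolved paternal track (no orientation search needed)
      fv <- matrix(NA_integer_, n_alleles, L)
      Tlab <- matrix(NA_character_, n_alleles, L)
      for (j in seq_along(fo)) {
        x <- fo[j]
        ai <- 2L * j - 1L; bi <- 2L * j
        if (!all(is.na(Gpat[x, ]))) {
          fv[ai, ] <- APat[x, ]; fv[bi, ] <- AMat[x, ]
          Tlab[ai, ] <- Gpat[x, ]; Tlab[bi, ] <- Gmat[x, ]
        } else {
          Tlab[ai, ] <- paste0(x, "|A")
          Tlab[bi, ] <- paste0(x, "|B")
        }
      }
      res <- .chunk_flow(chunk, gm, vi, cMs, freqs[vi], max_states,
                         founder_values = fv)
      for (j in seq_along(fo)) {
        x <- fo[j]
        ai <- 2L * j - 1L; bi <- 2L * j
        if (all(is.na(Gpat[x, ]))) {
          Gpat[x, ] <- Tlab[ai, ]; Gmat[x, ] <- Tlab[bi, ]
          APat[x, ] <- res$val[ai, ]; AMat[x, ] <- res$val[bi, ]
          Conf[x, ] <- res$conf
        }
      }
      new_ids <- res$ids[vapply(res$ids, function(i) all(is.na(Gpat[i, ])),
                                logical(1))]
      ni <- match(new_ids, res$ids)
      for (l in seq_len(L)) {
        Gpat[new_ids, l] <- Tlab[res$OP[ni, l], l]
        Gmat[new_ids, l] <- Tlab[res$OM[ni, l], l]
        APat[new_ids, l] <- res$val[res$OP[ni, l], l]
        AMat[new_ids, l] <- res$val[res$OM[ni, l], l]
        Conf[new_ids, l] <- res$conf[l]
      }
    }
    loci_list[[ch]] <- data.frame(chrom = ch, pos = gm$variants$pos[vi],
                                  cM = cMs, stringsAsFactors = FALSE)
    pat_list[[ch]] <- Gpat; mat_list[[ch]] <- Gmat
    pa_list[[ch]] <- APat; ma_list[[ch]] <- AMat; cf_list[[ch]] <- Conf
  }
  structure(list(
    ids = ped$id,
    loci = do.call(rbind, c(loci_list, list(make.row.names = FALSE))),
    pat = do.call(cbind, pat_list), mat = do.call(cbind, mat_list),
    pat_allele = do.call(cbind, pa_list),
    mat_allele = do.call(cbind, ma_list),
    confidence = do.call(cbind, cf_list)), class = "HaplotypeFlow")
}

#' @export
print.HaplotypeFlow <- function(x, ...) {
  cat("HaplotypeFlow: ", length(x$ids), " individuals x ", nrow(x$loci),
      " loci (", length(unique(x$loci$chrom)), " chromosome(s)), mean ",
      "confidence ", round(mean(x$confidence, na.rm = TRUE), 3), "\n",
      sep = "")
  invisible(x)
}

#' Maximal haplotype sharing among cases
#'
#' For each locus, the maximum over founder-haplotype labels of the number
#' of distinct cases carrying that label, and the genome-wide maximum.
#'
#' @param flow a `HaplotypeFlow`
#' @param cases character vector of affected individual ids; ids absent
#'   from the flow are dropped with a warning
#' @return list with `per_locus` (data.frame: chrom, pos, max_shared,
#'   label of the top haplotype, ties = number of labels achieving the
#'   maximum) and `genome_max` (the genome-wide maximum count)
#' @export
max_haplotype_sharing <- function(flow, cases) {
  missing_ids <- setdiff(cases, flow$ids)
  if (length(missing_ids)) {
    warning("cases absent from flow excluded: ",
            paste(missing_ids, collapse = ", "))
    cases <- setdiff(cases, missing_ids)
  }
  ci <- match(cases, flow$ids)
  L <- nrow(flow$loci)
  max_shared <- integer(L); top <- character(L); ties <- integer(L)
  for (l in seq_len(L)) {
    labs <- c(flow$pat[ci, l], flow$mat[ci, l])
    who <- rep(cases, 2)
    ok <- !is.na(labs)
    if (!any(ok)) { max_shared[l] <- 0L; top[l] <- NA; ties[l] <- 0L; next }
    counts <- vapply(split(who[ok], labs[ok]),
                     function(x) length(unique(x)), integer(1))
    max_shared[l] <- max(counts)
    winners <- names(counts)[counts == max(counts)]
    top[l] <- winners[1]
    ties[l] <- length(winners)
  }
  list(per_locus = data.frame(chrom = flow$loci$chrom, pos = flow$loci$pos,
                              max_shared = max_shared, label = top,
                              ties = ties, stringsAsFactors = FALSE),
       genome_max = if (L) max(max_shared) else 0L)
}

#' Write a haplotype flow in long tab-delimited format
#' @param flow a `HaplotypeFlow`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_flow <- function(flow, path) {
  L <- nrow(flow$loci)
  long <- data.frame(
    individual = rep(flow$ids, each = L),
    chrom = rep(flow$loci$chrom, length(flow$ids)),
    pos = rep(flow$loci$pos, length(flow$ids)),
    label_paternal = as.vector(t(flow$pat)),
    label_maternal = as.vector(t(flow$mat)),
    confidence = round(as.vector(t(flow$confidence)), 4),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
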