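# Shared fixtures: small pedigrees, single-marker gene drops, and the flow
# accuracy metric used against gene-drop truth.

trio_ped <- function(affection = c("unknown", "unknown", "affected")) {
  build_pedigree(data.frame(
    id = c("f", "m", "c"), father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
    sex = c("male", "female", "unknown"), affection = affection,
    stringsAsFactors = FALSE))
}

nuclear_ped <- function(n_kids = 3, affection = NULL) {
  ids <- c("f", "m", paste0("k", seq_len(n_kids)))
  ped <- data.frame(
    id = ids, father = c(NA, NA, rep("f", n_kids)),
    mother = c(NA, NA, rep("m", n_kids)),
    sex = c("male", "female", rep("unknown", n_kids)),
    stringsAsFactors = FALSE)
  if (!is.null(affection)) ped$affection <- affection
  build_pedigree(ped)
}

# three generations: top couple, their children married to founder spouses
three_gen_ped <- function(n_branches = 2, n_grandkids = 2) {
  rows <- data.frame(id = c("f", "m"), father = NA, mother = NA,
                     stringsAsFactors = FALSE)
  for (b in seq_len(n_branches)) {
    cid <- paste0("c", b); sid <- paste0("s", b)
    rows <- rbind(rows,
                  data.frame(id = cid, father = "f", mother = "m"),
                  data.frame(id = sid, father = NA, mother = NA))
    for (j in seq_len(n_grandkids))
      rows <- rbind(rows, data.frame(id = paste0("g", b, j),
                                     father = cid, mother = sid))
  }
  build_pedigree(rows)
}

# drop one biallelic marker through a pedigree; returns dosages + haplotype
# sources so tests have transmission truth
drop_one_marker <- function(ped, p = 0.5) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  hA <- hB <- integer(n)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      hA[i] <- stats::rbinom(1, 1, p); hB[i] <- stats::rbinom(1, 1, p)
    } else {
      hA[i] <- if (stats::runif(1) < 0.5) hA[fa[i]] else hB[fa[i]]
      hB[i] <- if (stats::runif(1) < 0.5) hA[mo[i]] else hB[mo[i]]
    }
  }
  stats::setNames(hA + hB, ped$id)
}

# random <= 12-meiosis pedigree with a consistent marker and affection, for
# oracle-equivalence checks
random_small_ped <- function(seed) {
  set.seed(seed)
  rows <- data.frame(id = c("f", "m"), father = NA, mother = NA,
                     stringsAsFactors = FALSE)
  nk <- sample(2:4, 1)
  for (k in paste0("k", seq_len(nk)))
    rows <- rbind(rows, data.frame(id = k, father = "f", mother = "m"))
  if (nk <= 4 && stats::runif(1) < 0.6) {
    rows <- rbind(rows, data.frame(id = "sp", father = NA, mother = NA))
    for (j in seq_len(sample(1:min(2, 6 - nk), 1)))
      rows <- rbind(rows, data.frame(id = paste0("g", j),
                                     father = "k1", mother = "sp"))
  }
  ped <- build_pedigree(rows)
  p <- stats::runif(1, 0.2, 0.8)
  g <- drop_one_marker(ped, p)
  g[stats::runif(nrow(ped)) < 0.15] <- NA
  aff <- stats::runif(nrow(ped)) < 0.4
  aff[sample(nrow(ped), 1)] <- TRUE
  ped$affection <- ifelse(aff, "affected", "unaffected")
  list(ped = ped, g = g, p = p)
}

single_marker_gm <- function(g) {
  genotype_matrix(data.frame(chrom = "1", pos = 1000, ref = "A", alt = "G"),
                  matrix(as.integer(g), nrow = 1,
                         dimnames = list(NULL, names(g))))
}

# per-allele-slot flow accuracy over non-founders, modulo swapping each
# founder's two haplotype labels (coordinate descent over the swaps)
flow_slot_accuracy <- function(truth, fl, ped, truth_cols = NULL,
                               fl_cols = NULL) {
  founders <- ped$id[is_founder(ped)]
  nonf <- ped$id[!is_founder(ped)]
  if (is.null(truth_cols)) truth_cols <- seq_len(ncol(truth$pat))
  if (is.null(fl_cols)) fl_cols <- seq_len(ncol(fl$pat))
  tp <- truth$pat[nonf, truth_cols, drop = FALSE]
  tm <- truth$mat[nonf, truth_cols, drop = FALSE]
  score <- function(swap) {
    rp <- fl$pat; rm <- fl$mat
    for (f in founders[swap]) {
      a <- paste0(f, "|A"); b <- paste0(f, "|B")
      rp[fl$pat == a] <- b; rp[fl$pat == b] <- a
      rm[fl$mat == a] <- b; rm[fl$mat == b] <- a
    }
    mean(c(rp[nonf, fl_cols] == tp, rm[nonf, fl_cols] == tm), na.rm = TRUE)
  }
  swap <- stats::setNames(rep(FALSE, length(founders)), founders)
  for (pass in 1:2) for (f in founders) {
    s1 <- swap; s1[f] <- TRUE
    s0 <- swap; s0[f] <- FALSE
    swap[f] <- score(s1) > score(s0)
  }
  score(swap)
}

# standard informative-panel simulation config for flow tests
flow_test_config <- function(seed, ...) {
  sim_config(generations = 3L, n_snps_per_chrom = 200L, cm_spacing = 0.5,
             snp_freq_range = c(0.5, 0.5), n_risk_loci = 5L, seed = seed,
             ...)
}
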