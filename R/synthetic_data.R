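# Synthetic multiplex-pedigree datasets with the statistical structure the
# analyses assume: multi-generation pedigrees with large sibships, founder
# haplotypes under HWE, recombination under a cM map (Haldane), a logistic
# liability combining a common-variant risk score with rare penetrant
# founder variants, and a configurable phenocopy rate.

#' Simulation configuration
#'
#' @param generations number of generations (default 4, as in a large
#'   four-generation multiplex family)
#' @param mean_sibship mean number of children per mating (default 10;
#'   sibships are drawn as 1 + Poisson(mean - 1), whose quartiles bracket
#'   the 8-11 band at the default)
#' @param reproduce_prob probability that a non-founder marries a new
#'   founder spouse and has children (default 0.7, giving several hundred
#'   members over four generations)
#' @param n_chrom,n_snps_per_chrom,cm_spacing framework SNP map: markers
#'   every `cm_spacing` cM (default 0.5) on each chromosome
#' @param snp_freq_range founder alt-allele frequency range for framework
#'   SNPs (drawn uniformly)
#' @param n_risk_loci number of unlinked common risk loci (default 127, the
#'   size of a GWAS-derived risk panel)
#' @param risk_raf_range,risk_or_range ranges for risk-allele frequencies
#'   and per-allele odds ratios of the risk loci
#' @param causal list of rare causal variants, each a list with `chrom`,
#'   `cM` (position), `founder` (id, or NA for the first founder), `side`
#'   ("A"/"B") and `or` (carrier odds ratio)
#' @param baseline_prevalence population disease prevalence (default
#'   0.013)
#' @param phenocopy_rate probability that a non-carrier of any causal
#'   variant is affected regardless of liability (default 0.05)
#' @param seed RNG seed (mandatory)
#' @return a `SimulationConfig` list
#' @export
sim_config <- function(generations = 4L, mean_sibship = 10, reproduce_prob = 0.7,
                       n_chrom = 1L, n_snps_per_chrom = 200L, cm_spacing = 0.5,
                       snp_freq_range = c(0.2, 0.8),
                       n_risk_loci = 127L,
                       risk_raf_range = c(0.05, 0.5),
                       risk_or_range = c(1.05, 1.3),
                       causal = list(),
                       baseline_prevalence = 0.013,
                       phenocopy_rate = 0.05,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(generations >= 1, mean_sibship >= 1,
            reproduce_prob >= 0, reproduce_prob <= 1,
            baseline_prevalence > 0, baseline_prevalence < 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1)
  structure(list(generations = as.integer(generations),
                 mean_sibship = mean_sibship,
                 reproduce_prob = reproduce_prob,
                 n_chrom = as.integer(n_chrom),
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 cm_spacing = cm_spacing,
                 snp_freq_range = snp_freq_range,
                 n_risk_loci = as.integer(n_risk_loci),
                 risk_raf_range = risk_raf_range,
                 risk_or_range = risk_or_range,
                 causal = causal,
                 baseline_prevalence = baseline_prevalence,
                 phenocopy_rate = phenocopy_rate,
                 seed = as.integer(seed)), class = "SimulationConfig")
}

#' Simulate a multi-generation pedigree structure
#'
#' One founder couple starts the pedigree; every individual born into the
#' pedigree marries a new founder spouse with probability
#' `reproduce_prob` (always, in the first generation) and produces a
#' sibship of size 1 + Poisson(mean_sibship - 1). Deterministic given the
#' seed.
#'
#' @param cfg a `SimulationConfig`
#' @return a `Pedigree`
#' @export
simulate_pedigree_structure <- function(cfg) {
  set.seed(cfg$seed)
  counter <- 0L
  new_id <- function() { counter <<- counter + 1L
    sprintf("I%04d", counter) }
  rows <- list()
  add <- function(id, fa, mo, sex)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father = fa, mother = mo, sex = sex,
      stringsAsFactors = FALSE)
  p1 <- new_id(); p2 <- new_id()
  add(p1, NA, NA, "male"); add(p2, NA, NA, "female")
  current <- list(list(father = p1, mother = p2))
  if (cfg$generations > 1) for (g in 2:cfg$generations) {
    nxt <- list()
    for (cpl in current) {
      nkids <- 1L + stats::rpois(1, cfg$mean_sibship - 1)
      for (k in seq_len(nkids)) {
        kid <- new_id()
        sex <- sample(c("male", "female"), 1)
        add(kid, cpl$father, cpl$mother, sex)
        if (g < cfg$generations && stats::runif(1) < cfg$reproduce_prob) {
          sp <- new_id()
          add(sp, NA, NA, if (sex == "male") "female" else "male")
          nxt[[length(nxt) + 1L]] <-
            if (sex == "male") list(father = kid, mother = sp)
            else list(father = sp, mother = kid)
        }
      }
    }
    current <- nxt
  }
  build_pedigree(do.call(rbind, rows))
}

#' Deterministic balanced multiplex pedigree
#'
#' A fixed pedigree for reproducible benchmarks: one founder couple, every
#' child marries a new founder spouse and has exactly `sibship` children,
#' down to `generations` generations. Complements the stochastic
#' [simulate_pedigree_structure()].
#'
#' @param generations number of generations (>= 2)
#' @param sibship children per mating
#' @return a `Pedigree` (all affection unknown)
#' @export
balanced_pedigree <- function(generations = 3L, sibship = 5L) {
  stopifnot(generations >= 2, sibship >= 1)
  rows <- list(data.frame(id = c("F1", "M1"), father = NA, mother = NA,
                          sex = c("male", "female"), stringsAsFactors = FALSE))
  couples <- list(c("F1", "M1"))
  for (g in 2:generations) {
    nxt <- list()
    for (ci in seq_along(couples)) {
      cpl <- couples[[ci]]
      for (k in seq_len(sibship)) {
        kid <- paste0("G", g, "_", ci, "_", k)
        sex <- if (k %% 2 == 1) "male" else "female"
        rows[[length(rows) + 1L]] <- data.frame(
          id = kid, father = cpl[1], mother = cpl[2], sex = sex,
          stringsAsFactors = FALSE)
        if (g < generations) {
          sp <- paste0(kid, "s")
          rows[[length(rows) + 1L]] <- data.frame(
            id = sp, father = NA, mother = NA,
            sex = if (sex == "male") "female" else "male",
            stringsAsFactors = FALSE)
          nxt[[length(nxt) + 1L]] <-
            if (sex == "male") c(kid, sp) else c(sp, kid)
        }
      }
    }
    couples <- nxt
  }
  build_pedigree(do.call(rbind, rows))
}

#' Gene-drop simulation of framework SNPs with flow truth
#'
#' Founder haplotypes are drawn independently per marker under HWE at
#' uniform frequencies from `snp_freq_range`; each meiosis recombines
#' between adjacent markers with the Haldane fraction for the map spacing.
#' Returns observed genotypes plus the true haplotype flow (per
#' individual, per locus founder-haplotype labels), the evaluation truth
#' for [reconstruct_flow()] and [impute_from_flow()].
#'
#' @param ped a `Pedigree`
#' @param cfg a `SimulationConfig`
#' @return list with `gm` (a `GenotypeMatrix`), `map` (a `MarkerMap`) and
#'   `truth` (a `HaplotypeFlow` with confidence 1)
#' @export
gene_drop <- function(ped, cfg) {
  set.seed(cfg$seed + 1L)
  L1 <- cfg$n_snps_per_chrom
  chroms <- as.character(seq_len(cfg$n_chrom))
  map <- marker_map(rep(chroms, each = L1),
                    rep(seq_len(L1) * 1000L, cfg$n_chrom),
                    rep((seq_len(L1) - 1L) * cfg$cm_spacing, cfg$n_chrom))
  L <- nrow(map)
  freqs <- stats::runif(L, cfg$snp_freq_range[1], cfg$snp_freq_range[2])
  theta <- haldane(cfg$cm_spacing)
  n <- nrow(ped)
  founder <- is_founder(ped)
  hapA <- matrix(NA_integer_, n, L); hapB <- matrix(NA_integer_, n, L)
  labA <- matrix(NA_character_, n, L); labB <- matrix(NA_character_, n, L)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  per_chrom <- split(seq_len(L), map$chrom)
  meiosis <- function(h1, h2, l1, l2, idx) {
    # recombinant gamete across the chromosomes in idx
    allele <- integer(length(idx)); lab <- character(length(idx))
    for (ii in per_chrom) {
      src <- integer(length(ii))
      src[1] <- stats::rbinom(1, 1, 0.5)
      if (length(ii) > 1) {
        sw <- stats::rbinom(length(ii) - 1, 1, theta)
        src[-1] <- (src[1] + cumsum(sw)) %% 2
      }
      allele[ii] <- ifelse(src == 0, h1[ii], h2[ii])
      lab[ii] <- ifelse(src == 0, l1[ii], l2[ii])
    }
    list(allele = allele, lab = lab)
  }
  for (i in seq_len(n)) {
    if (founder[i]) {
      hapA[i, ] <- stats::rbinom(L, 1, freqs)
      hapB[i, ] <- stats::rbinom(L, 1, freqs)
      labA[i, ] <- paste0(ped$id[i], "|A")
      labB[i, ] <- paste0(ped$id[i], "|B")
    } else {
      gp <- meiosis(hapA[fa[i], ], hapB[fa[i], ],
                    labA[fa[i], ], labB[fa[i], ], seq_len(L))
      gm_ <- meiosis(hapA[mo[i], ], hapB[mo[i], ],
                     labA[mo[i], ], labB[mo[i], ], seq_len(L))
      hapA[i, ] <- gp$allele; labA[i, ] <- gp$lab
      hapB[i, ] <- gm_$allele; labB[i, ] <- gm_$lab
    }
  }
  dosage <- t(hapA + hapB)
  gm <- genotype_matrix(
    data.frame(chrom = map$chrom, pos = map$pos,
               id = paste0("snp", seq_len(L)), ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    dosage, samples = ped$id)
  truth <- structure(list(
    ids = ped$id, loci = as.data.frame(map),
    pat = labA, mat = labB,
    pat_allele = hapA, mat_allele = hapB,
    confidence = matrix(1, n, L)), class = "HaplotypeFlow")
  rownames(truth$pat) <- rownames(truth$mat) <- ped$id
  list(gm = gm, map = map, truth = truth, freqs = freqs)
}

# Dosage of a rare causal variant: carriage of one founder haplotype label
# at the nearest map position, read from the truth flow.
.causal_dosage <- function(truth, cv, ped) {
  founder_id <- if (is.null(cv$founder) || is.na(cv$founder))
    ped$id[is_founder(ped)][1] else cv$founder
  side <- if (is.null(cv$side)) "A" else cv$side
  label <- paste0(founder_id, "|", side)
  on_chr <- which(truth$loci$chrom == as.character(cv$chrom))
  l <- on_chr[which.min(abs(truth$loci$cM[on_chr] - cv$cM))]
  (truth$pat[, l] == label) + (truth$mat[, l] == label)
}

#' Simulate unlinked common risk-locus genotypes
#'
#' Gene-drops `n_risk_loci` biallelic loci with free recombination between
#' them (each locus segregates independently through the pedigree).
#'
#' @param ped a `Pedigree`
#' @param cfg a `SimulationConfig`
#' @return list with `gm` (a `GenotypeMatrix` of risk-locus dosages) and
#'   `loci` (a `RiskLocusTable`)
#' @export
simulate_risk_loci <- function(ped, cfg) {
  set.seed(cfg$seed + 2L)
  R <- cfg$n_risk_loci
  raf <- stats::runif(R, cfg$risk_raf_range[1], cfg$risk_raf_range[2])
  or <- stats::runif(R, cfg$risk_or_range[1], cfg$risk_or_range[2])
  n <- nrow(ped)
  founder <- is_founder(ped)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  hapA <- matrix(NA_integer_, n, R); hapB <- matrix(NA_integer_, n, R)
  for (i in seq_len(n)) {
    if (founder[i]) {
      hapA[i, ] <- stats::rbinom(R, 1, raf)
      hapB[i, ] <- stats::rbinom(R, 1, raf)
    } else {
      pick_f <- stats::rbinom(R, 1, 0.5)
      pick_m <- stats::rbinom(R, 1, 0.5)
      hapA[i, ] <- ifelse(pick_f == 0, hapA[fa[i], ], hapB[fa[i], ])
      hapB[i, ] <- ifelse(pick_m == 0, hapA[mo[i], ], hapB[mo[i], ])
    }
  }
  loci <- risk_locus_table(data.frame(
    id = paste0("risk", seq_len(R)), raf = raf, or_per_allele = or,
    model = "additive", stringsAsFactors = FALSE))
  gm <- genotype_matrix(
    data.frame(chrom = "risk", pos = seq_len(R), id = loci$id,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    t(hapA + hapB), samples = ped$id)
  list(gm = gm, loci = loci)
}

#' Assign affection status from a liability model
#'
#' Disease probability is logistic: baseline logit plus additive log-OR
#' contributions of the common risk loci plus the log-OR of any carried
#' rare causal variant. Phenocopies are then added: non-carriers of every
#' causal variant become affected with probability `phenocopy_rate`
#' regardless of liability. Deterministic given the seed.
#'
#' @param ped a `Pedigree`
#' @param risk list from [simulate_risk_loci()] (or NULL for no common
#'   component)
#' @param truth truth `HaplotypeFlow` from [gene_drop()] (needed when
#'   `cfg$causal` is non-empty)
#' @param cfg a `SimulationConfig`
#' @return list with `affection` (named character vector), `carrier`
#'   (named dosage matrix of causal variants, individuals x variants) and
#'   `phenocopy` (named logical)
#' @export
assign_phenotypes <- function(ped, risk, truth, cfg) {
  set.seed(cfg$seed + 3L)
  n <- nrow(ped)
  eta <- rep(stats::qlogis(cfg$baseline_prevalence), n)
  if (!is.null(risk)) {
    lor <- log(risk$loci$or_per_allele)
    # contributions centered at the population mean dosage, so the baseline
    # prevalence refers to an average-risk individual
    g <- risk$gm$dosage[risk$loci$id, ped$id, drop = FALSE] -
      2 * risk$loci$raf
    eta <- eta + as.numeric(crossprod(g, lor))
  }
  carrier <- matrix(0L, n, length(cfg$causal),
                    dimnames = list(ped$id, NULL))
  if (length(cfg$causal)) {
    for (k in seq_along(cfg$causal)) {
      cv <- cfg$causal[[k]]
      dk <- .causal_dosage(truth, cv, ped)
      carrier[, k] <- dk
      eta <- eta + dk * log(cv$or)
    }
  }
  p <- stats::plogis(eta)
  affected <- stats::runif(n) < p
  noncar <- rowSums(carrier) == 0
  pheno <- noncar & (stats::runif(n) < cfg$phenocopy_rate)
  affected <- affected | pheno
  list(affection = stats::setNames(
    ifelse(affected, "affected", "unaffected"), ped$id),
    carrier = carrier,
    phenocopy = stats::setNames(pheno & affected, ped$id))
}

#' Simulate a complete analysis-ready dataset
#'
#' Pedigree structure, framework SNPs with flow truth, unlinked risk loci,
#' causal-variant carriage and affection status, in one call.
#'
#' @param cfg a `SimulationConfig`
#' @param ped optional fixed `Pedigree` (e.g. from [balanced_pedigree()]);
#'   default is a fresh [simulate_pedigree_structure()] draw
#' @return list with `ped` (affection filled in), `gm`, `map`, `truth`,
#'   `risk`, `phenotypes`
#' @export
simulate_dataset <- function(cfg, ped = NULL) {
  if (is.null(ped)) ped <- simulate_pedigree_structure(cfg)
  gd <- gene_drop(ped, cfg)
  risk <- simulate_risk_loci(ped, cfg)
  phen <- assign_phenotypes(ped, risk, gd$truth, cfg)
  ped$affection <- unname(phen$affection[ped$id])
  list(ped = ped, gm = gd$gm, map = gd$map, truth = gd$truth,
       freqs = gd$freqs, risk = risk, phenotypes = phen, cfg = cfg)
}

#' Build a synthetic exome annotation table around a simulated dataset
#'
#' Creates an annotation table for the filter cascade containing the causal
#' variant(s) (severe consequence, rare everywhere, shared by carriers)
#' plus decoy variants constructed to fail exactly one stage each
#' (non-autosomal, mild consequence, common in a reference population,
#' excess case missingness, low case sharing), so the number of survivors
#' of every stage is known by construction.
#'
#' @param dataset from [simulate_dataset()]
#' @param family family label for the per-family count columns
#' @param n_decoys decoys per failure class (default 5)
#' @return data.frame annotation table (one row per variant transcript)
#' @export
build_annotation_table <- function(dataset, family = "A", n_decoys = 5L) {
  ped <- dataset$ped
  cases <- ped$id[ped$affection == "affected"]
  n_cases <- length(cases)
  mk <- function(chrom, pos, consequence, freq_ref, carriers, genotyped,
                 missing_cases, carol = FALSE, condel = FALSE, cadd = 10) {
    df <- data.frame(chrom = chrom, pos = pos, ref = "C", alt = "T",
                     gene = paste0("GENE", pos), consequence = consequence,
                     deleterious_carol = carol, deleterious_condel = condel,
                     cadd = cadd, freq_exac = freq_ref, freq_1kg = freq_ref,
                     localfreq_panel = freq_ref,
                     stringsAsFactors = FALSE)
    df[[paste0("case_carriers_", family)]] <- carriers
    df[[paste0("case_genotyped_", family)]] <- genotyped
    df[[paste0("case_missing_", family)]] <- missing_cases
    df
  }
  rows <- list()
  # causal variants: pass everything
  for (k in seq_len(ncol(dataset$phenotypes$carrier))) {
    carr <- dataset$phenotypes$carrier[cases, k]
    cv_chrom <- as.character(dataset$cfg$causal[[k]]$chrom %||% 1)
    rows[[length(rows) + 1L]] <- mk(
      chrom = cv_chrom, pos = 500000L + k,
      consequence = "frameshift", freq_ref = 0.001,
      carriers = sum(carr >= 1), genotyped = n_cases, missing_cases = 0L)
  }
  seqpos <- function(k) 600000L + k
  for (k in seq_len(n_decoys)) {
    rows[[length(rows) + 1L]] <- mk("X", seqpos(k), "frameshift", 0.001,
                                    n_cases, n_cases, 0L)             # non-autosomal
    rows[[length(rows) + 1L]] <- mk("2", seqpos(k), "synonymous", 0.001,
                                    n_cases, n_cases, 0L, cadd = 30)  # mild class
    rows[[length(rows) + 1L]] <- mk("3", seqpos(k), "frameshift", 0.20,
                                    n_cases, n_cases, 0L)             # common
    rows[[length(rows) + 1L]] <- mk("4", seqpos(k), "frameshift", 0.001,
                                    n_cases, n_cases,
                                    9999L)                            # missingness
    rows[[length(rows) + 1L]] <- mk("5", seqpos(k), "frameshift", 0.001,
                                    floor(0.3 * n_cases), n_cases, 0L) # low sharing
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end causal-variant recovery experiment
#'
#' Simulates a multiplex pedigree carrying one rare penetrant causal
#' variant on a founder haplotype, then runs the full discovery pipeline:
#' genotype QC, haplotype-flow reconstruction, within-family imputation of
#' exome variants observed only in a sequenced subset, kinship mixed-model
#' Wald tests, and the prioritization cascade. Returns the rank of the
#' causal variant among prioritized variants ordered by minimum P (`Inf`
#' when the causal variant is filtered out).
#'
#' @param seed RNG seed for the replicate
#' @param ped pedigree to use (default: balanced 3-generation, sibship 5)
#' @param n_decoys number of neutral segregating decoy variants placed on
#'   random founder haplotypes (default 29)
#' @param sequenced_fraction fraction of individuals with exome data
#'   (default 0.6)
#' @param causal_or carrier odds ratio of the causal variant (default 500,
#'   a near-fully-penetrant dominant effect)
#' @return list with `rank`, `p_causal`, `n_prioritized`, `n_cases`
#' @export
causal_recovery_rank <- function(seed, ped = balanced_pedigree(3L, 5L),
                                 n_decoys = 29L, sequenced_fraction = 0.6,
                                 causal_or = 500) {
  cfg <- sim_config(generations = 3L, n_snps_per_chrom = 200L,
                    cm_spacing = 0.5, snp_freq_range = c(0.5, 0.5),
                    n_risk_loci = 20L,
                    causal = list(list(chrom = 1, cM = 50, founder = "F1",
                                       side = "A", or = causal_or)),
                    seed = seed)
  ds <- simulate_dataset(cfg, ped = ped)
  ped <- ds$ped
  cases <- ped$id[ped$affection == "affected"]
  if (length(cases) < 2) return(list(rank = Inf, p_causal = NA_real_,
                                     n_prioritized = 0L,
                                     n_cases = length(cases)))
  # QC
  q <- snp_qc_filter(ds$gm, ped, miss_max = 0.05, maf_min = 0.01)
  mz <- mendelian_zero(q$gm, ped)
  gm <- mendelian_fill(mz$gm, ped)
  # flow
  fl <- reconstruct_flow(ped, gm, ds$map)
  # exome variants observed in a sequenced subset only
  set.seed(cfg$seed + 4L)
  seqd <- sample(ped$id, round(sequenced_fraction * nrow(ped)))
  truth_dosage <- function(label, l) {
    (ds$truth$pat[, l] == label) + (ds$truth$mat[, l] == label)
  }
  founders <- ped$id[is_founder(ped)]
  variants <- list(list(label = "F1|A",
                        l = which.min(abs(ds$map$cM - 50)), causal = TRUE))
  for (k in seq_len(n_decoys)) {
    variants[[k + 1L]] <- list(
      label = paste0(sample(founders, 1), "|", sample(c("A", "B"), 1)),
      l = sample(seq_len(nrow(ds$map)), 1), causal = FALSE)
  }
  carriages <- lapply(variants, function(v) {
    td <- truth_dosage(v$label, v$l)
    list(chrom = ds$map$chrom[v$l], pos = ds$map$pos[v$l],
         dosages = stats::setNames(
           ifelse(ped$id %in% seqd, td, NA_integer_), ped$id))
  })
  imp <- impute_variants(fl, carriages)
  # kinship mixed-model Wald tests on observed + imputed dosages
  K <- 2 * pedigree_kinship(ped)
  y <- as.numeric(ped$affection == "affected")
  vc <- fit_lmm_null(y, K)
  pvals <- vapply(seq_along(variants), function(k) {
    x <- imp$dosages[k, ped$id]
    x[is.na(x)] <- 0L
    if (stats::sd(x) == 0) return(NA_real_)
    wald_test(y, x, vc)$p
  }, numeric(1))
  # annotation + cascade
  ann <- do.call(rbind, lapply(seq_along(variants), function(k) {
    d <- imp$dosages[k, cases]
    data.frame(chrom = "1", pos = ds$map$pos[variants[[k]]$l] + k,
               ref = "C", alt = "T", gene = paste0("GENE", k),
               consequence = "frameshift", deleterious_carol = FALSE,
               deleterious_condel = FALSE, cadd = 25,
               freq_exac = 0.001, localfreq_panel = 0.001,
               case_carriers_FAM = sum(!is.na(d) & d >= 1),
               case_genotyped_FAM = sum(!is.na(d)),
               case_missing_FAM = sum(is.na(d)),
               causal = variants[[k]]$causal, stringsAsFactors = FALSE)
  }))
  cfg_f <- filter_config(case_missing_max = c(FAM = 20L))
  casc <- variant_cascade(ann, cfg_f, family = "FAM", units = "FAM")
  surv <- casc$variants
  if (!nrow(surv)) return(list(rank = Inf, p_causal = NA_real_,
                               n_prioritized = 0L, n_cases = length(cases)))
  pv <- matrix(pvals[match(surv$gene, ann$gene)], ncol = 1,
               dimnames = list(NULL, "FAM"))
  ranked <- rank_variants(surv, pv)
  rank <- which(ranked$causal)
  list(rank = if (length(rank)) rank else Inf,
       p_causal = pvals[1], n_prioritized = nrow(ranked),
       n_cases = length(cases))
}

#' Write a simulated dataset to disk
#'
#' Emits PED/FAM, a plain-text VCF of the framework SNPs, the marker map,
#' the risk-locus table, the annotation table and the truth flow, all as
#' plain-text tab-delimited files that round-trip through the package
#' readers.
#'
#' @param dataset from [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return named character vector of written file paths
#' @export
emit_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ped = file.path(dir, "family.ped"),
    vcf = file.path(dir, "snps.vcf"),
    map = file.path(dir, "markers.map"),
    risk = file.path(dir, "risk_loci.tsv"),
    risk_vcf = file.path(dir, "risk_genotypes.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    flow = file.path(dir, "truth_flow.tsv"))
  write_ped(dataset$ped, paths["ped"])
  write_vcf_genotypes(dataset$gm, paths["vcf"])
  write_marker_map(dataset$map, paths["map"])
  write_risk_loci(dataset$risk$loci, paths["risk"])
  write_vcf_genotypes(dataset$risk$gm, paths["risk_vcf"])
  ann <- build_annotation_table(dataset)
  utils::write.table(ann, paths["annotation"], quote = FALSE,
                     row.names = FALSE, sep = "\t")
  write_flow(dataset$truth, paths["flow"])
  paths
}
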