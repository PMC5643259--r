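#' Risk-locus table constructor
#'
#' Validates a table of disease-associated risk loci used for genetic risk
#' scores. Additive loci contribute `dosage * log(OR)`; genotype-class loci
#' (the NOD2-style exception) are grouped by `class_group` and contribute a
#' single class log-OR determined by the combined variant count across the
#' group: 0 variants -> 0, 1 variant -> `log(class_or_1)`, 2 or more
#' (homozygous or compound heterozygous) -> `log(class_or_2)`.
#'
#' @param loci data.frame with columns `id`, `raf` (risk-allele frequency in
#'   (0,1)), `or_per_allele` (additive odds ratio, > 0), `model`
#'   (`"additive"` or `"genotype_class"`), and for genotype-class loci
#'   `class_or_1`, `class_or_2` and `class_group`
#' @return the validated table with class `RiskLocusTable`
#' @export
risk_locus_table <- function(loci) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "raf", "model") %in% names(loci)))
  if (anyDuplicated(loci$id)) stop("duplicate locus ids")
  if (any(loci$raf <= 0 | loci$raf >= 1)) stop("raf must be in (0,1)")
  if (!all(loci$model %in% c("additive", "genotype_class")))
    stop("model must be 'additive' or 'genotype_class'")
  add <- loci$model == "additive"
  if (any(add) && (is.null(loci$or_per_allele) ||
                   any(is.na(loci$or_per_allele[add]) |
                       loci$or_per_allele[add] <= 0)))
    stop("additive loci need or_per_allele > 0")
  gc <- !add
  if (any(gc)) {
    if (is.null(loci$class_or_1) || is.null(loci$class_or_2) ||
        any(is.na(loci$class_or_1[gc])) || any(is.na(loci$class_or_2[gc])))
      stop("genotype_class loci need class_or_1 and class_or_2 ",
           "(no built-in defaults)")
    if (is.null(loci$class_group)) loci$class_group <- NA_character_
    loci$class_group[gc & is.na(loci$class_group)] <- "class1"
  } else {
    if (is.null(loci$class_group)) loci$class_group <- NA_character_
  }
  class(loci) <- c("RiskLocusTable", "data.frame")
  loci
}

#' Read / write a risk-locus table (tab-delimited)
#' @param path file path
#' @return a `RiskLocusTable`
#' @export
read_risk_loci <- function(path) {
  risk_locus_table(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
}

#' @rdname read_risk_loci
#' @param loci a `RiskLocusTable`
#' @export
write_risk_loci <- function(loci, path) {
  utils::write.table(as.data.frame(loci), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Per-locus log-odds contribution to a genetic risk score
#'
#' @param dosage risk-allele count 0/1/2, or `NA` (missing). A missing call
#'   contributes the expected contribution under Hardy-Weinberg equilibrium
#'   at the locus risk-allele frequency.
#' @param locus one row of a `RiskLocusTable` (additive loci only; genotype
#'   class groups are handled jointly in [compute_grs()])
#' @return log-odds contribution in natural-log units
#' @export
locus_contribution <- function(dosage, locus) {
  if (locus$model != "additive")
    stop("genotype_class loci are scored jointly by group; use compute_grs")
  lor <- log(locus$or_per_allele)
  ifelse(is.na(dosage), 2 * locus$raf * lor, dosage * lor)
}

# Class contribution of one genotype-class group given the combined variant
# count across the group's loci (NA count = unknown).
.class_lor <- function(count, or1, or2) {
  ifelse(count >= 2, log(or2), ifelse(count >= 1, log(or1), 0))
}

# Expected class contribution when some group members are missing: observed
# count is known, missing members add HWE-distributed counts.
.class_expected <- function(obs_count, miss_rafs, or1, or2) {
  # distribution of the sum of missing dosages under HWE
  probs <- 1
  for (p in miss_rafs) {
    g <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    new <- rep(0, length(probs) + 2)
    for (d in 0:2) new[seq_along(probs) + d] <- new[seq_along(probs) + d] +
        probs * g[d + 1]
    probs <- new
  }
  total <- obs_count + seq_along(probs) - 1
  sum(probs * .class_lor(total, or1, or2))
}

#' Compute genetic risk scores
#'
#' Sums per-locus log-odds contributions (natural-log units) assuming
#' additivity within and between loci, except genotype-class groups which
#' contribute one class log-OR based on the combined variant count.
#' Missing genotypes contribute their HWE-expected value and are counted in
#' `n_loci_imputed`. Individuals with no observed loci are excluded.
#'
#' @param gm a `GenotypeMatrix` whose variant ids (or `chrom:pos` keys)
#'   match the locus ids
#' @param loci a `RiskLocusTable`
#' @return a `GRSProfile` data.frame: `id`, `score`, `n_loci_observed`,
#'   `n_loci_imputed`, `low_coverage` (TRUE when < 50% of loci observed)
#' @export
compute_grs <- function(gm, loci) {
  stopifnot(inherits(loci, "RiskLocusTable"))
  idx <- match(loci$id, gm$variants$id)
  if (all(is.na(idx)))
    idx <- match(loci$id, paste0(gm$variants$chrom, ":", gm$variants$pos))
  found <- !is.na(idx)
  if (!any(found)) stop("no risk loci found in the genotype matrix")
  d <- matrix(NA_integer_, nrow(loci), length(gm$samples),
              dimnames = list(loci$id, gm$samples))
  d[found, ] <- gm$dosage[idx[found], , drop = FALSE]

  score <- numeric(length(gm$samples))
  add <- which(loci$model == "additive")
  for (j in add)
    score <- score + locus_contribution(d[j, ], loci[j, ])
  for (grp in unique(stats::na.omit(loci$class_group))) {
    rows <- which(!is.na(loci$class_group) & loci$class_group == grp)
    or1 <- loci$class_or_1[rows[1]]; or2 <- loci$class_or_2[rows[1]]
    dg <- d[rows, , drop = FALSE]
    obs <- colSums(dg, na.rm = TRUE)
    n_miss <- colSums(is.na(dg))
    contrib <- .class_lor(obs, or1, or2)
    for (s in which(n_miss > 0)) {
      miss_rafs <- loci$raf[rows][is.na(dg[, s])]
      contrib[s] <- .class_expected(obs[s], miss_rafs, or1, or2)
    }
    score <- score + contrib
  }
  n_obs <- colSums(!is.na(d))
  out <- data.frame(id = gm$samples, score = score,
                    n_loci_observed = n_obs,
                    n_loci_imputed = nrow(loci) - n_obs,
                    low_coverage = n_obs < 0.5 * nrow(loci),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[n_obs > 0, , drop = FALSE]
  class(out) <- c("GRSProfile", "data.frame")
  out
}

# Genotype distribution at one additive locus among cases:
# P(g | case) proportional to HWE(g; raf) * OR^g.
.case_geno_probs <- function(raf, or) {
  g <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2) * or^(0:2)
  g / sum(g)
}

# Combined-count distribution for a genotype-class group among controls
# (HWE) or cases (reweighted by the class OR).
.class_count_probs <- function(rafs, or1, or2, case = FALSE) {
  probs <- 1
  for (p in rafs) {
    g <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    new <- rep(0, length(probs) + 2)
    for (d in 0:2) new[seq_along(probs) + d] <- new[seq_along(probs) + d] +
        probs * g[d + 1]
    probs <- new
  }
  if (case) {
    w <- exp(.class_lor(seq_along(probs) - 1, or1, or2))
    probs <- probs * w / sum(probs * w)
  }
  probs
}

#' Simulate reference case/control score distributions
#'
#' Draws `n` control and `n` case genotype profiles from the risk-locus
#' table: controls per-locus from HWE at the risk-allele frequency, cases
#' from P(g | case) proportional to P(g | HWE) * OR(g). Scores are computed
#' as in [compute_grs()].
#'
#' @param loci a `RiskLocusTable`
#' @param n number of simulated individuals per group (default 1000)
#' @param seed RNG seed (required, for reproducibility)
#' @return list with numeric vectors `case` and `control` of length `n`
#' @export
simulate_reference <- function(loci, n = 1000L, seed) {
  stopifnot(inherits(loci, "RiskLocusTable"), n >= 1)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  control <- numeric(n); case <- numeric(n)
  add <- which(loci$model == "additive")
  for (j in add) {
    p <- loci$raf[j]; lor <- log(loci$or_per_allele[j])
    control <- control + stats::rbinom(n, 2, p) * lor
    gcase <- sample(0:2, n, replace = TRUE,
                    prob = .case_geno_probs(p, loci$or_per_allele[j]))
    case <- case + gcase * lor
  }
  for (grp in unique(stats::na.omit(loci$class_group))) {
    rows <- which(!is.na(loci$class_group) & loci$class_group == grp)
    or1 <- loci$class_or_1[rows[1]]; or2 <- loci$class_or_2[rows[1]]
    pc <- .class_count_probs(loci$raf[rows], or1, or2, case = FALSE)
    pa <- .class_count_probs(loci$raf[rows], or1, or2, case = TRUE)
    counts_ctl <- sample(seq_along(pc) - 1L, n, replace = TRUE, prob = pc)
    counts_cas <- sample(seq_along(pa) - 1L, n, replace = TRUE, prob = pa)
    control <- control + .class_lor(counts_ctl, or1, or2)
    case <- case + .class_lor(counts_cas, or1, or2)
  }
  list(case = case, control = control)
}

#' Compare genetic risk scores between groups
#'
#' Pairwise two-sided Mann-Whitney-Wilcoxon tests between all non-empty
#' groups, plus fold-differences of each group against a reference
#' distribution. Because scores are log odds, the fold-difference is
#' reported both as `exp(median(A) - median(ref))` and as the ratio of raw
#' medians.
#'
#' @param scores numeric vector of scores
#' @param groups group label per score (NA dropped)
#' @param reference optional numeric vector of reference scores (e.g. the
#'   simulated control or case distribution) for fold-differences
#' @return list with `pairwise` (data.frame: group_a, group_b, p, n_a, n_b)
#'   and `folds` (data.frame: group, median, fold_exp, fold_ratio; NULL
#'   when no reference given)
#' @export
compare_grs_groups <- function(scores, groups, reference = NULL) {
  keep <- !is.na(groups) & !is.na(scores)
  scores <- scores[keep]; groups <- as.character(groups[keep])
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least 2 non-empty groups")
  combs <- utils::combn(gl, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    a <- scores[groups == combs[1, k]]
    b <- scores[groups == combs[2, k]]
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    data.frame(group_a = combs[1, k], group_b = combs[2, k], p = p,
               n_a = length(a), n_b = length(b), stringsAsFactors = FALSE)
  }))
  folds <- NULL
  if (!is.null(reference)) {
    mref <- stats::median(reference)
    folds <- do.call(rbind, lapply(gl, function(g) {
      mg <- stats::median(scores[groups == g])
      data.frame(group = g, median = mg,
                 fold_exp = exp(mg - mref),
                 fold_ratio = if (mref != 0) mg / mref else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(pairwise = pw, folds = folds)
}
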