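add_loci <- function(ors, rafs = rep(0.3, length(ors))) {
  risk_locus_table(data.frame(
    id = paste0("L", seq_along(ors)), raf = rafs, or_per_allele = ors,
    model = "additive", stringsAsFactors = FALSE))
}

grs_gm <- function(dosage, loci_ids, samples) {
  genotype_matrix(
    data.frame(chrom = "risk", pos = seq_along(loci_ids), id = loci_ids,
               ref = "A", alt = "G"),
    dosage, samples = samples)
}

test_that("locus contributions follow the additive log-odds model", {
  loci <- add_loci(c(1.5, 2))
  expect_equal(locus_contribution(0, loci[1, ]), 0)
  expect_equal(locus_contribution(2, loci[1, ]), 2 * log(1.5))
  # missing dosage contributes its HWE expectation 2*raf*log(OR)
  expect_equal(locus_contribution(NA, loci[1, ]), 2 * 0.3 * log(1.5))
})

test_that("compute_grs sums contributions and is order/split invariant", {
  loci <- add_loci(c(2, 1.5))
  d <- rbind(c(0L, 1L), c(0L, 2L))   # a: (0,0); b: (1,2)
  colnames(d) <- c("a", "b")
  gm <- grs_gm(d, loci$id, c("a", "b"))
  prof <- compute_grs(gm, loci)
  expect_equal(prof$score[prof$id == "a"], 0)
  expect_equal(prof$score[prof$id == "b"], log(2) + 2 * log(1.5))

  # permuting locus order leaves scores unchanged
  perm <- loci[2:1, ]
  class(perm) <- class(loci)
  gm_perm <- grs_gm(d[2:1, , drop = FALSE], perm$id, c("a", "b"))
  expect_equal(compute_grs(gm_perm, perm)$score, prof$score)

  # splitting the table and summing partial scores is a no-op
  s1 <- compute_grs(gm, {x <- loci[1, ]; class(x) <- class(loci); x})
  s2 <- compute_grs(gm, {x <- loci[2, ]; class(x) <- class(loci); x})
  expect_equal(s1$score + s2$score, prof$score)
})

test_that("genotype-class groups score a single class contribution", {
  loci <- risk_locus_table(data.frame(
    id = c("n1", "n2", "n3"), raf = c(0.05, 0.02, 0.03),
    or_per_allele = NA_real_, model = "genotype_class",
    class_or_1 = 3, class_or_2 = 17, class_group = "NOD2",
    stringsAsFactors = FALSE))
  # compound heterozygote (one copy each of two variants): the ">=2" class
  # once, not a sum of per-variant terms
  d <- matrix(c(1L, 1L, 0L,   # compound het
                1L, 0L, 0L,   # single carrier
                2L, 0L, 0L,   # homozygote
                0L, 0L, 0L),  # none
              3, 4, dimnames = list(NULL, c("cpd", "single", "hom", "none")))
  gm <- grs_gm(d, loci$id, colnames(d))
  prof <- compute_grs(gm, loci)
  s <- setNames(prof$score, prof$id)
  expect_equal(unname(s["cpd"]), log(17))
  expect_equal(unname(s["hom"]), log(17))
  expect_equal(unname(s["single"]), log(3))
  expect_equal(unname(s["none"]), 0)
  # class ORs are mandatory configuration
  expect_error(risk_locus_table(data.frame(
    id = "n1", raf = 0.05, model = "genotype_class",
    stringsAsFactors = FALSE)), "class_or")
})

test_that("simulated case genotypes follow the Bayes-reweighted HWE law", {
  loci1 <- add_loci(2, rafs = 0.5)
  ref <- simulate_reference(loci1, n = 20000, seed = 4)
  # brute-force oracle over the 3 genotypes: P(g|case) ~ HWE(g) * OR^g
  pg <- c(0.25 * 1, 0.5 * 2, 0.25 * 4)
  pg <- pg / sum(pg)
  emp1 <- mean(ref$case == log(2))
  emp2 <- mean(ref$case == 2 * log(2))
  se <- sqrt(pg * (1 - pg) / 20000)
  expect_lt(abs(emp1 - pg[2]), 3 * se[2])
  expect_lt(abs(emp2 - pg[3]), 3 * se[3])
  # control scores match the closed-form mean
  expect_lt(abs(mean(ref$control) - 2 * 0.5 * log(2)), 0.02)
})

test_that("null reference distributions coincide; stronger ORs raise cases", {
  set.seed(44)
  null_loci <- add_loci(rep(1, 10), rafs = runif(10, 0.1, 0.9))
  ref <- simulate_reference(null_loci, n = 2000, seed = 6)
  expect_equal(median(ref$case), 0)
  expect_equal(median(ref$control), 0)

  loci <- add_loci(rep(1.3, 10))
  strong <- add_loci(rep(2.6, 10))
  r1 <- simulate_reference(loci, n = 1000, seed = 7)
  r2 <- simulate_reference(strong, n = 1000, seed = 7)
  expect_gt(median(r2$case), median(r1$case))
  # reproducible given seed
  r1b <- simulate_reference(loci, n = 1000, seed = 7)
  expect_identical(r1, r1b)
})

test_that("group comparison uses the exact two-sided rank-sum test", {
  cmp <- compare_grs_groups(c(1, 2, 3, 4, 5, 6),
                            c("a", "a", "a", "b", "b", "b"))
  expect_equal(cmp$pairwise$p, 0.1)   # 2 * (1 / choose(6,3)) ... enumerated
  same <- compare_grs_groups(c(1, 2, 3, 1, 2, 3),
                             c("a", "a", "a", "b", "b", "b"))
  expect_gt(same$pairwise$p, 0.99)
  expect_error(compare_grs_groups(1:3, rep("a", 3)), "2 non-empty groups")

  # fold-differences on the log-odds scale
  cmp2 <- compare_grs_groups(c(1, 1, 2, 2), c("x", "x", "y", "y"),
                             reference = c(0, 0))
  folds <- setNames(cmp2$folds$fold_exp, cmp2$folds$group)
  expect_equal(unname(folds["y"]), exp(2))
})

test_that("liability-simulated pedigrees show the expected GRS ordering", {
  cfg <- sim_config(generations = 4, mean_sibship = 6, reproduce_prob = 0.8,
                    n_snps_per_chrom = 10, n_risk_loci = 127,
                    risk_or_range = c(1.1, 1.6), phenocopy_rate = 0,
                    seed = 21)
  ped <- simulate_pedigree_structure(cfg)
  risk <- simulate_risk_loci(ped, cfg)
  phen <- assign_phenotypes(ped, risk, NULL, cfg)
  ped$affection <- unname(phen$affection[ped$id])
  prof <- compute_grs(risk$gm, risk$loci)
  med <- tapply(prof$score, classify_fidr(ped)[prof$id], median)
  expect_gt(med[["affected"]], med[["unaffected+aFiDR"]])
  expect_gt(med[["unaffected+aFiDR"]], med[["unaffected-aFiDR"]])
})

test_that("rare-variant-driven families show a flat GRS (no case excess)", {
  # affection driven by a rare penetrant variant, not the common loci: the
  # case-vs-unaffected+aFiDR comparison should be non-significant
  ped <- balanced_pedigree(3, 5)
  cfg <- flow_test_config(seed = 15,
                          causal = list(list(chrom = 1, cM = 50,
                                             founder = "F1", side = "A",
                                             or = 500)))
  ds <- simulate_dataset(cfg, ped = ped)
  prof <- compute_grs(ds$risk$gm, ds$risk$loci)
  grp <- classify_fidr(ds$ped)[prof$id]
  keep <- grp %in% c("affected", "unaffected+aFiDR")
  cmp <- compare_grs_groups(prof$score[keep], grp[keep])
  expect_gt(cmp$pairwise$p, 0.05)
})
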