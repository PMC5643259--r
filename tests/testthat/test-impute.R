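# A hand-built flow for label-assignment unit tests: 4 individuals, 3 loci
# on one chromosome; labels fixed by construction.
toy_flow <- function() {
  ids <- c("a", "b", "c", "d")
  pat <- matrix(c("F3|A", "F3|A", "F3|A",
                  "F3|A", "F3|A", "F3|A",
                  "F4|A", "F4|A", "F4|A",
                  "F4|B", "F4|B", "F4|B"),
                4, 3, byrow = TRUE, dimnames = list(ids, NULL))
  mat <- matrix(c("F5|B", "F5|B", "F5|B",
                  "F5|B", "F5|B", "F5|B",
                  "F5|A", "F5|A", "F5|A",
                  "F5|A", "F5|A", "F5|A"),
                4, 3, byrow = TRUE, dimnames = list(ids, NULL))
  structure(list(
    ids = ids,
    loci = data.frame(chrom = "1", pos = c(100, 200, 300), cM = 0:2),
    pat = pat, mat = mat,
    pat_allele = matrix(NA_integer_, 4, 3),
    mat_allele = matrix(NA_integer_, 4, 3),
    confidence = matrix(1, 4, 3)), class = "HaplotypeFlow")
}

test_that("assign_founder_haplotype finds minimal separating label sets", {
  fl <- toy_flow()
  # single het carrier "a": only F3|A separates a from the non-carriers
  res <- assign_founder_haplotype(fl, list(
    chrom = "1", pos = 200, dosages = c(a = 1, c = 0, d = 0)))
  expect_false(res$conflict)
  expect_equal(res$labels, "F3|A")

  # two carriers sharing F3|A, non-carriers lacking it
  res2 <- assign_founder_haplotype(fl, list(
    chrom = "1", pos = 200, dosages = c(a = 1, b = 1, c = 0, d = 0)))
  expect_equal(res2$labels, "F3|A")

  # carriers with disjoint labels while non-carriers cover both: conflict
  res3 <- assign_founder_haplotype(fl, list(
    chrom = "1", pos = 200, dosages = c(a = 1, d = 1, b = 0, c = 0)))
  expect_true(res3$conflict)
})

test_that("impute_from_flow counts assigned labels and keeps observations", {
  fl <- toy_flow()
  carriage <- list(chrom = "1", pos = 200, dosages = c(a = 1, c = 0))
  res <- assign_founder_haplotype(fl, carriage)
  imp <- impute_from_flow(fl, res, carriage)
  got <- setNames(imp$dosage, imp$id)
  expect_equal(unname(got["b"]), 1L)   # b carries F3|A
  expect_equal(unname(got["d"]), 0L)   # d carries neither label
  expect_equal(unname(got["a"]), 1L)   # observed, untouched
  expect_false(imp$imputed[imp$id == "a"])
  expect_true(imp$imputed[imp$id == "b"])
  # conflict input refuses to impute
  bad <- assign_founder_haplotype(fl, list(
    chrom = "1", pos = 200, dosages = c(a = 1, d = 1, b = 0, c = 0)))
  expect_error(impute_from_flow(fl, bad, carriage), "conflict")
})

test_that("imputation is a fixed point when imputed calls become observed", {
  fl <- toy_flow()
  carriage <- list(chrom = "1", pos = 200, dosages = c(a = 1, c = 0))
  res <- assign_founder_haplotype(fl, carriage)
  imp <- impute_from_flow(fl, res, carriage)
  carriage2 <- list(chrom = "1", pos = 200,
                    dosages = setNames(imp$dosage, imp$id))
  res2 <- assign_founder_haplotype(fl, carriage2)
  expect_false(res2$conflict)
  expect_equal(res2$labels, res$labels)
  imp2 <- impute_from_flow(fl, res2, carriage2)
  expect_equal(imp2$dosage, imp$dosage)
})

test_that("flow-based imputation matches gene-drop truth", {
  ped <- balanced_pedigree(3, 5)
  cfg <- flow_test_config(seed = 5)
  gd <- gene_drop(ped, cfg)
  fl <- reconstruct_flow(ped, gd$gm, gd$map)
  set.seed(11)
  correct <- 0; total <- 0
  for (rep in 1:12) {
    l <- sample(20:180, 1)
    lab <- sample(paste0(ped$id[is_founder(ped)][1:4], "|A"), 1)
    truth <- (gd$truth$pat[, l] == lab) + (gd$truth$mat[, l] == lab)
    seqd <- sample(ped$id, round(0.6 * nrow(ped)))
    if (!any(truth[seqd] >= 1)) next
    carr <- list(chrom = "1", pos = gd$map$pos[l],
                 dosages = setNames(
                   ifelse(ped$id %in% seqd, truth, NA_integer_), ped$id))
    asg <- assign_founder_haplotype(fl, carr)
    if (asg$conflict) next
    imp <- impute_from_flow(fl, asg$labels, carr)
    nonseq <- setdiff(ped$id, seqd)
    got <- imp$dosage[match(nonseq, imp$id)]
    ok <- !is.na(got)
    correct <- correct + sum(got[ok] == truth[nonseq][ok])
    total <- total + sum(ok)
  }
  expect_gt(total, 100)
  expect_gt(correct / total, 0.95)
})

test_that("conflict rate grows with injected genotyping error", {
  ped <- balanced_pedigree(3, 4)
  cfg <- flow_test_config(seed = 19)
  gd <- gene_drop(ped, cfg)
  fl <- reconstruct_flow(ped, gd$gm, gd$map)
  conflict_rate <- vapply(c(0, 0.25), function(err) {
    set.seed(31)
    fails <- 0; tries <- 0
    for (rep in 1:30) {
      l <- sample(30:170, 1)
      lab <- sample(paste0(ped$id[is_founder(ped)][1:4],
                           "|", c("A", "B")), 1)
      truth <- (gd$truth$pat[, l] == lab) + (gd$truth$mat[, l] == lab)
      obs <- truth
      flip <- runif(length(obs)) < err
      obs[flip] <- ifelse(obs[flip] >= 1, 0L, 1L)
      if (!any(obs >= 1)) next
      carr <- list(chrom = "1", pos = gd$map$pos[l],
                   dosages = setNames(obs, ped$id))
      tries <- tries + 1
      if (assign_founder_haplotype(fl, carr)$conflict) fails <- fails + 1
    }
    fails / max(tries, 1)
  }, numeric(1))
  expect_gt(conflict_rate[2], conflict_rate[1])
})
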