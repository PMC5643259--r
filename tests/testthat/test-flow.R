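test_that("a fully informative nuclear family has a forced flow", {
  ped <- nuclear_ped(2)
  # founders carry distinct homozygous/heterozygous patterns making every
  # transmission unambiguous at both markers
  variants <- data.frame(chrom = "1", pos = c(1000, 2000), ref = "A",
                         alt = "G")
  # marker 1: f=1 (A|G phased by kids), m=0; marker 2: f=0, m=1
  d <- rbind(c(1L, 0L, 1L, 0L),
             c(0L, 1L, 1L, 0L))
  gm <- genotype_matrix(variants, d,
                        samples = c("f", "m", "k1", "k2"))
  map <- marker_map(c("1", "1"), c(1000, 2000), c(0, 1))
  fl <- reconstruct_flow(ped, gm, map, max_bits = 8)
  # k1 carries f's alt at marker 1 and m's alt at marker 2; k2 neither
  expect_true(all(fl$pat["f", ] == "f|A"))
  expect_true(all(fl$mat["f", ] == "f|B"))
  k1pat <- fl$pat["k1", ]
  k2pat <- fl$pat["k2", ]
  # the two sibs inherited different paternal haplotypes at marker 1
  expect_true(k1pat[1] != k2pat[1])
  # allele content at marker 1 must match genotypes
  expect_equal(unname(fl$pat_allele["k1", 1] + fl$mat_allele["k1", 1]), 1L)
  expect_equal(unname(fl$pat_allele["k2", 1] + fl$mat_allele["k2", 1]), 0L)
})

test_that("flow invariants hold: founder labels constant, children reachable", {
  ped <- balanced_pedigree(3, 4)
  cfg <- flow_test_config(seed = 3)
  gd <- gene_drop(ped, cfg)
  fl <- reconstruct_flow(ped, gd$gm, gd$map)
  founders <- ped$id[is_founder(ped)]
  for (f in founders) {
    expect_length(unique(fl$pat[f, ]), 1)
    expect_length(unique(fl$mat[f, ]), 1)
  }
  # each non-founder label is one of the corresponding parent's two labels
  nonf <- ped$id[!is_founder(ped)]
  for (i in nonf) {
    fa <- ped$father[ped$id == i]
    ok <- fl$pat[i, ] == fl$pat[fa, ] | fl$pat[i, ] == fl$mat[fa, ]
    expect_true(all(ok[!is.na(ok)]))
  }
})

test_that("flow reconstruction matches gene-drop truth on a 3-gen pedigree", {
  ped <- balanced_pedigree(3, 5)
  cfg <- flow_test_config(seed = 5)
  gd <- gene_drop(ped, cfg)
  fl <- reconstruct_flow(ped, gd$gm, gd$map)
  expect_gt(flow_slot_accuracy(gd$truth, fl, ped), 0.95)
})

test_that("splitting then reassembling equals unsplit inference", {
  ped <- three_gen_ped(1, 3)   # bits 11: tractable whole and in chunks
  cfg <- flow_test_config(seed = 9)
  gd <- gene_drop(ped, cfg)
  whole <- reconstruct_flow(ped, gd$gm, gd$map, max_bits = 16,
                            max_meioses = 16)
  split <- reconstruct_flow(ped, gd$gm, gd$map, max_bits = 4,
                            max_meioses = 8)
  agree <- mean(whole$pat == split$pat & whole$mat == split$mat,
                na.rm = TRUE)
  expect_gt(agree, 0.98)
})

test_that("flow accuracy does not degrade with denser markers", {
  # paired design: the same gene-dropped chromosome decoded from the full
  # panel versus a 1-in-4 thinning, scored at the shared loci
  ped <- balanced_pedigree(3, 4)
  cfg <- flow_test_config(seed = 13)
  gd <- gene_drop(ped, cfg)
  thin <- seq(1, 200, by = 4)
  gm_thin <- pedflow:::subset_gm(gd$gm, variants = thin)
  fl_full <- reconstruct_flow(ped, gd$gm, gd$map)
  fl_thin <- reconstruct_flow(ped, gm_thin, gd$map)
  acc_full <- flow_slot_accuracy(gd$truth, fl_full, ped,
                                 truth_cols = thin, fl_cols = thin)
  acc_thin <- flow_slot_accuracy(gd$truth, fl_thin, ped,
                                 truth_cols = thin)
  expect_gte(acc_full, acc_thin - 0.005)
})

test_that("max haplotype sharing counts distinct cases per founder label", {
  ped <- balanced_pedigree(3, 4)
  cfg <- flow_test_config(seed = 7)
  gd <- gene_drop(ped, cfg)
  # cases = carriers of F1|A at locus 100 (truth): sharing there equals the
  # case count
  lab <- "F1|A"
  carriers <- ped$id[gd$truth$pat[, 100] == lab |
                       gd$truth$mat[, 100] == lab]
  ms <- max_haplotype_sharing(gd$truth, carriers)
  expect_equal(ms$per_locus$max_shared[100], length(carriers))
  expect_equal(ms$per_locus$label[100], lab)
  expect_equal(ms$genome_max, max(ms$per_locus$max_shared))

  # all-unknown flow: zero sharing
  blank <- gd$truth
  blank$pat[] <- NA_character_; blank$mat[] <- NA_character_
  expect_equal(max_haplotype_sharing(blank, carriers)$genome_max, 0L)

  # absent cases are dropped with a warning
  expect_warning(max_haplotype_sharing(gd$truth, c(carriers, "ghost")),
                 "ghost")
})

test_that("flow files round-trip the long format", {
  ped <- nuclear_ped(2)
  cfg <- sim_config(n_snps_per_chrom = 10, n_risk_loci = 2, seed = 2)
  gd <- gene_drop(ped, cfg)
  path <- tempfile(fileext = ".tsv")
  write_flow(gd$truth, path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(tab), nrow(ped) * 10)
  expect_equal(sort(unique(tab$individual)), sort(ped$id))
  k1 <- tab[tab$individual == "k1", ]
  expect_equal(k1$label_paternal, unname(gd$truth$pat["k1", ]))
})
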