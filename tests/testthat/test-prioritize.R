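ann_row <- function(chrom = "1", pos = 1000, consequence = "missense",
                    carol = FALSE, condel = FALSE, cadd = 10,
                    freq_exac = 0.001, localfreq_panel = 0.001,
                    case_missing_A = 0L, carriers = 5L, genotyped = 10L,
                    ref = "C", alt = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = paste0("G", pos), consequence = consequence,
             deleterious_carol = carol, deleterious_condel = condel,
             cadd = cadd, freq_exac = freq_exac,
             localfreq_panel = localfreq_panel,
             case_missing_A = case_missing_A,
             case_carriers_A = carriers, case_genotyped_A = genotyped,
             stringsAsFactors = FALSE)
}

test_that("consequence filter keeps severe classes and damaging missense", {
  cfg <- filter_config()
  keep1 <- consequence_filter(ann_row(consequence = "frameshift", cadd = 5),
                              cfg)
  expect_true(keep1)
  keep2 <- consequence_filter(
    ann_row(consequence = "missense", carol = FALSE, condel = FALSE,
            cadd = 19), cfg)
  expect_false(keep2)
  # the CADD clause attaches to missense, not synonymous
  keep3 <- consequence_filter(ann_row(consequence = "synonymous",
                                      cadd = 30), cfg)
  expect_false(keep3)
  keep4 <- consequence_filter(ann_row(consequence = "missense", cadd = 21),
                              cfg)
  expect_true(keep4)
  keep5 <- consequence_filter(ann_row(consequence = "missense",
                                      condel = TRUE, cadd = 1), cfg)
  expect_true(keep5)
  expect_warning(consequence_filter(ann_row(consequence = NA), cfg),
                 "without consequence")
  # any transcript sufficing: two rows of one variant
  two <- rbind(ann_row(consequence = "synonymous"),
               ann_row(consequence = "splice_donor"))
  expect_true(consequence_filter(two, cfg))
})

test_that("frequency filter uses strict inequalities per source", {
  cfg <- filter_config()
  expect_false(frequency_filter(ann_row(freq_exac = 0.03), cfg))
  expect_true(frequency_filter(ann_row(freq_exac = 0.02,
                                       localfreq_panel = 0.04), cfg))
  expect_true(frequency_filter(ann_row(freq_exac = 0.025), cfg))  # boundary
  expect_false(frequency_filter(ann_row(localfreq_panel = 0.051), cfg))
  expect_true(frequency_filter(ann_row(freq_exac = NA), cfg))     # missing
})

test_that("missingness filter applies the per-family case limits", {
  cfg <- filter_config()
  expect_false(missingness_filter(ann_row(case_missing_A = 21L), cfg, "A"))
  expect_true(missingness_filter(ann_row(case_missing_A = 20L), cfg, "A"))
  b11 <- ann_row(case_missing_A = 11L)
  names(b11)[names(b11) == "case_missing_A"] <- "case_missing_B"
  expect_false(missingness_filter(b11, cfg, "B"))
  b10 <- ann_row(case_missing_A = 10L)
  names(b10)[names(b10) == "case_missing_A"] <- "case_missing_B"
  expect_true(missingness_filter(b10, cfg, "B"))
  expect_error(missingness_filter(ann_row(), cfg, "Z"), "family Z")
})

test_that("sharing prioritization reproduces the printed carrier fractions", {
  cfg <- filter_config()
  v <- rbind(ann_row(carriers = 8L, genotyped = 9L),     # 0.889
             ann_row(pos = 2000, carriers = 15L, genotyped = 19L),  # 0.789
             ann_row(pos = 3000, carriers = 5L, genotyped = 10L))   # 0.5
  sh <- sharing_prioritize(v, "A", cfg)
  expect_equal(round(sh$sharing[, "A"], 3), c(0.889, 0.789, 0.5))
  expect_equal(sh$prioritized, c(TRUE, TRUE, FALSE))
})

test_that("variants rank by minimum P across units with coordinate ties", {
  v <- rbind(ann_row(pos = 100), ann_row(pos = 50), ann_row(pos = 70))
  p <- cbind(A = c(0.014, 0.3, 0.3), A0 = c(6.1e-5, NA, 0.3))
  r <- rank_variants(v, p)
  expect_equal(r$pos, c(100, 50, 70))
  expect_equal(r$min_p[1], 6.1e-5)
  expect_equal(r$min_p_unit[1], "A0")
  expect_equal(r$min_p[2:3], c(0.3, 0.3))   # tie broken by coordinate
  # a variant with no computable P ranks last and is flagged
  p2 <- cbind(A = c(0.5, NA, 0.1))
  r2 <- rank_variants(v, p2)
  expect_equal(r2$pos, c(70, 100, 50))
  expect_true(r2$no_p[3])
})

test_that("the cascade matches a set-arithmetic oracle and is order-stable", {
  # constructed table: every failure mode represented
  tab <- rbind(
    ann_row(pos = 1, consequence = "frameshift"),                 # survives
    ann_row(pos = 2, consequence = "missense", condel = TRUE),    # survives
    ann_row(pos = 3, consequence = "synonymous", cadd = 40),      # class
    ann_row(pos = 4, freq_exac = 0.3, consequence = "stop_gained"),  # freq
    ann_row(pos = 5, consequence = "stop_gained",
            case_missing_A = 25L),                                # missing
    ann_row(chrom = "X", pos = 6, consequence = "stop_gained"),   # autosome
    ann_row(pos = 7, consequence = "frameshift", carriers = 2L))  # sharing
  casc <- variant_cascade(tab, filter_config(), family = "A", units = "A")
  # independent set-arithmetic oracle
  keep_cons <- tab$consequence %in% c("frameshift", "stop_gained") |
    (tab$consequence == "missense" &
       (tab$deleterious_carol | tab$deleterious_condel | tab$cadd > 20))
  keep_freq <- !(tab$freq_exac > 0.025 | tab$localfreq_panel > 0.05)
  keep_miss <- tab$case_missing_A <= 20
  keep_auto <- tab$chrom %in% as.character(1:22)
  keep_all <- keep_cons & keep_freq & keep_miss & keep_auto
  prio <- keep_all & (tab$case_carriers_A / tab$case_genotyped_A >= 0.6)
  expect_equal(unname(casc$counts["input"]), nrow(tab))
  expect_equal(unname(casc$counts["missingness"]), sum(keep_all))
  expect_equal(unname(casc$counts["prioritized"]), sum(prio))
  expect_equal(sort(casc$variants$pos), sort(tab$pos[prio]))

  # exclusion filters are pure conjunctions: permuting rows cannot change
  # the surviving set
  set.seed(4)
  perm <- tab[sample(nrow(tab)), ]
  casc2 <- variant_cascade(perm, filter_config(), family = "A", units = "A")
  expect_setequal(casc2$variants$pos, casc$variants$pos)
})
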