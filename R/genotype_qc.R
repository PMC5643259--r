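#' SNP quality-control filter
#'
#' Removes SNPs with call missingness above `miss_max`, minor allele
#' frequency below `maf_min`, or Hardy-Weinberg deviation among founders at
#' a 1-df chi-squared P value below `hwe_p_min`. Missingness and MAF are
#' computed over all samples; the HWE test uses founder genotype counts
#' only (observed vs expected AA/Aa/aa under HWE at the founder allele
#' frequency, no continuity correction). SNPs with no called founders skip
#' the HWE filter and are logged in the report.
#'
#' @param gm a `GenotypeMatrix`
#' @param ped a `Pedigree` identifying founders (samples absent from the
#'   pedigree are ignored for HWE)
#' @param miss_max maximum fraction of missing calls (default 0.01)
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param hwe_p_min minimum founder HWE P value (default 1e-5)
#' @return list with `gm` (filtered `GenotypeMatrix`) and `report` (a
#'   `QcReport`: per-filter removal counts and thresholds)
#' @export
snp_qc_filter <- function(gm, ped, miss_max = 0.01, maf_min = 0.01,
                          hwe_p_min = 1e-5) {
  stopifnot(miss_max > 0, miss_max < 1, maf_min > 0, maf_min < 1)
  d <- gm$dosage
  missing_frac <- rowMeans(is.na(d))
  af <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(af)] <- 0

  founder_ids <- intersect(ped$id[is_founder(ped)], gm$samples)
  hwe_p <- rep(NA_real_, nrow(d))
  if (length(founder_ids)) {
    fd <- d[, founder_ids, drop = FALSE]
    n0 <- rowSums(fd == 0L, na.rm = TRUE)
    n1 <- rowSums(fd == 1L, na.rm = TRUE)
    n2 <- rowSums(fd == 2L, na.rm = TRUE)
    hwe_p <- hwe_chisq_p(n0, n1, n2)
  }
  no_founder_calls <- is.na(hwe_p)

  fail_miss <- missing_frac > miss_max
  fail_maf <- maf < maf_min
  fail_hwe <- !no_founder_calls & hwe_p < hwe_p_min
  keep <- !(fail_miss | fail_maf | fail_hwe)

  report <- structure(list(
    n_input = nrow(d), n_output = sum(keep),
    removed_missingness = sum(fail_miss),
    removed_maf = sum(fail_maf & !fail_miss),
    removed_hwe = sum(fail_hwe & !fail_miss & !fail_maf),
    hwe_skipped_no_founders = sum(no_founder_calls),
    thresholds = c(miss_max = miss_max, maf_min = maf_min,
                   hwe_p_min = hwe_p_min)), class = "QcReport")
  list(gm = subset_gm(gm, variants = which(keep)), report = report)
}

#' Hardy-Weinberg 1-df chi-squared P value from genotype counts
#' @param n0,n1,n2 counts of reference-homozygous, heterozygous and
#'   alternate-homozygous genotypes (vectorized)
#' @return P values (NA where no genotypes)
#' @export
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  chi <- rep(NA_real_, length(n))
  ok <- n > 0 & p > 0 & p < 1
  chi[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] + (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  chi[n > 0 & !ok] <- 0   # monomorphic in founders: no deviation testable
  stats::pchisq(chi, df = 1, lower.tail = FALSE)
}

#' @export
print.QcReport <- function(x, ...) {
  cat("SNP QC: ", x$n_input, " -> ", x$n_output, " variants\n",
      "  removed: missingness ", x$removed_missingness,
      ", MAF ", x$removed_maf, ", founder HWE ", x$removed_hwe, "\n",
      "  HWE skipped (no founder calls): ", x$hwe_skipped_no_founders, "\n",
      sep = "")
  invisible(x)
}

#' Write a QC report as a tab-delimited log
#' @param report a `QcReport`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_qc_report <- function(report, path) {
  fields <- c("n_input", "n_output", "removed_missingness", "removed_maf",
              "removed_hwe", "hwe_skipped_no_founders")
  tab <- data.frame(field = c(fields, names(report$thresholds)),
                    value = c(unlist(report[fields]), report$thresholds))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

# Duo/trio Mendelian conflict detection. Returns a logical matrix (variants x
# samples) marking genotypes to zero. Trio rules for dosages: child 2 with a
# parent 0 (or child 0 with a parent 2) implicates child + that parent; child
# het with both parents 0 or both 2 implicates all three.
.mendel_conflicts <- function(gm, ped) {
  d <- gm$dosage
  zero <- matrix(FALSE, nrow(d), ncol(d), dimnames = dimnames(d))
  kids <- ped$id[!is.na(ped$father)]
  for (k in kids) {
    if (!(k %in% gm$samples)) next
    fa <- ped$father[ped$id == k]
    mo <- ped$mother[ped$id == k]
    ck <- d[, k]
    gfa <- if (fa %in% gm$samples) d[, fa] else rep(NA_integer_, nrow(d))
    gmo <- if (mo %in% gm$samples) d[, mo] else rep(NA_integer_, nrow(d))
    conf_fa <- !is.na(ck) & !is.na(gfa) & abs(ck - gfa) == 2L
    conf_mo <- !is.na(ck) & !is.na(gmo) & abs(ck - gmo) == 2L
    conf_both <- !is.na(ck) & ck == 1L & !is.na(gfa) & !is.na(gmo) &
      gfa == gmo & gfa != 1L
    zero[conf_fa | conf_mo | conf_both, k] <- TRUE
    if (fa %in% gm$samples) zero[conf_fa | conf_both, fa] <- TRUE
    if (mo %in% gm$samples) zero[conf_mo | conf_both, mo] <- TRUE
  }
  zero
}

#' Zero Mendelian-inconsistent genotypes
#'
#' Detects duo and trio Mendelian inconsistencies and sets the child and
#' the implicated parent(s) to missing at the conflicting SNP. Consistent
#' genotypes are untouched.
#'
#' @param gm a `GenotypeMatrix`
#' @param ped a `Pedigree`
#' @return list with `gm` (cleaned matrix) and `n_errors` (number of
#'   conflicting (SNP, child) events detected)
#' @export
mendelian_zero <- function(gm, ped) {
  zero <- .mendel_conflicts(gm, ped)
  kid_cols <- intersect(ped$id[!is.na(ped$father)], gm$samples)
  n_err <- sum(zero[, kid_cols, drop = FALSE])
  gm$dosage[zero] <- NA_integer_
  list(gm = gm, n_errors = n_err)
}

#' Deterministic Mendelian fill-in of missing child genotypes
#'
#' Populates a child's missing call when it is forced by the parents:
#' both parents homozygous reference -> 0; both homozygous alternate -> 2;
#' one 0 and one 2 -> 1 (obligate heterozygote). All other configurations
#' are left missing. Apply after [mendelian_zero()].
#'
#' @param gm a `GenotypeMatrix`
#' @param ped a `Pedigree`
#' @return a `GenotypeMatrix` with forced calls filled in
#' @export
mendelian_fill <- function(gm, ped) {
  d <- gm$dosage
  kids <- ped$id[!is.na(ped$father)]
  for (k in kids) {
    if (!(k %in% gm$samples)) next
    fa <- ped$father[ped$id == k]
    mo <- ped$mother[ped$id == k]
    if (!(fa %in% gm$samples) || !(mo %in% gm$samples)) next
    gfa <- d[, fa]; gmo <- d[, mo]
    forced <- is.na(d[, k]) & !is.na(gfa) & !is.na(gmo) &
      gfa != 1L & gmo != 1L
    d[forced, k] <- as.integer((gfa[forced] + gmo[forced]) / 2)
  }
  gm$dosage <- d
  gm
}
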