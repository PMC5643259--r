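# Exome variant filter cascade and prioritization. Operates on a
# tab-delimited annotation table, one row per (variant, transcript):
#   chrom, pos, ref, alt, gene, consequence, deleterious_carol,
#   deleterious_condel (logical), cadd (phred), pop-frequency columns
#   (prefix "freq_", e.g. freq_exac_nfe, freq_1kg_eur; local reference
#   panels use prefix "localfreq_", e.g. localfreq_panel), and per-family
#   carrier/missingness count columns used by the sharing and missingness
#   rules.

.severe_classes <- c("start_lost", "stop_gained", "stop_lost",
                     "splice_acceptor", "splice_donor", "frameshift")

#' Default filter-cascade configuration
#'
#' @param pop_freq_max maximum reference-population (e.g. 1000 Genomes,
#'   ExAC) alternate-allele frequency; variants strictly above are dropped
#'   (default 0.025)
#' @param local_freq_max maximum local-panel frequency (default 0.05)
#' @param case_missing_max named vector: per-family limit on the number of
#'   cases with missing calls
#' @param share_min minimum fraction of genotyped cases carrying the
#'   variant within a family or designated subfamily (default 0.60)
#' @param cadd_min CADD threshold for the missense rescue clause
#'   (default 20, strict "greater than")
#' @param cadd_all_classes widen the CADD clause beyond missense
#'   (default FALSE: it attaches to missense only)
#' @return a `FilterConfig` list
#' @export
filter_config <- function(pop_freq_max = 0.025, local_freq_max = 0.05,
                          case_missing_max = c(A = 20L, B = 10L),
                          share_min = 0.60, cadd_min = 20,
                          cadd_all_classes = FALSE) {
  stopifnot(pop_freq_max > 0, pop_freq_max < 1,
            local_freq_max > 0, local_freq_max < 1,
            share_min > 0, share_min <= 1)
  structure(list(pop_freq_max = pop_freq_max,
                 local_freq_max = local_freq_max,
                 case_missing_max = case_missing_max,
                 share_min = share_min, cadd_min = cadd_min,
                 cadd_all_classes = cadd_all_classes),
            class = "FilterConfig")
}

#' Consequence filter
#'
#' Keep a variant iff any transcript carries a severe class (start/stop
#' loss or gain, splice donor/acceptor, frameshift), or is missense and
#' predicted deleterious by CAROL or Condel or has CADD strictly above the
#' threshold. Variants with no consequence annotation are dropped with a
#' warning. Synonymous and other mild classes are dropped regardless of
#' CADD (the CADD clause attaches to missense; set `cadd_all_classes` to
#' widen it).
#'
#' @param variants annotation data.frame (may hold several transcript rows
#'   per variant; rows are grouped by chrom:pos:ref:alt)
#' @param cfg a `FilterConfig`
#' @return logical keep flag per unique variant, named by variant key
#' @export
consequence_filter <- function(variants, cfg = filter_config()) {
  key <- .variant_key(variants)
  cons <- tolower(as.character(variants$consequence))
  no_ann <- is.na(cons) | cons == ""
  if (any(no_ann))
    warning(sum(no_ann), " transcript row(s) without consequence annotation")
  severe <- cons %in% .severe_classes
  carol <- isTRUE_vec(variants$deleterious_carol)
  condel <- isTRUE_vec(variants$deleterious_condel)
  cadd_hi <- !is.na(variants$cadd) & variants$cadd > cfg$cadd_min
  missense_ok <- cons == "missense" & (carol | condel | cadd_hi)
  row_keep <- !no_ann & (severe | missense_ok |
                           (cfg$cadd_all_classes & cadd_hi))
  tapply(row_keep, key, any)[unique(key)]
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & as.logical(x)

.variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Population-frequency filter
#'
#' Drop a variant iff any reference-population frequency (columns prefixed
#' `freq_`) is strictly above `pop_freq_max`, or any local-panel frequency
#' (columns prefixed `localfreq_`) is strictly above `local_freq_max`.
#' Missing frequencies do not exclude.
#'
#' @param variants annotation data.frame (one row per variant)
#' @param cfg a `FilterConfig`
#' @return logical keep flag per row
#' @export
frequency_filter <- function(variants, cfg = filter_config()) {
  popc <- grep("^freq_", names(variants), value = TRUE)
  locc <- grep("^localfreq_", names(variants), value = TRUE)
  over <- rep(FALSE, nrow(variants))
  for (cc in popc) {
    v <- variants[[cc]]
    over <- over | (!is.na(v) & v > cfg$pop_freq_max)
  }
  for (cc in locc) {
    v <- variants[[cc]]
    over <- over | (!is.na(v) & v > cfg$local_freq_max)
  }
  !over
}

#' Case-missingness filter
#'
#' Drop a variant iff its call is missing in strictly more cases than the
#' per-family limit.
#'
#' @param variants annotation data.frame with column
#'   `case_missing_<family>`
#' @param cfg a `FilterConfig` (see `case_missing_max`)
#' @param family family label selecting the limit and count column
#' @return logical keep flag per row
#' @export
missingness_filter <- function(variants, cfg = filter_config(),
                               family = "A") {
  lim <- unname(cfg$case_missing_max[family])
  if (is.null(lim) || is.na(lim))
    stop("no case_missing_max configured for family ", family)
  cm <- variants[[paste0("case_missing_", family)]]
  if (is.null(cm)) stop("missing column case_missing_", family)
  is.na(cm) | cm <= lim
}

#' Sharing-based prioritization
#'
#' A variant is prioritized when the fraction of genotyped cases carrying
#' it (dosage >= 1) reaches `share_min` in the whole family or in any
#' designated subfamily. Units with no genotyped cases are skipped.
#'
#' @param variants annotation data.frame with, per unit `u`, columns
#'   `case_carriers_<u>` and `case_genotyped_<u>`
#' @param units character vector of unit labels (whole family first, e.g.
#'   `c("A", "A0", "A1", "A2")`)
#' @param cfg a `FilterConfig`
#' @return list with `prioritized` (logical per row) and `sharing` (matrix
#'   of per-unit sharing fractions)
#' @export
sharing_prioritize <- function(variants, units, cfg = filter_config()) {
  frac <- sapply(units, function(u) {
    carriers <- variants[[paste0("case_carriers_", u)]]
    genotyped <- variants[[paste0("case_genotyped_", u)]]
    if (is.null(carriers) || is.null(genotyped))
      stop("missing carrier/genotyped columns for unit ", u)
    ifelse(!is.na(genotyped) & genotyped > 0, carriers / genotyped, NA_real_)
  })
  frac <- matrix(frac, nrow = nrow(variants),
                 dimnames = list(NULL, units))
  hit <- frac >= cfg$share_min
  hit[is.na(hit)] <- FALSE
  list(prioritized = rowSums(hit) > 0, sharing = frac)
}

#' Rank variants by minimum association P value across units
#'
#' Each variant is keyed by its minimum P over the analysis units (whole
#' family and subfamilies); ascending order, ties broken by genomic
#' coordinate; variants with no computable P rank last and are flagged.
#'
#' @param variants annotation data.frame (one row per variant)
#' @param pvalues matrix or data.frame of per-unit P values, rows aligned
#'   to `variants`, columns named by unit
#' @return `variants` reordered, with columns `min_p`, `min_p_unit` and
#'   `no_p` appended
#' @export
rank_variants <- function(variants, pvalues) {
  pm <- as.matrix(pvalues)
  stopifnot(nrow(pm) == nrow(variants))
  min_p <- suppressWarnings(apply(pm, 1, min, na.rm = TRUE))
  no_p <- !is.finite(min_p)
  min_p[no_p] <- NA_real_
  unit <- colnames(pm)[apply(pm, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))]
  out <- variants
  out$min_p <- min_p
  out$min_p_unit <- unit
  out$no_p <- no_p
  ord <- order(no_p, min_p, .chrom_rank(out$chrom), out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.integer(x))
  ifelse(is.na(num), 100L + as.integer(factor(x)), num)
}

#' Restrict an annotation table to the autosomes
#' @param variants annotation data.frame
#' @return logical keep flag per row (chromosomes 1-22, with or without a
#'   "chr" prefix)
#' @export
autosome_filter <- function(variants) {
  x <- suppressWarnings(as.integer(sub("^chr", "",
                                       as.character(variants$chrom))))
  !is.na(x) & x >= 1 & x <= 22
}

#' Run the full exome filter cascade
#'
#' Autosome restriction, consequence filter, population-frequency filter
#' and case-missingness filter (pure conjunctions, so order-invariant),
#' then sharing-based prioritization. Input may contain several transcript
#' rows per variant; the output has one row per surviving variant.
#'
#' @param variants annotation data.frame (transcript-level rows allowed)
#' @param cfg a `FilterConfig`
#' @param family family label for the missingness limit
#' @param units sharing units (family plus subfamilies)
#' @return list with `variants` (prioritized rows, incl. sharing columns),
#'   `counts` (survivors after each stage) and `kept` (logical per unique
#'   input variant)
#' @export
variant_cascade <- function(variants, cfg = filter_config(), family = "A",
                            units = family) {
  key <- .variant_key(variants)
  cons_keep <- consequence_filter(variants, cfg)   # per unique key
  first <- !duplicated(key)
  vu <- variants[first, , drop = FALSE]
  ku <- key[first]
  keep_auto <- autosome_filter(vu)
  keep_cons <- as.logical(cons_keep[ku])
  keep_freq <- frequency_filter(vu, cfg)
  keep_miss <- missingness_filter(vu, cfg, family)
  keep <- keep_auto & keep_cons & keep_freq & keep_miss
  surv <- vu[keep, , drop = FALSE]
  sh <- sharing_prioritize(surv, units, cfg)
  out <- surv[sh$prioritized, , drop = FALSE]
  sharing <- sh$sharing[sh$prioritized, , drop = FALSE]
  colnames(sharing) <- paste0("share_", colnames(sharing))
  out <- cbind(out, sharing)
  rownames(out) <- NULL
  list(variants = out,
       counts = c(input = nrow(vu),
                  autosomal = sum(keep_auto),
                  consequence = sum(keep_auto & keep_cons),
                  frequency = sum(keep_auto & keep_cons & keep_freq),
                  missingness = sum(keep),
                  prioritized = nrow(out)),
       kept = stats::setNames(keep, ku))
}
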