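#' Construct a genotype matrix
#'
#' Container for biallelic genotype dosages: variants in rows, samples in
#' columns, calls in {0, 1, 2, NA} counting copies of the alternate allele.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `id`; positions must be strictly increasing
#'   within each chromosome
#' @param dosage integer matrix, `nrow(variants)` x number of samples
#' @param samples sample ids (defaults to `colnames(dosage)`)
#' @return a `GenotypeMatrix`
#' @export
genotype_matrix <- function(variants, dosage, samples = colnames(dosage)) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == nrow(dosage))
  if (is.null(variants$id))
    variants$id <- paste0(variants$chrom, ":", variants$pos)
  if (is.null(samples)) stop("sample ids required")
  bad <- unlist(lapply(split(variants$pos, variants$chrom),
                       function(p) any(diff(p) <= 0)))
  if (any(bad)) stop("positions must be strictly increasing within chromosome")
  dosage <- matrix(as.integer(dosage), nrow = nrow(variants),
                   dimnames = list(variants$id, samples))
  if (any(!is.na(dosage) & (dosage < 0L | dosage > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  structure(list(variants = variants, dosage = dosage, samples = samples),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix: ", nrow(x$dosage), " variants x ", length(x$samples),
      " samples, ", round(100 * mean(is.na(x$dosage)), 2), "% missing\n",
      sep = "")
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

# Subset helper used throughout the pipeline.
subset_gm <- function(gm, variants = NULL, samples = NULL) {
  v <- if (is.null(variants)) seq_len(nrow(gm$dosage)) else variants
  s <- if (is.null(samples)) gm$samples else samples
  structure(list(variants = gm$variants[v, , drop = FALSE],
                 dosage = gm$dosage[v, s, drop = FALSE],
                 samples = s),
            class = "GenotypeMatrix")
}

#' Alternate-allele frequencies of a genotype matrix
#' @param gm a `GenotypeMatrix`
#' @param samples optional subset of sample ids
#' @return numeric vector of alt-allele frequencies (NA where no calls)
#' @export
allele_freqs <- function(gm, samples = NULL) {
  d <- if (is.null(samples)) gm$dosage else gm$dosage[, samples, drop = FALSE]
  rowMeans(d, na.rm = TRUE) / 2
}

#' Read genotypes from a VCF file
#'
#' Reads the GT field of a VCF (v4.x) into a `GenotypeMatrix`. Only
#' biallelic SNV/indel records are kept.
#'
#' @param path path to a VCF file (plain text or gzipped)
#' @return a `GenotypeMatrix`
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  genotype_matrix(
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
               id = ifelse(is.na(fix$ID) | fix$ID == ".",
                           paste0(fix$CHROM, ":", fix$POS), fix$ID),
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    dos, samples = colnames(gt))
}

#' Write a genotype matrix as a VCF v4.2 file
#' @param gm a `GenotypeMatrix`
#' @param path output path (plain text)
#' @param imputed_flag optional logical matrix, same shape as the dosage
#'   matrix; `TRUE` calls are annotated `IMP` in the genotype field's
#'   per-record INFO column (`INFO=IMPUTED` listing sample ids)
#' @return invisibly, `path`
#' @export
write_vcf_genotypes <- function(gm, path, imputed_flag = NULL) {
  gtcode <- c("0/0", "0/1", "1/1")
  d <- gm$dosage
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d)] <- gtcode[d[!is.na(d)] + 1L]
  info <- rep(".", nrow(d))
  if (!is.null(imputed_flag)) {
    ni <- rowSums(imputed_flag, na.rm = TRUE)
    info[ni > 0] <- paste0("IMPUTED=", ni[ni > 0])
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=pedflow",
              "##INFO=<ID=IMPUTED,Number=1,Type=Integer,Description=\"Number of flow-imputed genotype calls\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- paste(gm$variants$chrom, gm$variants$pos, gm$variants$id,
                gm$variants$ref, gm$variants$alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
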