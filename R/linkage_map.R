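#' Haldane map function
#'
#' Converts a genetic distance in centiMorgans to a recombination fraction:
#' theta = (1 - exp(-2 d / 100)) / 2.
#'
#' @param cm genetic distance in cM (>= 0, vectorized)
#' @return recombination fraction in [0, 0.5)
#' @examples
#' haldane(10)  # ~0.0906
#' @export
haldane <- function(cm) {
  if (any(cm < 0)) stop("genetic distance must be non-negative")
  0.5 * (1 - exp(-2 * cm / 100))
}

#' Inverse Haldane map function
#' @param theta recombination fraction in [0, 0.5)
#' @return genetic distance in cM
#' @export
haldane_inv <- function(theta) {
  stopifnot(all(theta >= 0 & theta < 0.5))
  -50 * log(1 - 2 * theta)
}

#' Marker map constructor
#'
#' @param chrom chromosome per marker
#' @param pos physical position (1-based)
#' @param cM genetic position in centiMorgans, non-decreasing within
#'   chromosome
#' @return a `MarkerMap` data.frame
#' @export
marker_map <- function(chrom, pos, cM) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(cM))
  bad <- unlist(lapply(split(cM, chrom), function(x) any(diff(x) < 0)))
  if (any(bad)) stop("genetic positions must be non-decreasing within chromosome")
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    cM = as.numeric(cM), stringsAsFactors = FALSE)
  class(out) <- c("MarkerMap", "data.frame")
  out
}

#' Read / write a marker map (tab-delimited chrom, pos, cM)
#' @param path file path
#' @export
read_marker_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  marker_map(tab$chrom, tab$pos, tab$cM)
}

#' @rdname read_marker_map
#' @param map a `MarkerMap`
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Parametric disease model for linkage
#'
#' @param q disease allele frequency
#' @param f penetrances (f0, f1, f2) for 0/1/2 copies of the disease
#'   allele; `f0` is the phenocopy rate. Default is an affected-only
#'   dominant model with a 5% phenocopy rate: q = 0.001,
#'   f = (0.05, 0.5, 0.5).
#' @return a `DiseaseModel` list
#' @export
disease_model <- function(q = 0.001, f = c(0.05, 0.5, 0.5)) {
  stopifnot(q > 0, q < 1, length(f) == 3,
            all(f >= 0), all(f <= 1), !is.unsorted(f))
  structure(list(q = q, f = f, phenocopy = f[1]), class = "DiseaseModel")
}

#' Greedy LD pruning of markers in founders
#'
#' Single pass per chromosome keeping a marker only when its squared
#' correlation with every previously kept marker on the chromosome is
#' below `r2_max`, computed over founder genotypes.
#'
#' @param gm a `GenotypeMatrix`
#' @param ped a `Pedigree` (founder genotypes define the correlations)
#' @param r2_max maximum allowed pairwise r-squared (default 0.1)
#' @return integer indices of retained variants
#' @export
ld_prune <- function(gm, ped, r2_max = 0.1) {
  founders <- intersect(ped$id[is_founder(ped)], gm$samples)
  d <- gm$dosage[, founders, drop = FALSE]
  keep <- logical(nrow(d))
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    kept <- integer(0)
    for (i in idx) {
      if (stats::sd(d[i, ], na.rm = TRUE) == 0 || all(is.na(d[i, ]))) next
      ok <- TRUE
      for (j in kept) {
        r <- suppressWarnings(stats::cor(d[i, ], d[j, ],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 >= r2_max) { ok <- FALSE; break }
      }
      if (ok) { kept <- c(kept, i); keep[i] <- TRUE }
    }
  }
  which(keep)
}
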