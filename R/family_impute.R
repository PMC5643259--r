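# Within-family imputation of exome variants from the reconstructed
# haplotype flow: sequenced carriers place a rare variant on founder
# haplotypes, whose carriage then determines dosages for relatives with
# SNP data but no exome data.

# Labels at an arbitrary position: the nearest flanking flow locus on each
# side must agree (per individual, per haplotype side); otherwise the flow
# is unknown there. Returns a 2-column character matrix (pat, mat) aligned
# to flow$ids.
.flow_labels_at <- function(flow, chrom, pos) {
  on_chr <- which(flow$loci$chrom == chrom)
  if (!length(on_chr)) {
    return(matrix(NA_character_, length(flow$ids), 2,
                  dimnames = list(flow$ids, c("pat", "mat"))))
  }
  ps <- flow$loci$pos[on_chr]
  left <- if (any(ps <= pos)) on_chr[max(which(ps <= pos))] else NA_integer_
  right <- if (any(ps >= pos)) on_chr[min(which(ps >= pos))] else NA_integer_
  pick <- function(m) {
    if (is.na(left)) return(m[, right])
    if (is.na(right)) return(m[, left])
    ifelse(!is.na(m[, left]) & !is.na(m[, right]) & m[, left] == m[, right],
           m[, left], NA_character_)
  }
  out <- cbind(pat = pick(flow$pat), mat = pick(flow$mat))
  rownames(out) <- flow$ids
  out
}

#' Assign a rare variant to founder haplotypes
#'
#' Finds the minimal set of founder-haplotype labels such that every
#' sequenced carrier holds at least one label of the set (a homozygous
#' carrier must hold two, counted with multiplicity) and no sequenced
#' non-carrier holds any. Carriers with unknown flow at the position are
#' excluded and logged in the result.
#'
#' @param flow a `HaplotypeFlow`
#' @param carriage list describing the variant: `chrom`, `pos`, and
#'   `dosages`, a named vector of observed dosages (0/1/2/NA) for the
#'   sequenced individuals
#' @param max_noncarrier_hits tolerance knob: number of non-carriers
#'   allowed to hold a candidate label (default 0, the strict rule)
#' @return list with `labels` (character vector, the assigned set),
#'   `conflict` (logical), `excluded` (carriers with unknown flow) and
#'   `position` info
#' @export
assign_founder_haplotype <- function(flow, carriage,
                                     max_noncarrier_hits = 0L) {
  dos <- carriage$dosages
  lab <- .flow_labels_at(flow, carriage$chrom, carriage$pos)
  seqd <- names(dos)[!is.na(dos)]
  seqd <- intersect(seqd, flow$ids)
  carriers <- seqd[dos[seqd] >= 1]
  noncar <- seqd[dos[seqd] == 0]
  if (!length(carriers))
    return(list(labels = character(0), conflict = TRUE,
                excluded = character(0),
                reason = "no observed carrier"))
  known <- !is.na(lab[carriers, "pat"]) & !is.na(lab[carriers, "mat"])
  excluded <- carriers[!known]
  carriers <- carriers[known]
  if (!length(carriers))
    return(list(labels = character(0), conflict = TRUE, excluded = excluded,
                reason = "no carrier with resolved flow"))
  forbidden <- unique(stats::na.omit(c(lab[noncar, "pat"],
                                       lab[noncar, "mat"])))
  # labels held by non-carriers are forbidden unless within tolerance
  if (max_noncarrier_hits > 0) {
    hits <- table(c(lab[noncar, "pat"], lab[noncar, "mat"]))
    forbidden <- names(hits)[hits > max_noncarrier_hits]
  }
  cand <- sort(unique(stats::na.omit(c(lab[carriers, "pat"],
                                       lab[carriers, "mat"]))))
  covers <- function(set) {
    all(vapply(carriers, function(i) {
      have <- c(lab[i, "pat"], lab[i, "mat"])
      need <- dos[i]
      sum(have %in% set) >= need
    }, logical(1)))
  }
  ok_sets <- list()
  for (s in cand) if (!(s %in% forbidden) && covers(s))
    ok_sets <- c(ok_sets, list(s))
  if (!length(ok_sets) && length(cand) > 1) {
    prs <- utils::combn(cand, 2, simplify = FALSE)
    for (s in prs) if (!any(s %in% forbidden) && covers(s))
      ok_sets <- c(ok_sets, list(s))
  }
  # a homozygous-only carriage can need a founder's two haplotypes -- the
  # pair search above covers that since both labels appear in cand
  if (!length(ok_sets))
    return(list(labels = character(0), conflict = TRUE, excluded = excluded,
                reason = "no label set separates carriers from non-carriers"))
  labels <- ok_sets[[1]]   # minimal size first; lexicographically smallest
  list(labels = labels, conflict = FALSE, excluded = excluded,
       chrom = carriage$chrom, pos = carriage$pos)
}

#' Impute a variant onto non-sequenced relatives from the haplotype flow
#'
#' Given the founder-haplotype label set carrying a variant, every
#' individual's dosage is the number of assigned labels among its two flow
#' labels at the position; individuals with unknown flow stay missing.
#' Observed (sequenced) genotypes are authoritative and never overwritten.
#'
#' @param flow a `HaplotypeFlow`
#' @param labels assignment from [assign_founder_haplotype()] (the function
#'   errors on a conflict assignment)
#' @param carriage as in [assign_founder_haplotype()]
#' @return data.frame with `id`, `dosage` (int or NA), `imputed` (TRUE for
#'   flow-derived calls, FALSE for observed ones)
#' @export
impute_from_flow <- function(flow, labels, carriage) {
  if (is.list(labels) && !is.null(labels$conflict)) {
    if (labels$conflict) stop("conflicting label assignment; variant failed")
    labels <- labels$labels
  }
  lab <- .flow_labels_at(flow, carriage$chrom, carriage$pos)
  dos_obs <- carriage$dosages
  out <- data.frame(id = flow$ids, dosage = NA_integer_, imputed = NA,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    i <- out$id[r]
    if (i %in% names(dos_obs) && !is.na(dos_obs[i])) {
      out$dosage[r] <- as.integer(dos_obs[i])
      out$imputed[r] <- FALSE
    } else if (!is.na(lab[i, "pat"]) && !is.na(lab[i, "mat"])) {
      out$dosage[r] <- sum(lab[i, c("pat", "mat")] %in% labels)
      out$imputed[r] <- TRUE
    }
  }
  out
}

#' Impute a set of variants and report per-variant success
#'
#' Applies [assign_founder_haplotype()] then [impute_from_flow()] to each
#' variant. A variant is successful when no conflict arose and at least one
#' individual received an imputed call.
#'
#' @param flow a `HaplotypeFlow`
#' @param carriages list of carriage descriptors (chrom, pos, dosages)
#' @return list with `dosages` (variants x individuals integer matrix),
#'   `imputed` (logical matrix marking flow-derived calls) and `status`
#'   (data.frame: variant, success, n_imputed, conflict)
#' @export
impute_variants <- function(flow, carriages) {
  n <- length(carriages)
  D <- matrix(NA_integer_, n, length(flow$ids),
              dimnames = list(NULL, flow$ids))
  I <- matrix(FALSE, n, length(flow$ids), dimnames = list(NULL, flow$ids))
  status <- data.frame(variant = seq_len(n), success = FALSE,
                       n_imputed = 0L, conflict = FALSE)
  for (k in seq_len(n)) {
    asg <- assign_founder_haplotype(flow, carriages[[k]])
    if (asg$conflict) { status$conflict[k] <- TRUE; next }
    imp <- impute_from_flow(flow, asg$labels, carriages[[k]])
    D[k, imp$id] <- imp$dosage
    I[k, imp$id] <- !is.na(imp$imputed) & imp$imputed
    status$n_imputed[k] <- sum(I[k, ])
    status$success[k] <- status$n_imputed[k] >= 1
  }
  list(dosages = D, imputed = I, status = status)
}
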