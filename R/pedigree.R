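#' Build a pedigree from individual records
#'
#' Constructs a validated `Pedigree` object from a table of individuals.
#' Founders have both parent fields missing; non-founders must have both
#' parents present in the table. A topological generation index is assigned
#' (founders are generation 0, every child is strictly below both parents).
#'
#' @param records a data.frame with columns `id`, `father`, `mother`
#'   (use `NA`, `""` or `"0"` for a missing parent), and optionally `sex`
#'   (`"male"`, `"female"`, `"unknown"` or PED codes 1/2/0), `affection`
#'   (`"affected"`, `"unaffected"`, `"unknown"` or PED codes 2/1/0/-9),
#'   `sequenced` and `genotyped` (logical flags).
#' @return a `Pedigree`: a data.frame with columns `id`, `father`, `mother`,
#'   `sex`, `affection`, `sequenced`, `genotyped`, `generation`, ordered so
#'   that every parent precedes its children.
#' @examples
#' ped <- build_pedigree(data.frame(
#'   id = c("f", "m", "c"), father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
#'   sex = c("male", "female", "unknown"),
#'   affection = c("unaffected", "unaffected", "affected")))
#' ped$generation  # 0 0 1
#' @export
build_pedigree <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("id", "father", "mother")
  if (!all(need %in% names(records)))
    stop("records must have columns id, father, mother")
  id <- as.character(records$id)
  if (anyDuplicated(id)) stop("duplicate individual ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  norm_parent <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
    x
  }
  father <- norm_parent(records$father)
  mother <- norm_parent(records$mother)
  if (any(is.na(father) != is.na(mother)))
    stop("individuals must have either both parents or neither (half-specified: ",
         paste(id[is.na(father) != is.na(mother)], collapse = ", "), ")")
  miss_f <- setdiff(stats::na.omit(father), id)
  miss_m <- setdiff(stats::na.omit(mother), id)
  if (length(miss_f) || length(miss_m))
    stop("referenced parent(s) missing from records: ",
         paste(unique(c(miss_f, miss_m)), collapse = ", "))
  if (any(!is.na(father) & (father == id | mother == id)))
    stop("cycle detected: individual is its own parent")

  sex <- .norm_sex(if (is.null(records$sex)) rep(NA, length(id)) else records$sex)
  affection <- .norm_affection(
    if (is.null(records$affection)) rep(NA, length(id)) else records$affection)
  sequenced <- if (is.null(records$sequenced)) rep(FALSE, length(id)) else
    as.logical(records$sequenced)
  genotyped <- if (is.null(records$genotyped)) rep(TRUE, length(id)) else
    as.logical(records$genotyped)

  # Kahn topological sort; also detects ancestral cycles
  fi <- match(father, id)
  mi <- match(mother, id)
  gen <- rep(NA_integer_, length(id))
  gen[is.na(fi)] <- 0L
  remaining <- which(is.na(gen))
  while (length(remaining)) {
    ready <- remaining[!is.na(gen[fi[remaining]]) & !is.na(gen[mi[remaining]])]
    if (!length(ready)) stop("cycle detected in pedigree structure")
    gen[ready] <- pmax(gen[fi[ready]], gen[mi[ready]]) + 1L
    remaining <- setdiff(remaining, ready)
  }

  ord <- order(gen, match(id, id))
  ped <- data.frame(id = id, father = father, mother = mother, sex = sex,
                    affection = affection, sequenced = sequenced,
                    genotyped = genotyped, generation = gen,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("Pedigree", "data.frame")
  ped
}

.norm_sex <- function(x) {
  x <- as.character(x)
  out <- rep("unknown", length(x))
  out[x %in% c("1", "male", "M", "m")] <- "male"
  out[x %in% c("2", "female", "F", "f")] <- "female"
  out
}

.norm_affection <- function(x) {
  x <- as.character(x)
  out <- rep("unknown", length(x))
  out[x %in% c("2", "affected")] <- "affected"
  out[x %in% c("1", "unaffected")] <- "unaffected"
  out
}

#' @export
print.Pedigree <- function(x, ...) {
  nf <- sum(is.na(x$father))
  cat("Pedigree: ", nrow(x), " individuals (", nf, " founders, ",
      nrow(x) - nf, " non-founders), ", max(x$generation) + 1L,
      " generations, ", sum(x$affection == "affected"), " affected\n", sep = "")
  invisible(x)
}

#' Founder indicator
#' @param ped a `Pedigree`
#' @return logical vector, `TRUE` for individuals with no parents in the
#'   pedigree.
#' @export
is_founder <- function(ped) is.na(ped$father)

#' Meiosis bit-size of a pedigree
#'
#' The Lander-Green complexity measure `2n - f`, with `n` non-founders and
#' `f` founders. Individuals whose parents are absent from `ped` count as
#' founders.
#' @param ped a `Pedigree`
#' @return integer bit count
#' @export
pedigree_bits <- function(ped) {
  n <- sum(!is.na(ped$father))
  f <- sum(is.na(ped$father))
  2L * n - f
}

#' Pedigree kinship matrix
#'
#' Expected kinship coefficients phi from the pedigree structure by the
#' standard recursion: founders are pairwise unrelated and non-inbred
#' (phi(i,i) = 1/2), and for a non-founder `i` with parents `f`, `m`,
#' phi(i,i) = (1 + phi(f,m))/2 and phi(i,j) = (phi(f,j) + phi(m,j))/2 for
#' any `j` that is not a descendant of `i`.
#'
#' @param ped a `Pedigree`
#' @return a `KinshipMatrix`: symmetric positive semi-definite matrix with
#'   dimnames set to the individual ids.
#' @examples
#' ped <- build_pedigree(data.frame(id = c("f","m","c1","c2"),
#'   father = c(NA, NA, "f", "f"), mother = c(NA, NA, "m", "m")))
#' k <- pedigree_kinship(ped)
#' k["c1", "c2"]  # full sibs: 0.25
#' @export
pedigree_kinship <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  # ped is in topological order: parents precede children
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      prev <- seq_len(i - 1L)
      phi[i, prev] <- 0.5 * (phi[fi[i], prev] + phi[mi[i], prev])
      phi[prev, i] <- phi[i, prev]
      phi[i, i] <- 0.5 * (1 + phi[fi[i], mi[i]])
    }
  }
  class(phi) <- c("KinshipMatrix", class(phi))
  phi
}

#' Classify individuals by affected first-degree relatives
#'
#' Splits individuals into `"affected"`, `"unaffected+aFiDR"` (unaffected
#' with at least one affected first-degree relative) and
#' `"unaffected-aFiDR"`. First-degree relatives are parents, full siblings
#' and offspring. Individuals of unknown affection get `NA` and relatives
#' of unknown affection never count as affected.
#'
#' @param ped a `Pedigree`
#' @return named character vector of group labels, one per individual.
#' @export
classify_fidr <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  id <- ped$id
  aff <- ped$affection == "affected"
  has_aff_fidr <- vapply(seq_along(id), function(i) {
    rel <- character(0)
    if (!is.na(ped$father[i])) {
      rel <- c(rel, ped$father[i], ped$mother[i])
      sibs <- id[!is.na(ped$father) & ped$father == ped$father[i] &
                   ped$mother == ped$mother[i] & id != id[i]]
      rel <- c(rel, sibs)
    }
    kids <- id[(!is.na(ped$father) & ped$father == id[i]) |
                 (!is.na(ped$mother) & ped$mother == id[i])]
    rel <- unique(c(rel, kids))
    any(aff[match(rel, id)])
  }, logical(1))
  out <- ifelse(aff, "affected",
                ifelse(has_aff_fidr, "unaffected+aFiDR", "unaffected-aFiDR"))
  out[ped$affection == "unknown"] <- NA_character_
  out[aff] <- "affected"
  names(out) <- id
  out
}

# Nuclear families of a pedigree: one entry per mating, with parent pair and
# children; the atoms of the divide-and-conquer split.
.nuclear_families <- function(ped) {
  kids <- !is.na(ped$father)
  if (!any(kids)) return(list())
  key <- paste(ped$father[kids], ped$mother[kids], sep = "\r")
  split_children <- split(ped$id[kids], key)
  lapply(names(split_children), function(k) {
    pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
    list(father = pr[1], mother = pr[2], children = split_children[[k]],
         members = c(pr, split_children[[k]]))
  })
}

# bits = 2n - f for a subset of individuals, counting as non-founder only
# those whose both parents are inside the subset.
.subset_bits <- function(ped, members) {
  sub <- ped[match(members, ped$id), , drop = FALSE]
  nonf <- !is.na(sub$father) & sub$father %in% members & sub$mother %in% members
  2L * sum(nonf) - sum(!nonf)
}

#' Split a pedigree into tractable overlapping sub-pedigrees
#'
#' Divide-and-conquer decomposition for inheritance-vector inference on
#' pedigrees too large for exact computation. The pedigree is cut into its
#' nuclear families, which are then greedily merged while the Lander-Green
#' bit size `2n - f` stays within `max_bits`. Connector individuals (a child
#' in one nuclear family, a parent in another) are duplicated across chunks
#' and recorded in the overlap map so chunk-local inferences can be
#' reassembled.
#'
#' @param ped a `Pedigree`
#' @param max_bits maximum allowed bit size per chunk (default 20)
#' @param max_meioses optional additional cap on the meiosis count `2n` of
#'   a chunk (exact inference enumerates `2^(2n)` inheritance vectors, so
#'   callers doing exact HMM work pass a small value here; default
#'   unlimited)
#' @param max_founders optional cap on founders per chunk (emission sums
#'   enumerate `4^f` founder-allele assignments; default unlimited)
#' @return a list with `chunks` (list of `Pedigree` objects), `overlap`
#'   (named list: individual id -> integer vector of chunk indices, for
#'   individuals in more than one chunk), and `bits` (per-chunk bit sizes).
#' @export
split_pedigree <- function(ped, max_bits = 20L, max_meioses = Inf,
                           max_founders = Inf) {
  stopifnot(inherits(ped, "Pedigree"))
  .fits <- function(members) {
    sub <- ped[match(members, ped$id), , drop = FALSE]
    nonf <- !is.na(sub$father) & sub$father %in% members &
      sub$mother %in% members
    n <- sum(nonf); f <- sum(!nonf)
    (2L * n - f) <= max_bits && 2L * n <= max_meioses && f <= max_founders
  }
  if (pedigree_bits(ped) <= max_bits &&
      2L * sum(!is.na(ped$father)) <= max_meioses &&
      sum(is.na(ped$father)) <= max_founders) {
    chunks <- list(ped)
    ov <- list()
  } else {
    fams <- .nuclear_families(ped)
    fam_bits <- vapply(fams, function(f) .subset_bits(ped, f$members), integer(1))
    if (any(fam_bits > max_bits))
      stop("unsplittable: a single nuclear family has bits ",
           max(fam_bits), " > max_bits ", max_bits)
    if (!all(vapply(fams, function(f) .fits(f$members), logical(1))))
      stop("unsplittable: a single nuclear family exceeds max_meioses/",
           "max_founders")
    # greedy agglomeration over the family-overlap graph
    memb <- lapply(fams, `[[`, "members")
    unassigned <- seq_along(fams)
    groups <- list()
    while (length(unassigned)) {
      cur <- unassigned[1]
      unassigned <- unassigned[-1]
      cur_members <- memb[[cur]]
      repeat {
        shared <- vapply(unassigned, function(j)
          length(intersect(memb[[j]], cur_members)), integer(1))
        cand <- unassigned[shared > 0]
        if (!length(cand)) break
        cand <- cand[order(-shared[shared > 0])]
        merged <- FALSE
        for (j in cand) {
          newm <- union(cur_members, memb[[j]])
          if (.fits(newm)) {
            cur_members <- newm
            unassigned <- setdiff(unassigned, j)
            merged <- TRUE
            break
          }
        }
        if (!merged) break
      }
      groups <- c(groups, list(cur_members))
    }
    chunks <- lapply(groups, function(m) .sub_pedigree(ped, m))
    counts <- table(unlist(lapply(chunks, function(ch) ch$id)))
    ov_ids <- names(counts[counts > 1])
    ov <- lapply(ov_ids, function(i)
      which(vapply(chunks, function(ch) i %in% ch$id, logical(1))))
    names(ov) <- ov_ids
  }
  list(chunks = chunks, overlap = ov,
       bits = vapply(chunks, pedigree_bits, integer(1)))
}

# Restrict a pedigree to a member set; individuals whose parents fall outside
# become chunk-founders.
.sub_pedigree <- function(ped, members) {
  sub <- ped[match(members, ped$id), , drop = FALSE]
  drop_par <- !is.na(sub$father) &
    !(sub$father %in% members & sub$mother %in% members)
  sub$father[drop_par] <- NA_character_
  sub$mother[drop_par] <- NA_character_
  build_pedigree(sub)
}

#' Read a PED/FAM pedigree file
#'
#' Whitespace-delimited with columns family, id, father, mother, sex
#' (1 male / 2 female / 0 unknown), phenotype (1 unaffected / 2 affected /
#' 0 or -9 missing); `0` marks a missing parent.
#'
#' @param path file path
#' @return a `Pedigree` (the family column is kept as attribute `family`).
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6) stop("PED file needs >= 6 columns: ", path)
  ped <- build_pedigree(data.frame(
    id = tab[[2]], father = tab[[3]], mother = tab[[4]],
    sex = tab[[5]], affection = ifelse(tab[[6]] %in% c("0", "-9"), "unknown",
                                       tab[[6]]),
    stringsAsFactors = FALSE))
  attr(ped, "family") <- tab[[1]][match(ped$id, tab[[2]])]
  ped
}

#' Write a pedigree in PED/FAM format
#' @param ped a `Pedigree`
#' @param path output file path
#' @param family family label for column 1 (single value or per-individual)
#' @return invisibly, `path`
#' @export
write_ped <- function(ped, path, family = "FAM1") {
  sexcode <- c(male = "1", female = "2", unknown = "0")
  affcode <- c(unaffected = "1", affected = "2", unknown = "0")
  tab <- data.frame(
    family = family, id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = sexcode[ped$sex], phen = affcode[ped$affection],
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write a kinship matrix as tab-delimited text
#' @param k a `KinshipMatrix`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_kinship <- function(k, path) {
  utils::write.table(cbind(id = rownames(k), as.data.frame(unclass(k))),
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
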