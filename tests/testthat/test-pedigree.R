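test_that("build_pedigree validates structure and assigns generations", {
  one <- build_pedigree(data.frame(id = "solo", father = NA, mother = NA))
  expect_equal(nrow(one), 1)
  expect_equal(one$generation, 0L)

  trio <- trio_ped()
  expect_equal(trio$generation[match(c("f", "m", "c"), trio$id)],
               c(0L, 0L, 1L))

  expect_error(build_pedigree(data.frame(
    id = "x", father = "x", mother = "y")), "cycle|missing")
  expect_error(build_pedigree(data.frame(
    id = c("a", "b"), father = c(NA, "ghost"), mother = c(NA, "a"))),
    "missing")
  expect_error(build_pedigree(data.frame(
    id = c("a", "b"), father = c(NA, "b"), mother = c(NA, NA))),
    "both parents or neither")
  # mutual ancestry
  expect_error(build_pedigree(data.frame(
    id = c("a", "b", "p"), father = c("b", "a", NA),
    mother = c("p", "p", NA))), "cycle")
})

test_that("pedigree kinship matches closed forms", {
  rows <- data.frame(
    id = c("gf", "gm", "f", "fs", "m", "c1", "c2", "u", "cc"),
    father = c(NA, NA, "gf", "gf", NA, "f", "f", NA, "fs"),
    mother = c(NA, NA, "gm", "gm", NA, "m", "m", NA, "u"),
    stringsAsFactors = FALSE)
  ped <- build_pedigree(rows)
  k <- pedigree_kinship(ped)
  expect_equal(k["f", "c1"], 0.25)          # parent-offspring
  expect_equal(k["c1", "c2"], 0.25)         # full sibs
  expect_equal(k["c1", "cc"], 0.0625)       # first cousins
  expect_equal(unname(diag(k)), rep(0.5, nrow(ped)))  # non-inbred selves
  expect_equal(k["gf", "m"], 0)             # unrelated founders
  expect_true(isSymmetric(unclass(k)))
})

test_that("pedigree kinship is PSD on random synthetic pedigrees", {
  for (seed in 1:5) {
    cfg <- sim_config(generations = 4, mean_sibship = 3,
                      reproduce_prob = 0.7, seed = seed)
    ped <- simulate_pedigree_structure(cfg)
    k <- pedigree_kinship(ped)
    expect_gte(min(eigen(unclass(k), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-9)
  }
})

test_that("pedigree kinship agrees with gene-drop realized kinship", {
  ped <- three_gen_ped(3, 3)
  phi <- pedigree_kinship(ped)
  set.seed(99)
  n_loci <- 10000
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  # drop founder-allele labels at unlinked loci; realized kinship is the
  # fraction of randomly drawn allele pairs IBD
  labA <- matrix(0L, n, n_loci); labB <- matrix(0L, n, n_loci)
  cnt <- 0L
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      labA[i, ] <- cnt + 1L; labB[i, ] <- cnt + 2L; cnt <- cnt + 2L
    } else {
      pick <- stats::runif(n_loci) < 0.5
      labA[i, ] <- ifelse(pick, labA[fa[i], ], labB[fa[i], ])
      pick <- stats::runif(n_loci) < 0.5
      labB[i, ] <- ifelse(pick, labA[mo[i], ], labB[mo[i], ])
    }
  }
  pairs <- list(c("f", "c1"), c("c1", "g11"), c("g11", "g21"), c("f", "s1"))
  for (pr in pairs) {
    i <- match(pr[1], ped$id); j <- match(pr[2], ped$id)
    realized <- mean((labA[i, ] == labA[j, ]) + (labA[i, ] == labB[j, ]) +
                       (labB[i, ] == labA[j, ]) + (labB[i, ] == labB[j, ])) / 4
    expect_lt(abs(realized - phi[pr[1], pr[2]]), 0.02)
  }
})

test_that("classify_fidr applies the first-degree-relative definition", {
  ped <- build_pedigree(data.frame(
    id = c("af", "um", "uc", "lone1", "lone2", "lc"),
    father = c(NA, NA, "af", NA, NA, "lone1"),
    mother = c(NA, NA, "um", NA, NA, "lone2"),
    affection = c("affected", "unaffected", "unaffected",
                  "unaffected", "unaffected", "unaffected"),
    stringsAsFactors = FALSE))
  g <- classify_fidr(ped)
  expect_equal(unname(g["uc"]), "unaffected+aFiDR")   # child of affected
  # spouse of an affected individual is not a first-degree relative
  expect_equal(unname(g["um"]), "unaffected-aFiDR")
  expect_equal(unname(g["lone1"]), "unaffected-aFiDR")
  expect_equal(unname(g["lc"]), "unaffected-aFiDR")
})

test_that("a constructed family has exactly one case without affected FiDR", {
  # cases: two sibs (each other's FiDR), their affected father, and one
  # isolated case in a different branch with no affected first-degree kin
  ped <- build_pedigree(data.frame(
    id = c("gf", "gm", "p1", "sp1", "p2", "sp2", "a1", "a2", "b1", "b2"),
    father = c(NA, NA, "gf", NA, "gf", NA, "p1", "p1", "p2", "p2"),
    mother = c(NA, NA, "gm", NA, "gm", NA, "sp1", "sp1", "sp2", "sp2"),
    affection = c("unaffected", "unaffected", "affected", "unaffected",
                  "unaffected", "unaffected", "affected", "affected",
                  "affected", "unaffected"),
    stringsAsFactors = FALSE))
  g <- classify_fidr(ped)
  cases <- names(g)[g == "affected"]
  has_fidr <- vapply(cases, function(i) {
    fa <- ped$father[ped$id == i]; mo <- ped$mother[ped$id == i]
    rel <- c(fa, mo,
             ped$id[!is.na(ped$father) & ped$father %in% fa &
                      ped$mother %in% mo & ped$id != i],
             ped$id[(!is.na(ped$father) & ped$father == i) |
                      (!is.na(ped$mother) & ped$mother == i)])
    any(ped$affection[ped$id %in% rel] == "affected")
  }, logical(1))
  expect_equal(sum(!has_fidr), 1L)
  expect_equal(cases[!has_fidr], "b1")
})

test_that("split_pedigree covers the pedigree with bounded chunks", {
  # already small: identity
  small <- nuclear_ped(3)
  sp <- split_pedigree(small, max_bits = 20)
  expect_length(sp$chunks, 1)
  expect_length(sp$overlap, 0)

  # forced split: two nuclear families joined by one connector
  ped <- three_gen_ped(1, 2)   # f,m -> c1 + s1 -> g11,g12
  sp2 <- split_pedigree(ped, max_bits = 2)
  expect_length(sp2$chunks, 2)
  expect_true("c1" %in% names(sp2$overlap))
  expect_length(sp2$overlap[["c1"]], 2)

  # large random pedigree: property check
  cfg <- sim_config(generations = 4, mean_sibship = 6,
                    reproduce_prob = 0.85, seed = 15)
  big <- simulate_pedigree_structure(cfg)
  expect_gt(nrow(big), 150)
  spb <- split_pedigree(big, max_bits = 20)
  expect_true(all(spb$bits <= 20))
  covered <- unique(unlist(lapply(spb$chunks, function(ch) ch$id)))
  expect_setequal(covered, big$id)
  # union of chunk edges reproduces the original parent-child edge set
  edges <- function(ped) {
    kids <- !is.na(ped$father)
    sort(c(paste(ped$father[kids], ped$id[kids]),
           paste(ped$mother[kids], ped$id[kids])))
  }
  chunk_edges <- sort(unique(unlist(lapply(spb$chunks, edges))))
  expect_equal(chunk_edges, edges(big))

  # a single over-large nuclear family cannot be split
  expect_error(split_pedigree(nuclear_ped(12), max_bits = 20),
               "unsplittable")
})

test_that("PED files round-trip", {
  ped <- trio_ped(affection = c("unaffected", "affected", "affected"))
  path <- tempfile(fileext = ".ped")
  write_ped(ped, path)
  back <- read_ped(path)
  expect_equal(back$id, ped$id)
  expect_equal(back$father, ped$father)
  expect_equal(back$affection, ped$affection)
  expect_equal(back$sex, ped$sex)
})
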