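test_that("pedigree validation enforces haplodiploid rules and ordering", {
  rec <- data.frame(id = c("x1", "s1", "d1"), sex = c("F", "M", "F"),
                    dam = c("d1", NA, NA), sire = c("s1", NA, NA))
  ped <- buildPedigree(rec)   # offspring listed first: must be re-ordered
  expect_equal(pedIds(ped)[3], "x1")

  expect_error(buildPedigree(data.frame(
    id = c("m1", "m2"), sex = "M", dam = NA, sire = c(NA, "m1"))),
    "cannot have a sire")
  expect_error(buildPedigree(data.frame(
    id = "a", sex = "F", dam = "a", sire = NA)), "own parent")
  expect_error(buildPedigree(data.frame(
    id = c("a", "a"), sex = "F", dam = NA, sire = NA)), "duplicate")
  expect_error(buildPedigree(data.frame(
    id = "a", sex = "F", dam = "ghost", sire = NA)), "unknown dam")
})

test_that("tabular haplodiploid relatedness matches the classic constants", {
  A <- relatedness(haplodiploidAmatrix(sibPedigree()))
  expect_equal(A["g1", "g2"], 0.75)       # full sisters
  expect_equal(A["g1", "h1"], 0.50)       # paternal half-sisters
  expect_equal(A["d1", "g1"], 0.50)       # mother-daughter
  expect_equal(A["s", "g1"], 1.00)        # sire-daughter (haploid sire)
  expect_equal(A["d1", "d2"], 0)          # unrelated founders
  expect_equal(A["d1", "d1"], 1)          # non-inbred female diagonal
  expect_equal(A["s", "s"], 2)            # haploid male self, a = 2f
  expect_true(isSymmetric(A))
})

test_that("the diploid-only limit reproduces the standard tabular method", {
  # two diploid parents, two full sibs and a maternal half sib
  ped <- buildPedigree(data.frame(
    id = c("p1", "p2", "p3", "c1", "c2", "c3"), sex = "F",
    dam = c(NA, NA, NA, "p1", "p1", "p1"),
    sire = c(NA, NA, NA, "p2", "p2", "p3")), strict = FALSE)
  A <- relatedness(haplodiploidAmatrix(ped))
  expect_equal(A["c1", "c2"], 0.5)        # full sibs
  expect_equal(A["c1", "c3"], 0.25)       # half sibs
  expect_equal(A["p1", "c1"], 0.5)
  expect_equal(A["c1", "c1"], 1)
})

test_that("gene-dropping oracle agrees with the tabular matrix", {
  ped <- sibPedigree()
  gd <- geneDropCoancestry(ped, "g1", "g2", n_reps = 4e4, seed = 2)
  expect_lt(abs(gd$a - 0.75), 3 * gd$se)
  # mother-daughter IBD is constant across drops: zero MC error, exact 0.5
  gd2 <- geneDropCoancestry(ped, "d1", "g1", n_reps = 4e4, seed = 3)
  expect_lt(abs(gd2$a - 0.5), max(3 * gd2$se, 1e-9))
  # founder female with herself: coancestry 1/2 exactly
  gd3 <- geneDropCoancestry(ped, "d1", "d1", n_reps = 1000, seed = 4)
  expect_equal(gd3$a, 1)
  expect_error(geneDropCoancestry(ped, "g1", "g2", n_reps = 0), "n_reps")
})

test_that("random pedigrees: tabular entries sit within oracle error", {
  for (seed in 1:2) {
    ped <- randomPedigree(18, seed)
    A <- relatedness(haplodiploidAmatrix(ped))
    ids <- pedIds(ped)
    set.seed(seed + 100)
    pick <- t(replicate(8, sample(ids, 2)))
    for (r in seq_len(nrow(pick))) {
      gd <- geneDropCoancestry(ped, pick[r, 1], pick[r, 2],
                               n_reps = 3e4, seed = seed * 7 + r)
      tol <- max(3 * gd$se, 1e-12)
      expect_lt(abs(A[pick[r, 1], pick[r, 2]] - gd$a), tol + 1e-9)
    }
  }
})

test_that("phenotyped submatrix selects and stays positive definite", {
  ped <- sibPedigree()
  A <- haplodiploidAmatrix(ped)
  expect_equal(relatedness(phenotypedSubmatrix(A, pedIds(ped))),
               relatedness(A))
  one <- phenotypedSubmatrix(A, "g1")
  expect_equal(unname(relatedness(one)[1, 1]), 1)
  expect_error(phenotypedSubmatrix(A, "nobody"), "not in relatedness")

  # three full sisters: off-diagonals all 0.75
  ped3 <- buildPedigree(data.frame(
    id = c("s", "d", "a", "b", "c"), sex = c("M", "F", "F", "F", "F"),
    dam = c(NA, NA, "d", "d", "d"), sire = c(NA, NA, "s", "s", "s")))
  S <- relatedness(phenotypedSubmatrix(haplodiploidAmatrix(ped3),
                                       c("a", "b", "c")))
  expect_equal(unname(S[upper.tri(S)]), rep(0.75, 3))

  # the half-sib design's female submatrix is positive definite
  sim <- generateHalfsib(smallHalfsibDesign(), halfsibTruth(), seed = 1)
  Afull <- haplodiploidAmatrix(buildPedigree(sim$pedigree))
  fem <- sim$pedigree$id[!is.na(sim$pedigree$dam)]
  ev <- eigen(relatedness(phenotypedSubmatrix(Afull, fem)),
              symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})
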