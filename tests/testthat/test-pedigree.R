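test_that("pedigree files round-trip across dialects and handle missing codes", {
  famFile <- tempfile(fileext = ".fam")
  writeLines(c(
    "f1 fa 0 0 1 -9",
    "f1 mo 0 0 2 -9",
    "f1 ch fa mo 2 -9"
  ), famFile)
  ped <- readPedigree(famFile, "plink_fam")
  expect_s4_class(ped, "Pedigree")
  expect_length(ped, 3L)
  expect_equal(sum(isFounder(ped)), 2L)
  expect_true(is.na(pedFather(ped)["fa"]))

  # missing father code "0": founder-side null
  famFile2 <- tempfile(fileext = ".fam")
  writeLines(c(
    "f1 mo 0 0 2 -9",
    "f1 ch 0 mo 1 -9"
  ), famFile2)
  ped2 <- readPedigree(famFile2, "plink_fam")
  expect_true(is.na(pedFather(ped2)["ch"]))
  expect_identical(unname(pedMother(ped2)["ch"]), "mo")

  # csv dialect with remapped column names
  csvFile <- tempfile(fileext = ".csv")
  write.csv(data.frame(person = c("a", "b", "c"), dad = c("", "", "a"),
                       mum = c("", "", "b"), gender = c("M", "F", "F")),
            csvFile, row.names = FALSE)
  ped3 <- readPedigree(csvFile, "csv",
                       columns = list(id_col = "person", father_col = "dad",
                                      mother_col = "mum", sex_col = "gender"))
  expect_equal(unname(pedSex(ped3)), c(1L, 2L, 2L))

  # write + re-read is lossless
  out <- tempfile(fileext = ".fam")
  writeFam(ped, out)
  ped4 <- readPedigree(out, "plink_fam")
  expect_identical(pedIds(ped4), pedIds(ped))
  expect_identical(pedFather(ped4), pedFather(ped))
  expect_identical(pedSex(ped4), pedSex(ped))
})

test_that("malformed pedigrees are rejected with structural errors", {
  cyc <- tempfile(fileext = ".fam")
  writeLines(c(
    "f1 a c 0 1 -9",
    "f1 b a 0 1 -9",
    "f1 c b 0 1 -9"
  ), cyc)
  expect_error(suppressWarnings(readPedigree(cyc, "plink_fam")), "cycle")

  expect_error(
    pedigree(c("a", "a"), c(NA, NA), c(NA, NA)),
    "duplicate"
  )
  expect_error(
    pedigree(c("a", "b", "c"), c(NA, NA, "a"), c(NA, NA, "b"),
             sex = c(2, 1, 1)),
    "sex inconsistent"
  )
  expect_error(
    pedigree("a", "a", NA),
    "own parent"
  )
})

test_that("unknown parents are materialized as founders with a warning", {
  expect_warning(
    ped <- pedigree(c("a"), c("x"), c("y"), sex = 1),
    "added as founders"
  )
  expect_length(ped, 3L)
  expect_equal(sum(isFounder(ped)), 2L)
})

test_that("families partition the cohort into connected components", {
  ped <- pedigree(
    id = c("a", "b", "c", "d", "e", "f", "solo"),
    father = c(NA, NA, "a", NA, NA, "d", NA),
    mother = c(NA, NA, "b", NA, NA, "e", NA),
    sex = c(1, 2, 1, 1, 2, 2, 1)
  )
  fam <- families(ped)
  expect_length(unique(fam), 3L)
  expect_equal(unname(table(fam)[fam["solo"]]), 1L, ignore_attr = TRUE)
  expect_equal(fam[["a"]], fam[["c"]])
  expect_false(fam[["a"]] == fam[["d"]])

  expect_length(unique(families(makeThreeGen7())), 1L)
})

test_that("relative pairs are classified per first-degree/spouse definitions", {
  trio <- makeTrio()
  pairs <- classifyPairs(trio)
  expect_equal(sum(pairs$relation == "parent-offspring"), 2L)
  expect_equal(sum(pairs$relation == "spouse"), 1L)

  sibs <- pedigree(c("f", "m", "s1", "s2"), c(NA, NA, "f", "f"),
                   c(NA, NA, "m", "m"), sex = c(1, 2, 1, 2))
  expect_equal(sum(classifyPairs(sibs)$relation == "full-sibling"), 1L)

  # half-siblings are not first-degree
  half <- pedigree(c("f1", "f2", "m", "h1", "h2"),
                   c(NA, NA, NA, "f1", "f2"),
                   c(NA, NA, NA, "m", "m"), sex = c(1, 1, 2, 1, 2))
  expect_equal(sum(classifyPairs(half)$relation == "full-sibling"), 0L)

  # consanguineous spouse pairs are flagged
  incest <- pedigree(c("f", "m", "s1", "s2", "k"),
                     c(NA, NA, "f", "f", "s1"),
                     c(NA, NA, "m", "m", "s2"), sex = c(1, 2, 1, 2, 1))
  sp <- classifyPairs(incest)
  sp <- sp[sp$relation == "spouse", ]
  expect_true(sp$consanguineous[sp$id1 == "s1" | sp$id2 == "s1"])
  expect_false(sp$consanguineous[sp$id1 == "f" & sp$id2 == "m"])

  # declared partner links classify childless couples
  childless <- pedigree(c("a", "b"), c(NA, NA), c(NA, NA), sex = c(1, 2),
                        partners = cbind("a", "b"))
  expect_equal(classifyPairs(childless)$relation, "spouse")
})

test_that("simulator sibling and spouse pairs are recovered exactly", {
  sim <- simulateCohort(simConfig(
    nFamilies = 30L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("y")), G = matrix(0.5), R = matrix(0.5),
    seed = 77L
  ))
  pairs <- classifyPairs(sim$ped)
  expect_equal(sum(pairs$relation == "full-sibling"), 30L)
  expect_equal(sum(pairs$relation == "spouse"), 30L)
  expect_equal(sum(pairs$relation == "parent-offspring"), 30L * 4L)
})

test_that("relationship matrix reproduces textbook identities", {
  founders <- pedigree(c("a", "b"), c(NA, NA), c(NA, NA), sex = c(1, 2))
  expect_equal(unname(relationshipMatrix(founders)), diag(2))

  ped <- pedigree(
    id = c("gf", "gm", "f", "m", "c1", "c2", "m2", "h"),
    father = c(NA, NA, "gf", NA, "f", "f", NA, "f"),
    mother = c(NA, NA, "gm", NA, "m", "m", NA, "m2"),
    sex = c(1, 2, 1, 2, 1, 2, 2, 1)
  )
  A <- relationshipMatrix(ped)
  expect_equal(A["f", "c1"], 0.5)       # parent-offspring
  expect_equal(A["c1", "c2"], 0.5)      # full siblings
  expect_equal(A["gf", "c1"], 0.25)     # grandparent-grandchild
  expect_equal(A["c1", "h"], 0.25)      # half siblings
  expect_equal(unname(diag(A)), rep(1, 8))

  inbred <- pedigree(c("f", "m", "s1", "s2", "k"),
                     c(NA, NA, "f", "f", "s1"),
                     c(NA, NA, "m", "m", "s2"), sex = c(1, 2, 1, 2, 1))
  expect_equal(relationshipMatrix(inbred)["k", "k"], 1.25)
  expect_equal(inbreeding(inbred)[["k"]], 0.25)
})

test_that("relationship matrix is PSD, permutation-invariant and subsettable", {
  for (s in 1:5) {
    ped <- randomPedigree(maxSize = 20L, seed = 300L + s)
    A <- relationshipMatrix(ped)
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    # founders block is the identity
    f <- names(which(isFounder(ped)))
    Af <- A[f, f]
    expect_equal(unname(Af), diag(length(f)))
  }

  ped <- randomPedigree(maxSize = 15L, seed = 11L)
  A <- relationshipMatrix(ped)
  perm <- sample(pedIds(ped))
  ped2 <- pedigree(perm,
                   pedFather(ped)[perm],
                   pedMother(ped)[perm],
                   pedSex(ped)[perm])
  A2 <- relationshipMatrix(ped2)
  expect_equal(A2[rownames(A), colnames(A)], A, tolerance = 1e-12)

  # subset: unphenotyped connecting ancestors still contribute
  sibs <- pedigree(c("f", "m", "s1", "s2"), c(NA, NA, "f", "f"),
                   c(NA, NA, "m", "m"), sex = c(1, 2, 1, 2))
  Asub <- relationshipMatrix(sibs, ids = c("s1", "s2"))
  expect_equal(Asub["s1", "s2"], 0.5)
  expect_error(relationshipMatrix(sibs, ids = c("s1", "nope")),
               "not in pedigree")

  # sparse and dense agree
  As <- relationshipMatrix(ped, sparse = TRUE)
  expect_lt(max(abs(as.matrix(As) - A)), 1e-10)
})

test_that("tabular relatedness agrees with gene-dropping Monte Carlo", {
  ped <- randomPedigree(maxSize = 15L, seed = 42L)
  A <- relationshipMatrix(ped)
  gd <- geneDropRelatedness(ped, nrep = 100000L, seed = 43L)
  dev <- abs(A - gd$A)
  # entries with zero MC error (founder pairs) must match exactly
  expect_true(all(dev[gd$se == 0] < 1e-12))
  z <- dev[gd$se > 0] / gd$se[gd$se > 0]
  expect_gte(mean(z <= 3), 0.99)
  expect_lt(max(z), 5)
})
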