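test_that("pedigree construction validates identifiers", {
  expect_error(pedigree(c("a", "a"), c(NA, NA), c(NA, NA)), "duplicate")
  expect_error(pedigree("x", "x", NA), "own parent")
  # same id as sire somewhere and dam elsewhere is rejected
  expect_error(
    pedigree(c("p", "k1", "k2"), c(NA, "p", NA), c(NA, NA, "p")),
    "both sire and dam"
  )
  # undeclared parents are added as founders with a warning ...
  expect_warning(ped <- pedigree("k", "s", "d"), "founders")
  expect_equal(nAnimals(ped), 3L)
  # ... or rejected in strict mode
  expect_error(pedigree("k", "s", "d", strict = TRUE), "never declared")
})

test_that("unknown-parent encodings are normalised", {
  ped <- pedigree(c("s", "k1", "k2", "k3"),
                  c("0", "s", "NA", ""),
                  c("", "0", "0", "NA"))
  expect_identical(slot(ped, "sire"), c(NA, "s", NA, NA))
  expect_identical(slot(ped, "dam"), rep(NA_character_, 4))
})

test_that("sorting is stable, idempotent and puts parents first", {
  # reversed chain: youngest first, each animal sired by the next in file
  n <- 10
  id <- sprintf("c%02d", 1:n)
  sire <- c(sprintf("c%02d", 2:n), NA)
  ped <- sortPedigree(pedigree(id, sire, rep(NA_character_, n)))
  expect_identical(animalIds(ped)[1], sprintf("c%02d", n))
  expect_true(isSorted(ped))
  expect_identical(animalIds(sortPedigree(ped)), animalIds(ped))

  set.seed(11)
  for (rep in 1:10) {
    ped <- randomPedigree(50)
    perm <- sample(nAnimals(ped))
    shuffled <- pedigree(animalIds(ped)[perm], slot(ped, "sire")[perm],
                         slot(ped, "dam")[perm])
    resorted <- sortPedigree(shuffled)
    pos <- stats::setNames(seq_len(50), animalIds(resorted))
    sp <- pos[slot(resorted, "sire")]
    dp <- pos[slot(resorted, "dam")]
    expect_true(all(sp < pos | is.na(sp)))
    expect_true(all(dp < pos | is.na(dp)))
  }
})

test_that("cycles are reported with the animals involved", {
  expect_error(
    sortPedigree(pedigree(c("a", "b"), c("b", "a"), c(NA, NA))),
    "cycle.*a.*b"
  )
})

test_that("relationship matrix has the forced small-pedigree values", {
  two <- sortPedigree(pedigree(c("f1", "f2"), c(NA, NA), c(NA, NA)))
  expect_equal(relationshipMatrix(two), diag(2), ignore_attr = TRUE)

  trio <- sortPedigree(pedigree(c("s", "d", "k"), c(NA, NA, "s"),
                                c(NA, NA, "d")))
  A <- relationshipMatrix(trio)
  expect_equal(A["k", "s"], 0.5)
  expect_equal(A["k", "d"], 0.5)
  expect_equal(A["k", "k"], 1.0)
})

test_that("relationship matrix requires a sorted pedigree", {
  ped <- pedigree(c("k", "s", "d"), c("s", NA, NA), c("d", NA, NA))
  expect_false(isSorted(ped))
  expect_error(relationshipMatrix(ped), "sorted")
})

test_that("file order does not affect A once sorted", {
  set.seed(21)
  ped <- randomPedigree(40)
  perm <- sample(40)
  shuffled <- sortPedigree(pedigree(animalIds(ped)[perm],
                                    slot(ped, "sire")[perm],
                                    slot(ped, "dam")[perm]))
  A1 <- relationshipMatrix(ped)
  A2 <- relationshipMatrix(shuffled)
  ids <- animalIds(ped)
  expect_equal(A1[ids, ids], A2[ids, ids], tolerance = 1e-12)
})

test_that("A agrees with the recursive kinship oracle and is PSD", {
  set.seed(31)
  for (rep in 1:15) {
    ped <- randomPedigree(sample(20:50, 1))
    A <- relationshipMatrix(ped)
    expect_equal(max(abs(A - 2 * kinshipOracle(ped))), 0, tolerance = 1e-12)
    expect_lt(abs(max(abs(A - t(A)))), 1e-14)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("founder block of A is the identity", {
  set.seed(41)
  ped <- randomPedigree(60)
  A <- relationshipMatrix(ped)
  f <- is.na(slot(ped, "sire")) & is.na(slot(ped, "dam"))
  expect_equal(A[f, f], diag(sum(f)), ignore_attr = TRUE)
})

test_that("inbreeding matches the classical values and A's diagonal", {
  founders <- founderPedigree(c("x", "y", "z"))
  expect_equal(unname(inbreeding(founders)), c(0, 0, 0))

  # full-sib mating: offspring of two full sibs has F = 0.25
  ped <- sortPedigree(pedigree(
    c("gs", "gd", "s", "d", "k"),
    c(NA, NA, "gs", "gs", "s"),
    c(NA, NA, "gd", "gd", "d")))
  expect_equal(unname(inbreeding(ped)["k"]), 0.25)

  set.seed(51)
  ped <- randomPedigree(60)
  expect_equal(unname(inbreeding(ped)),
               unname(diag(relationshipMatrix(ped)) - 1), tolerance = 1e-12)
})

test_that("pedigree files round-trip and autodetect the delimiter", {
  set.seed(61)
  ped <- randomPedigree(30)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writePedigree(ped, tsv)
  back <- readPedigree(tsv)
  expect_identical(animalIds(back), animalIds(ped))
  expect_identical(slot(back, "sire"), slot(ped, "sire"))

  csv <- withr::local_tempfile(fileext = ".csv")
  writePedigree(ped, csv, sep = ",")
  expect_identical(animalIds(readPedigree(csv)), animalIds(ped))
})

test_that("a dam listed after her offspring still yields the same A", {
  rows <- data.frame(
    id = c("k", "s", "d"), sire = c("s", NA, NA), dam = c("d", NA, NA))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(
    data.frame(animal = rows$id, sire = ifelse(is.na(rows$sire), 0, rows$sire),
               dam = ifelse(is.na(rows$dam), 0, rows$dam), birth_year = 2016),
    f, sep = ",", row.names = FALSE, quote = FALSE)
  ped <- sortPedigree(readPedigree(f))
  A <- relationshipMatrix(ped)
  expect_equal(A["k", "s"], 0.5)
  expect_equal(A["k", "d"], 0.5)
})
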