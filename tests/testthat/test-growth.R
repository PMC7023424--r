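# records with two kids measured at several ages, for design-shape checks
twoKidRecords <- function(ages = c(0, 3, 6, 9, 12)) {
  kids <- data.frame(kid_id = c("k1", "k2"), dam_id = c("D1", "D2"),
                     sire_id = c("S1", "S1"), stringsAsFactors = FALSE)
  measures <- expand.grid(kid_id = c("k1", "k2"), age_months = ages,
                          stringsAsFactors = FALSE)
  measures$bw <- 2 + measures$age_months
  measures$cg <- 30 + 2 * measures$age_months
  makeRecords(kids, measures)
}

test_that("design dimensions follow the model structure", {
  kids <- data.frame(kid_id = "k1", dam_id = "D1", sire_id = "S1",
                     stringsAsFactors = FALSE)
  meas <- data.frame(kid_id = "k1", age_months = 0, bw = 2.0, cg = 31)
  rec <- makeRecords(kids, meas)
  ped <- founderPedigree(c("S1", "D1", "k1"))
  d <- buildGrowthDesign(rec, ped, "cg")
  expect_length(slot(d, "cellLevels"), 1L)
  expect_equal(nAnimals(slot(d, "pedigree")), 3L)
  expect_length(slot(d, "peLevels"), 1L)

  rec2 <- twoKidRecords()
  ped2 <- founderPedigree(c("S1", "D1", "D2", "k1", "k2"))
  d2 <- buildGrowthDesign(rec2, ped2, "cg")
  # repeatability structure: one permanent-env level per kid, five visits
  expect_length(slot(d2, "peLevels"), 2L)
  expect_equal(as.integer(table(slot(d2, "pe"))), c(5L, 5L))
  expect_length(slot(d2, "cellLevels"), 5L)
})

test_that("design column counts match independent tallies of the records", {
  cfg <- simulationConfig(n_kids = 150, n_dams = 70, n_sires = 10,
                          n_herds = 4)
  herd <- simulateHerd(cfg, seed = 13)
  d <- buildGrowthDesign(herd$records, herd$pedigree, "cg")
  m <- measures(herd$records)
  k <- kids(herd$records)
  ki <- match(m$kid_id, k$kid_id)
  cells <- unique(paste(m$age_months, k$sex[ki], k$parity[ki],
                        k$birth_type[ki]))
  expect_length(slot(d, "cellLevels"), length(cells))
  expect_length(slot(d, "damLevels"), length(unique(k$dam_id[ki])))
  expect_length(slot(d, "peLevels"), length(unique(m$kid_id)))
  expect_length(slot(d, "herdLevels"), length(unique(k$herd[ki])))
  expect_equal(length(slot(d, "y1")), nrow(m))
})

test_that("design rejects records of animals missing from the pedigree", {
  rec <- twoKidRecords()
  ped <- founderPedigree(c("S1", "D1", "k1"))  # k2, D2 missing
  expect_error(buildGrowthDesign(rec, ped, "cg"), "k2|D2")
  expect_error(
    buildGrowthDesign(makeRecords(data.frame(kid_id = character(0)),
                                  data.frame(kid_id = character(0))),
                      ped, "cg"),
    "empty")
})

test_that("missing second-trait visits are masked, not dropped", {
  rec <- twoKidRecords()
  m <- measures(rec)
  m$cg[c(2, 5)] <- NA
  rec <- makeRecords(kids(rec), m)
  ped <- founderPedigree(c("S1", "D1", "D2", "k1", "k2"))
  d <- buildGrowthDesign(rec, ped, "cg")
  expect_equal(length(slot(d, "y1")), nrow(m))
  expect_equal(sum(!slot(d, "obs2")), 2L)
})

test_that("same-seed chains are sample-identical", {
  cfg <- simulationConfig(n_kids = 80, n_dams = 40, n_sires = 8, n_herds = 3)
  herd <- simulateHerd(cfg, seed = 17)
  ch1 <- fitGrowthModel(herd$records, herd$pedigree, "cg", nIter = 150,
                        burnIn = 50, thin = 2, seed = 5, blockEvery = 40)
  ch2 <- fitGrowthModel(herd$records, herd$pedigree, "cg", nIter = 150,
                        burnIn = 50, thin = 2, seed = 5, blockEvery = 40)
  expect_identical(chainSamples(ch1), chainSamples(ch2))
  ch3 <- fitGrowthModel(herd$records, herd$pedigree, "cg", nIter = 150,
                        burnIn = 50, thin = 2, seed = 6, blockEvery = 40)
  expect_false(identical(chainSamples(ch1), chainSamples(ch3)))
})

test_that("every retained covariance sample is positive definite", {
  cfg <- simulationConfig(n_kids = 80, n_dams = 40, n_sires = 8, n_herds = 3)
  herd <- simulateHerd(cfg, seed = 19)
  ch <- fitGrowthModel(herd$records, herd$pedigree, "cg", nIter = 600,
                       burnIn = 100, thin = 2, seed = 1)
  s <- chainSamples(ch)
  for (t in c("a", "m", "p", "c", "e")) {
    v11 <- s[, paste0(t, ".11")]
    v12 <- s[, paste0(t, ".12")]
    v22 <- s[, paste0(t, ".22")]
    expect_true(all(v11 > 0))
    expect_true(all(v22 > 0))
    expect_true(all(v11 * v22 - v12^2 > 0))
  }
})

test_that("a null additive truth is recovered as a small component", {
  null_bw <- c(s2a = 1e-9, s2m = 0.2, s2p = 0.6, s2c = 0.2, s2e = 1.5)
  null_cg <- c(s2a = 1e-9, s2m = 0.9, s2p = 2.0, s2c = 0.6, s2e = 7.5)
  cfg <- simulationConfig(
    n_kids = 500, n_dams = 200, n_sires = 40, n_herds = 10,
    components = list(bw = null_bw, cg = null_cg, bl = null_cg,
                      hw = null_cg),
    rg = c(cg = 0, bl = 0, hw = 0))
  herd <- simulateHerd(cfg, seed = 23)
  ch <- fitGrowthModel(herd$records, herd$pedigree, "cg", nIter = 4000,
                       burnIn = 1000, thin = 3, seed = 1, blockEvery = 50)
  s <- chainSamples(ch)
  expect_lt(stats::median(s[, "a.11"]), 0.1 * stats::median(s[, "e.11"]))
})

test_that("with no data the sampler reproduces the fixed prior", {
  ped <- founderPedigree(sprintf("f%02d", 1:10))
  d <- methods::new("GrowthDesign",
    y1 = numeric(0), y2 = numeric(0), obs2 = logical(0),
    cell = integer(0), anim = integer(0), dam = integer(0),
    pe = integer(0), herd = integer(0),
    cellLevels = character(0), damLevels = character(0),
    peLevels = character(0), herdLevels = character(0),
    pedigree = ped, traits = c("bw", "cg"))
  ch <- fitGrowthModel(d, priors = priorSpec(nu = 4, scale = 0.1),
                       nIter = 6000, burnIn = 1000, thin = 2, seed = 3)
  s <- chainSamples(ch)
  # IW(4, 0.1 I) marginal of a diagonal element is IG(3/2, 1/20): compare
  # the sampled median with the closed-form median (the mean has no
  # finite-variance estimator under this heavy-tailed prior)
  med_ref <- 0.05 / stats::qgamma(0.5, shape = 1.5)
  for (t in c("m", "p", "c", "e")) {
    expect_equal(stats::median(s[, paste0(t, ".11")]), med_ref,
                 tolerance = 0.15)
  }
})

test_that("posterior heritability matches a parent-offspring oracle", {
  # parents carry their own records, single record per animal, additive +
  # residual truth; the midparent regression slope is an unbiased h2 oracle
  set.seed(29)
  nfam <- 250
  sire <- sprintf("s%03d", 1:nfam)
  dam <- sprintf("d%03d", 1:nfam)
  koff <- sprintf("k%03d", 1:(3 * nfam))
  fam <- rep(seq_len(nfam), each = 3)
  pd <- paste0("pd_", c(sire, dam))   # pseudo-dams for founder records
  ped <- sortPedigree(pedigree(c(pd, sire, dam, koff),
                               c(rep(NA, 4 * nfam), sire[fam]),
                               c(rep(NA, 4 * nfam), dam[fam])))
  h2true <- 0.5
  a <- drop(simulateBreedingValues(ped, matrix(1, 1, 1), seed = 31))
  y <- 10 + a + stats::rnorm(nAnimals(ped), 0, 1)  # a = e = 1
  ids <- animalIds(ped)
  names(y) <- ids
  # records for real animals only; recorded founders get a private
  # pseudo-dam (a founder in the pedigree) for the maternal factor
  rec_ids <- ids[!grepl("^pd_", ids)]
  sire_of <- stats::setNames(slot(ped, "sire"), ids)[rec_ids]
  dam_of <- stats::setNames(slot(ped, "dam"), ids)[rec_ids]
  kids_df <- data.frame(
    kid_id = rec_ids, sire_id = sire_of,
    dam_id = ifelse(is.na(dam_of), paste0("pd_", rec_ids), dam_of),
    # several herd levels so the (null) common-env term is identified
    herd = sample(sprintf("H%02d", 1:10), length(rec_ids), TRUE),
    stringsAsFactors = FALSE)
  meas <- data.frame(kid_id = rec_ids, age_months = 0, bw = y[rec_ids],
                     cg = NA_real_, bl = NA_real_, hw = NA_real_)
  rec <- makeRecords(kids_df, meas)
  ch <- fitGrowthModel(rec, ped, "cg", nIter = 8000, burnIn = 2000,
                       thin = 4, seed = 1, blockEvery = 40)
  s <- chainSamples(ch)
  h2post <- mean(heritability(s[, "a.11"], s[, "m.11"], s[, "p.11"],
                              s[, "c.11"], s[, "e.11"]))
  pos <- stats::setNames(seq_along(ids), ids)
  off <- grepl("^k", ids)
  mid <- (y[pos[slot(ped, "sire")[off]]] + y[pos[slot(ped, "dam")[off]]]) / 2
  oracle <- stats::coef(stats::lm(y[off] ~ mid))[2]
  expect_equal(h2post, unname(oracle), tolerance = 0.15)
  expect_equal(h2post, h2true, tolerance = 0.15)
})
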