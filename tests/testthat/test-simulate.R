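# a small herd configuration reused across generator tests
smallConfig <- function(...) {
  simulationConfig(n_kids = 200, n_dams = 90, n_sires = 12, n_herds = 4, ...)
}

# flat two-age configuration with essentially no deaths, for moment checks
flatConfig <- function(n_kids, n_dams, n_sires, n_herds, ...) {
  simulationConfig(
    n_kids = n_kids, n_dams = n_dams, n_sires = n_sires, n_herds = n_herds,
    age_months = c(0, 3), bw_age_means = c(2.1, 6.4),
    cg_age_means = c(30, 42), bl_age_means = c(28, 39),
    hw_age_means = c(28, 38), record_targets = c(n_kids, n_kids),
    survival = list(s2a = 0.05, s2m = 0.05, s2c = 1.78, s2e = 0.05,
                    bw_slope = 0.1, horizon = 360,
                    mortality_single = 1e-9, mortality_twin = 1e-9),
    ...)
}

test_that("config validation rejects impossible settings", {
  expect_error(simulationConfig(n_kids = 100, n_dams = 5, years = 2016),
               "infeasible")
  expect_error(simulationConfig(twin_fraction = 1.4))
  comps <- simulationConfig(n_kids = 50, n_dams = 25, n_sires = 5)$components
  comps$bw[["s2a"]] <- -1
  expect_error(simulationConfig(n_kids = 50, n_dams = 25, n_sires = 5,
                                components = comps), "negative")
})

test_that("survival calibration solves the probit targets exactly", {
  cfg <- simulationConfig()
  sv <- cfg$survival
  st <- cfg$survival_sigma_total
  # single-kid one-year death probability implied by the derived baseline
  mu_single <- cfg$survival_baseline +
    sv$bw_slope * (cfg$bw_age_means[1] - cfg$twin_effect_bw * cfg$twin_kid_share)
  expect_equal(pnorm((log(sv$horizon) - mu_single) / st),
               sv$mortality_single, tolerance = 1e-10)
  mu_twin <- mu_single + sv$bw_slope * cfg$twin_effect_bw +
    cfg$survival_twin_direct
  expect_equal(pnorm((log(sv$horizon) - mu_twin) / st),
               sv$mortality_twin, tolerance = 1e-10)
})

test_that("pedigree generator hits the study structure exactly", {
  cfg <- simulationConfig()
  ped <- simulatePedigree(cfg, seed = 1)
  ids <- animalIds(ped)
  expect_equal(sum(grepl("^K", ids)), 1538L)
  k <- kids(simulateRecords(cfg, seed = 1))
  expect_equal(nrow(k), 1538L)
  expect_equal(length(unique(k$dam_id)), 645L)
  expect_lte(length(unique(k$sire_id)), 106L)
  expect_true(isSorted(ped))
})

test_that("twin fraction controls litter sizes", {
  cfg <- smallConfig(twin_fraction = 0)
  k <- kids(simulateRecords(cfg, seed = 3))
  expect_true(all(k$birth_type == "single"))
  expect_equal(mean(table(k$litter_id)), 1.0)

  # ~10,000 litters: binomial expectation 1 + 0.4
  big <- flatConfig(n_kids = 14000, n_dams = 5000, n_sires = 400,
                    n_herds = 50)
  k <- kids(simulateRecords(big, seed = 4))
  expect_equal(mean(table(k$litter_id)), 1.4, tolerance = 0.02)
})

test_that("same seed reproduces byte-identical output files", {
  cfg <- smallConfig()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateHerd(cfg, seed = 9, dir = d1)
  simulateHerd(cfg, seed = 9, dir = d2)
  for (f in c("pedigree.tsv", "records.tsv", "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("breeding values follow the pedigree recursion", {
  set.seed(5)
  # zero covariance gives exactly zero values
  ped <- randomPedigree(40)
  expect_true(all(simulateBreedingValues(ped, matrix(0, 2, 2),
                                         seed = 1) == 0))

  # founder sample covariance approaches G0 (5% at 5000 founders)
  G0 <- diag(c(0.58, 2.56))
  founders <- founderPedigree(sprintf("f%04d", 1:5000))
  a <- simulateBreedingValues(founders, G0, seed = 6)
  expect_equal(unname(diag(stats::cov(a))), c(0.58, 2.56), tolerance = 0.05)

  # parent-offspring covariance is G0/2 (Monte-Carlo over 5000 pairs)
  np <- 5000
  ped2 <- sortPedigree(pedigree(
    c(sprintf("s%04d", 1:np), sprintf("k%04d", 1:np)),
    c(rep(NA, np), sprintf("s%04d", 1:np)),
    rep(NA_character_, 2 * np)))
  a2 <- simulateBreedingValues(ped2, G0, seed = 7)
  po <- stats::cov(a2[1:np, 1], a2[np + 1:np, 1])
  expect_equal(po, 0.58 / 2, tolerance = 0.05 * 0.58)
})

test_that("non-PSD additive covariance is rejected", {
  ped <- founderPedigree(c("a", "b"))
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulateBreedingValues(ped, bad), "positive semidefinite")
})

test_that("zero variances give deterministic fixed-effect means", {
  zero <- c(s2a = 0, s2m = 0, s2p = 0, s2c = 0, s2e = 1e-12)
  cfg <- smallConfig(
    components = list(bw = zero, cg = zero, bl = zero, hw = zero),
    sex_effect_bw = 0, sex_effect_conf = 0,
    twin_effect_bw = 0, twin_effect_conf = 0)
  rec <- simulateRecords(cfg, seed = 8)
  m <- measures(rec)
  for (i in seq_along(cfg$age_months)) {
    at <- m$bw[m$age_months == cfg$age_months[i]]
    expect_equal(at, rep(cfg$bw_age_means[i], length(at)), tolerance = 1e-4)
  }
})

test_that("simulated variance components match their targets", {
  cfg <- flatConfig(n_kids = 20000, n_dams = 6000, n_sires = 900,
                    n_herds = 300)
  rec <- simulateRecords(cfg, seed = 42, returnEffects = TRUE)
  ef <- attr(rec, "effects")
  truth <- cfg$components$bw
  # realised latent components (common env is drawn sum-to-zero)
  expect_equal(stats::var(ef$additive[, 1]), truth[["s2a"]], tolerance = 0.1)
  expect_equal(stats::var(ef$maternal[, 1]), truth[["s2m"]], tolerance = 0.1)
  expect_equal(stats::var(ef$permanent[, 1]), truth[["s2p"]],
               tolerance = 0.1)
  expect_equal(stats::var(ef$common[, 1]),
               truth[["s2c"]] * (1 - 1 / cfg$n_herds), tolerance = 0.15)

  # data-only method of moments on grouped means --------------------------
  m <- measures(rec)
  k <- kids(rec)
  ki <- match(m$kid_id, k$kid_id)
  y <- m$bw - stats::ave(m$bw, m$age_months)          # age-detrended
  y <- y - stats::ave(y, k$sex[ki])                   # sex contrast out
  y <- y - stats::ave(y, k$birth_type[ki])            # twin contrast out
  # residual variance from within-kid contrasts (2 records per kid)
  sp <- split(y, m$kid_id)
  stopifnot(all(lengths(sp) == 2))
  dmat <- matrix(unlist(sp), nrow = 2)
  s2e_hat <- stats::var(dmat[1, ] - dmat[2, ]) / 2
  expect_equal(s2e_hat, truth[["s2e"]], tolerance = 0.1)

  # kid-level persistent variance: a + m + p + c(realised)
  u <- colMeans(dmat)
  persist_hat <- stats::var(u) - s2e_hat / 2
  persist_tr <- truth[["s2a"]] + truth[["s2m"]] + truth[["s2p"]] +
    truth[["s2c"]] * (1 - 1 / cfg$n_herds)
  expect_equal(persist_hat, persist_tr, tolerance = 0.1 * persist_tr)

  # grouped-mean covariances: pair sums via the (sum^2 - sum of squares)
  # identity, u already centred by the contrasts above
  kk <- k[match(names(sp), k$kid_id), ]
  pairStats <- function(g) {
    S <- tapply(u, g, sum)
    Q <- tapply(u^2, g, sum)
    n <- tapply(u, g, length)
    c(num = sum(S^2 - Q), den = sum(n * (n - 1)))
  }
  damlev <- pairStats(kk$dam_id)
  litlev <- pairStats(kk$litter_id)
  herdlev <- pairStats(kk$herd)
  sirelev <- pairStats(kk$sire_id)
  sdlev <- pairStats(paste(kk$sire_id, kk$dam_id))
  # dam mates from different litters: cov = a/4 + m + c
  damx <- (damlev["num"] - litlev["num"]) / (damlev["den"] - litlev["den"])
  damx_tr <- truth[["s2a"]] / 4 + truth[["s2m"]] +
    truth[["s2c"]] * (1 - 1 / cfg$n_herds)
  expect_equal(unname(damx), damx_tr, tolerance = 0.1 * damx_tr)
  # herd mates sharing neither sire nor dam (inclusion-exclusion): cov = c
  hx_num <- herdlev["num"] - sirelev["num"] - damlev["num"] + sdlev["num"]
  hx_den <- herdlev["den"] - sirelev["den"] - damlev["den"] + sdlev["den"]
  expect_equal(unname(hx_num / hx_den),
               truth[["s2c"]] * (1 - 1 / cfg$n_herds),
               tolerance = 0.2 * truth[["s2c"]])
  # full sibs minus cross-litter dam mates isolates a/4 (noisier contrast)
  fullsib <- litlev["num"] / litlev["den"]
  expect_equal(unname(4 * (fullsib - damx)), truth[["s2a"]],
               tolerance = 0.3 * truth[["s2a"]])
})

test_that("record counts thin with age like the study's attrition", {
  cfg <- simulationConfig()
  m <- measures(simulateRecords(cfg, seed = 2))
  counts <- as.integer(table(factor(m$age_months, levels = cfg$age_months)))
  expect_equal(counts[1], 1538L)
  expect_true(all(diff(counts) < 0))
  expect_equal(counts, cfg$record_targets, tolerance = 0.12)
})

test_that("measurements never occur after death", {
  cfg <- smallConfig()
  rec <- simulateRecords(cfg, seed = 10)
  m <- measures(rec)
  k <- kids(rec)
  ki <- match(m$kid_id, k$kid_id)
  expect_true(all(m$age_months * 30 <= k$survival_days[ki]))
  expect_true(all(k$censored == (k$survival_days >= 360)))
})
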