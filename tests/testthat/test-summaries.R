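makeChain <- function(samples, model = "growth") {
  n <- nrow(samples)
  methods::new("MCMCChain", samples = samples,
               meta = list(model = model, n_iter = n, burn_in = 0L,
                           thin = 1L, seed = 1L))
}

growthSamples <- function(n, seed = 1) {
  set.seed(seed)
  cols <- goatQG:::.GROWTH_PAR
  s <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (t in c("a", "m", "p", "c", "e")) {
    v1 <- stats::rgamma(n, 5, 10)
    v2 <- stats::rgamma(n, 5, 2)
    r <- stats::runif(n, -0.9, 0.9)
    s[, paste0(t, ".11")] <- v1
    s[, paste0(t, ".22")] <- v2
    s[, paste0(t, ".12")] <- r * sqrt(v1 * v2)
  }
  s
}

test_that("HPD intervals are the shortest covering windows", {
  expect_equal(unname(hpdInterval(rep(3, 10))), c(3, 3))
  h <- hpdInterval(1:100, 0.95)
  expect_equal(unname(h[2] - h[1]), 95)
  expect_error(hpdInterval(2), "2 finite samples")
  expect_error(hpdInterval(1:10, 1.2), "prob")
  # as prob -> 1 the interval converges to the sample range
  x <- stats::rnorm(500)
  expect_equal(unname(hpdInterval(x, 0.9999)), range(x))
  # bimodal sample: the interval sits on the denser mode
  x <- c(rep(0, 90), rep(10, 10))
  expect_equal(unname(hpdInterval(x, 0.85)), c(0, 0))
})

test_that("95% HPD of standard-normal draws matches +-1.96", {
  set.seed(123)
  h <- hpdInterval(stats::rnorm(100000), 0.95)
  expect_equal(unname(h[1]), -1.96, tolerance = 0.05 / 1.96)
  expect_equal(unname(h[2]), 1.96, tolerance = 0.05 / 1.96)
})

test_that("heritability and repeatability reproduce the reference rows", {
  # posterior-mean components, body weight block
  expect_equal(round(heritability(0.58, 0.22, 0.55, 0.41, 1.57), 2), 0.17)
  # posterior-median components, body weight block
  expect_equal(round(repeatability(0.57, 0.23, 0.54, 0.42, 1.57), 2), 0.33)
  # chest girth means
  expect_equal(round(repeatability(2.56, 1.5, 2.08, 1.15, 7.95), 2), 0.30)
  expect_equal(heritability(0, 1, 1, 1, 1), 0)
  expect_equal(heritability(1, 1, 1, 1, 1), 0.2)
  # with no permanent environment, repeatability equals heritability
  expect_equal(repeatability(0.6, 0.2, 0, 0.1, 1),
               heritability(0.6, 0.2, 0, 0.1, 1))
  expect_error(heritability(0, 0, 0, 0, 0), "positive")
  expect_error(repeatability(-0.1, 1, 1, 1, 1), "non-negative")
})

test_that("genetic correlation is the usual standardised covariance", {
  expect_equal(geneticCorrelation(2, 0, 3), 0)
  expect_equal(geneticCorrelation(5, 5, 5), 1)
  expect_error(geneticCorrelation(0, 0, 1), "positive")
  g11 <- c(1, 2); g22 <- c(4, 1); g12 <- c(1, -0.5)
  expect_equal(geneticCorrelation(g11, g12, g22),
               g12 / sqrt(g11 * g22))
})

test_that("derived parameters respect their arithmetic identities", {
  s <- growthSamples(500)
  gp <- geneticParameters(makeChain(s))
  comp1 <- s[, c("a.11", "m.11", "p.11", "c.11", "e.11")]
  expect_equal(gp[, "s2ph.1"], unname(rowSums(comp1)))
  expect_true(all(gp[, "h2.1"] >= 0))
  expect_true(all(gp[, "h2.1"] <= gp[, "r.1"]))
  expect_true(all(gp[, "r.1"] <= 1))
  expect_true(all(gp[, "r_g"] >= -1 & gp[, "r_g"] <= 1))
})

test_that("chain summaries are order-invariant and degenerate-safe", {
  s <- growthSamples(400)
  ch <- makeChain(s)
  sm1 <- summarizeChain(ch)
  perm <- sample(nrow(s))
  sm2 <- summarizeChain(makeChain(s[perm, ]))
  expect_equal(sm1$mean, sm2$mean)
  expect_equal(sm1$lower, sm2$lower)

  const <- makeChain(s[rep(1, 50), ])
  smc <- summarizeChain(const)
  expect_equal(smc$mean, smc$median)
  expect_equal(smc$lower, smc$upper)
  expect_error(summarizeChain(makeChain(s[0, , drop = FALSE])), "empty")
})

test_that("effective sample size tracks the autocorrelation time", {
  set.seed(7)
  n <- 4000
  iid <- makeChain(cbind(x = stats::rnorm(n)), model = "growth")
  # bypass geneticParameters for a single-column chain
  ess_iid <- goatQG:::.iact(stats::rnorm(n))
  expect_equal(n / ess_iid, n, tolerance = 0.2)

  rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), n))
  expect_equal(n / goatQG:::.iact(ar), n * (1 - rho) / (1 + rho),
               tolerance = 0.3)
  expect_true(is.na(goatQG:::.iact(rep(1, 200))))
})

test_that("chainDiagnostics reports per-parameter ESS and Geweke z", {
  set.seed(8)
  s <- growthSamples(600)
  d <- chainDiagnostics(makeChain(s))
  expect_setequal(d$parameter, colnames(s))
  expect_true(all(d$ess > 0, na.rm = TRUE))
  expect_true(all(abs(d$geweke_z) < 5, na.rm = TRUE))
  # constant parameter flagged
  s[, "a.12"] <- 1
  d2 <- chainDiagnostics(makeChain(s))
  expect_true(d2$constant[d2$parameter == "a.12"])
  expect_true(is.na(d2$ess[d2$parameter == "a.12"]))
  expect_error(chainDiagnostics(makeChain(s[1:50, ])), "100")
})

test_that("summary tables can be written as delimited text", {
  sm <- summarizeChain(makeChain(growthSamples(100)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSummary(sm, f)
  back <- utils::read.delim(f)
  expect_equal(back$parameter, sm$parameter)
  expect_equal(back$mean, sm$mean, tolerance = 1e-9)
})
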