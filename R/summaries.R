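#' @include survival.R
NULL

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing \code{ceiling(prob * n)} of the
#' sorted samples.
#'
#' @param samples numeric vector of posterior draws.
#' @param prob coverage in (0, 1); default 0.95.
#' @return numeric c(lower, upper).
#' @examples
#' hpdInterval(1:100, 0.95)
#' @export
hpdInterval <- function(samples, prob = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stop("need at least 2 finite samples")
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)")
  x <- sort(samples)
  k <- ceiling(prob * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

.checkComponents <- function(...) {
  comps <- list(...)
  lens <- vapply(comps, length, integer(1))
  n <- max(lens)
  comps <- lapply(comps, rep_len, n)
  mat <- do.call(cbind, comps)
  if (any(mat < 0)) stop("variance components must be non-negative")
  tot <- rowSums(mat)
  if (any(tot <= 0)) stop("total (phenotypic) variance must be positive")
  list(mat = mat, tot = tot)
}

#' Heritability from variance components
#'
#' \eqn{h^2 = \sigma^2_a / \sigma^2_{ph}} with \eqn{\sigma^2_{ph} =
#' \sigma^2_a + \sigma^2_m + \sigma^2_p + \sigma^2_c + \sigma^2_e}.
#' Vectorised over posterior samples: feed the per-sample components and
#' summarise the resulting ratio samples (mean of ratios, not ratio of
#' means).
#'
#' @param s2a,s2m,s2p,s2c,s2e additive, maternal, permanent environmental,
#'   common environmental and residual variances (vectors recycle).
#' @return numeric vector of heritabilities.
#' @examples
#' heritability(0.58, 0.22, 0.55, 0.41, 1.57)  # ~0.17
#' @export
heritability <- function(s2a, s2m, s2p, s2c, s2e) {
  ck <- .checkComponents(s2a, s2m, s2p, s2c, s2e)
  ck$mat[, 1] / ck$tot
}

#' Repeatability from variance components
#'
#' \eqn{r = (\sigma^2_a + \sigma^2_p) / \sigma^2_{ph}}: the fraction of
#' phenotypic variance tied to the animal across repeated records, an
#' upper bound on heritability.
#'
#' @inheritParams heritability
#' @return numeric vector of repeatabilities.
#' @examples
#' repeatability(0.57, 0.23, 0.54, 0.42, 1.57)  # ~0.33
#' @export
repeatability <- function(s2a, s2m, s2p, s2c, s2e) {
  ck <- .checkComponents(s2a, s2m, s2p, s2c, s2e)
  (ck$mat[, 1] + ck$mat[, 3]) / ck$tot
}

#' Genetic correlation from additive (co)variances
#'
#' \eqn{r_g = g_{12} / \sqrt{g_{11} g_{22}}}.  No artificial clipping is
#' applied: samples stay in [-1, 1] exactly when the sampled 2x2 additive
#' matrix is positive semidefinite.
#'
#' @param g11,g22 additive variances of traits 1 and 2 (must be positive).
#' @param g12 additive covariance.
#' @return numeric vector of correlations.
#' @export
geneticCorrelation <- function(g11, g12, g22) {
  n <- max(length(g11), length(g12), length(g22))
  g11 <- rep_len(g11, n); g12 <- rep_len(g12, n); g22 <- rep_len(g22, n)
  if (any(g11 <= 0) || any(g22 <= 0)) {
    stop("additive variances must be positive")
  }
  g12 / sqrt(g11 * g22)
}

#' Per-sample derived genetic parameters of a chain
#'
#' For a growth chain: phenotypic variance, heritability and repeatability
#' of each trait and the genetic correlation, computed sample-wise from the
#' retained covariance draws.  For a survival chain: the heritability
#' ratio.
#'
#' @param chain an [MCMCChain-class].
#' @return numeric matrix, one row per retained sample.
#' @export
geneticParameters <- function(chain) {
  stopifnot(methods::is(chain, "MCMCChain"))
  s <- chain@samples
  if (chain@meta$model == "growth") {
    out <- cbind(
      s2ph.1 = s[, "a.11"] + s[, "m.11"] + s[, "p.11"] + s[, "c.11"] +
        s[, "e.11"],
      s2ph.2 = s[, "a.22"] + s[, "m.22"] + s[, "p.22"] + s[, "c.22"] +
        s[, "e.22"],
      h2.1 = heritability(s[, "a.11"], s[, "m.11"], s[, "p.11"],
                          s[, "c.11"], s[, "e.11"]),
      h2.2 = heritability(s[, "a.22"], s[, "m.22"], s[, "p.22"],
                          s[, "c.22"], s[, "e.22"]),
      r.1 = repeatability(s[, "a.11"], s[, "m.11"], s[, "p.11"],
                          s[, "c.11"], s[, "e.11"]),
      r.2 = repeatability(s[, "a.22"], s[, "m.22"], s[, "p.22"],
                          s[, "c.22"], s[, "e.22"]),
      r_g = geneticCorrelation(s[, "a.11"], s[, "a.12"], s[, "a.22"])
    )
  } else if (chain@meta$model == "survival") {
    out <- cbind(
      h2 = survivalHeritability(s[, "s2a"], s[, "s2m"], s[, "s2c"],
                                s[, "s2e"])
    )
  } else {
    stop(sprintf("unknown chain model: %s", chain@meta$model))
  }
  out
}

#' Posterior summary table of a chain
#'
#' Mean, median and HPD limits for every sampled parameter and every
#' derived genetic parameter ([geneticParameters()]), derived quantities
#' computed sample-wise before summarising.  Invariant to sample order.
#'
#' @param chain an [MCMCChain-class].
#' @param prob HPD coverage (default 0.95).
#' @return data.frame with columns parameter, mean, median, lower, upper.
#' @export
summarizeChain <- function(chain, prob = 0.95) {
  stopifnot(methods::is(chain, "MCMCChain"))
  s <- chain@samples
  if (!nrow(s)) stop("empty chain")
  full <- cbind(s, geneticParameters(chain))
  res <- t(apply(full, 2, function(x) {
    h <- if (length(unique(x)) == 1) c(x[1], x[1]) else hpdInterval(x, prob)
    c(mean(x), stats::median(x), h[1], h[2])
  }))
  data.frame(parameter = colnames(full),
             mean = res[, 1], median = res[, 2],
             lower = res[, 3], upper = res[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a posterior summary table as delimited text
#' @param summary data.frame from [summarizeChain()].
#' @param path output path.
#' @param sep separator (default tab).
#' @return invisibly, \code{path}.
#' @export
writeSummary <- function(summary, path, sep = "\t") {
  utils::write.table(summary, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# integrated autocorrelation time by Geyer's initial positive sequence
.iact <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  lag_max <- min(n - 1, floor(10 * sqrt(n)))
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
  tau <- 1
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  tau
}

#' Convergence diagnostics for a chain
#'
#' Effective sample size per parameter from the integrated autocorrelation
#' time (initial-positive-sequence estimator) and a Geweke-style z score
#' comparing the means of the first \code{frac1} and last \code{frac2} of
#' the retained samples (variances scaled by each window's effective size).
#' Constant parameters are flagged with \code{NA} diagnostics.
#'
#' @param chain an [MCMCChain-class] with at least 100 retained samples.
#' @param frac1,frac2 Geweke window fractions (defaults 0.1 and 0.5).
#' @return data.frame with columns parameter, ess, geweke_z, constant.
#' @export
chainDiagnostics <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  stopifnot(methods::is(chain, "MCMCChain"))
  s <- chain@samples
  n <- nrow(s)
  if (n < 100) stop("need at least 100 retained samples for diagnostics")
  out <- lapply(colnames(s), function(p) {
    x <- s[, p]
    tau <- .iact(x)
    if (is.na(tau)) {
      return(data.frame(parameter = p, ess = NA_real_,
                        geweke_z = NA_real_, constant = TRUE))
    }
    ess <- n / tau
    a <- x[seq_len(max(2, floor(frac1 * n)))]
    b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
    ta <- .iact(a); tb <- .iact(b)
    se <- sqrt(stats::var(a) * ta / length(a) +
                 stats::var(b) * tb / length(b))
    z <- if (is.finite(se) && se > 0) (mean(a) - mean(b)) / se else NA_real_
    data.frame(parameter = p, ess = ess, geweke_z = z, constant = FALSE)
  })
  do.call(rbind, out)
}
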