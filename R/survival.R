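#' @include growth.R
NULL

#' Censor kid survival records at a horizon
#'
#' Builds the accelerated-failure-time design: kids alive at the horizon
#' are flagged censored with their time set to the horizon; deaths keep
#' their observed day count, with zero-day deaths floored at half a day
#' before taking logs.  The fixed part is an intercept plus the kid's
#' recorded birth weight; random terms are additive (pedigree), maternal
#' (dam) and herd x birth-year x season.
#'
#' @param records a [KidRecords-class]; every kid needs survival days and a
#'   birth-weight record.
#' @param ped a [Pedigree-class] covering all kids and parents.
#' @param horizon censoring horizon in days (default 360); must not exceed
#'   the horizon the data were recorded under.
#' @return a [SurvivalDesign-class].
#' @export
censorRecords <- function(records, ped, horizon = 360) {
  stopifnot(methods::is(records, "KidRecords"), methods::is(ped, "Pedigree"))
  if (!isSorted(ped)) ped <- sortPedigree(ped)
  k <- records@kids
  if (anyNA(k$survival_days)) {
    stop("survival_days must be present for every kid")
  }
  if (any(k$survival_days < 0)) stop("negative survival days")
  flagged <- !is.na(k$censored) & k$censored
  if (any(flagged & k$survival_days < horizon)) {
    stop("records already censored before the requested horizon are not supported")
  }
  censored <- k$survival_days >= horizon | flagged
  days <- pmin(k$survival_days, horizon)
  days[days == 0] <- 0.5     # documented floor for day-of-birth deaths
  log_time <- log(days)
  log_time[censored] <- log(horizon)

  m <- records@measures
  birth <- m[m$age_months == 0 & !is.na(m$bw), ]
  bw0 <- birth$bw[match(k$kid_id, birth$kid_id)]
  if (anyNA(bw0)) {
    stop(sprintf("kid(s) without a birth-weight record: %s",
                 paste(utils::head(k$kid_id[is.na(bw0)], 5), collapse = ", ")))
  }
  if (any(bw0 <= 0)) {
    warning(sprintf(
      "%d kid(s) with non-positive recorded birth weight (kept as covariate values)",
      sum(bw0 <= 0)))
  }
  anim <- match(k$kid_id, animalIds(ped))
  if (anyNA(anim)) {
    stop(sprintf("kid(s) absent from pedigree: %s",
                 paste(utils::head(k$kid_id[is.na(anim)], 5), collapse = ", ")))
  }
  dam_f <- factor(k$dam_id)
  grp_f <- factor(paste(k$herd, k$birth_year, k$season, sep = ":"))
  X <- cbind(intercept = 1, birth_weight = bw0)
  methods::new("SurvivalDesign",
    logTime = log_time, censored = censored, X = X,
    anim = as.integer(anim), dam = as.integer(dam_f),
    group = as.integer(grp_f),
    groupLevels = levels(grp_f), damLevels = levels(dam_f),
    pedigree = ped, horizon = horizon)
}

# sparse incidence for the survival model: X columns | animals | dams | groups
.survIncidence <- function(design) {
  n <- length(design@logTime)
  p <- ncol(design@X)
  np <- nAnimals(design@pedigree)
  nd <- length(design@damLevels)
  ng <- length(design@groupLevels)
  Xs <- methods::as(Matrix::Matrix(design@X, sparse = TRUE), "CsparseMatrix")
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 3),
    j = c(design@anim, np + design@dam, np + nd + design@group),
    x = 1, dims = c(n, np + nd + ng))
  cbind(Xs, Z)
}

.survPriorPads <- function(design, ai) {
  p <- ncol(design@X)
  np <- nAnimals(design@pedigree)
  nd <- length(design@damLevels)
  ng <- length(design@groupLevels)
  q <- p + np + nd + ng
  rows <- rep(seq_len(np), diff(ai$ptr))
  Apad <- Matrix::sparseMatrix(i = p + rows, j = p + ai$idx + 1L,
                               x = ai$val, dims = c(q, q))
  blockDiag <- function(off, len) {
    Matrix::sparseMatrix(i = off + seq_len(len), j = off + seq_len(len),
                         x = 1, dims = c(q, q))
  }
  list(A = Apad, M = blockDiag(p + np, nd), C = blockDiag(p + np + nd, ng),
       q = q, dims = c(p = p, np = np, nd = nd, ng = ng))
}

.initSurvState <- function(design) {
  n <- length(design@logTime)
  p <- ncol(design@X)
  np <- nAnimals(design@pedigree)
  nd <- length(design@damLevels)
  ng <- length(design@groupLevels)
  y <- design@logTime
  b <- numeric(p)
  b[1] <- mean(y)
  v <- max(stats::var(y), 1e-3)
  e <- y - b[1]
  list(b = b, a = numeric(np), m = numeric(nd), c = numeric(ng),
       var = c(0.2 * v, 0.2 * v, 0.2 * v, 0.5 * v), y = y, e = e)
}

# joint draw of all survival location effects given current variances
.jointSurvDraw <- function(stt, W, pads) {
  v <- stt$var
  d <- pads$dims
  theta_old <- c(stt$b, stt$a, stt$m, stt$c)
  fitted <- as.numeric(W %*% theta_old)
  y <- stt$e + fitted   # current augmented log-times
  CC <- Matrix::crossprod(W) / v[4] + pads$A / v[1] + pads$M / v[2] +
    pads$C / v[3]
  CC <- methods::as(Matrix::forceSymmetric(CC), "CsparseMatrix")
  rhs <- as.numeric(Matrix::crossprod(W, y)) / v[4]
  ch <- Matrix::Cholesky(CC, LDL = FALSE, perm = TRUE)
  mean_ <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  z <- stats::rnorm(length(rhs))
  noise <- as.numeric(Matrix::solve(ch,
    Matrix::solve(ch, z, system = "Lt"), system = "Pt"))
  theta <- mean_ + noise
  off <- cumsum(c(0, d["p"], d["np"], d["nd"]))
  stt$b <- theta[seq_len(d["p"])]
  stt$a <- theta[off[2] + seq_len(d["np"])]
  stt$m <- theta[off[3] + seq_len(d["nd"])]
  stt$c <- theta[off[4] + seq_len(d["ng"])]
  stt$e <- y - as.numeric(W %*% theta)
  stt$y <- y
  stt
}

#' Fit the censored log-normal AFT animal model by Gibbs sampling
#'
#' Log survival time is modelled as intercept + birth-weight slope +
#' additive (pedigree) + maternal (dam) + herd-year-season + residual, all
#' random effects Gaussian on the log scale.  Right-censored kids have
#' their log times augmented each scan from the truncated-normal full
#' conditional above log(horizon); variances are drawn from inverse-gamma
#' full conditionals (the additive one through \eqn{a' A^{-1} a}).  As in
#' [fitGrowthModel()], compiled single-site scans are interleaved with
#' periodic joint draws of all location effects from the sparse mixed-model
#' equations.
#'
#' @param x a [KidRecords-class] (with \code{ped}) or a
#'   [SurvivalDesign-class].
#' @param ped pedigree; required with a records object.
#' @param horizon censoring horizon in days.
#' @param priors a [priorSpec()]; scalar terms use the inverse-gamma
#'   reduction (shape \code{nu/2}, rate \code{scale/2}).
#' @param errorFamily residual family on the time scale; only
#'   \code{"lognormal"} (Gaussian on log-time) is supported, as only
#'   Gaussian effects yield the variance-ratio heritability this model
#'   reports.
#' @param nIter,burnIn,thin chain settings.
#' @param seed RNG seed.
#' @param blockEvery interval between joint location draws (0 disables).
#' @return an [MCMCChain-class] with columns \code{intercept},
#'   \code{birth_weight} (the log-scale slope), \code{s2a}, \code{s2m},
#'   \code{s2c}, \code{s2e}; the final augmented log-times are kept in the
#'   metadata as \code{augmented_logtime}.
#' @export
fitSurvivalModel <- function(x, ped = NULL, horizon = 360,
                             priors = priorSpec(),
                             errorFamily = c("lognormal", "exponential"),
                             nIter = 100000L, burnIn = 10000L, thin = 10L,
                             seed = 1L, blockEvery = 20L) {
  errorFamily <- match.arg(errorFamily)
  if (errorFamily == "exponential") {
    stop("exponential-error AFT is not implemented; use the log-normal family")
  }
  if (methods::is(x, "KidRecords")) {
    if (is.null(ped)) stop("a pedigree is required with a records object")
    design <- censorRecords(x, ped, horizon)
  } else if (methods::is(x, "SurvivalDesign")) {
    design <- x
  } else {
    stop("x must be a KidRecords or SurvivalDesign object")
  }
  stopifnot(inherits(priors, "PriorSpec"))
  if (all(design@censored)) {
    stop("all records are censored: survival time is unidentifiable")
  }
  if (nIter <= burnIn) stop("nIter must exceed burnIn")
  ai <- .ainvRows(design@pedigree)
  use_block <- blockEvery > 0
  if (use_block) {
    W <- .survIncidence(design)
    pads <- .survPriorPads(design, ai)
  }
  set.seed(as.integer(seed))
  stt <- .initSurvState(design)
  sv_scale <- .priorScale(priors, max(stats::var(design@logTime), 1e-3))
  p <- ncol(design@X)
  samples <- matrix(NA_real_, nIter, p + 4)
  it <- 0L
  seg <- if (use_block) as.integer(blockEvery) else as.integer(nIter)
  while (it < nIter) {
    S <- min(seg, nIter - it)
    res <- gibbs_aft_scan_cpp(
      design@censored, log(design@horizon), design@X,
      design@anim, design@dam, design@group,
      nAnimals(design@pedigree), length(design@damLevels),
      length(design@groupLevels),
      ai$ptr, ai$idx, ai$val,
      priors$nu / 2, sv_scale / 2, stt, S)
    samples[it + seq_len(S), ] <- res$samples
    stt <- res$state
    it <- it + S
    if (use_block && it < nIter) {
      stt <- .jointSurvDraw(stt, W, pads)
    }
  }
  keep <- seq.int(burnIn + thin, nIter, by = thin)
  samples <- samples[keep, , drop = FALSE]
  colnames(samples) <- c(colnames(design@X), "s2a", "s2m", "s2c", "s2e")
  methods::new("MCMCChain",
    samples = samples,
    meta = list(model = "survival",
                n_iter = as.integer(nIter), burn_in = as.integer(burnIn),
                thin = as.integer(thin), seed = as.integer(seed),
                block_every = as.integer(blockEvery),
                priors = c(unclass(priors), list(scale_used = sv_scale)),
                horizon = design@horizon,
                n_kids = length(design@logTime),
                n_censored = sum(design@censored),
                n_animals = nAnimals(design@pedigree),
                n_dams = length(design@damLevels),
                n_groups = length(design@groupLevels),
                augmented_logtime = as.numeric(stt$y)))
}

#' Heritability of survival on the log-time scale
#'
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_m + \sigma^2_c +
#' \sigma^2_e)} — the survival model carries no permanent-environment term
#' (one survival outcome per kid).
#'
#' @param s2a,s2m,s2c,s2e variance components (vectors recycle).
#' @return numeric vector of ratios.
#' @examples
#' survivalHeritability(0.05, 0.05, 1.78, 0.05)
#' @export
survivalHeritability <- function(s2a, s2m, s2c, s2e) {
  if (any(c(s2a, s2m, s2c, s2e) < 0)) {
    stop("variance components must be non-negative")
  }
  tot <- s2a + s2m + s2c + s2e
  if (any(tot <= 0)) stop("total variance must be positive")
  s2a / tot
}
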