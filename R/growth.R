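#' @include records-io.R
NULL

#' Prior specification for the variance-component samplers
#'
#' One inverse-Wishart prior shared by all 2x2 covariance terms of the
#' bivariate growth model (degrees of freedom \code{nu}, diagonal scale
#' matrix); scalar terms of the survival model use its dimension-1
#' reduction, the inverse gamma with shape \code{nu/2} and rate
#' \code{scale/2}.
#'
#' By default (\code{scale = NULL}) the scale is set \emph{per fit} to
#' \code{fraction} times the raw within-cell phenotypic variance of each
#' trait, i.e. the prior expects each of the five terms to carry a modest
#' share of the phenotypic variance.  This keeps the prior weakly
#' informative \emph{on the scale of the data}: a fixed small scale (say
#' 0.1) looks innocuous but in a weakly identified variance decomposition
#' it actively drags the maternal, permanent-environment and
#' common-environment components towards zero and piles their variance
#' onto the additive term, whose full conditional is dominated by the
#' pedigree-augmented effects.  A fixed numeric \code{scale} is still
#' accepted (and used exactly) for analyses that need a set prior, e.g.
#' prior-predictive checks.
#'
#' @param nu degrees of freedom; must exceed 1 (dimension - 1 for 2x2).
#'   The default \code{nu = 3} (dimension + 1) gives heavy-tailed
#'   marginals and a uniform prior on the within-term correlation, so the
#'   prior does not pin weakly identified components near any particular
#'   value; its mean is undefined, which is the price of that flatness.
#' @param scale scalar scale, or \code{NULL} for the data-scaled default.
#' @param fraction share of each trait phenotypic variance used as scale
#'   when \code{scale} is \code{NULL}.
#' @return list of class \code{PriorSpec}.
#' @export
priorSpec <- function(nu = 3, scale = NULL, fraction = 0.2) {
  if (nu <= 1) stop("prior degrees of freedom must exceed dimension - 1")
  if (!is.null(scale) && scale <= 0) stop("prior scale must be positive")
  if (fraction <= 0) stop("prior fraction must be positive")
  structure(list(nu = nu, scale = scale, fraction = fraction),
            class = "PriorSpec")
}

# resolve the (possibly data-scaled) prior scale for one trait
.priorScale <- function(priors, rawvar) {
  if (!is.null(priors$scale)) priors$scale else priors$fraction * rawvar
}

#' Build the design for the bivariate growth model
#'
#' One row per measurement visit.  Fixed effects are the full
#' age x sex x parity x birth-type interaction coded as cell means with
#' unobserved cells dropped; random terms are additive (pedigree position),
#' maternal (dam), permanent environment (kid) and common environment
#' (herd).  Visits with a missing second trait are masked for imputation,
#' not dropped; visits with missing body weight are dropped with a warning.
#'
#' @param records a [KidRecords-class].
#' @param ped a [Pedigree-class] containing every recorded kid and both of
#'   its parents (sorted automatically if needed).
#' @param trait2 the conformation trait paired with body weight:
#'   \code{"cg"}, \code{"bl"} or \code{"hw"}.
#' @return a [GrowthDesign-class].
#' @export
buildGrowthDesign <- function(records, ped, trait2 = c("cg", "bl", "hw")) {
  stopifnot(methods::is(records, "KidRecords"), methods::is(ped, "Pedigree"))
  trait2 <- match.arg(trait2)
  if (!isSorted(ped)) ped <- sortPedigree(ped)
  m <- records@measures
  k <- records@kids
  if (!nrow(m)) stop("empty record set: no measurement rows")
  drop_bw <- is.na(m$bw)
  if (any(drop_bw)) {
    warning(sprintf("dropping %d visit(s) with missing body weight",
                    sum(drop_bw)))
    m <- m[!drop_bw, , drop = FALSE]
    if (!nrow(m)) stop("empty record set after dropping missing body weight")
  }
  ki <- match(m$kid_id, k$kid_id)
  parents <- c(k$sire_id[ki], k$dam_id[ki])
  miss_ped <- setdiff(unique(c(m$kid_id, parents[!is.na(parents)])),
                      animalIds(ped))
  if (length(miss_ped)) {
    stop(sprintf("animal(s) absent from pedigree: %s",
                 paste(utils::head(miss_ped, 5), collapse = ", ")))
  }
  cov_na <- is.na(k$sex[ki]) | is.na(k$parity[ki]) |
    is.na(k$birth_type[ki]) | is.na(m$age_months)
  if (any(cov_na)) stop("missing fixed-effect covariates on measurement rows")

  cell_f <- interaction(m$age_months, k$sex[ki], k$parity[ki],
                        k$birth_type[ki], drop = TRUE, sep = ":")
  dam_f <- factor(k$dam_id[ki])
  pe_f <- factor(m$kid_id)
  herd_f <- factor(k$herd[ki])
  y2 <- m[[trait2]]
  methods::new("GrowthDesign",
    y1 = as.numeric(m$bw), y2 = as.numeric(y2), obs2 = !is.na(y2),
    cell = as.integer(cell_f), anim = match(m$kid_id, animalIds(ped)),
    dam = as.integer(dam_f), pe = as.integer(pe_f),
    herd = as.integer(herd_f),
    cellLevels = levels(cell_f), damLevels = levels(dam_f),
    peLevels = levels(pe_f), herdLevels = levels(herd_f),
    pedigree = ped, traits = c("bw", trait2))
}

.GROWTH_PAR <- as.vector(outer(c("11", "12", "22"),
                               c("a", "m", "p", "c", "e"),
                               function(s, t) paste(t, s, sep = ".")))

# sparse incidence of all location effects, one row per measurement visit;
# column blocks: cells | pedigree animals | dams | kids (pe) | herds
.growthIncidence <- function(design) {
  n <- length(design@y1)
  nc <- length(design@cellLevels)
  np <- nAnimals(design@pedigree)
  nd <- length(design@damLevels)
  nk <- length(design@peLevels)
  nh <- length(design@herdLevels)
  offs <- cumsum(c(0, nc, np, nd, nk))
  Matrix::sparseMatrix(
    i = rep(seq_len(n), 5),
    j = c(design@cell, offs[2] + design@anim, offs[3] + design@dam,
          offs[4] + design@pe, offs[5] + design@herd),
    x = 1, dims = c(n, nc + np + nd + nk + nh))
}

# q x q padded prior-structure matrices (additive block carries A^{-1})
.growthPriorPads <- function(design, ai) {
  nc <- length(design@cellLevels)
  np <- nAnimals(design@pedigree)
  nd <- length(design@damLevels)
  nk <- length(design@peLevels)
  nh <- length(design@herdLevels)
  q <- nc + np + nd + nk + nh
  rows <- rep(seq_len(np), diff(ai$ptr))
  Apad <- Matrix::sparseMatrix(i = nc + rows, j = nc + ai$idx + 1L,
                               x = ai$val, dims = c(q, q))
  blockDiag <- function(off, len) {
    Matrix::sparseMatrix(i = off + seq_len(len), j = off + seq_len(len),
                         x = 1, dims = c(q, q))
  }
  list(A = Apad, M = blockDiag(nc + np, nd), P = blockDiag(nc + np + nd, nk),
       C = blockDiag(nc + np + nd + nk, nh), q = q,
       dims = c(nc = nc, np = np, nd = nd, nk = nk, nh = nh))
}

.cov3ToMat <- function(v) matrix(c(v[1], v[2], v[2], v[3]), 2, 2)

# Precomputed triplet assembler for the 2q x 2q mixed-model-equation
# coefficient matrix  sum_t  kron(S_t, B_t)  with fixed sparse structure
# matrices S_t and varying dense 2x2 blocks B_t.  Only lower-triangle
# entries are kept; sparseMatrix() then sums duplicates into a symmetric
# matrix in one pass, which is far cheaper than repeated sparse additions.
.kronAssembler <- function(structs, q) {
  I <- integer(0); J <- integer(0)
  piece <- list()
  for (nm in names(structs)) {
    Tm <- methods::as(methods::as(structs[[nm]], "generalMatrix"),
                      "TsparseMatrix")
    i0 <- Tm@i; j0 <- Tm@j; v <- Tm@x
    ii <- integer(0); jj <- integer(0); vv <- numeric(0); bi <- integer(0)
    k <- 0L
    for (s in 1:2) for (t in 1:2) {
      k <- k + 1L
      ri <- 2L * i0 + s
      ci <- 2L * j0 + t
      keep <- ri >= ci
      ii <- c(ii, ri[keep]); jj <- c(jj, ci[keep])
      vv <- c(vv, v[keep]); bi <- c(bi, rep(k, sum(keep)))
    }
    piece[[nm]] <- list(v = vv, bidx = bi, n = length(vv))
    I <- c(I, ii); J <- c(J, jj)
  }
  list(I = I, J = J, piece = piece, dim = 2L * q)
}

# B per structure as 2x2 matrices, order matching the assembler call
.assembleCC <- function(asm, Bs) {
  xs <- vector("list", length(Bs))
  for (u in seq_along(Bs)) {
    p <- asm$piece[[u]]
    xs[[u]] <- p$v * as.vector(Bs[[u]])[p$bidx]
  }
  Matrix::sparseMatrix(i = asm$I, j = asm$J, x = unlist(xs, use.names = FALSE),
                       dims = c(asm$dim, asm$dim), symmetric = TRUE)
}

# initial chain state: cell means for the fixed part, zero effects,
# moderate covariances anchored on the raw cell-residual variance
.initGrowthState <- function(design) {
  n <- length(design@y1)
  nc <- max(length(design@cellLevels), 1L)
  np <- nAnimals(design@pedigree)
  nd <- max(length(design@damLevels), 1L)
  nk <- max(length(design@peLevels), 1L)
  nh <- max(length(design@herdLevels), 1L)
  b1 <- rep(0, nc); b2 <- rep(0, nc)
  v1 <- v2 <- 1
  if (n > 0) {
    mu1 <- mean(design@y1)
    b1 <- tapply(design@y1, factor(design@cell, levels = seq_len(nc)), mean)
    b1[is.na(b1)] <- mu1
    yy2 <- design@y2[design@obs2]
    mu2 <- if (length(yy2)) mean(yy2) else 0
    cc2 <- design@cell[design@obs2]
    b2 <- tapply(yy2, factor(cc2, levels = seq_len(nc)), mean)
    b2[is.na(b2)] <- mu2
    r1 <- design@y1 - b1[design@cell]
    v1 <- max(stats::var(r1), 1e-3)
    if (length(yy2) > 1) {
      r2 <- yy2 - b2[cc2]
      v2 <- max(stats::var(r2), 1e-3)
    }
  }
  cv <- function(s) c(s * v1, 0.05 * s * sqrt(v1 * v2), s * v2)
  e1 <- design@y1 - b1[design@cell]
  e2 <- ifelse(design@obs2, design@y2 - b2[design@cell], 0)
  list(b1 = as.numeric(b1), b2 = as.numeric(b2),
       a1 = numeric(np), a2 = numeric(np),
       m1 = numeric(nd), m2 = numeric(nd),
       p1 = numeric(nk), p2 = numeric(nk),
       c1 = numeric(nh), c2 = numeric(nh),
       cov = c(cv(0.3), cv(0.2), cv(0.2), cv(0.2), cv(0.5)),
       e1 = as.numeric(e1), e2 = as.numeric(e2), rawvar = c(v1, v2))
}

# Blocked update: draw every location effect jointly from its Gaussian full
# conditional given the current covariances, via the sparse mixed-model
# equations with the A^{-1} (x) G^{-1} additive penalty.  This is what lets
# the chain traverse the weakly identified ridges (additive vs permanent
# environment, additive family means vs maternal/herd effects) that
# single-site scans cross only very slowly.
.jointGrowthDraw <- function(stt, design, W, WtW, pads, asm) {
  cov <- stt$cov
  Gi <- solve(.cov3ToMat(cov[1:3]))
  Mi <- solve(.cov3ToMat(cov[4:6]))
  Pi <- solve(.cov3ToMat(cov[7:9]))
  Ci <- solve(.cov3ToMat(cov[10:12]))
  R0 <- .cov3ToMat(cov[13:15])
  R0i <- solve(R0)
  d <- pads$dims
  TH <- cbind(c(stt$b1, stt$a1, stt$m1, stt$p1, stt$c1),
              c(stt$b2, stt$a2, stt$m2, stt$p2, stt$c2))
  fitted <- as.matrix(W %*% TH)
  Y <- cbind(stt$e1 + fitted[, 1], stt$e2 + fitted[, 2])
  CC <- .assembleCC(asm, list(R0i, Gi, Mi, Pi, Ci))
  rhs <- as.numeric(t(as.matrix(Matrix::crossprod(W, Y)) %*% R0i))
  ch <- Matrix::Cholesky(CC, LDL = FALSE, perm = TRUE)
  mean_ <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  z <- stats::rnorm(length(rhs))
  noise <- as.numeric(Matrix::solve(ch,
    Matrix::solve(ch, z, system = "Lt"), system = "Pt"))
  theta <- mean_ + noise
  THn <- t(matrix(theta, 2, pads$q))
  off <- cumsum(c(0, d["nc"], d["np"], d["nd"], d["nk"]))
  stt$b1 <- THn[seq_len(d["nc"]), 1]; stt$b2 <- THn[seq_len(d["nc"]), 2]
  stt$a1 <- THn[off[2] + seq_len(d["np"]), 1]
  stt$a2 <- THn[off[2] + seq_len(d["np"]), 2]
  stt$m1 <- THn[off[3] + seq_len(d["nd"]), 1]
  stt$m2 <- THn[off[3] + seq_len(d["nd"]), 2]
  stt$p1 <- THn[off[4] + seq_len(d["nk"]), 1]
  stt$p2 <- THn[off[4] + seq_len(d["nk"]), 2]
  stt$c1 <- THn[off[5] + seq_len(d["nh"]), 1]
  stt$c2 <- THn[off[5] + seq_len(d["nh"]), 2]
  fit_n <- as.matrix(W %*% THn)
  stt$e1 <- Y[, 1] - fit_n[, 1]
  stt$e2 <- Y[, 2] - fit_n[, 2]
  stt
}

# Pieces of the restricted (location-effects-integrated) log likelihood
# that depend on G0 and P0, given the current augmented data and R0/M0/C0.
# Used by the Metropolis exchange move below; all terms constant in
# (G0, P0) are dropped.
.growthMarginalPiece <- function(Gm, Pm, base, pads, rhs) {
  if (!all(is.finite(Gm)) || !all(is.finite(Pm)) ||
      det(Gm) <= 0 || det(Pm) <= 0 || Gm[1, 1] <= 0 || Pm[1, 1] <= 0) {
    return(-Inf)
  }
  Gi <- solve(Gm)
  Pi <- solve(Pm)
  CC <- .assembleCC(base$asm, list(base$R0i, Gi, base$Mi, Pi, base$Ci))
  ch <- tryCatch(Matrix::Cholesky(CC, LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ldet <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
  quad <- sum(rhs * as.numeric(Matrix::solve(ch, rhs, system = "A")))
  np <- pads$dims[["np"]]
  nk <- pads$dims[["nk"]]
  -0.5 * (np * log(det(Gm)) + nk * log(det(Pm)) + ldet - quad)
}

.iwLogDens <- function(S0, nu, X) {
  # inverse-Wishart_2(nu, S0) log density up to a constant
  dX <- det(X)
  if (!is.finite(dX) || dX <= 0) return(-Inf)
  -0.5 * ((nu + 3) * log(dX) + sum(diag(S0 %*% solve(X))))
}

# Metropolis exchange of variance between the additive and the
# permanent-environment covariance (G0 + P0 held fixed), accepted against
# the marginal likelihood with all location effects integrated out via the
# sparse mixed-model equations.  The additive-vs-permanent split is only
# weakly identified at herd scale, so the Gibbs chain alone crosses this
# ridge far too slowly; this move lets the chain traverse it directly.
.ridgeSwapGrowth <- function(stt, design, W, WtW, pads, asm, priors, s1,
                             s2, n_prop = 2L, tau = 0.25) {
  cov <- stt$cov
  G <- .cov3ToMat(cov[1:3]); M <- .cov3ToMat(cov[4:6])
  P <- .cov3ToMat(cov[7:9]); C <- .cov3ToMat(cov[10:12])
  R0 <- .cov3ToMat(cov[13:15])
  Mi <- solve(M); Ci <- solve(C); R0i <- solve(R0)
  TH <- cbind(c(stt$b1, stt$a1, stt$m1, stt$p1, stt$c1),
              c(stt$b2, stt$a2, stt$m2, stt$p2, stt$c2))
  fitted <- as.matrix(W %*% TH)
  Y <- cbind(stt$e1 + fitted[, 1], stt$e2 + fitted[, 2])
  base <- list(asm = asm, R0i = R0i, Mi = Mi, Ci = Ci)
  rhs <- as.numeric(t(as.matrix(Matrix::crossprod(W, Y)) %*% R0i))
  S0 <- diag(c(s1, s2))
  nu <- priors$nu
  cur <- .growthMarginalPiece(G, P, base, pads, rhs) +
    .iwLogDens(S0, nu, G) + .iwLogDens(S0, nu, P)
  K <- 0.5 * (G + P)   # invariant under the exchange: symmetric proposal
  for (rep in seq_len(n_prop)) {
    delta <- stats::rnorm(1, 0, tau)
    Gp <- G + delta * K
    Pp <- P - delta * K
    prop <- .growthMarginalPiece(Gp, Pp, base, pads, rhs)
    if (is.finite(prop)) {
      prop <- prop + .iwLogDens(S0, nu, Gp) + .iwLogDens(S0, nu, Pp)
    }
    if (is.finite(prop) && log(stats::runif(1)) < prop - cur) {
      G <- Gp; P <- Pp; cur <- prop
    }
  }
  stt$cov[1:3] <- c(G[1, 1], G[1, 2], G[2, 2])
  stt$cov[7:9] <- c(P[1, 1], P[1, 2], P[2, 2])
  stt
}

#' Fit the bivariate repeatability-maternal animal model by Gibbs sampling
#'
#' Location effects (fixed cells, additive, maternal, permanent
#' environment, common environment) and the five 2x2 covariance matrices
#' are sampled by a hybrid Gibbs scheme: single-site scans in compiled code
#' (additive and permanent-environment effects of a recorded animal drawn
#' as one block), interleaved every \code{blockEvery} iterations with a
#' joint draw of all location effects from the sparse mixed-model equations
#' with the \eqn{A^{-1} \otimes G_0^{-1}} additive penalty.  Each
#' covariance matrix is drawn from its inverse-Wishart full conditional
#' (the additive one through the \eqn{a' A^{-1} a} quadratic form).
#' Missing second-trait observations are imputed by data augmentation.
#' Chains are exactly reproducible for a given \code{seed}.
#'
#' The study-scale protocol is 100,000 iterations, 10,000 burn-in and a
#' thinning interval of 10; those are the defaults, but shorter chains are
#' appropriate for simulation experiments.
#'
#' @param x a [KidRecords-class] (with \code{ped}) or a prebuilt
#'   [GrowthDesign-class].
#' @param ped pedigree; required when \code{x} is a records object.
#' @param trait2 conformation trait paired with body weight.
#' @param priors a [priorSpec()].
#' @param nIter,burnIn,thin chain settings.
#' @param seed RNG seed.
#' @param blockEvery interval (in iterations) between joint location
#'   draws; 0 disables them (pure single-site scans).
#' @return an [MCMCChain-class] with columns \code{a.11, a.12, a.22, m.11,
#'   ..., e.22}: the additive, maternal, permanent-environment,
#'   common-environment and residual covariance components (trait order:
#'   body weight, then the paired trait).
#' @examples
#' \donttest{
#' cfg <- simulationConfig(n_kids = 120, n_dams = 60, n_sires = 10,
#'                         n_herds = 4)
#' herd <- simulateHerd(cfg, seed = 1)
#' ch <- fitGrowthModel(herd$records, herd$pedigree, trait2 = "cg",
#'                      nIter = 600, burnIn = 100, thin = 5, seed = 1)
#' summarizeChain(ch)
#' }
#' @export
fitGrowthModel <- function(x, ped = NULL, trait2 = c("cg", "bl", "hw"),
                           priors = priorSpec(),
                           nIter = 100000L, burnIn = 10000L, thin = 10L,
                           seed = 1L, blockEvery = 20L) {
  if (methods::is(x, "KidRecords")) {
    if (is.null(ped)) stop("a pedigree is required with a records object")
    design <- buildGrowthDesign(x, ped, trait2)
  } else if (methods::is(x, "GrowthDesign")) {
    design <- x
  } else {
    stop("x must be a KidRecords or GrowthDesign object")
  }
  stopifnot(inherits(priors, "PriorSpec"))
  if (nIter <= burnIn) stop("nIter must exceed burnIn")
  n <- length(design@y1)
  ai <- .ainvRows(design@pedigree)
  use_block <- blockEvery > 0 && n > 0
  if (use_block) {
    W <- .growthIncidence(design)
    WtW <- Matrix::crossprod(W)
    pads <- .growthPriorPads(design, ai)
    asm <- .kronAssembler(list(R = WtW, A = pads$A, M = pads$M, P = pads$P,
                               C = pads$C), pads$q)
  }
  set.seed(as.integer(seed))
  stt <- .initGrowthState(design)
  s1 <- .priorScale(priors, stt$rawvar[1])
  s2 <- .priorScale(priors, stt$rawvar[2])
  stt$rawvar <- NULL
  # map each permanent-env level to its pedigree animal
  pe2anim <- rep(1L, max(length(design@peLevels), 1L))
  pe2anim[design@pe] <- design@anim
  samples <- matrix(NA_real_, nIter, 15)
  it <- 0L
  seg <- if (use_block) as.integer(blockEvery) else as.integer(nIter)
  while (it < nIter) {
    S <- min(seg, nIter - it)
    res <- gibbs_bivar_scan_cpp(
      design@y1, design@obs2,
      design@cell, design@anim, design@dam, design@pe, design@herd,
      pe2anim,
      max(length(design@cellLevels), 1L), nAnimals(design@pedigree),
      max(length(design@damLevels), 1L), max(length(design@peLevels), 1L),
      max(length(design@herdLevels), 1L),
      ai$ptr, ai$idx, ai$val,
      priors$nu, s1, s2, stt, S)
    samples[it + seq_len(S), ] <- res$samples
    stt <- res$state
    it <- it + S
    if (use_block && it < nIter) {
      stt <- .ridgeSwapGrowth(stt, design, W, WtW, pads, asm, priors, s1, s2)
      stt <- .jointGrowthDraw(stt, design, W, WtW, pads, asm)
    }
  }
  keep <- seq.int(burnIn + thin, nIter, by = thin)
  samples <- samples[keep, , drop = FALSE]
  colnames(samples) <- .GROWTH_PAR
  methods::new("MCMCChain",
    samples = samples,
    meta = list(model = "growth", traits = design@traits,
                n_iter = as.integer(nIter), burn_in = as.integer(burnIn),
                thin = as.integer(thin), seed = as.integer(seed),
                block_every = as.integer(blockEvery),
                priors = c(unclass(priors),
                           list(scale_used = c(s1, s2))),
                n_records = n,
                n_cells = length(design@cellLevels),
                n_animals = nAnimals(design@pedigree),
                n_dams = length(design@damLevels),
                n_kids = length(design@peLevels),
                n_herds = length(design@herdLevels)))
}
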