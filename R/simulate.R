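#' @include config.R
NULL

# Stage substreams: one user-facing seed, expanded by a fixed counter scheme
# so each generation stage is independently reproducible.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 100000000L) * 10L + as.integer(stage)
}

# Deterministic herd structure: founders, litters, kid covariates.
# Returns the pedigree rows plus the kid-level metadata the record
# generator needs.  All randomness under stage-0 of `seed`.
.simulateStructure <- function(config, seed) {
  set.seed(.stageSeed(seed, 0L))
  nh <- config$n_herds
  herds <- sprintf("H%02d", seq_len(nh))
  village <- sprintf("V%02d", seq_len(nh))
  province <- ifelse(seq_len(nh) <= ceiling(nh / 2), "Gitega", "Rutana")

  sire_id <- sprintf("S%04d", seq_len(config$n_sires))
  dam_id <- sprintf("D%04d", seq_len(config$n_dams))
  sire_herd <- rep_len(seq_len(nh), config$n_sires)
  dam_herd <- rep_len(seq_len(nh), config$n_dams)
  sires_by_herd <- split(sire_id, sire_herd)

  n_target <- config$n_kids
  # generate litters in dam passes until the kid target is reached; the
  # last litter is trimmed so the count is exact
  max_litters <- config$n_dams * (2L + n_target %/% config$n_dams)
  lit_dam <- rep(seq_len(config$n_dams),
                 length.out = max_litters)
  lit_pass <- rep(seq_len(max_litters %/% config$n_dams + 1L),
                  each = config$n_dams)[seq_len(max_litters)]
  lit_size <- 1L + stats::rbinom(max_litters, 1L, config$twin_fraction)
  csum <- cumsum(lit_size)
  n_lit <- which(csum >= n_target)[1]
  lit_size <- lit_size[seq_len(n_lit)]
  lit_size[n_lit] <- lit_size[n_lit] - (csum[n_lit] - n_target)
  lit_dam <- lit_dam[seq_len(n_lit)]
  lit_pass <- lit_pass[seq_len(n_lit)]
  lit_herd <- dam_herd[lit_dam]
  lit_sire <- vapply(lit_herd, function(h) {
    pool <- sires_by_herd[[as.character(h)]]
    if (is.null(pool)) pool <- sire_id    # herd without its own sire
    if (length(pool) == 1L) pool else sample(pool, 1L)
  }, character(1))
  lit_year <- if (length(config$years) == 1L) {
    rep(config$years, n_lit)
  } else {
    sample(config$years, n_lit, replace = TRUE)
  }
  lit_season <- sample(1:2, n_lit, replace = TRUE)
  li <- rep(seq_len(n_lit), lit_size)
  n_kids <- length(li)
  kids <- data.frame(
    kid_id = sprintf("K%05d", seq_len(n_kids)),
    sire_id = lit_sire[li],
    dam_id = dam_id[lit_dam[li]],
    sex = ifelse(stats::runif(n_kids) < 0.5, "male", "female"),
    birth_type = ifelse(lit_size[li] == 2L, "twin", "single"),
    parity = pmin(lit_pass[li], 3L),
    herd = herds[lit_herd[li]],
    village = village[lit_herd[li]],
    province = province[lit_herd[li]],
    birth_year = lit_year[li],
    season = lit_season[li],
    litter_id = sprintf("L%05d", li),
    stringsAsFactors = FALSE
  )
  ped <- pedigree(
    id = c(sire_id, dam_id, kids$kid_id),
    sire = c(rep(NA, config$n_sires + config$n_dams), kids$sire_id),
    dam = c(rep(NA, config$n_sires + config$n_dams), kids$dam_id),
    birthYear = c(rep(NA_integer_, config$n_sires + config$n_dams),
                  kids$birth_year)
  )
  list(pedigree = ped, kids = kids)
}

#' Simulate a herd pedigree
#'
#' Founder sires and dams are assigned round-robin to village herds; dams
#' produce litters (singles or twins per \code{twin_fraction}) in repeated
#' passes, each litter sired within the dam's herd, until exactly
#' \code{n_kids} kids exist (the last litter is trimmed if needed).  At the
#' default scale this yields exactly 1538 kids from all 645 dams and at
#' most 106 sires.  Deterministic given \code{seed}.
#'
#' @param config a [simulationConfig()].
#' @param seed RNG seed (default: the config's seed).
#' @return a sorted [Pedigree-class].
#' @export
simulatePedigree <- function(config = simulationConfig(),
                             seed = config$seed) {
  .simulateStructure(config, seed)$pedigree
}

#' Simulate additive genetic (breeding) values down a pedigree
#'
#' Recursive generation: founders draw from \eqn{N(0, G_0)}; an offspring's
#' value is the parent average plus a Mendelian-sampling deviation with
#' covariance \eqn{G_0 (0.5 - 0.25 (F_s + F_d))} (one unknown parent:
#' \eqn{G_0 (0.75 - 0.25 F)}; both unknown: \eqn{G_0}).  Works for any
#' trait dimension; the sample covariance across many founders converges to
#' \eqn{G_0} and parent-offspring covariance to \eqn{G_0/2}.
#'
#' @param ped a sorted [Pedigree-class].
#' @param G0 founder additive covariance (d x d matrix or scalar).
#' @param seed RNG seed.
#' @return numeric matrix, one row per animal in pedigree order.
#' @export
simulateBreedingValues <- function(ped, G0, seed = 1L) {
  .checkSorted(ped, "simulateBreedingValues")
  G0 <- as.matrix(G0)
  d <- nrow(G0)
  if (!isSymmetric(unname(G0), tol = 1e-8)) stop("G0 must be symmetric")
  ev <- eigen(G0, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    stop("G0 must be positive semidefinite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d) # G0 = L L'
  Fi <- inbreeding(ped)
  pp <- .parentPositions(ped)
  n <- nAnimals(ped)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * d), n, d)
  a <- matrix(0, n, d)
  if (d == 1L) {
    # scalar fast path (the trait-coupling machinery draws many of these)
    s <- pp$sire; dm <- pp$dam
    sdL <- as.numeric(L)
    z <- Z[, 1] * sdL
    av <- numeric(n)
    for (i in seq_len(n)) {
      si <- s[i]; di <- dm[i]
      av[i] <- if (si == 0L && di == 0L) z[i]
      else if (si != 0L && di != 0L) {
        0.5 * (av[si] + av[di]) +
          sqrt(0.5 - 0.25 * (Fi[si] + Fi[di])) * z[i]
      } else {
        p <- max(si, di)
        0.5 * av[p] + sqrt(0.75 - 0.25 * Fi[p]) * z[i]
      }
    }
    a[, 1] <- av
    rownames(a) <- animalIds(ped)
    return(a)
  }
  for (i in seq_len(n)) {
    s <- pp$sire[i]
    dm <- pp$dam[i]
    if (s == 0L && dm == 0L) {
      a[i, ] <- L %*% Z[i, ]
    } else if (s != 0L && dm != 0L) {
      k <- sqrt(0.5 - 0.25 * (Fi[s] + Fi[dm]))
      a[i, ] <- 0.5 * (a[s, ] + a[dm, ]) + k * (L %*% Z[i, ])
    } else {
      p <- max(s, dm)
      k <- sqrt(0.75 - 0.25 * Fi[p])
      a[i, ] <- 0.5 * a[p, ] + k * (L %*% Z[i, ])
    }
  }
  rownames(a) <- animalIds(ped)
  a
}

# standardized pedigree-correlated additive vector (variance 1 in founders)
.stdAdditive <- function(ped, seed) {
  drop(simulateBreedingValues(ped, matrix(1, 1, 1), seed = seed))
}

# centered iid effects: q levels, variance s2, sum-to-zero.  Common
# environment levels are few, so the realised mean of raw draws would be
# confounded with the fixed means; centering keeps the fixed-effect
# calibration exact at the cost of a 1/q deflation of realised variance.
.centeredEffects <- function(q, s2) {
  x <- stats::rnorm(q, 0, sqrt(s2))
  x - mean(x)
}

#' Simulate kid growth, conformation and survival records
#'
#' Generates, for the herd structure implied by \code{config} and
#' \code{seed}, the four growth traits at every surviving and observed age
#' class and the right-censored survival outcome, under the generative
#' model the fitting modules assume: trait value = fixed cell mean +
#' additive (pedigree) + maternal (iid per dam) + permanent environment
#' (iid per kid) + common environment (herd, centered) + residual; log
#' survival time = baseline + slope x birth weight + twin effect + additive
#' + maternal + herd-year-season (centered) + residual, censored at the
#' horizon.  Conformation traits are coupled to body weight through the
#' configured additive genetic correlations and within-term environmental
#' correlations.
#'
#' @param config a [simulationConfig()].
#' @param seed RNG seed (default: the config's seed).
#' @param returnEffects if TRUE, attach the latent per-kid effect
#'   components as attribute \code{"effects"} (used for generator
#'   diagnostics).
#' @return a [KidRecords-class].
#' @export
simulateRecords <- function(config = simulationConfig(),
                            seed = config$seed, returnEffects = FALSE) {
  st <- .simulateStructure(config, seed)
  ped <- st$pedigree
  kids <- st$kids
  nk <- nrow(kids)
  ids <- animalIds(ped)
  kid_pos <- match(kids$kid_id, ids)
  dam_f <- factor(kids$dam_id)
  herd_f <- factor(kids$herd)
  n_dam <- nlevels(dam_f)
  n_herd <- nlevels(herd_f)

  traits <- c("bw", "cg", "bl", "hw")
  comp <- config$components

  # --- additive effects: shared standardized BW core + trait-specifics ---
  a_std <- list()
  a_std$core <- .stdAdditive(ped, .stageSeed(seed, 1L))
  for (k in seq_along(traits[-1])) {
    a_std[[traits[k + 1]]] <- .stdAdditive(ped, .stageSeed(seed, 1L + k))
  }
  a_surv_std <- .stdAdditive(ped, .stageSeed(seed, 5L))

  addv <- matrix(0, nk, 4, dimnames = list(NULL, traits))
  addv[, "bw"] <- sqrt(comp$bw[["s2a"]]) * a_std$core[kid_pos]
  for (tr in traits[-1]) {
    rho <- config$rg[[tr]]
    addv[, tr] <- sqrt(comp[[tr]][["s2a"]]) *
      (rho * a_std$core[kid_pos] +
         sqrt(1 - rho^2) * a_std[[tr]][kid_pos])
  }

  set.seed(.stageSeed(seed, 6L))

  # --- iid terms with within-term correlation to the BW component --------
  corrTerm <- function(q, s2_bw, s2_t, rho_t, centered = FALSE) {
    z0 <- stats::rnorm(q)
    out <- matrix(0, q, 4, dimnames = list(NULL, traits))
    out[, "bw"] <- sqrt(s2_bw) * z0
    for (tr in traits[-1]) {
      zt <- stats::rnorm(q)
      out[, tr] <- sqrt(s2_t[[tr]]) *
        (rho_t[[tr]] * z0 + sqrt(1 - rho_t[[tr]]^2) * zt)
    }
    if (centered) out <- sweep(out, 2, colMeans(out))
    out
  }
  s2_of <- function(w) vapply(traits[-1], function(tr) comp[[tr]][[w]],
                              numeric(1))
  mat <- corrTerm(n_dam, comp$bw[["s2m"]], s2_of("s2m"), config$env_corr)
  pev <- corrTerm(nk, comp$bw[["s2p"]], s2_of("s2p"), config$env_corr)
  cev <- corrTerm(n_herd, comp$bw[["s2c"]], s2_of("s2c"), config$env_corr,
                  centered = TRUE)

  # --- fixed-effect means (sex and birth-type contrasts centered) --------
  share <- config$twin_kid_share
  is_male <- kids$sex == "male"
  is_twin <- kids$birth_type == "twin"
  fixedMean <- function(tr, age_idx) {
    means <- config[[paste0(tr, "_age_means")]]
    sexe <- if (tr == "bw") config$sex_effect_bw else config$sex_effect_conf
    twine <- if (tr == "bw") config$twin_effect_bw else
      config$twin_effect_conf
    means[age_idx] + sexe * (is_male - 0.5) + twine * (is_twin - share)
  }

  # --- survival ----------------------------------------------------------
  sv <- config$survival
  a_surv <- sqrt(sv$s2a) * a_surv_std[kid_pos]
  m_surv <- stats::rnorm(n_dam, 0, sqrt(sv$s2m))
  hys_f <- factor(paste(kids$herd, kids$birth_year, kids$season, sep = ":"))
  c_surv <- .centeredEffects(nlevels(hys_f), sv$s2c)
  e_surv <- stats::rnorm(nk, 0, sqrt(sv$s2e))

  # --- assemble measurement rows (birth first: BW at birth feeds survival)
  n_age <- length(config$age_months)
  resid <- array(stats::rnorm(nk * n_age * 4), c(nk, n_age, 4))
  sdres <- vapply(traits, function(tr) sqrt(comp[[tr]][["s2e"]]), numeric(1))
  # correlate residuals of conformation traits with the BW residual
  for (k in 2:4) {
    rho <- config$env_corr[[traits[k]]]
    resid[, , k] <- rho * resid[, , 1] + sqrt(1 - rho^2) * resid[, , k]
  }
  traitValue <- function(tr, k, age_idx) {
    fixedMean(tr, age_idx) + addv[, tr] +
      mat[as.integer(dam_f), tr] + pev[, tr] +
      cev[as.integer(herd_f), tr] + sdres[[tr]] * resid[, age_idx, k]
  }
  bw_all <- sapply(seq_len(n_age), function(ai) traitValue("bw", 1, ai))
  cg_all <- sapply(seq_len(n_age), function(ai) traitValue("cg", 2, ai))
  bl_all <- sapply(seq_len(n_age), function(ai) traitValue("bl", 3, ai))
  hw_all <- sapply(seq_len(n_age), function(ai) traitValue("hw", 4, ai))

  bw_birth <- bw_all[, 1]
  log_st <- config$survival_baseline + sv$bw_slope * bw_birth +
    config$survival_twin_direct * is_twin +
    a_surv + m_surv[as.integer(dam_f)] +
    c_surv[as.integer(hys_f)] + e_surv
  st <- exp(log_st)
  censored <- st >= sv$horizon
  survival_days <- pmin(floor(st), sv$horizon)
  survival_days[censored] <- sv$horizon

  observe <- matrix(FALSE, nk, n_age)
  age_days <- config$age_months * 30
  for (ai in seq_len(n_age)) {
    alive <- st >= age_days[ai]
    seen <- stats::runif(nk) < config$p_observe[ai]
    observe[, ai] <- alive & seen
  }
  observe[, 1] <- TRUE  # birth visit always recorded

  rows <- which(observe, arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  measures <- data.frame(
    kid_id = kids$kid_id[rows[, 1]],
    age_months = config$age_months[rows[, 2]],
    bw = bw_all[rows],
    cg = cg_all[rows],
    bl = bl_all[rows],
    hw = hw_all[rows],
    stringsAsFactors = FALSE
  )
  kids$survival_days <- as.numeric(survival_days)
  kids$censored <- censored
  kids$birth_date <- sprintf("%d-%02d-15", kids$birth_year,
                             ifelse(kids$season == 1L, 4L, 10L))
  rec <- methods::new("KidRecords", kids = kids, measures = measures)
  if (returnEffects) {
    attr(rec, "effects") <- list(
      additive = addv, maternal = mat, permanent = pev, common = cev,
      dam_index = as.integer(dam_f), herd_index = as.integer(herd_f),
      survival = list(additive = a_surv, maternal = m_surv[as.integer(dam_f)],
                      group = c_surv[as.integer(hys_f)], residual = e_surv,
                      log_time = log_st)
    )
  }
  rec
}

#' Simulate a full synthetic herd (pedigree + records)
#'
#' Convenience wrapper around [simulatePedigree()] and [simulateRecords()];
#' optionally writes the pedigree, records and the YAML configuration to a
#' directory for file-based reruns.
#'
#' @param config a [simulationConfig()].
#' @param seed RNG seed.
#' @param dir optional output directory (created if missing).
#' @return list with elements \code{pedigree} and \code{records}.
#' @export
simulateHerd <- function(config = simulationConfig(), seed = config$seed,
                         dir = NULL) {
  ped <- simulatePedigree(config, seed)
  rec <- simulateRecords(config, seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writePedigree(ped, file.path(dir, "pedigree.tsv"))
    writeRecords(rec, file.path(dir, "records.tsv"))
    writeSimulationConfig(config, file.path(dir, "config.yaml"))
  }
  list(pedigree = ped, records = rec)
}
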