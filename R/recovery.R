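#' @include descriptives.R
NULL

#' Simulation-based parameter-recovery experiment
#'
#' For each replicate seed: simulate a herd under \code{config}, fit the
#' requested model with a scaled-down chain, and record whether each true
#' variance component (and the derived genetic parameters) is covered by
#' its posterior HPD interval.  This is the package's end-to-end check that
#' the samplers recover the generative truth at nominal rates.
#'
#' @param config a [simulationConfig()]; its variance components are the
#'   truth being recovered.
#' @param model \code{"growth"} or \code{"survival"}.
#' @param trait2 paired trait for the growth model.
#' @param nReplicates number of replicate seeds (>= 2).
#' @param nIter,burnIn,thin chain settings per replicate.
#' @param blockEvery joint-location-draw interval passed to the samplers.
#' @param prob HPD coverage level.
#' @param seed base seed; replicate r uses \code{seed + r - 1}.
#' @return data.frame with one row per replicate x parameter: replicate,
#'   parameter, truth, mean, median, lower, upper, covered.
#' @export
recoveryExperiment <- function(config, model = c("growth", "survival"),
                               trait2 = "cg", nReplicates = 20,
                               nIter = 20000L, burnIn = 2000L, thin = 10L,
                               prob = 0.95, seed = 1L, blockEvery = 50L) {
  model <- match.arg(model)
  if (nReplicates < 2) stop("need at least 2 replicates")
  rows <- list()
  for (r in seq_len(nReplicates)) {
    rseed <- as.integer(seed) + r - 1L
    herd <- simulateHerd(config, seed = rseed)
    if (model == "growth") {
      chain <- fitGrowthModel(herd$records, herd$pedigree, trait2 = trait2,
                              nIter = nIter, burnIn = burnIn, thin = thin,
                              seed = rseed, blockEvery = blockEvery)
      comp <- config$components$bw
      truth <- c(
        a.11 = unname(comp[["s2a"]]), m.11 = unname(comp[["s2m"]]),
        p.11 = unname(comp[["s2p"]]), c.11 = unname(comp[["s2c"]]),
        e.11 = unname(comp[["s2e"]]),
        h2.1 = unname(heritability(comp[["s2a"]], comp[["s2m"]],
                                   comp[["s2p"]], comp[["s2c"]],
                                   comp[["s2e"]])),
        r.1 = unname(repeatability(comp[["s2a"]], comp[["s2m"]],
                                   comp[["s2p"]], comp[["s2c"]],
                                   comp[["s2e"]])),
        r_g = unname(config$rg[[trait2]])
      )
    } else {
      chain <- fitSurvivalModel(herd$records, herd$pedigree,
                                horizon = config$survival$horizon,
                                nIter = nIter, burnIn = burnIn, thin = thin,
                                seed = rseed, blockEvery = blockEvery)
      sv <- config$survival
      truth <- c(
        s2a = sv$s2a, s2m = sv$s2m, s2c = sv$s2c, s2e = sv$s2e,
        h2 = survivalHeritability(sv$s2a, sv$s2m, sv$s2c, sv$s2e)
      )
    }
    summ <- summarizeChain(chain, prob = prob)
    for (p in names(truth)) {
      s <- summ[summ$parameter == p, ]
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, parameter = p, truth = truth[[p]],
        mean = s$mean, median = s$median, lower = s$lower, upper = s$upper,
        covered = truth[[p]] >= s$lower & truth[[p]] <= s$upper,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-parameter coverage of a recovery experiment
#' @param recovery data.frame from [recoveryExperiment()].
#' @return data.frame: parameter, truth, replicates, coverage.
#' @export
coverageTable <- function(recovery) {
  sp <- split(recovery, recovery$parameter)
  out <- lapply(sp, function(d) {
    data.frame(parameter = d$parameter[1], truth = d$truth[1],
               replicates = nrow(d), coverage = mean(d$covered),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
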