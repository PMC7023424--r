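#' @include pedigree.R
NULL

#' Published posterior summaries used as the package's reference truth
#'
#' Posterior mean, median and 95% HPD limits of the variance components and
#' derived genetic parameters from the Burundi smallholder indigenous-goat
#' kid study this package emulates (1538 kids, 645 dams, 106 sires recorded
#' 2016-2019).  The simulator's default true variance components are the
#' Mean column of this table; the arithmetic cross-checks in the test suite
#' recompute the heritability and repeatability rows from the component
#' rows.
#'
#' Components are additive (\code{a}), maternal (\code{m}), permanent
#' environmental (\code{p}), common environmental (\code{c}) and residual
#' (\code{e}) variances; units are kg^2 for body weight, cm^2 for the
#' conformation traits and squared log-days for survival.
#'
#' @return data.frame with columns trait, parameter, mean, median, lower,
#'   upper.
#' @examples
#' ref <- referenceParameters()
#' bw <- ref[ref$trait == "bw" & ref$parameter %in%
#'           c("s2a", "s2m", "s2p", "s2c", "s2e"), ]
#' round(heritability(bw$mean[1], bw$mean[2], bw$mean[3],
#'                    bw$mean[4], bw$mean[5]), 2)
#' @export
referenceParameters <- function() {
  rows <- rbind(
    # trait, parameter, mean, median, lower, upper
    c("bw", "s2a", 0.58, 0.57, 0.37, 0.79),
    c("bw", "s2m", 0.22, 0.23, 0.09, 0.38),
    c("bw", "s2p", 0.55, 0.54, 0.37, 0.70),
    c("bw", "s2c", 0.41, 0.42, 0.33, 0.53),
    c("bw", "s2e", 1.57, 1.57, 1.50, 1.61),
    c("bw", "h2", 0.17, 0.17, 0.11, 0.23),
    c("bw", "r", 0.33, 0.33, 0.29, 0.38),
    c("cg", "s2a", 2.56, 2.53, 1.44, 3.65),
    c("cg", "s2m", 1.50, 1.49, 0.76, 2.20),
    c("cg", "s2p", 2.08, 2.08, 1.23, 2.88),
    c("cg", "s2c", 1.15, 1.15, 0.80, 1.50),
    c("cg", "s2e", 7.95, 7.95, 7.56, 8.31),
    c("cg", "h2", 0.16, 0.16, 0.09, 0.24),
    c("cg", "r", 0.30, 0.30, 0.26, 0.35),
    c("bl", "s2a", 0.59, 0.54, 0.0004, 1.49),
    c("bl", "s2m", 1.00, 1.00, 0.39, 1.59),
    c("bl", "s2p", 3.10, 3.12, 2.31, 3.86),
    c("bl", "s2c", 1.19, 1.19, 0.86, 1.54),
    c("bl", "s2e", 7.00, 6.99, 6.67, 7.34),
    c("bl", "h2", 0.05, 0.04, 0.0003, 0.11),
    c("bl", "r", 0.29, 0.28, 0.23, 0.33),
    c("hw", "s2a", 1.65, 1.61, 0.86, 2.50),
    c("hw", "s2m", 1.37, 1.36, 0.79, 1.94),
    c("hw", "s2p", 1.77, 1.78, 1.14, 2.41),
    c("hw", "s2c", 1.12, 1.11, 0.83, 1.44),
    c("hw", "s2e", 5.96, 5.96, 5.68, 6.25),
    c("hw", "h2", 0.13, 0.14, 0.07, 0.21),
    c("hw", "r", 0.29, 0.29, 0.24, 0.34),
    c("survival", "s2a", 0.05, 0.06, 0.03, 0.10),
    c("survival", "s2m", 0.05, 0.06, 0.03, 0.10),
    c("survival", "s2c", 1.78, 1.81, 1.35, 2.32),
    c("survival", "s2e", 0.05, 0.05, 0.03, 0.09),
    c("survival", "h2", 0.02, 0.02, 0.01, 0.04),
    c("rg", "bw_cg", 0.79, 0.75, 0.52, 0.90),
    c("rg", "bw_bl", 0.65, 0.61, 0.24, 0.85),
    c("rg", "bw_hw", 0.74, 0.72, 0.47, 0.87)
  )
  out <- data.frame(
    trait = rows[, 1], parameter = rows[, 2],
    mean = as.numeric(rows[, 3]), median = as.numeric(rows[, 4]),
    lower = as.numeric(rows[, 5]), upper = as.numeric(rows[, 6]),
    stringsAsFactors = FALSE
  )
  out
}

# convenience lookups used by the simulator defaults and tests
.refComponents <- function(trait, column = "mean") {
  ref <- referenceParameters()
  comps <- c("s2a", "s2m", "s2p", "s2c", "s2e")
  if (trait == "survival") comps <- c("s2a", "s2m", "s2c", "s2e")
  sub <- ref[ref$trait == trait & ref$parameter %in% comps, ]
  stats::setNames(sub[[column]][match(comps, sub$parameter)], comps)
}

.refGeneticCorrelation <- function(trait2) {
  ref <- referenceParameters()
  ref$mean[ref$trait == "rg" & ref$parameter == paste0("bw_", trait2)]
}
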