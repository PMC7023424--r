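#' @include RcppExports.R
NULL

#' Pedigree of a recorded herd
#'
#' Holds one row per animal with its sire and dam (possibly unknown) and
#' birth year.  Identifiers are exact strings after whitespace trimming; an
#' unknown parent is stored as \code{NA}.  A pedigree is \emph{sorted} when
#' every parent precedes all of its offspring, the order required by the
#' tabular relationship-matrix recursion.
#'
#' @slot id character vector of unique animal identifiers.
#' @slot sire character vector of sire identifiers (\code{NA} = unknown).
#' @slot dam character vector of dam identifiers (\code{NA} = unknown).
#' @slot birthYear integer vector of birth years (\code{NA} allowed).
#'
#' @seealso [readPedigree()], [sortPedigree()], [relationshipMatrix()],
#'   [inbreeding()]
#' @export
setClass("Pedigree",
  representation(
    id = "character",
    sire = "character",
    dam = "character",
    birthYear = "integer"
  ),
  validity = function(object) {
    n <- length(object@id)
    if (length(object@sire) != n || length(object@dam) != n ||
        length(object@birthYear) != n) {
      return("id, sire, dam and birthYear must have equal length")
    }
    if (anyNA(object@id)) return("animal ids must not be NA")
    dup <- object@id[duplicated(object@id)]
    if (length(dup)) {
      return(sprintf("duplicate animal id(s): %s",
                     paste(unique(dup), collapse = ", ")))
    }
    sires <- unique(object@sire[!is.na(object@sire)])
    dams <- unique(object@dam[!is.na(object@dam)])
    both <- intersect(sires, dams)
    if (length(both)) {
      return(sprintf("identifier(s) used as both sire and dam: %s",
                     paste(both, collapse = ", ")))
    }
    self <- object@id == object@sire | object@id == object@dam
    if (any(self, na.rm = TRUE)) {
      return(sprintf("animal(s) listed as their own parent: %s",
                     paste(object@id[which(self)], collapse = ", ")))
    }
    TRUE
  }
)

#' Kid records: covariates, repeated measurements and survival
#'
#' Container for one recording campaign.  The \code{kids} slot holds one row
#' per kid (identity, parents, sex, birth type, parity class, herd, village,
#' province, birth date, survival days and censoring flag); the
#' \code{measures} slot holds one row per kid x age-class visit with body
#' weight (kg), chest girth, body length and height at withers (cm).
#'
#' @slot kids data.frame of kid-level fields.
#' @slot measures data.frame of repeated measurements.
#'
#' @seealso [simulateRecords()], [readRecords()], [writeRecords()]
#' @export
setClass("KidRecords",
  representation(kids = "data.frame", measures = "data.frame"),
  validity = function(object) {
    kf <- c("kid_id", "sire_id", "dam_id", "sex", "birth_type", "parity",
            "herd", "village", "province", "birth_year", "season",
            "survival_days", "censored")
    missk <- setdiff(kf, names(object@kids))
    if (length(missk)) {
      return(sprintf("kids slot lacks column(s): %s",
                     paste(missk, collapse = ", ")))
    }
    mf <- c("kid_id", "age_months", "bw", "cg", "bl", "hw")
    missm <- setdiff(mf, names(object@measures))
    if (length(missm)) {
      return(sprintf("measures slot lacks column(s): %s",
                     paste(missm, collapse = ", ")))
    }
    if (anyDuplicated(object@kids$kid_id)) {
      return("duplicate kid_id in kids slot")
    }
    if (!all(object@measures$kid_id %in% object@kids$kid_id)) {
      return("measures refer to kid_id absent from kids slot")
    }
    sd <- object@kids$survival_days
    cn <- object@kids$censored
    bad <- !is.na(sd) & sd < 0
    if (any(bad)) return("negative survival_days")
    if (any(!is.na(cn) & cn & !is.na(sd) & sd < 360 - 1e-9 & sd != 360)) {
      # censoring at a different horizon is legal; only flag impossible rows
      NULL
    }
    for (v in c("bw", "cg", "bl", "hw")) {
      x <- object@measures[[v]]
      if (any(!is.finite(x) & !is.na(x))) {
        return(sprintf("non-finite %s measurement", v))
      }
    }
    TRUE
  }
)

#' Retained samples of a Gibbs chain
#'
#' One row per retained post-burn-in, thinned iteration; one column per
#' sampled parameter.  \code{meta} records the model, trait pair, chain
#' settings, seed and priors so a run can be reproduced exactly.
#'
#' @slot samples numeric matrix of retained draws.
#' @slot meta named list of run metadata.
#'
#' @seealso [fitGrowthModel()], [fitSurvivalModel()], [summarizeChain()]
#' @export
setClass("MCMCChain",
  representation(samples = "matrix", meta = "list"),
  validity = function(object) {
    if (!is.numeric(object@samples)) return("samples must be numeric")
    if (is.null(colnames(object@samples))) {
      return("samples must have column names")
    }
    m <- object@meta
    need <- c("model", "n_iter", "burn_in", "thin", "seed")
    missm <- setdiff(need, names(m))
    if (length(missm)) {
      return(sprintf("meta lacks field(s): %s", paste(missm, collapse = ", ")))
    }
    expect <- (m$n_iter - m$burn_in) %/% m$thin
    if (nrow(object@samples) != expect) {
      return(sprintf("retained rows (%d) != (n_iter - burn_in)/thin (%d)",
                     nrow(object@samples), expect))
    }
    TRUE
  }
)

#' Design for the bivariate growth model
#'
#' Incidence information for one trait pair, one row per measurement visit:
#' the fixed-effect cell (full age x sex x parity x birth-type interaction,
#' empty cells dropped), and level indices for the additive (pedigree
#' position), maternal (dam), permanent-environment (kid) and
#' common-environment (herd) terms.  Missing second-trait values are masked,
#' not dropped.
#'
#' @slot y1,y2 numeric observation vectors (trait 2 may contain NA).
#' @slot obs2 logical mask of observed trait-2 values.
#' @slot cell,anim,dam,pe,herd integer level indices (1-based).
#' @slot cellLevels,damLevels,peLevels,herdLevels character level labels.
#' @slot pedigree the sorted [Pedigree-class] behind the additive term.
#' @slot traits character(2), trait names.
#' @export
setClass("GrowthDesign",
  representation(
    y1 = "numeric", y2 = "numeric", obs2 = "logical",
    cell = "integer", anim = "integer", dam = "integer",
    pe = "integer", herd = "integer",
    cellLevels = "character", damLevels = "character",
    peLevels = "character", herdLevels = "character",
    pedigree = "Pedigree", traits = "character"
  ),
  validity = function(object) {
    n <- length(object@y1)
    lens <- c(length(object@y2), length(object@obs2), length(object@cell),
              length(object@anim), length(object@dam), length(object@pe),
              length(object@herd))
    if (any(lens != n)) return("row counts inconsistent across slots")
    if (anyNA(object@y1)) return("trait-1 observations must be complete")
    if (any(is.na(object@y2[object@obs2]))) {
      return("obs2 mask marks NA trait-2 values as observed")
    }
    for (s in c("cell", "anim", "dam", "pe", "herd")) {
      idx <- slot(object, s)
      top <- switch(s,
        cell = length(object@cellLevels),
        anim = length(object@pedigree@id),
        dam = length(object@damLevels),
        pe = length(object@peLevels),
        herd = length(object@herdLevels))
      if (any(idx < 1L | idx > top)) {
        return(sprintf("%s indices out of range", s))
      }
    }
    if (length(object@traits) != 2) return("traits must name two traits")
    TRUE
  }
)

#' Design for the censored AFT survival model
#'
#' One row per kid: log survival time (days), censoring flag (TRUE = alive
#' at the horizon, time set to the horizon), fixed covariate matrix
#' (intercept and birth weight), and level indices for additive, maternal
#' and herd-year-season terms.
#'
#' @slot logTime numeric log survival days.
#' @slot censored logical censoring flags.
#' @slot X numeric fixed-covariate matrix.
#' @slot anim,dam,group integer level indices (1-based).
#' @slot groupLevels,damLevels character level labels.
#' @slot pedigree the sorted [Pedigree-class].
#' @slot horizon numeric censoring horizon in days.
#' @export
setClass("SurvivalDesign",
  representation(
    logTime = "numeric", censored = "logical", X = "matrix",
    anim = "integer", dam = "integer", group = "integer",
    groupLevels = "character", damLevels = "character",
    pedigree = "Pedigree", horizon = "numeric"
  ),
  validity = function(object) {
    n <- length(object@logTime)
    if (n == 0) return("empty survival design")
    if (length(object@censored) != n || nrow(object@X) != n ||
        length(object@anim) != n || length(object@dam) != n ||
        length(object@group) != n) {
      return("row counts inconsistent across slots")
    }
    lh <- log(object@horizon)
    if (any(abs(object@logTime[object@censored] - lh) > 1e-9)) {
      return("censored rows must carry log(horizon) as their time")
    }
    if (any(object@logTime > lh + 1e-9)) {
      return("uncensored times must not exceed the horizon")
    }
    TRUE
  }
)

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  cat(sprintf("Pedigree: %d animals (%d founders)%s\n",
              length(object@id), nf,
              if (isSorted(object)) ", sorted" else ""))
})

setMethod("show", "KidRecords", function(object) {
  cat(sprintf(
    "KidRecords: %d kids, %d measurement rows, %d dams, %d herds\n",
    nrow(object@kids), nrow(object@measures),
    length(unique(object@kids$dam_id)),
    length(unique(object@kids$herd))))
})

setMethod("show", "MCMCChain", function(object) {
  m <- object@meta
  cat(sprintf(
    "MCMCChain [%s]: %d retained samples of %d parameters (n_iter %d, burn-in %d, thin %d, seed %s)\n",
    m$model, nrow(object@samples), ncol(object@samples),
    m$n_iter, m$burn_in, m$thin, as.character(m$seed)))
})

setMethod("show", "GrowthDesign", function(object) {
  cat(sprintf(
    "GrowthDesign (%s, %s): %d rows, %d cells, %d pedigree animals, %d dams, %d kids, %d herds; %d trait-2 values masked\n",
    object@traits[1], object@traits[2], length(object@y1),
    length(object@cellLevels), length(object@pedigree@id),
    length(object@damLevels), length(object@peLevels),
    length(object@herdLevels), sum(!object@obs2)))
})

setMethod("show", "SurvivalDesign", function(object) {
  cat(sprintf(
    "SurvivalDesign: %d kids (%d censored at %g d), %d pedigree animals, %d dams, %d herd-year-season groups\n",
    length(object@logTime), sum(object@censored), object@horizon,
    length(object@pedigree@id), length(object@damLevels),
    length(object@groupLevels)))
})
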