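#' @include AllClasses.R
NULL

#' Number of animals in a pedigree
#' @param object a [Pedigree-class].
#' @return integer count.
#' @export
setGeneric("nAnimals", function(object) standardGeneric("nAnimals"))

#' Animal identifiers in pedigree order
#' @param object a [Pedigree-class].
#' @return character vector.
#' @export
setGeneric("animalIds", function(object) standardGeneric("animalIds"))

#' Is a pedigree topologically sorted (parents before offspring)?
#' @param object a [Pedigree-class].
#' @return logical flag.
#' @export
setGeneric("isSorted", function(object) standardGeneric("isSorted"))

#' Topologically sort a pedigree
#'
#' Orders animals so every parent precedes all of its offspring, keeping the
#' original file order among ties (stable Kahn ordering).  Idempotent on an
#' already-sorted pedigree.
#'
#' @param object a [Pedigree-class].
#' @return a sorted [Pedigree-class].
#' @export
setGeneric("sortPedigree", function(object) standardGeneric("sortPedigree"))

#' Additive genetic relationship matrix
#'
#' Builds the dense additive relationship matrix A by the tabular
#' recursion: for animal j with parents s and d (unknown parents contribute
#' nothing), \eqn{a_{ij} = (a_{is} + a_{id})/2} for earlier animals i, and
#' \eqn{a_{jj} = 1 + a_{sd}/2}.  The diagonal equals 1 plus the inbreeding
#' coefficient; memory is quadratic in the number of animals (dense storage
#' is intended for herd-scale pedigrees of a few thousand animals).
#'
#' @param object a sorted [Pedigree-class].
#' @return symmetric numeric matrix with animal ids as dimnames.
#' @export
setGeneric("relationshipMatrix",
           function(object) standardGeneric("relationshipMatrix"))

#' Inbreeding coefficients
#'
#' \eqn{F_i} is half the additive relationship between the parents of i;
#' founders and animals with an unknown parent get 0.
#'
#' @param object a sorted [Pedigree-class].
#' @return named numeric vector of F per animal.
#' @export
setGeneric("inbreeding", function(object) standardGeneric("inbreeding"))

#' Kid-level table of a records object
#' @param object a [KidRecords-class].
#' @return data.frame, one row per kid.
#' @export
setGeneric("kids", function(object) standardGeneric("kids"))

#' Measurement table of a records object
#' @param object a [KidRecords-class].
#' @return data.frame, one row per kid x age-class visit.
#' @export
setGeneric("measures", function(object) standardGeneric("measures"))

#' Retained samples of a chain
#' @param object an [MCMCChain-class].
#' @return numeric matrix, one row per retained iteration.
#' @export
setGeneric("chainSamples", function(object) standardGeneric("chainSamples"))

#' Metadata of a chain
#' @param object an [MCMCChain-class].
#' @return named list (model, chain settings, seed, priors, counts).
#' @export
setGeneric("chainMeta", function(object) standardGeneric("chainMeta"))
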