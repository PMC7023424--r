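#' @include AllGenerics.R
NULL

.UNKNOWN <- c("", "0", "NA", ".", "na")

.cleanId <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% .UNKNOWN] <- NA_character_
  x
}

#' Construct a pedigree from vectors
#'
#' @param id character animal identifiers (unique).
#' @param sire,dam character parent identifiers; \code{NA}, \code{""},
#'   \code{"0"} or \code{"NA"} mean unknown.
#' @param birthYear optional integer birth years.
#' @param strict if TRUE, a parent id never declared as an animal is an
#'   error; otherwise such parents are auto-added as founders with a warning.
#' @return a [Pedigree-class] (unsorted; see [sortPedigree()]).
#' @examples
#' ped <- pedigree(c("s1", "d1", "k1"), c(NA, NA, "s1"), c(NA, NA, "d1"))
#' relationshipMatrix(sortPedigree(ped))
#' @export
pedigree <- function(id, sire, dam, birthYear = NA_integer_, strict = FALSE) {
  id <- .cleanId(id)
  sire <- .cleanId(sire)
  dam <- .cleanId(dam)
  if (anyNA(id)) stop("animal ids must be non-missing")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop(sprintf("duplicate animal id(s): %s", paste(dup, collapse = ", ")))
  }
  birthYear <- rep_len(as.integer(birthYear), length(id))
  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  undeclared <- setdiff(parents, id)
  if (length(undeclared)) {
    if (strict) {
      stop(sprintf("parent id(s) never declared as animals: %s",
                   paste(undeclared, collapse = ", ")))
    }
    warning(sprintf("adding %d undeclared parent(s) as founders: %s",
                    length(undeclared),
                    paste(utils::head(undeclared, 5), collapse = ", ")))
    id <- c(undeclared, id)
    sire <- c(rep(NA_character_, length(undeclared)), sire)
    dam <- c(rep(NA_character_, length(undeclared)), dam)
    birthYear <- c(rep(NA_integer_, length(undeclared)), birthYear)
  }
  methods::new("Pedigree", id = id, sire = sire, dam = dam,
               birthYear = birthYear)
}

#' Read a pedigree file
#'
#' Delimited text with columns animal, sire, dam and optionally birth year
#' (header names matched loosely; comma or tab autodetected).  Unknown
#' parents may be coded as empty, \code{0} or \code{NA}.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) autodetects "," vs tab.
#' @param strict passed to [pedigree()]: error on undeclared parent ids.
#' @return a validated [Pedigree-class].
#' @export
readPedigree <- function(path, sep = NULL, strict = FALSE) {
  if (!file.exists(path)) stop(sprintf("pedigree file not found: %s", path))
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = FALSE)
  nm <- tolower(names(tab))
  pick <- function(keys) {
    hit <- which(nm %in% keys)
    if (!length(hit)) stop(sprintf(
      "pedigree file %s lacks a column named one of: %s",
      path, paste(keys, collapse = "/")))
    tab[[hit[1]]]
  }
  id <- pick(c("animal", "id", "animal_id", "kid", "kid_id"))
  sire <- pick(c("sire", "sire_id", "father"))
  dam <- pick(c("dam", "dam_id", "mother"))
  byr <- if (any(nm %in% c("birth_year", "year", "birthyear"))) {
    suppressWarnings(as.integer(tab[[which(nm %in%
      c("birth_year", "year", "birthyear"))[1]]]))
  } else NA_integer_
  pedigree(id, sire, dam, byr, strict = strict)
}

#' Write a pedigree file
#'
#' Emits the pedigree (typically sorted first) as delimited text in the same
#' layout [readPedigree()] accepts; unknown parents are written as \code{0}.
#'
#' @param object a [Pedigree-class].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return invisibly, \code{path}.
#' @export
writePedigree <- function(object, path, sep = "\t") {
  stopifnot(methods::is(object, "Pedigree"))
  tab <- data.frame(
    animal = object@id,
    sire = ifelse(is.na(object@sire), "0", object@sire),
    dam = ifelse(is.na(object@dam), "0", object@dam),
    birth_year = object@birthYear,
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname nAnimals
setMethod("nAnimals", "Pedigree", function(object) length(object@id))

#' @rdname animalIds
setMethod("animalIds", "Pedigree", function(object) object@id)

#' @rdname isSorted
setMethod("isSorted", "Pedigree", function(object) {
  pos <- seq_along(object@id)
  names(pos) <- object@id
  sp <- pos[object@sire]
  dp <- pos[object@dam]
  ok_s <- is.na(object@sire) | (!is.na(sp) & sp < pos)
  ok_d <- is.na(object@dam) | (!is.na(dp) & dp < pos)
  all(ok_s & ok_d)
})

#' @rdname sortPedigree
setMethod("sortPedigree", "Pedigree", function(object) {
  n <- length(object@id)
  pos <- seq_len(n)
  names(pos) <- object@id
  sp <- unname(pos[object@sire])   # NA where parent unknown
  dp <- unname(pos[object@dam])
  indeg <- (!is.na(sp)) + (!is.na(dp))
  # children adjacency
  kids_of <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sp[i], dp[i])) {
      if (!is.na(p)) kids_of[[p]] <- c(kids_of[[p]], i)
    }
  }
  order_out <- integer(0)
  ready <- which(indeg == 0L)        # ascending = stable original order
  while (length(ready)) {
    i <- ready[1]
    ready <- ready[-1]
    order_out <- c(order_out, i)
    for (ch in kids_of[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        ready <- sort(c(ready, ch))  # keep stable ascending queue
      }
    }
  }
  if (length(order_out) < n) {
    cyc <- setdiff(seq_len(n), order_out)
    stop(sprintf("pedigree contains a cycle involving: %s",
                 paste(object@id[cyc], collapse = ", ")))
  }
  methods::new("Pedigree",
               id = object@id[order_out],
               sire = object@sire[order_out],
               dam = object@dam[order_out],
               birthYear = object@birthYear[order_out])
})

.parentPositions <- function(object) {
  pos <- seq_along(object@id)
  names(pos) <- object@id
  s <- unname(pos[object@sire])
  d <- unname(pos[object@dam])
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  list(sire = as.integer(s), dam = as.integer(d))
}

.checkSorted <- function(object, what) {
  if (!isSorted(object)) {
    stop(sprintf("%s requires a sorted pedigree; call sortPedigree() first",
                 what))
  }
}

#' @rdname relationshipMatrix
setMethod("relationshipMatrix", "Pedigree", function(object) {
  .checkSorted(object, "relationshipMatrix")
  pp <- .parentPositions(object)
  A <- tabular_A_cpp(pp$sire, pp$dam)
  dimnames(A) <- list(object@id, object@id)
  A
})

#' @rdname inbreeding
setMethod("inbreeding", "Pedigree", function(object) {
  .checkSorted(object, "inbreeding")
  pp <- .parentPositions(object)
  n <- length(object@id)
  memo <- new.env(parent = emptyenv(), size = 2L * n)
  FF <- numeric(n)
  # memoised kinship recursion: only the pairs reachable from parent
  # couples are visited, so memory stays linear for herd pedigrees
  # (a dense A at this size would be quadratic)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + phi(pp$sire[i], pp$dam[i]))
    } else {
      0.5 * (phi(i, pp$sire[j]) + phi(i, pp$dam[j]))
    }
    memo[[key]] <- val
    val
  }
  for (i in seq_len(n)) {
    s <- pp$sire[i]
    d <- pp$dam[i]
    FF[i] <- if (s == 0L || d == 0L) 0 else phi(s, d)
  }
  names(FF) <- object@id
  FF
})

# Sparse CSR rows of A^{-1} for the samplers.  A is inverted densely once
# (solve-based, per the package contract); entries below `tol` are dropped —
# the inverse of a pedigree relationship matrix is structurally sparse, so
# the threshold removes only round-off noise.
.ainvRows <- function(ped, tol = 1e-8) {
  A <- relationshipMatrix(ped)
  Ai <- solve(A)
  Ai <- (Ai + t(Ai)) / 2
  n <- nrow(Ai)
  ptr <- integer(n + 1)
  idx <- integer(0)
  val <- numeric(0)
  keep <- abs(Ai) > tol
  diag(keep) <- TRUE
  idx_list <- lapply(seq_len(n), function(i) which(keep[i, ]))
  counts <- vapply(idx_list, length, integer(1))
  ptr <- c(0L, cumsum(counts))
  idx <- unlist(idx_list, use.names = FALSE) - 1L
  val <- unlist(lapply(seq_len(n), function(i) Ai[i, idx_list[[i]]]),
                use.names = FALSE)
  list(ptr = as.integer(ptr), idx = as.integer(idx), val = as.numeric(val))
}
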