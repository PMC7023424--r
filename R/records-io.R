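#' @include simulate.R
NULL

#' @rdname kids
setMethod("kids", "KidRecords", function(object) object@kids)

#' @rdname measures
setMethod("measures", "KidRecords", function(object) object@measures)

.KID_COLS <- c("kid_id", "sire_id", "dam_id", "sex", "birth_type", "parity",
               "herd", "village", "province", "birth_year", "season",
               "birth_date", "litter_id", "survival_days", "censored")

#' Write kid records to a delimited file
#'
#' Long layout: one \code{measure} row per kid x age-class visit and one
#' \code{survival} row per kid, both carrying the kid-level covariates.
#'
#' @param object a [KidRecords-class].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return invisibly, \code{path}.
#' @export
writeRecords <- function(object, path, sep = "\t") {
  stopifnot(methods::is(object, "KidRecords"))
  k <- object@kids
  for (col in .KID_COLS) if (is.null(k[[col]])) k[[col]] <- NA
  m <- object@measures
  meas <- cbind(
    row_type = "measure",
    k[match(m$kid_id, k$kid_id),
      setdiff(.KID_COLS, c("survival_days", "censored"))],
    m[c("age_months", "bw", "cg", "bl", "hw")],
    survival_days = NA_real_, censored = NA
  )
  surv <- cbind(
    row_type = "survival",
    k[setdiff(.KID_COLS, c("survival_days", "censored"))],
    age_months = NA_real_, bw = NA_real_, cg = NA_real_, bl = NA_real_,
    hw = NA_real_,
    k[c("survival_days", "censored")]
  )
  out <- rbind(meas, surv)
  out <- out[order(out$kid_id, out$row_type), ]
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read kid records from a delimited file
#'
#' Inverse of [writeRecords()].
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} autodetects "," vs tab.
#' @return a [KidRecords-class].
#' @export
readRecords <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("records file not found: %s", path))
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (is.null(tab$row_type)) stop(sprintf("%s lacks a row_type column", path))
  surv <- tab[tab$row_type == "survival", ]
  meas <- tab[tab$row_type == "measure", ]
  if (!nrow(surv)) stop(sprintf("%s has no survival rows", path))
  kids <- surv[setdiff(.KID_COLS, character(0))]
  kids$censored <- as.logical(kids$censored)
  rownames(kids) <- NULL
  measures <- meas[c("kid_id", "age_months", "bw", "cg", "bl", "hw")]
  rownames(measures) <- NULL
  methods::new("KidRecords", kids = kids, measures = measures)
}

#' @rdname chainSamples
setMethod("chainSamples", "MCMCChain", function(object) object@samples)

#' @rdname chainMeta
setMethod("chainMeta", "MCMCChain", function(object) object@meta)

#' Write a chain as a samples table plus JSON-free metadata sidecar
#'
#' The samples go to \code{path} as delimited text (one row per retained
#' iteration); the metadata (model, seed, chain settings, priors) goes to
#' \code{paste0(path, ".meta.yaml")}.
#'
#' @param object an [MCMCChain-class].
#' @param path samples file path.
#' @return invisibly, \code{path}.
#' @export
writeChain <- function(object, path) {
  stopifnot(methods::is(object, "MCMCChain"))
  utils::write.table(as.data.frame(object@samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- object@meta
  meta <- lapply(meta, function(x) if (is.list(x)) x else as.vector(x))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
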