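#' @include summaries.R
NULL

#' Per-age growth summary
#'
#' Mean, standard deviation and record count per age class for each of the
#' four growth traits, missing measurements excluded trait-wise.
#'
#' @param records a [KidRecords-class].
#' @return data.frame with columns trait, age_months, n, mean, sd.
#' @export
growthSummary <- function(records) {
  stopifnot(methods::is(records, "KidRecords"))
  m <- records@measures
  if (!nrow(m)) stop("empty record set")
  ages <- sort(unique(m$age_months))
  rows <- list()
  for (tr in c("bw", "cg", "bl", "hw")) {
    for (a in ages) {
      x <- m[[tr]][m$age_months == a]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, age_months = a, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else
          if (length(x) == 1) 0 else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Phenotypic correlations of body weight with the conformation traits
#'
#' Product-moment correlations on complete pairs.  By default raw records
#' are pooled across age classes (so the common growth trend contributes);
#' \code{withinAge = TRUE} additionally reports age-class-specific
#' correlations.
#'
#' @param records a [KidRecords-class].
#' @param withinAge also report per-age correlations.
#' @return data.frame with columns trait, age (\code{"pooled"} or the age
#'   class), n, correlation.
#' @export
phenotypicCorrelations <- function(records, withinAge = FALSE) {
  stopifnot(methods::is(records, "KidRecords"))
  m <- records@measures
  one <- function(x, y, label, age) {
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    r <- if (n < 3) NA_real_
    else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) NA_real_
    else stats::cor(x[ok], y[ok])
    data.frame(trait = label, age = as.character(age), n = n,
               correlation = r, stringsAsFactors = FALSE)
  }
  out <- list()
  for (tr in c("cg", "bl", "hw")) {
    out[[length(out) + 1]] <- one(m$bw, m[[tr]], tr, "pooled")
    if (withinAge) {
      for (a in sort(unique(m$age_months))) {
        sub <- m[m$age_months == a, ]
        out[[length(out) + 1]] <- one(sub$bw, sub[[tr]], tr, a)
      }
    }
  }
  res <- do.call(rbind, out)
  if (all(is.na(res$correlation))) {
    warning("correlations undefined (constant or too few complete pairs)")
  }
  res
}

#' Mortality and litter-size report
#'
#' One-year mortality overall (under two denominators: kids with a known
#' outcome, and all kids) and by birth type, plus mean litter size overall
#' and per province.  A death is a kid with survival days below the
#' horizon and no censoring flag.
#'
#' @param records a [KidRecords-class].
#' @param horizon days (default 360).
#' @return list with elements \code{mortality} (data.frame: stratum, n,
#'   deaths, rate) and \code{litter_size} (data.frame: province, litters,
#'   mean_size).
#' @export
mortalityReport <- function(records, horizon = 360) {
  stopifnot(methods::is(records, "KidRecords"))
  k <- records@kids
  known <- !is.na(k$survival_days)
  dead <- known & k$survival_days < horizon &
    !(!is.na(k$censored) & k$censored)
  strat <- function(label, idx) {
    data.frame(stratum = label, n = sum(idx), deaths = sum(dead & idx),
               rate = if (sum(idx)) sum(dead & idx) / sum(idx) else NA_real_,
               stringsAsFactors = FALSE)
  }
  mort <- rbind(
    strat("overall (known outcome)", known),
    strat("overall (all kids)", rep(TRUE, nrow(k))),
    strat("single", known & k$birth_type == "single"),
    strat("twin", known & k$birth_type == "twin")
  )
  litter_key <- if (!is.null(k$litter_id)) k$litter_id else
    paste(k$dam_id, k$birth_date, sep = ":")
  sizes <- tapply(rep(1, nrow(k)), litter_key, sum)
  prov <- tapply(k$province, litter_key, function(x) x[1])
  ls <- rbind(
    data.frame(province = "overall", litters = length(sizes),
               mean_size = mean(sizes), stringsAsFactors = FALSE),
    do.call(rbind, lapply(sort(unique(prov)), function(p) {
      data.frame(province = p, litters = sum(prov == p),
                 mean_size = mean(sizes[prov == p]),
                 stringsAsFactors = FALSE)
    }))
  )
  list(mortality = mort, litter_size = ls)
}

#' Human-readable descriptive report
#'
#' Prints the growth summary, phenotypic correlations and mortality report
#' for a records object and invisibly returns them.
#'
#' @param records a [KidRecords-class].
#' @param horizon censoring horizon in days.
#' @return invisibly, list(growth, correlations, mortality).
#' @export
describeRecords <- function(records, horizon = 360) {
  g <- growthSummary(records)
  p <- phenotypicCorrelations(records)
  m <- mortalityReport(records, horizon)
  bw <- g[g$trait == "bw", ]
  cat("Body weight by age (months): mean +/- sd (n)\n")
  for (i in seq_len(nrow(bw))) {
    cat(sprintf("  %4.0f: %5.2f +/- %4.2f (%d)\n", bw$age_months[i],
                bw$mean[i], bw$sd[i], bw$n[i]))
  }
  cat("Phenotypic correlations of BW with cg/bl/hw (pooled):",
      paste(sprintf("%.3f", p$correlation[p$age == "pooled"]),
            collapse = " "), "\n")
  ov <- m$mortality[m$mortality$stratum == "overall (known outcome)", ]
  cat(sprintf("One-year mortality: %.1f%% (%d/%d known outcomes)\n",
              100 * ov$rate, ov$deaths, ov$n))
  for (s in c("single", "twin")) {
    r <- m$mortality[m$mortality$stratum == s, ]
    cat(sprintf("  %s: %.1f%%\n", s, 100 * r$rate))
  }
  cat(sprintf("Mean litter size: %.2f over %d litters\n",
              m$litter_size$mean_size[1], m$litter_size$litters[1]))
  invisible(list(growth = g, correlations = p, mortality = m))
}
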