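# Shared fixtures and independent oracles used across the suite.

# Random valid pedigree: sexes fixed up front so an id is only ever a sire
# or only ever a dam; parents drawn from earlier animals or left unknown.
randomPedigree <- function(n, n_founders = max(4L, n %/% 5L),
                           p_unknown = 0.15) {
  id <- sprintf("A%04d", seq_len(n))
  sex <- rep(c("M", "F"), length.out = n)
  sire <- dam <- rep(NA_character_, n)
  for (i in seq.int(n_founders + 1L, n)) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males) && stats::runif(1) > p_unknown) {
      sire[i] <- id[sample(males, 1L)]
    }
    if (length(females) && stats::runif(1) > p_unknown) {
      dam[i] <- id[sample(females, 1L)]
    }
  }
  sortPedigree(pedigree(id, sire, dam))
}

# Independent recursive kinship-coefficient oracle (memoised).  The
# additive relationship is 2 x kinship; kinship(i,i) = (1 + F_i)/2 with
# F_i = kinship(sire_i, dam_i).
kinshipOracle <- function(ped) {
  ids <- animalIds(ped)
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  sire <- pos[slot(ped, "sire")]
  dam <- pos[slot(ped, "dam")]
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L || is.na(i) || is.na(j)) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + phi(sire[i], dam[i]))
    } else {
      # j is the later-born animal in a sorted pedigree
      0.5 * (phi(i, sire[j]) + phi(i, dam[j]))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    K[i, j] <- K[j, i] <- phi(i, j)
  }
  dimnames(K) <- list(ids, ids)
  K
}

# Minimal hand-built records object for unit tests.
makeRecords <- function(kids, measures) {
  defaults <- list(sire_id = NA_character_, dam_id = "D1", sex = "female",
                   birth_type = "single", parity = 1L, herd = "H1",
                   village = "V1", province = "P1", birth_year = 2016L,
                   season = 1L, birth_date = "2016-04-15",
                   survival_days = 360, censored = TRUE)
  for (nm in names(defaults)) {
    if (is.null(kids[[nm]])) kids[[nm]] <- rep(defaults[[nm]], nrow(kids))
  }
  for (nm in c("bw", "cg", "bl", "hw")) {
    if (is.null(measures[[nm]])) {
      measures[[nm]] <- rep(NA_real_, nrow(measures))
    }
  }
  if (is.null(measures$age_months)) {
    measures$age_months <- rep(0, nrow(measures))
  }
  methods::new("KidRecords", kids = kids, measures = measures)
}

# founder-only pedigree covering the given animals
founderPedigree <- function(ids) {
  sortPedigree(pedigree(ids, rep(NA_character_, length(ids)),
                        rep(NA_character_, length(ids))))
}
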