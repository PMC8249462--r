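## Pedigree reconstruction and pedigree-based inbreeding.
##
## A pedigree is a directed acyclic genealogy with sire/dam links. Kinship
## coefficients are computed by the tabular recursion (equivalent to the
## Meuwissen-Luo algorithm for inbreeding): processing individuals so that
## parents precede offspring,
##   f(i,i) = (1 + f(sire_i, dam_i)) / 2
##   f(i,j) = (f(sire_i, j) + f(dam_i, j)) / 2   for j preceding i,
## with unknown parents contributing 0. Unknown parents are treated as
## distinct unrelated founders (never merged), so reported inbreeding is a
## lower bound. All coefficients are dyadic rationals (k / 2^m) and are
## therefore represented exactly in double precision for any realistic
## pedigree depth.

#' Construct a pedigree
#'
#' @param id character vector of individual ids (unique)
#' @param sire,dam parent ids; `NA`, `""` or `"0"` mean unknown
#' @param sex "M"/"F"/"UNKNOWN" (recycled)
#' @param natal_pack territory code of the natal pack, or `NA`
#' @param birth_year monitoring year of birth (labeled by starting calendar
#'   year; the monitoring year runs May 1 to April 30), or `NA`
#' @return object of class `pedigree` (a data.frame with a `founder` flag),
#'   rows sorted so parents precede offspring
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = "UNKNOWN",
                     natal_pack = NA, birth_year = NA) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  ped <- data.frame(id = id, sire = clean(rep_len(sire, length(id))),
                    dam = clean(rep_len(dam, length(id))),
                    sex = rep_len(as.character(sex), length(id)),
                    natal_pack = clean(rep_len(natal_pack, length(id))),
                    birth_year = rep_len(as.integer(birth_year), length(id)),
                    stringsAsFactors = FALSE)
  ## parents referenced but not listed are added as founders
  miss <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(miss)) {
    ped <- rbind(ped, data.frame(
      id = miss,
      sire = NA_character_, dam = NA_character_,
      sex = ifelse(miss %in% ped$sire, "M", "F"),
      natal_pack = NA_character_, birth_year = NA_integer_,
      stringsAsFactors = FALSE))
  }
  ped$founder <- is.na(ped$sire) & is.na(ped$dam)
  ord <- topo_order(ped)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  sx <- stats::setNames(ped$sex, ped$id)
  bad_sire <- !is.na(ped$sire) & sx[ped$sire] == "F"
  bad_dam <- !is.na(ped$dam) & sx[ped$dam] == "M"
  if (any(bad_sire, na.rm = TRUE) || any(bad_dam, na.rm = TRUE))
    stop("sex-inconsistent parent links for: ",
         paste(ped$id[which(bad_sire | bad_dam)], collapse = ", "))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

## Kahn topological sort; names the cycle on failure
topo_order <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) for (p in c(si[i], di[i])) if (!is.na(p)) {
    indeg[i] <- indeg[i] + 1L
    kids[[p]] <- c(kids[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n)
    stop("pedigree cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders)\n",
              nrow(x), sum(x$founder)))
  invisible(x)
}

#' Full kinship matrix of a pedigree
#'
#' @param ped a [pedigree]
#' @return symmetric numeric matrix of kinship coefficients f(i, j) with
#'   dimnames = ids; diagonal entries are f(i,i) = (1 + F_i)/2
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    ## rows are in topological order: parents already complete
    if (i > 1L) {
      js <- seq_len(i - 1L)
      ks <- if (is.na(si[i])) 0 else K[si[i], js]
      kd <- if (is.na(di[i])) 0 else K[di[i], js]
      K[i, js] <- (ks + kd) / 2
      K[js, i] <- K[i, js]
    }
    fpar <- if (is.na(si[i]) || is.na(di[i])) 0 else K[si[i], di[i]]
    K[i, i] <- (1 + fpar) / 2
  }
  K
}

#' Kinship coefficient between two individuals
#'
#' @param ped a [pedigree]
#' @param i,j individual ids
#' @return f(i, j), the probability that one random allele from each is
#'   identical by descent
#' @export
kinship <- function(ped, i, j) {
  if (!all(c(i, j) %in% ped$id))
    stop("unknown id(s): ", paste(setdiff(c(i, j), ped$id), collapse = ", "))
  K <- kinship_matrix(ped)
  K[i, j]
}

#' Pedigree inbreeding coefficient of a breeding pair's offspring
#'
#' Fp equals the kinship of the two breeders. Values are reported both raw
#' and rounded half-up to 3 decimals (the reporting convention of the
#' German monitoring tables).
#'
#' @param ped a [pedigree]
#' @param male,female breeder ids (must be in the pedigree)
#' @return list with `Fp` (exact) and `Fp_rounded`
#' @export
inbreeding_coefficient <- function(ped, male, female) {
  f <- kinship(ped, male, female)
  list(Fp = f, Fp_rounded = round_half_up(f, 3))
}

#' Inbreeding coefficients of all pedigree members
#' @param ped a [pedigree]
#' @return named numeric vector F_i = f(sire_i, dam_i) (0 for founders)
#' @export
inbreeding <- function(ped) {
  K <- kinship_matrix(ped)
  stats::setNames(2 * diag(K) - 1, ped$id)
}

#' Mendelian-exclusion parentage assignment
#'
#' Tests an offspring genotype against candidate breeding pairs. A locus is
#' compatible when the offspring's two alleles can be split so that one is
#' carried by the sire and the other by the dam. A candidate survives if it
#' is comparable at `min_comparable` loci or more and incompatible at no
#' more than `max_mendelian_mismatches` of them. Candidates can be
#' pre-filtered by activity year and distance to the sampling location.
#'
#' @param offspring single-row [genotype_table] (or an id into `genotypes`)
#' @param candidates data.frame of candidate pairs with columns `territory`,
#'   `male`, `female`, `first_year`, `last_year` and optionally `lat`, `lon`
#' @param genotypes [genotype_table] holding the parental genotypes
#' @param year plausible birth monitoring year of the offspring (NA = skip
#'   the temporal filter)
#' @param location optional `c(lat, lon)` of the offspring's sampling site
#' @param max_km radius of the spatial filter (default 50 km)
#' @param max_mendelian_mismatches tolerated incompatible loci (default 1,
#'   matching the observed scale of single-allele transmission mismatches)
#' @param min_comparable minimum comparable loci per candidate (default 8);
#'   candidates below it are marked untestable, not excluded
#' @return list with `status` ("ASSIGNED"/"UNASSIGNED"), `pair` (row of
#'   `candidates` or NULL), `surviving` (indices), `untestable` (indices)
#' @export
assign_parentage <- function(offspring, candidates, genotypes, year = NA,
                             location = NULL, max_km = 50,
                             max_mendelian_mismatches = 1L,
                             min_comparable = 8L) {
  if (is.character(offspring))
    offspring <- subset_genotypes(genotypes, offspring)
  keep <- rep(TRUE, nrow(candidates))
  if (!is.na(year))
    keep <- keep & candidates$first_year <= year & candidates$last_year >= year
  if (!is.null(location) && all(c("lat", "lon") %in% names(candidates))) {
    d <- geodesic_distance(location[1], location[2],
                           candidates$lat, candidates$lon)
    keep <- keep & !is.na(d) & d <= max_km
  }
  surviving <- integer(0); untestable <- integer(0)
  for (ci in which(keep)) {
    m <- candidates$male[ci]; f <- candidates$female[ci]
    if (!all(c(m, f) %in% ids(genotypes))) { untestable <- c(untestable, ci); next }
    res <- mendelian_mismatches(offspring$A[1, , ], genotypes$A[m, , ],
                                genotypes$A[f, , ])
    if (res$comparable < min_comparable) { untestable <- c(untestable, ci); next }
    if (res$mismatches <= max_mendelian_mismatches)
      surviving <- c(surviving, ci)
  }
  if (length(surviving) == 1L)
    list(status = "ASSIGNED", pair = candidates[surviving, , drop = FALSE],
         surviving = surviving, untestable = untestable)
  else
    list(status = "UNASSIGNED", pair = NULL, surviving = surviving,
         untestable = untestable)
}

## offspring o, sire s, dam d: 2 x L matrices (or L x 2); counts loci where
## no split of o's alleles across the two parents is transmissible
mendelian_mismatches <- function(o, s, d) {
  o <- matrix(o, ncol = 2); s <- matrix(s, ncol = 2); d <- matrix(d, ncol = 2)
  comparable <- 0L; mism <- 0L
  for (l in seq_len(nrow(o))) {
    if (anyNA(o[l, ]) || anyNA(s[l, ]) || anyNA(d[l, ])) next
    comparable <- comparable + 1L
    ok <- (o[l, 1] %in% s[l, ] && o[l, 2] %in% d[l, ]) ||
          (o[l, 2] %in% s[l, ] && o[l, 1] %in% d[l, ])
    if (!ok) mism <- mism + 1L
  }
  list(comparable = comparable, mismatches = mism)
}

#' Litter and breeder summary from a breeding-pair table
#'
#' Expands each pair's year range into one litter per monitoring year
#' (a range X-Y counts Y-X+1 litters), computes the offspring inbreeding
#' coefficient of every pair from the pedigree, and tallies the quantities
#' reported in recolonization summaries.
#'
#' @param pairs data.frame with `territory`, `male`, `female`,
#'   `first_year`, `last_year` (see [read_breeding_pairs()])
#' @param ped a [pedigree] containing all genotyped breeders
#' @param fp_threshold threshold for the "elevated inbreeding" tally
#'   (default 0.156)
#' @return list with `pairs` (input plus `Fp`, `Fp_rounded`, `n_litters`,
#'   `bond_years`), `litters` (one row per pair-year), `n_litters`,
#'   `mean_bond`, `min_bond`, `max_bond`, `n_litters_inbred` /
#'   `pct_litters_inbred` (Fp > 0), `n_litters_high_fp` /
#'   `pct_litters_high_fp` (Fp >= threshold), `breeders` (per-breeder
#'   origin/sex table) and `breeder_origin` (counts by sex and known vs
#'   unknown natal pack)
#' @export
litter_summary <- function(pairs, ped, fp_threshold = 0.156) {
  K <- kinship_matrix(ped)
  gt <- function(x) x %in% ped$id        # genotyped = present in pedigree
  fp <- mapply(function(m, f) {
    if (gt(m) && gt(f)) K[m, f] else NA_real_
  }, pairs$male, pairs$female)
  pairs$Fp <- ifelse(is.na(fp), 0, fp)   # ungenotyped breeder: founder, Fp 0
  pairs$Fp_rounded <- round_half_up(pairs$Fp, 3)
  pairs$bond_years <- pairs$last_year - pairs$first_year + 1L
  pairs$n_litters <- pairs$bond_years
  litters <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(territory = pairs$territory[i], male = pairs$male[i],
               female = pairs$female[i],
               year = seq.int(pairs$first_year[i], pairs$last_year[i]),
               Fp = pairs$Fp[i], Fp_rounded = pairs$Fp_rounded[i],
               stringsAsFactors = FALSE)
  }))
  nl <- nrow(litters)
  ## distinct genotyped breeders (Roman-numeral ungenotyped ids excluded)
  genotyped <- function(x) grepl("^GW", x)
  br <- rbind(
    data.frame(id = pairs$male, sex = "M", stringsAsFactors = FALSE),
    data.frame(id = pairs$female, sex = "F", stringsAsFactors = FALSE))
  br <- br[!duplicated(br$id) & genotyped(br$id), , drop = FALSE]
  np <- stats::setNames(ped$natal_pack, ped$id)
  br$natal_pack <- np[br$id]
  br$origin <- ifelse(is.na(br$natal_pack), "unknown", "known")
  origin <- table(sex = br$sex, origin = br$origin)
  list(pairs = pairs, litters = litters,
       n_pairs = nrow(pairs), n_litters = nl,
       mean_bond = mean(pairs$bond_years),
       min_bond = min(pairs$bond_years), max_bond = max(pairs$bond_years),
       n_litters_inbred = sum(litters$Fp > 0),
       pct_litters_inbred = 100 * sum(litters$Fp > 0) / nl,
       n_litters_high_fp = sum(litters$Fp >= fp_threshold),
       pct_litters_high_fp = 100 * sum(litters$Fp >= fp_threshold) / nl,
       n_breeders = nrow(br),
       breeders = br, breeder_origin = origin,
       fp_threshold = fp_threshold)
}

#' Read / write a pedigree file
#'
#' Plain-text CSV, one row per individual: `id`, `sire`, `dam` (0 or empty
#' = unknown), `sex`, `natal_pack`, `birth_year`.
#'
#' @param path file path
#' @return `read_pedigree`: a [pedigree]
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(birth_year = "integer"))
  pedigree(df$id, df$sire, df$dam, df$sex, df$natal_pack, df$birth_year)
}

#' @rdname read_pedigree
#' @param ped a [pedigree]
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[c("id", "sire", "dam", "sex", "natal_pack",
                              "birth_year")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a breeding-pair table
#'
#' CSV with columns `territory`, `male`, `female`, `first_year`,
#' `last_year` (and optionally natal packs and a published Fp column).
#'
#' @param path file path
#' @return data.frame
#' @export
read_breeding_pairs <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
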