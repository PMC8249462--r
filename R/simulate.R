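## Synthetic recolonization simulator.
##
## Generates a territorial wolf population with known pedigree, genotypes
## and sampling-error process so that every pipeline stage can be tested
## against ground truth: immigrants found packs, packs produce annual
## litters by Mendelian inheritance, matured offspring disperse, and
## vacant breeding slots are refilled with a male bias (females more often
## stay or take over their natal territory).

#' Simulation configuration
#'
#' Defaults mirror the regime observed during the German recolonization:
#' pack numbers growing roughly 30% per year, dispersal distances of tens
#' of kilometres, strongly male-biased among-pack dispersal, 13
#' microsatellite loci with 4-8 alleles each, and a multiple-tube sampling
#' process with per-call allelic dropout and rare false alleles.
#'
#' @param years number of simulated monitoring years
#' @param start_year first monitoring year label
#' @param n_founder_immigrants immigrants arriving per year
#' @param founder_freqs list per locus of named allele frequency vectors
#'   (names = fragment length in bp); default 13 loci, 4-8 uniform alleles
#' @param lat_range,lon_range territory grid extent (WGS84 box)
#' @param pack_founding_prob probability a paired disperser couple founds a
#'   new territory in a given year
#' @param litter_mean Poisson mean litter size (truncated at >= 1)
#' @param dispersal_mean_km mean of the exponential dispersal kernel
#' @param male_fill_prob probability a vacant breeding slot in an existing
#'   pack is refilled by an immigrating male (vs staying vacant)
#' @param female_fill_prob same for females (lower: among-pack dispersal is
#'   male-biased)
#' @param female_takeover_prob probability a resident daughter takes over a
#'   vacant female slot not filled from outside
#' @param breeder_mortality annual breeder mortality
#' @param juvenile_survival annual survival of not-yet-mature residents
#' @param disperser_loss annual loss (death/emigration) of dispersers
#' @param maturity_age age (years) at which offspring disperse
#' @param mtdna_pool named probabilities of founder mtDNA haplotypes
#' @param dropout_rate per replicate-locus probability that a heterozygote
#'   call loses one allele
#' @param false_allele_rate per replicate-locus probability that one allele
#'   is shifted by one repeat unit (+/- 2 bp)
#' @param locus_failure_rate per replicate-locus probability of total
#'   amplification failure
#' @param sex_marker_success per-replicate amplification probability of
#'   each sex marker
#' @param replicates PCR replicates per sample
#' @param samples_per_ind_year samples collected per individual per year
#' @param seed RNG seed (mandatory)
#' @return a `sim_config` list
#' @export
sim_config <- function(years = 30L, start_year = 2000L,
                       n_founder_immigrants = 2L,
                       founder_freqs = default_founder_freqs(),
                       lat_range = c(51, 54), lon_range = c(11, 15),
                       pack_founding_prob = 0.5, litter_mean = 4,
                       dispersal_mean_km = 70, male_fill_prob = 0.8,
                       female_fill_prob = 0.4, female_takeover_prob = 0.5,
                       breeder_mortality = 0.15, juvenile_survival = 0.55,
                       disperser_loss = 0.25, maturity_age = 2L,
                       mtdna_pool = c(HW01 = 0.8, HW02 = 0.2),
                       dropout_rate = 0.1, false_allele_rate = 0.01,
                       locus_failure_rate = 0.05, sex_marker_success = 0.95,
                       replicates = 4L, samples_per_ind_year = 1L, seed) {
  stopifnot_scalar(seed, "seed")
  cfg <- as.list(environment())
  probs <- c(pack_founding_prob, male_fill_prob, female_fill_prob,
             female_takeover_prob, breeder_mortality, juvenile_survival,
             disperser_loss, dropout_rate, false_allele_rate,
             locus_failure_rate, sex_marker_success, mtdna_pool)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Default founder allele frequencies: 13 loci, 4-8 uniform alleles
#' @return named list of allele frequency vectors
#' @export
default_founder_freqs <- function() {
  k <- rep(4:8, length.out = 13)
  fr <- lapply(seq_len(13), function(i) {
    al <- 100 + 2 * (0:(k[i] - 1))
    stats::setNames(rep(1 / k[i], k[i]), al)
  })
  names(fr) <- sprintf("L%02d", seq_len(13))
  fr
}

#' Simulate a recolonizing territorial population
#'
#' Year-stepped simulation: immigrants arrive as unrelated founders; pairs
#' of mature dispersers found new territories or refill vacant breeding
#' slots; packs with a complete pair produce one litter per monitoring
#' year; gametes are drawn per locus by Mendelian segregation; mtDNA is
#' maternal; runs are deterministic given the seed.
#'
#' @param config a [sim_config]
#' @return object of class `sim_truth`: `individuals` (data.frame),
#'   `pedigree` ([pedigree]), `genotypes` ([genotype_table]), `packs`,
#'   `litters`, `pairs` (breeding-pair table), `extinct` flag, `config`
#' @export
simulate_recolonization <- function(config) {
  set.seed(as.integer(config$seed))
  L <- length(config$founder_freqs)
  lnames <- names(config$founder_freqs)
  ## preallocated columns with capacity doubling (rbind-per-row is O(n^2))
  cap <- 512L; nid <- 0L
  blank <- function(proto) rep(proto, cap)
  ind <- list(id = blank(NA_character_), sex = blank(NA_character_),
              sire = blank(NA_character_), dam = blank(NA_character_),
              birth_year = blank(NA_integer_), natal_pack = blank(NA_character_),
              mtdna = blank(NA_character_), death_year = blank(NA_integer_),
              role = blank(NA_character_), pack = blank(NA_character_),
              lat = blank(NA_real_), lon = blank(NA_real_))
  G <- matrix(NA_integer_, cap, 2 * L)
  grow <- function() {
    for (nm in names(ind)) ind[[nm]] <<- c(ind[[nm]], rep(ind[[nm]][1][NA], cap))
    G <<- rbind(G, matrix(NA_integer_, cap, 2 * L))
    cap <<- 2L * cap
  }
  packs <- data.frame(code = character(0), lat = numeric(0), lon = numeric(0),
                      founded = integer(0), male = character(0),
                      female = character(0), active = logical(0),
                      stringsAsFactors = FALSE)
  litters <- NULL

  founder_geno <- function() {
    unlist(lapply(config$founder_freqs, function(p) {
      as.integer(sample(names(p), 2, replace = TRUE, prob = p))
    }), use.names = FALSE)
  }
  mendel_geno <- function(si, di) {
    gs <- G[si, ]; gd <- G[di, ]
    odd <- 2 * seq_len(L) - 1L
    v <- integer(2 * L)
    v[odd] <- gs[odd - 1L + sample.int(2, L, replace = TRUE)]
    v[odd + 1L] <- gd[odd - 1L + sample.int(2, L, replace = TRUE)]
    v
  }
  add_ind <- function(sex, sire, dam, year, natal, mtdna, role, pack,
                      lat, lon, geno) {
    if (nid == cap) grow()
    nid <<- nid + 1L
    id <- sprintf("SIM%04d%s", nid, if (sex == "M") "m" else "f")
    ind$id[nid] <<- id; ind$sex[nid] <<- sex
    ind$sire[nid] <<- sire; ind$dam[nid] <<- dam
    ind$birth_year[nid] <<- year; ind$natal_pack[nid] <<- natal
    ind$mtdna[nid] <<- mtdna; ind$death_year[nid] <<- NA_integer_
    ind$role[nid] <<- role; ind$pack[nid] <<- pack
    ind$lat[nid] <<- lat; ind$lon[nid] <<- lon
    G[nid, ] <<- geno
    id
  }
  idx <- function(id) match(id, ind$id)
  kernel_move <- function(lat, lon) {
    d <- stats::rexp(1, 1 / config$dispersal_mean_km)
    th <- stats::runif(1, 0, 2 * pi)
    nl <- lat + d * cos(th) / 111.32
    no <- lon + d * sin(th) / (111.32 * cos(lat * pi / 180))
    c(min(max(nl, config$lat_range[1]), config$lat_range[2]),
      min(max(no, config$lon_range[1]), config$lon_range[2]))
  }

  yrs <- config$start_year + seq_len(config$years) - 1L
  for (y in yrs) {
    ## 1. immigrant founders join the disperser pool
    for (k in seq_len(config$n_founder_immigrants)) {
      add_ind(sex = sample(c("M", "F"), 1),
              sire = NA_character_, dam = NA_character_,
              year = y - sample(2:4, 1),    # arrive as adults
              natal = NA_character_,
              mtdna = sample(names(config$mtdna_pool), 1,
                             prob = config$mtdna_pool),
              role = "disperser", pack = NA_character_,
              lat = stats::runif(1, config$lat_range[1], config$lat_range[2]),
              lon = stats::runif(1, config$lon_range[1], config$lon_range[2]),
              geno = founder_geno())
    }
    alive <- !is.na(ind$id) & is.na(ind$death_year)
    ## 2. mortality
    mort <- c(breeder = config$breeder_mortality,
              disperser = config$disperser_loss,
              resident = 1 - config$juvenile_survival)
    dies <- alive & stats::runif(length(ind$id)) < mort[ind$role]
    dies[is.na(dies)] <- FALSE
    ind$death_year[dies] <- y
    for (p in which(packs$active)) {
      if (!is.na(packs$male[p]) && !is.na(ind$death_year[idx(packs$male[p])]))
        packs$male[p] <- NA_character_
      if (!is.na(packs$female[p]) && !is.na(ind$death_year[idx(packs$female[p])]))
        packs$female[p] <- NA_character_
      if (is.na(packs$male[p]) && is.na(packs$female[p]))
        packs$active[p] <- FALSE
    }
    ## 3. maturation: residents of dispersal age leave their natal pack
    alive <- !is.na(ind$id) & is.na(ind$death_year)
    mature <- alive & ind$role == "resident" &
      (y - ind$birth_year) >= config$maturity_age
    ind$role[mature] <- "disperser"
    pool <- function(sex) which(alive & ind$role == "disperser" &
                                ind$sex == sex)
    ## 4. refill vacant breeding slots (male-biased among-pack dispersal)
    for (p in which(packs$active)) {
      if (is.na(packs$male[p]) && !is.na(packs$female[p]) &&
          stats::runif(1) < config$male_fill_prob) {
        cand <- setdiff(pool("M"), which(ind$natal_pack %in% packs$code[p]))
        if (length(cand)) {
          ch <- cand[sample.int(length(cand), 1)]
          packs$male[p] <- ind$id[ch]
          ind$role[ch] <- "breeder"; ind$pack[ch] <- packs$code[p]
        }
      }
      if (is.na(packs$female[p]) && !is.na(packs$male[p])) {
        filled <- FALSE
        if (stats::runif(1) < config$female_fill_prob) {
          cand <- setdiff(pool("F"), which(ind$natal_pack %in% packs$code[p]))
          if (length(cand)) {
            ch <- cand[sample.int(length(cand), 1)]
            packs$female[p] <- ind$id[ch]
            ind$role[ch] <- "breeder"; ind$pack[ch] <- packs$code[p]
            filled <- TRUE
          }
        }
        if (!filled && stats::runif(1) < config$female_takeover_prob) {
          cand <- which(alive & ind$sex == "F" & ind$role == "disperser" &
                        ind$natal_pack %in% packs$code[p])
          if (length(cand)) {
            ch <- cand[sample.int(length(cand), 1)]
            packs$female[p] <- ind$id[ch]
            ind$role[ch] <- "breeder"; ind$pack[ch] <- packs$code[p]
          }
        }
      }
    }
    ## 5. new pack founding by disperser pairs
    males <- pool("M"); males <- males[sample.int(length(males))]
    females <- pool("F"); females <- females[sample.int(length(females))]
    np <- min(length(males), length(females))
    if (np > 0) for (k in seq_len(np)) {
      if (stats::runif(1) >= config$pack_founding_prob) next
      m <- males[k]; f <- females[k]
      loc <- kernel_move(ind$lat[m], ind$lon[m])
      code <- sprintf("T%03d", nrow(packs) + 1L)
      packs[nrow(packs) + 1L, ] <- list(code, loc[1], loc[2], y,
                                        ind$id[m], ind$id[f], TRUE)
      ind$role[c(m, f)] <- "breeder"
      ind$pack[c(m, f)] <- code
      ind$lat[c(m, f)] <- loc[1]; ind$lon[c(m, f)] <- loc[2]
    }
    ## 6. reproduction: one litter per complete pair per monitoring year
    for (p in which(packs$active)) {
      m <- packs$male[p]; f <- packs$female[p]
      if (is.na(m) || is.na(f)) next
      size <- max(1L, stats::rpois(1, config$litter_mean))
      for (k in seq_len(size)) {
        add_ind(sex = sample(c("M", "F"), 1), sire = m, dam = f,
                year = y, natal = packs$code[p],
                mtdna = ind$mtdna[idx(f)],
                role = "resident", pack = packs$code[p],
                lat = packs$lat[p], lon = packs$lon[p],
                geno = mendel_geno(idx(m), idx(f)))
      }
      litters <- rbind(litters, data.frame(
        territory = packs$code[p], male = m, female = f, year = y,
        size = size, stringsAsFactors = FALSE))
    }
    if (!any(!is.na(ind$id) & is.na(ind$death_year))) break   # extinction
  }

  ind <- as.data.frame(lapply(ind, function(v) v[seq_len(nid)]),
                       stringsAsFactors = FALSE)
  G <- G[seq_len(nid), , drop = FALSE]
  A <- array(NA_integer_, dim = c(nrow(ind), L, 2),
             dimnames = list(ind$id, lnames, c("a", "b")))
  A[, , 1] <- G[, 2 * seq_len(L) - 1]
  A[, , 2] <- G[, 2 * seq_len(L)]
  pairs <- if (!is.null(litters)) {
    agg <- stats::aggregate(year ~ territory + male + female, litters,
                            function(v) c(min(v), max(v)))
    data.frame(territory = agg$territory, male = agg$male,
               female = agg$female, first_year = agg$year[, 1],
               last_year = agg$year[, 2], stringsAsFactors = FALSE)
  } else NULL
  structure(list(
    individuals = ind,
    pedigree = pedigree(ind$id, ind$sire, ind$dam, ind$sex,
                        ind$natal_pack, ind$birth_year),
    genotypes = genotype_table(A, ind$sex, ind$mtdna),
    packs = packs, litters = litters, pairs = pairs,
    extinct = all(!is.na(ind$death_year)),
    config = config), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d individuals, %d packs, %d litters%s\n",
              nrow(x$individuals), nrow(x$packs),
              if (is.null(x$litters)) 0L else nrow(x$litters),
              if (x$extinct) " (extinct)" else ""))
  invisible(x)
}

#' Simulate replicated non-invasive sampling of a population
#'
#' Emits a replicate-level sample table in the format of
#' [read_sample_table()]. Per replicate and locus the true genotype is
#' degraded: whole-locus failure, allelic dropout of one allele of a
#' heterozygote, or a false allele shifted by one repeat unit (2 bp).
#' Sex-marker amplification flags follow the true sex with a per-replicate
#' success rate.
#'
#' @param truth a `sim_truth`
#' @param config the same [sim_config] (seed lineage: sampling reseeds with
#'   `seed + 1`)
#' @param years restrict sampling to these monitoring years (default: all)
#' @param roles which roles are sampled (default breeders and residents,
#'   i.e. pack members)
#' @return list: `samples` (data.frame), `truth_map` (sample_id ->
#'   individual id), `errors` (injected error events)
#' @export
simulate_sampling <- function(truth, config, years = NULL,
                              roles = c("breeder", "resident")) {
  set.seed(as.integer(config$seed) + 1L)
  ind <- truth$individuals
  L <- length(config$founder_freqs)
  lnames <- names(config$founder_freqs)
  yrs <- years %||%
    seq(config$start_year, config$start_year + config$years - 1L)
  rows <- list(); map <- character(0); errors <- list()
  for (y in yrs) {
    live <- which(ind$birth_year <= y &
                  (is.na(ind$death_year) | ind$death_year > y) &
                  ind$role %in% roles)
    for (i in live) {
      for (s in seq_len(config$samples_per_ind_year)) {
        sid <- sprintf("%s_Y%d_S%d", ind$id[i], y, s)
        map[sid] <- ind$id[i]
        for (r in seq_len(config$replicates)) {
          row <- list(sample_id = sid, date = sprintf("%d-10-01", y),
                      lat = ind$lat[i] + stats::rnorm(1, 0, 0.02),
                      lon = ind$lon[i] + stats::rnorm(1, 0, 0.02),
                      type = "scat",
                      dbx6 = as.integer(stats::runif(1) < config$sex_marker_success),
                      dby7 = as.integer(ind$sex[i] == "M" &&
                               stats::runif(1) < config$sex_marker_success))
          for (l in seq_len(L)) {
            a <- truth$genotypes$A[ind$id[i], l, 1]
            b <- truth$genotypes$A[ind$id[i], l, 2]
            if (stats::runif(1) < config$locus_failure_rate) {
              a <- b <- NA_integer_
            } else {
              if (a != b && stats::runif(1) < config$dropout_rate) {
                keep <- if (stats::runif(1) < 0.5) a else b
                errors[[length(errors) + 1L]] <-
                  list(sample = sid, replicate = r, locus = lnames[l],
                       kind = "dropout")
                a <- b <- keep
              }
              if (stats::runif(1) < config$false_allele_rate) {
                shift <- sample(c(-2L, 2L), 1)
                if (stats::runif(1) < 0.5) a <- a + shift else b <- b + shift
                errors[[length(errors) + 1L]] <-
                  list(sample = sid, replicate = r, locus = lnames[l],
                       kind = "false_allele")
              }
            }
            row[[paste0(lnames[l], "_a")]] <- a
            row[[paste0(lnames[l], "_b")]] <- b
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  samples <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(samples))
    samples$replicate <- stats::ave(seq_len(nrow(samples)),
                                    samples$sample_id, FUN = seq_along)
  list(samples = samples, truth_map = map,
       errors = if (length(errors))
         do.call(rbind, lapply(errors, as.data.frame)) else NULL)
}
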