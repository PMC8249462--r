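test_that("simulated truth is Mendelian-consistent and maternally inherited", {
  cfg <- sim_config(years = 10L, seed = 51L)
  truth <- simulate_recolonization(cfg)
  ind <- truth$individuals
  g <- truth$genotypes
  off <- which(!is.na(ind$sire))
  expect_gt(length(off), 20L)
  for (i in off) {
    s <- ind$sire[i]; d <- ind$dam[i]
    for (l in loci(g)) {
      expect_true(any(g$A[ind$id[i], l, 1] == g$A[s, l, ]) ||
                  any(g$A[ind$id[i], l, 1] == g$A[d, l, ]))
      ok <- (g$A[ind$id[i], l, 1] %in% g$A[s, l, ] &
             g$A[ind$id[i], l, 2] %in% g$A[d, l, ]) |
            (g$A[ind$id[i], l, 2] %in% g$A[s, l, ] &
             g$A[ind$id[i], l, 1] %in% g$A[d, l, ])
      expect_true(ok)
    }
    expect_equal(ind$mtdna[i], ind$mtdna[match(d, ind$id)])
  }
  ## sex markers follow true sex in noise-free sampling
  cfg0 <- sim_config(years = 6L, dropout_rate = 0, false_allele_rate = 0,
                     locus_failure_rate = 0, sex_marker_success = 1,
                     seed = 52L)
  tr0 <- simulate_recolonization(cfg0)
  sam <- simulate_sampling(tr0, cfg0)
  sexes <- stats::setNames(tr0$individuals$sex, tr0$individuals$id)
  male <- sexes[sam$truth_map[sam$samples$sample_id]] == "M"
  expect_equal(unname(sam$samples$dby7), as.integer(male))
})

test_that("same seed gives byte-identical simulations", {
  cfg <- sim_config(years = 8L, seed = 53L)
  t1 <- simulate_recolonization(cfg)
  t2 <- simulate_recolonization(cfg)
  expect_identical(t1$individuals, t2$individuals)
  expect_identical(t1$genotypes$A, t2$genotypes$A)
  s1 <- simulate_sampling(t1, cfg, years = 2004:2006)
  s2 <- simulate_sampling(t2, cfg, years = 2004:2006)
  expect_identical(s1$samples, s2$samples)
})

test_that("sampling error limits behave as specified", {
  base <- sim_config(years = 6L, seed = 54L)
  truth <- simulate_recolonization(base)
  het <- function(sam) {
    la <- grep("_a$", names(sam$samples), value = TRUE)
    any(vapply(la, function(cl) {
      b <- sub("_a$", "_b", cl)
      any(sam$samples[[cl]] != sam$samples[[b]], na.rm = TRUE)
    }, logical(1)))
  }
  ## dropout = 1: every heterozygous replicate call collapses to homozygote
  cfg1 <- sim_config(years = 6L, dropout_rate = 1, false_allele_rate = 0,
                     locus_failure_rate = 0, seed = 54L)
  expect_false(het(simulate_sampling(truth, cfg1)))
  ## dropout = 0: replicate calls equal true genotypes
  cfg0 <- sim_config(years = 6L, dropout_rate = 0, false_allele_rate = 0,
                     locus_failure_rate = 0, seed = 54L)
  sam0 <- simulate_sampling(truth, cfg0)
  tm <- sam0$truth_map
  for (l in loci(truth$genotypes)[1:3]) {
    tru <- truth$genotypes$A[tm[sam0$samples$sample_id], l, ]
    expect_equal(unname(pmin(sam0$samples[[paste0(l, "_a")]],
                             sam0$samples[[paste0(l, "_b")]])),
                 unname(tru[, 1]))
  }
})

test_that("consensus heterozygote recovery matches the binomial bound", {
  ## with per-call dropout d and R replicates, a true heterozygote is
  ## recovered whenever the full pair appears in >= het_min replicates:
  ## P = 1 - pbinom(het_min - 1, R, (1-d)) (false alleles lower it slightly)
  cfg <- sim_config(years = 8L, dropout_rate = 0.1, false_allele_rate = 0,
                    locus_failure_rate = 0, seed = 55L)
  truth <- simulate_recolonization(cfg)
  sam <- simulate_sampling(truth, cfg)
  cons <- consensus_genotypes(sam$samples)
  tm <- sam$truth_map
  n_het <- 0L; n_rec <- 0L
  for (i in seq_len(nrow(cons$genotypes$A))) {
    sid <- ids(cons$genotypes)[i]
    tru <- truth$genotypes$A[tm[sid], , ]
    for (l in seq_len(nrow(tru))) {
      if (tru[l, 1] == tru[l, 2]) next
      n_het <- n_het + 1L
      n_rec <- n_rec + identical(unname(cons$genotypes$A[i, l, ]),
                                 unname(tru[l, ]))
    }
  }
  p_closed <- 1 - stats::pbinom(1, cfg$replicates, 1 - cfg$dropout_rate)
  expect_gt(n_het, 200L)
  expect_gte(n_rec / n_het, 0.95)
  expect_gt(n_rec / n_het, p_closed - 0.03)
})

test_that("a forced founder-pair full-sib mating yields Fp = 0.25", {
  ## one immigrant pair, no further immigration: any later pack is founded
  ## by descendants of the single founder pair
  cfg <- sim_config(years = 12L, n_founder_immigrants = 0L,
                    pack_founding_prob = 1, breeder_mortality = 0,
                    seed = 56L)
  ## hand-build the founder pair, then let the simulator continue:
  ## simplest route: run with immigrants in year 1 only via a 1-year run
  ## that we extend is not supported, so construct the pedigree directly
  ped <- pedigree(id = c("M0", "F0", "S1", "S2"),
                  sire = c(NA, NA, "M0", "M0"),
                  dam = c(NA, NA, "F0", "F0"),
                  sex = c("M", "F", "M", "F"))
  expect_equal(inbreeding_coefficient(ped, "S1", "S2")$Fp, 0.25)
  ## and confirm the simulator reaches the same value through its own
  ## pedigree when a sib pair happens to breed
  truth <- simulate_recolonization(sim_config(years = 14L, seed = 57L))
  sibs <- NULL
  pr <- truth$pairs
  ind <- truth$individuals
  for (i in seq_len(nrow(pr))) {
    m <- match(pr$male[i], ind$id); f <- match(pr$female[i], ind$id)
    if (!is.na(ind$sire[m]) && !is.na(ind$sire[f]) &&
        ind$sire[m] == ind$sire[f] && ind$dam[m] == ind$dam[f]) {
      fp <- inbreeding_coefficient(truth$pedigree, pr$male[i], pr$female[i])$Fp
      expect_gte(fp, 0.25)
      sibs <- c(sibs, i)
    }
  }
  succeed()  # sib pairings are stochastic; the Fp check above ran if any
})

test_that("default 30-year runs stay in the observed inbreeding regime", {
  cfg <- sim_config(seed = 58L)      # defaults: 30 years
  truth <- simulate_recolonization(cfg)
  expect_false(truth$extinct)
  K <- kinship_matrix(truth$pedigree)
  fp <- mapply(function(m, f) K[m, f], truth$litters$male,
               truth$litters$female)
  expect_gte(mean(fp), 0)
  expect_lte(mean(fp), 0.1)
})
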