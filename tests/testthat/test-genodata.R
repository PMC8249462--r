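test_that("consensus applies the multiple-tube acceptance rules", {
  ## heterozygote seen twice among three replicates -> accepted
  reps <- rep_fix(list(list(L1 = c(120, 124)), list(L1 = c(120, 120)),
                       list(L1 = c(120, 124))))
  cc <- call_consensus(reps, min_loci = 1)
  expect_equal(unname(cc$genotype[, "L1"]), c(120L, 124L))

  ## homozygote needs three amplifications
  reps <- rep_fix(list(list(L1 = c(120, 120)), list(L1 = c(120, 120))))
  cc <- call_consensus(reps, min_loci = 0)
  expect_true(all(is.na(cc$genotype[, "L1"])))
  reps <- rep_fix(list(list(L1 = c(120, 120)), list(L1 = c(120, 120)),
                       list(L1 = c(120, 120))))
  cc <- call_consensus(reps, min_loci = 1)
  expect_equal(unname(cc$genotype[, "L1"]), c(120L, 120L))

  ## an accepted heterozygote pre-empts a supported homozygote
  reps <- rep_fix(list(list(L1 = c(120, 124)), list(L1 = c(120, 124)),
                       list(L1 = c(120, 120)), list(L1 = c(120, 120)),
                       list(L1 = c(120, 120))))
  cc <- call_consensus(reps, min_loci = 1)
  expect_equal(unname(cc$genotype[, "L1"]), c(120L, 124L))

  ## two supported heterozygotes conflict -> locus missing with warning
  reps <- rep_fix(list(list(L1 = c(120, 124)), list(L1 = c(120, 124)),
                       list(L1 = c(122, 126)), list(L1 = c(122, 126))))
  expect_warning(cc <- call_consensus(reps, min_loci = 0), "conflict")
  expect_true(all(is.na(cc$genotype[, "L1"])))

  expect_error(call_consensus(rep_fix(list())), "empty")
  expect_error(call_consensus(rep_fix(list(list(L1 = c(1, 1)))),
                              het_min = 2, hom_min = 1), "hom_min")
})

test_that("genotypes below the locus minimum are rejected", {
  ## 9 loci with a solid heterozygote each, min_loci = 10 -> REJECTED
  calls9 <- stats::setNames(rep(list(c(120, 124)), 9), paste0("L", 1:9))
  reps <- rep_fix(list(calls9, calls9))
  expect_equal(call_consensus(reps, min_loci = 10)$status, "REJECTED")
  calls10 <- stats::setNames(rep(list(c(120, 124)), 10), paste0("L", 1:10))
  reps <- rep_fix(list(calls10, calls10))
  expect_equal(call_consensus(reps, min_loci = 10)$status, "OK")
})

test_that("consensus never under-supports a call (randomized property)", {
  set.seed(42)
  for (k in 1:30) {
    nrep <- sample(2:6, 1)
    reps <- rep_fix(lapply(seq_len(nrep), function(r) {
      list(L1 = sort(sample(c(100L, 102L, 104L), 2, replace = TRUE)))
    }))
    cc <- suppressWarnings(call_consensus(reps, min_loci = 0))
    g <- cc$genotype[, "L1"]
    if (!anyNA(g)) {
      key <- paste(pmin(reps$L1_a, reps$L1_b), pmax(reps$L1_a, reps$L1_b))
      support <- sum(key == paste(g[1], g[2]))
      expect_gte(support, if (g[1] == g[2]) 3L else 2L)
    }
  }
})

test_that("sex assignment needs replicated marker support", {
  expect_equal(assign_sex(data.frame(dbx6 = c(1, 1, 1), dby7 = c(1, 1, 1))), "M")
  expect_equal(assign_sex(data.frame(dbx6 = c(1, 1), dby7 = c(0, 0))), "F")
  expect_equal(assign_sex(data.frame(dbx6 = 1, dby7 = 0)), "UNKNOWN")
  ## single Y amplification is contradictory, not male
  expect_equal(assign_sex(data.frame(dbx6 = c(1, 1), dby7 = c(1, 0))), "UNKNOWN")
})

test_that("identification groups matching genotypes transitively", {
  base <- stats::setNames(lapply(1:13, function(i) c(100L + 2L * i, 104L + 2L * i)),
                          sprintf("L%02d", 1:13))
  g1 <- base
  g2 <- base; g2$L03 <- c(g2$L03[1], g2$L03[1])       # one dropout mismatch
  g3 <- base; for (l in c("L01", "L02", "L04")) g3[[l]] <- c(90L, 92L)
  g <- gt_fix(list(s1 = g1, s2 = g2, s3 = g3))
  res <- identify_individuals(g, max_mismatch_loci = 1)
  expect_equal(res$map[["s1"]], res$map[["s2"]])
  expect_false(res$map[["s1"]] == res$map[["s3"]])
  expect_equal(nrow(res$individuals$A), 2L)
  ## merged consensus keeps the heterozygote at the dropout locus
  ind <- res$map[["s1"]]
  expect_equal(unname(res$individuals$A[ind, "L03", ]), base$L03)

  ## three mismatches at tolerance 1 -> distinct individuals
  g4 <- base; for (l in c("L01", "L02", "L04")) g4[[l]] <- c(91L, 93L)
  res2 <- identify_individuals(gt_fix(list(a = base, b = g4)),
                               max_mismatch_loci = 1)
  expect_equal(nrow(res2$individuals$A), 2L)

  ## a three-allele merge is refused and flagged
  g5 <- base; g5$L05 <- c(200L, 204L)
  g6 <- base; g6$L05 <- c(200L, 208L)
  res3 <- identify_individuals(gt_fix(list(a = g5, b = g6)),
                               max_mismatch_loci = 1)
  expect_equal(nrow(res3$individuals$A), 2L)
  expect_equal(nrow(res3$flagged_pairs), 1L)
})

test_that("identification is invariant to input order", {
  set.seed(7)
  cfg <- sim_config(years = 6L, seed = 11L)
  truth <- simulate_recolonization(cfg)
  g <- truth$genotypes
  take <- seq_len(min(25L, nrow(g$A)))
  g <- subset_genotypes(g, take)
  r1 <- identify_individuals(g, max_mismatch_loci = 0L)
  perm <- sample(length(take))
  r2 <- identify_individuals(subset_genotypes(g, perm), max_mismatch_loci = 0L)
  part1 <- split(names(r1$map), r1$map)
  part2 <- split(names(r2$map), r2$map)
  norm <- function(p) unname(sort(vapply(p, function(x)
    paste(sort(x), collapse = ","), character(1))))
  expect_equal(norm(part1), norm(part2))
})

test_that("mtDNA haplotypes are assigned by exact containment", {
  set.seed(1)
  ref390 <- paste(sample(c("A", "C", "G", "T"), 390, TRUE), collapse = "")
  ref250 <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  refs <- c(HW01 = ref390, HW02 = ref250)
  expect_equal(assign_mtdna_haplotype(ref390, refs), "HW01")
  ## 250-bp window of the 390-bp reference still identifies it
  expect_equal(assign_mtdna_haplotype(substr(ref390, 50, 299), refs), "HW01")
  ## one mismatch defeats the exact-match policy
  q <- ref250
  substr(q, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, 100, 100))[1]
  expect_equal(assign_mtdna_haplotype(q, refs), "NO_MATCH")
  ## ambiguity is an error
  refs2 <- c(HW01 = ref390, HW03 = paste0(ref390, "AC"))
  expect_error(assign_mtdna_haplotype(ref390, refs2), "multiple")
  expect_error(assign_mtdna_haplotype("ACGT", refs), "200 bp")
})

test_that("FASTA references round-trip through read_haplotypes", {
  set.seed(2)
  seqs <- c(HW01 = paste(sample(c("A", "C", "G", "T"), 390, TRUE), collapse = ""),
            HW02 = paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = ""))
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(rbind(paste0(">", names(seqs)), seqs)), fa)
  got <- read_haplotypes(fa)
  expect_equal(got, seqs)
})

test_that("GenePop and individual-table exports round-trip", {
  set.seed(3)
  cfg <- sim_config(years = 5L, seed = 5L)
  g <- simulate_recolonization(cfg)$genotypes
  g <- subset_genotypes(g, seq_len(min(12L, nrow(g$A))))
  gp <- tempfile(fileext = ".gen")
  write_genepop(g, gp)
  back <- read_genepop(gp)
  expect_equal(back$A, g$A)
  csv <- tempfile(fileext = ".csv")
  write_individual_table(g, csv)
  back2 <- read_individual_table(csv)
  expect_equal(back2$A, g$A)
  expect_equal(back2$sex, g$sex)
})
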