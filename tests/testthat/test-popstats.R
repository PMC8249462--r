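test_that("allele frequencies count gene copies", {
  g <- gt_fix(list(i1 = list(L1 = c(100, 100)), i2 = list(L1 = c(100, 102))))
  fr <- allele_frequencies(g)
  expect_equal(unname(fr$L1$freq), c(0.75, 0.25))
  expect_equal(fr$L1$n_genes, 4L)
  ## all-missing locus dropped with warning
  g2 <- gt_fix(list(i1 = list(L1 = c(100, 100), L2 = c(NA, NA)),
                    i2 = list(L1 = c(100, 100), L2 = c(NA, NA))))
  expect_warning(fr2 <- allele_frequencies(g2), "untyped")
  expect_null(fr2$L2)
  expect_equal(unname(fr2$L1$freq), 1)
})

test_that("diversity summary matches hand-evaluated closed forms", {
  ## alleles {A,A,A,B}: He = (4/3)(1 - 0.625) = 0.5, Ho = 0.5, Ne = 1.6
  g <- gt_fix(list(i1 = list(L1 = c(100, 100)), i2 = list(L1 = c(100, 102))))
  ds <- diversity_summary(g, rarefaction_g = 2)
  row <- ds[ds$locus == "L1", ]
  expect_equal(row$He, 0.5)
  expect_equal(row$Ho, 0.5)
  expect_equal(row$Ne, 1.6)
  ## Ar(2) = [1 - C(1,2)/C(4,2)] + [1 - C(3,2)/C(4,2)] = 1.5
  expect_equal(row$Ar, 1.5)
  ## monomorphic degenerate case
  gm <- gt_fix(list(i1 = list(L1 = c(100, 100)), i2 = list(L1 = c(100, 100))))
  dm <- diversity_summary(gm, rarefaction_g = 2)[1, ]
  expect_equal(dm[, c("Na", "Ne", "Ho", "He", "Ar", "PIC")],
               data.frame(Na = 1, Ne = 1, Ho = 0, He = 0, Ar = 1, PIC = 0),
               ignore_attr = TRUE)
  expect_error(diversity_summary(g, rarefaction_g = 1), ">= 2")
})

test_that("diversity summary agrees with independent oracles on tiny data", {
  set.seed(9)
  for (k in 1:20) {
    n <- sample(2:4, 1)
    calls <- lapply(seq_len(n), function(i)
      list(L1 = sort(sample(c(100L, 102L, 104L), 2, TRUE))))
    names(calls) <- paste0("i", seq_len(n))
    g <- gt_fix(calls)
    copies <- c(g$A[, 1, 1], g$A[, 1, 2])
    cnt <- table(copies)
    ds <- diversity_summary(g, rarefaction_g = 2)[1, ]
    ## He: two-draw-without-replacement identity (independent route)
    expect_equal(ds$He, he_two_draw(as.integer(cnt)))
    ## Ar: exhaustive subset enumeration
    expect_equal(ds$Ar, ar_enumerate(copies, 2))
    ## Ho by direct inspection
    expect_equal(ds$Ho, mean(g$A[, 1, 1] != g$A[, 1, 2]))
  }
})

test_that("rarefaction is monotone in g and exact at full size", {
  set.seed(4)
  for (k in 1:10) {
    counts <- as.integer(table(sample(1:5, 20, TRUE)))
    n <- sum(counts)
    ar <- vapply(2:n, function(g) rarefied_richness(counts, g), numeric(1))
    expect_true(all(diff(ar) >= -1e-12))
    expect_equal(ar[length(ar)], length(counts))   # Ar(n) = Na
  }
})

test_that("PID and PIDsib match closed forms and the product rule", {
  g <- gt_fix(list(i1 = list(L1 = c(100, 100), L2 = c(100, 100)),
                   i2 = list(L1 = c(102, 102), L2 = c(102, 102)),
                   i3 = list(L1 = c(100, 102), L2 = c(100, 102)),
                   i4 = list(L1 = c(100, 102), L2 = c(100, 102))))
  ## both loci have p = q = 0.5
  ids <- probability_of_identity(allele_frequencies(g))
  expect_equal(ids$per_locus$PID, rep(0.375, 2))
  expect_equal(ids$per_locus$PIDsib, rep(0.59375, 2))
  expect_equal(ids$PID, 0.375^2)
  expect_equal(ids$PIDsib, 0.59375^2)
})

test_that("PID matches the genotype-enumeration oracle; products shrink", {
  set.seed(5)
  for (k in 1:10) {
    p <- as.vector(stats::rgamma(sample(2:5, 1), 1)); p <- p / sum(p)
    freqs <- list(L1 = list(freq = stats::setNames(p, seq_along(p))))
    pid <- probability_of_identity(structure(freqs, class = "allele_freqs"))
    expect_equal(pid$per_locus$PID, pid_enumerate(p))
    expect_true(pid$per_locus$PID <= pid$per_locus$PIDsib)
    expect_true(pid$per_locus$PIDsib <= 1)
  }
  ## multilocus PID non-increasing as loci are added
  cfg <- sim_config(years = 6L, seed = 21L)
  g <- simulate_recolonization(cfg)$genotypes
  fr <- allele_frequencies(g)
  cum <- 1
  for (l in names(fr)) {
    one <- probability_of_identity(structure(fr[l], class = "allele_freqs"))
    expect_true(one$PID * cum <= cum)
    cum <- cum * one$PID
  }
  all_l <- probability_of_identity(fr)
  expect_equal(all_l$PID, cum)
})

test_that("He estimator is unbiased under known frequencies", {
  set.seed(6)
  p <- c(0.5, 0.3, 0.2)
  target <- 1 - sum(p^2)
  hes <- replicate(300, {
    a <- sample(100 + 2 * (0:2), 2 * 12, TRUE, prob = p)
    A <- array(NA_integer_, dim = c(12, 1, 2),
               dimnames = list(paste0("i", 1:12), "L1", c("a", "b")))
    A[, 1, 1] <- a[1:12]; A[, 1, 2] <- a[13:24]
    diversity_summary(genotype_table(A), rarefaction_g = 2)[1, "He"]
  })
  se <- stats::sd(hes) / sqrt(length(hes))
  expect_lt(abs(mean(hes) - target), 3 * se)
})

test_that("HWE permutation test flags heterozygote deficit, not equilibrium", {
  ## all homozygotes at a 50:50 two-allele locus: extreme deficit
  calls <- c(rep(list(list(L1 = c(100, 100))), 25),
             rep(list(list(L1 = c(102, 102))), 25))
  names(calls) <- paste0("i", 1:50)
  g <- gt_fix(calls)
  res <- hwe_test(g, "L1", n_permutations = 2000L, seed = 1L)
  expect_lt(res$p_value, 0.01)
  ## monomorphic convention
  gm <- gt_fix(stats::setNames(rep(list(list(L1 = c(100, 100))), 6),
                               paste0("i", 1:6)))
  expect_equal(hwe_test(gm, "L1", 1000L, seed = 1L)$p_value, 1.0)
  expect_error(hwe_test(g, "L1", 100L, seed = 1L), "1000")
  ## determinism given seed
  r1 <- hwe_test(g, "L1", 1000L, seed = 3L)
  r2 <- hwe_test(g, "L1", 1000L, seed = 3L)
  expect_identical(r1, r2)
})

test_that("HWE test is calibrated under the null", {
  set.seed(8)
  p <- c(0.4, 0.35, 0.25)
  pvals <- replicate(300, {
    a <- matrix(sample(100 + 2 * (0:2), 2 * 30, TRUE, prob = p), ncol = 2)
    A <- array(NA_integer_, dim = c(30, 1, 2),
               dimnames = list(paste0("i", 1:30), "L1", c("a", "b")))
    A[, 1, ] <- a
    hwe_test(genotype_table(A), "L1", 1000L,
             seed = sample.int(1e6, 1))$p_value
  })
  rate <- mean(pvals < 0.05)
  ## binomial 3-sigma band around the nominal level (conservative test,
  ## discreteness pushes the rate slightly below alpha)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  expect_gt(rate, 0.001)
})
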