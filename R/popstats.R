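## Allele-frequency based diversity and identity statistics.
##
## All per-locus statistics are computed from gene-copy counts (2 per
## complete diploid genotype); multilocus summaries are unweighted means
## over loci (products for the identity probabilities).

#' Allele frequencies per locus
#'
#' Each non-missing diploid genotype contributes two gene copies. Loci with
#' zero typed copies are dropped with a warning.
#'
#' @param g a [genotype_table]
#' @return object of class `allele_freqs`: named list per locus with
#'   `freq` (named numeric, allele -> relative frequency), `count`
#'   (absolute copy counts) and `n_genes`
#' @export
allele_frequencies <- function(g) {
  if (nrow(g$A) < 1L) stop("need at least one genotype")
  out <- list()
  for (l in loci(g)) {
    copies <- c(g$A[, l, 1], g$A[, l, 2])
    copies <- copies[!is.na(copies)]
    if (!length(copies)) {
      warning("locus ", l, " untyped in all individuals; excluded")
      next
    }
    cnt <- table(copies)
    out[[l]] <- list(freq = as.numeric(cnt) / sum(cnt),
                     count = as.integer(cnt),
                     n_genes = as.integer(sum(cnt)))
    names(out[[l]]$freq) <- names(cnt)
    names(out[[l]]$count) <- names(cnt)
  }
  structure(out, class = "allele_freqs")
}

#' Per-locus and mean diversity summary
#'
#' Computes, per locus: observed allele count (Na), effective allele count
#' (Ne = 1/sum(p^2)), observed heterozygosity (Ho), Nei's unbiased expected
#' heterozygosity (He = n/(n-1) * (1 - sum(p^2)) with n the gene-copy
#' count), rarefied allelic richness Ar(g) and polymorphism information
#' content (PIC). The final row holds unweighted means over loci.
#'
#' Ar uses the hypergeometric rarefaction expectation over gene copies,
#' E\[A(g)\] = sum_i (1 - choose(n - n_i, g)/choose(n, g)), so that
#' Ar(n) = Na exactly.
#'
#' @param g a [genotype_table]
#' @param rarefaction_g gene-copy sample size for Ar; default: smallest
#'   per-locus number of typed gene copies
#' @return data.frame with one row per locus plus a `"mean"` row
#' @export
diversity_summary <- function(g, rarefaction_g = NULL) {
  fr <- allele_frequencies(g)
  if (is.null(rarefaction_g))
    rarefaction_g <- min(vapply(fr, `[[`, integer(1), "n_genes"))
  if (rarefaction_g < 2L) stop("rarefaction_g must be >= 2")
  rows <- lapply(names(fr), function(l) {
    p <- fr[[l]]$freq; ni <- fr[[l]]$count; n <- fr[[l]]$n_genes
    if (rarefaction_g > n)
      stop("rarefaction_g exceeds gene copies at locus ", l)
    s2 <- sum(p^2); s4 <- sum(p^4)
    a <- g$A[, l, 1]; b <- g$A[, l, 2]
    typed <- !is.na(a)
    ho <- mean(a[typed] != b[typed])
    he <- if (n > 2L) n / (n - 1) * (1 - s2) else NA_real_
    data.frame(locus = l, Na = length(p), Ne = 1 / s2, Ho = ho, He = he,
               Ar = rarefied_richness(ni, rarefaction_g),
               PIC = 1 - s2 - (s2^2 - s4), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(locus = "mean", Na = mean(tab$Na), Ne = mean(tab$Ne),
                         Ho = mean(tab$Ho), He = mean(tab$He),
                         Ar = mean(tab$Ar), PIC = mean(tab$PIC),
                         stringsAsFactors = FALSE)
  structure(rbind(tab, mean_row), rarefaction_g = rarefaction_g)
}

#' Rarefied allelic richness for one locus
#'
#' @param counts integer vector of allele copy counts
#' @param g standardized gene-copy sample size (2 <= g <= sum(counts))
#' @return expected number of alleles in a sample of `g` gene copies
#' @export
rarefied_richness <- function(counts, g) {
  n <- sum(counts)
  stopifnot(g >= 1L, g <= n)
  ## log-scale binomial ratios; choose(n - ni, g) = 0 when n - ni < g
  terms <- vapply(counts, function(ni) {
    if (n - ni < g) 1 else 1 - exp(lchoose(n - ni, g) - lchoose(n, g))
  }, numeric(1))
  sum(terms)
}

#' Probability of identity for unrelated individuals and for full siblings
#'
#' Per locus, PID = 2*(sum p^2)^2 - sum p^4 and
#' PIDsib = 0.25 + 0.5*sum(p^2) + 0.5*(sum p^2)^2 - 0.25*sum(p^4);
#' multilocus values are products over loci (independence assumption).
#'
#' @param freqs an `allele_freqs` object from [allele_frequencies()]
#' @return list: `per_locus` data.frame and multilocus `PID`, `PIDsib`
#' @export
probability_of_identity <- function(freqs) {
  if (!length(freqs)) stop("empty frequency table")
  rows <- lapply(names(freqs), function(l) {
    p <- freqs[[l]]$freq
    s2 <- sum(p^2); s4 <- sum(p^4)
    data.frame(locus = l, PID = 2 * s2^2 - s4,
               PIDsib = 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(per_locus = tab, PID = prod(tab$PID), PIDsib = prod(tab$PIDsib))
}

#' Hardy-Weinberg equilibrium permutation test for one locus
#'
#' Monte Carlo test that shuffles gene copies among individuals within the
#' locus and compares the heterozygote count of each permuted dataset with
#' the observed count. The two-sided p-value is
#' 2 * min(P(H <= obs), P(H >= obs)) with the add-one permutation
#' estimator, capped at 1. Monomorphic loci return 1 by convention.
#'
#' @param g a [genotype_table]
#' @param locus locus name
#' @param n_permutations at least 1000 (default 10000)
#' @param seed RNG seed (mandatory for reproducibility)
#' @return list with `p_value`, `observed_het`, `n`
#' @export
hwe_test <- function(g, locus, n_permutations = 10000L, seed) {
  stopifnot_scalar(seed, "seed")
  if (n_permutations < 1000L) stop("n_permutations must be >= 1000")
  a <- g$A[, locus, 1]; b <- g$A[, locus, 2]
  typed <- !is.na(a)
  a <- a[typed]; b <- b[typed]
  if (length(a) < 5L) stop("need >= 5 typed individuals at ", locus)
  copies <- c(a, b)
  if (length(unique(copies)) < 2L)
    return(list(p_value = 1.0, observed_het = 0L, n = length(a)))
  obs <- sum(a != b)
  n <- length(a)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_permutations), function(i) {
    s <- sample(copies)
    sum(s[seq_len(n)] != s[n + seq_len(n)])
  }, integer(1))
  p_lo <- (sum(perm <= obs) + 1) / (n_permutations + 1)
  p_hi <- (sum(perm >= obs) + 1) / (n_permutations + 1)
  list(p_value = min(1, 2 * min(p_lo, p_hi)), observed_het = obs, n = n)
}
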