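# Independent oracles and small fixture builders used across the suite.

# Build a genotype_table from a list of per-individual locus calls:
# gt_fix(list(i1 = list(L1 = c(120, 124), L2 = c(100, 100)), ...))
gt_fix <- function(x, sex = "UNKNOWN") {
  lnames <- unique(unlist(lapply(x, names)))
  A <- array(NA_integer_, dim = c(length(x), length(lnames), 2),
             dimnames = list(names(x), lnames, c("a", "b")))
  for (i in names(x)) for (l in names(x[[i]]))
    A[i, l, ] <- as.integer(x[[i]][[l]])
  genotype_table(A, sex = sex)
}

# Replicate-level sample table for a single sample from a list of
# per-replicate locus calls: rep_fix(list(list(L1 = c(120,124)), ...))
rep_fix <- function(reps, sample_id = "S1", dbx6 = 1, dby7 = 0) {
  lnames <- unique(unlist(lapply(reps, names)))
  rows <- lapply(seq_along(reps), function(r) {
    row <- list(sample_id = sample_id, replicate = r,
                dbx6 = dbx6, dby7 = dby7)
    for (l in lnames) {
      v <- reps[[r]][[l]]
      row[[paste0(l, "_a")]] <- if (is.null(v)) NA_integer_ else v[1]
      row[[paste0(l, "_b")]] <- if (is.null(v)) NA_integer_ else v[2]
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

# Monte Carlo gene-dropping kinship oracle: drop unique founder alleles
# through the pedigree and estimate P(IBD) for the given id pairs.
gene_drop_kinship <- function(ped, pairs, n_drops = 1e5) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  a1 <- matrix(0L, n_drops, n); a2 <- matrix(0L, n_drops, n)
  ctr <- 0L
  for (i in seq_len(n)) {     # topological order guaranteed by pedigree()
    if (is.na(si[i])) {
      a1[, i] <- ctr + 1L; a2[, i] <- ctr + 2L; ctr <- ctr + 2L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick, a1[, si[i]], a2[, si[i]])
      pick <- stats::runif(n_drops) < 0.5
      a2[, i] <- ifelse(pick, a1[, di[i]], a2[, di[i]])
    }
  }
  t(vapply(pairs, function(pr) {
    i <- match(pr[1], ped$id); j <- match(pr[2], ped$id)
    ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
           (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
    est <- mean(ibd) / 4
    c(est = est, se = stats::sd(ibd / 4) / sqrt(n_drops))
  }, numeric(2)))
}

# Random valid pedigree of about n individuals for property tests.
random_pedigree <- function(n = 30, n_founders = 8) {
  id <- sprintf("P%02d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:n_founders] <- rep(c("M", "F"), length.out = n_founders)
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    m <- which(sex[1:(i - 1)] == "M"); f <- which(sex[1:(i - 1)] == "F")
    sire[i] <- id[m[sample.int(length(m), 1)]]
    dam[i] <- id[f[sample.int(length(f), 1)]]
  }
  pedigree(id, sire, dam, sex)
}

# Unbiased expected heterozygosity by an independent route: the
# probability that two gene copies drawn without replacement differ.
he_two_draw <- function(counts) {
  n <- sum(counts)
  1 - sum(counts * (counts - 1)) / (n * (n - 1))
}

# Rarefied allelic richness by exhaustive subset enumeration (tiny n).
ar_enumerate <- function(copies, g) {
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(s) length(unique(copies[s]))))
}

# PID by enumeration over all unordered genotypes under HWE.
pid_enumerate <- function(p) {
  al <- seq_along(p)
  tot <- 0
  for (i in al) for (j in al[al >= i]) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    tot <- tot + pg^2
  }
  tot
}
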