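## Multiple-tube consensus genotyping, individual identification, sex and
## mtDNA haplotype assignment for non-invasively collected samples.

#' Consensus genotype for one sample from replicated PCR calls
#'
#' Implements the multiple-tube acceptance rule: a heterozygote allele pair
#' is accepted at a locus if the identical pair was observed in at least
#' `het_min` replicates; a homozygote if observed in at least `hom_min`
#' replicates and no heterozygote was accepted at that locus. Loci failing
#' both rules are missing. Samples with fewer than `min_loci` accepted loci
#' are rejected.
#'
#' @param replicates data.frame of replicate rows for a single sample
#'   (as from [read_sample_table()])
#' @param min_loci minimum accepted loci for the genotype to be accepted
#' @param het_min minimum replicate observations of a heterozygote pair
#' @param hom_min minimum replicate observations of a homozygote
#' @return list with `status` ("OK"/"REJECTED"), `genotype` (2-row matrix,
#'   loci in columns), `n_loci_typed`, `sex`, and `conflicts` (loci where
#'   two distinct heterozygote pairs both reached `het_min`)
#' @export
call_consensus <- function(replicates, min_loci = 10L, het_min = 2L,
                           hom_min = 3L) {
  if (is.null(replicates) || NROW(replicates) == 0L)
    stop("empty replicate set")
  if (het_min < 1L || hom_min < het_min)
    stop("need het_min >= 1 and hom_min >= het_min")
  lc <- locus_columns(replicates)
  geno <- matrix(NA_integer_, nrow = 2, ncol = length(lc),
                 dimnames = list(c("a", "b"), lc))
  conflicts <- character(0)
  for (l in lc) {
    a <- as.integer(replicates[[paste0(l, "_a")]])
    b <- as.integer(replicates[[paste0(l, "_b")]])
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    lo <- pmin(a[ok], b[ok]); hi <- pmax(a[ok], b[ok])
    key <- paste(lo, hi)
    tab <- table(key)
    het <- lo != hi
    het_keys <- names(tab)[names(tab) %in% key[het] & tab >= het_min]
    if (length(het_keys) > 1L) {           # two supported heterozygotes: refuse
      conflicts <- c(conflicts, l)
      next
    }
    if (length(het_keys) == 1L) {
      geno[, l] <- as.integer(strsplit(het_keys, " ")[[1]])
      next
    }
    hom_keys <- names(tab)[names(tab) %in% key[!het] & tab >= hom_min]
    if (length(hom_keys) == 1L)
      geno[, l] <- as.integer(strsplit(hom_keys, " ")[[1]])
    ## >1 supported homozygote cannot happen without a supported het pair
  }
  if (length(conflicts))
    warning("conflicting heterozygotes at: ", paste(conflicts, collapse = ", "))
  n_typed <- sum(!is.na(geno[1, ]))
  list(status = if (n_typed >= min_loci) "OK" else "REJECTED",
       genotype = geno, n_loci_typed = n_typed,
       sex = assign_sex(replicates), conflicts = conflicts)
}

#' Consensus genotypes for a whole sample table
#'
#' @param samples replicate-level sample table ([read_sample_table()])
#' @inheritParams call_consensus
#' @return list: `genotypes` (a [genotype_table] of accepted samples, ids =
#'   sample ids), `rejected` (sample ids), `meta` (per-sample date/lat/lon)
#' @export
consensus_genotypes <- function(samples, min_loci = 10L, het_min = 2L,
                                hom_min = 3L) {
  lc <- locus_columns(samples)
  sids <- unique(samples$sample_id)
  A <- array(NA_integer_, dim = c(length(sids), length(lc), 2),
             dimnames = list(sids, lc, c("a", "b")))
  sex <- character(length(sids)); keep <- logical(length(sids))
  for (i in seq_along(sids)) {
    cc <- call_consensus(samples[samples$sample_id == sids[i], , drop = FALSE],
                         min_loci, het_min, hom_min)
    A[i, , 1] <- cc$genotype["a", ]
    A[i, , 2] <- cc$genotype["b", ]
    sex[i] <- cc$sex
    keep[i] <- cc$status == "OK"
  }
  meta <- samples[!duplicated(samples$sample_id),
                  intersect(c("sample_id", "date", "lat", "lon", "type"),
                            names(samples)), drop = FALSE]
  list(genotypes = genotype_table(A[keep, , , drop = FALSE], sex[keep]),
       rejected = sids[!keep],
       meta = meta[match(sids[keep], meta$sample_id), , drop = FALSE])
}

#' Molecular sex from replicated X/Y marker amplifications
#'
#' Male if the Y-linked marker (DBY7) amplified in at least two replicates;
#' female if the X-linked marker (DBX6) amplified in at least two replicates
#' and DBY7 never amplified; UNKNOWN otherwise (including single-replicate
#' samples and contradictory Y amplification patterns).
#'
#' @param replicates data.frame with logical/0-1 columns `dbx6`, `dby7`
#' @return "M", "F" or "UNKNOWN"
#' @export
assign_sex <- function(replicates) {
  if (!all(c("dbx6", "dby7") %in% names(replicates))) return("UNKNOWN")
  x <- sum(replicates$dbx6 > 0, na.rm = TRUE)
  y <- sum(replicates$dby7 > 0, na.rm = TRUE)
  if (y >= 2L) "M"
  else if (x >= 2L && y == 0L) "F"
  else "UNKNOWN"
}

#' Group consensus genotypes into individuals
#'
#' Transitive (connected-component) grouping of genotypes whose pairwise
#' comparison mismatches at no more than `max_mismatch_loci` of the loci
#' typed in both, requiring at least `min_comparable` comparable loci. A
#' candidate match whose union of alleles at any locus would exceed two
#' distinct alleles (a fabricated third allele) is refused and flagged for
#' review rather than merged.
#'
#' @param g a [genotype_table] of accepted consensus genotypes (ids = samples)
#' @param max_mismatch_loci tolerated mismatching loci per pair (default 1,
#'   absorbing a single dropout-induced error)
#' @param min_comparable minimum loci typed in both genotypes for a
#'   comparison to count (default 8)
#' @return list: `individuals` ([genotype_table] of merged consensus, ids
#'   `IND001`...), `map` (named character, sample id -> individual id),
#'   `n_samples`, `mean_samples`, `fraction_single`, `flagged_pairs`
#' @export
identify_individuals <- function(g, max_mismatch_loci = 1L,
                                 min_comparable = 8L) {
  n <- nrow(g$A)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  flagged <- NULL
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      cmpb <- !is.na(g$A[i, , 1]) & !is.na(g$A[j, , 1])
      if (sum(cmpb) < min_comparable) next
      mm <- g$A[i, cmpb, 1] != g$A[j, cmpb, 1] | g$A[i, cmpb, 2] != g$A[j, cmpb, 2]
      if (sum(mm) > max_mismatch_loci) next
      ## refuse merges that would imply >2 alleles at a mismatching locus
      bad <- FALSE
      for (l in which(cmpb)[mm]) {
        if (length(unique(c(g$A[i, l, ], g$A[j, l, ]))) > 2L) { bad <- TRUE; break }
      }
      if (bad) {
        flagged <- rbind(flagged, data.frame(sample1 = ids(g)[i],
                                             sample2 = ids(g)[j]))
        next
      }
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  L <- length(loci(g))
  A <- array(NA_integer_, dim = c(length(groups), L, 2),
             dimnames = list(sprintf("IND%03d", seq_along(groups)), loci(g),
                             c("a", "b")))
  sex <- character(length(groups)); nsamp <- integer(length(groups))
  map <- character(n)
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    map[idx] <- dimnames(A)[[1]][k]
    nsamp[k] <- length(idx)
    sx <- setdiff(unique(g$sex[idx]), "UNKNOWN")
    sex[k] <- if (length(sx) == 1L) sx else "UNKNOWN"
    for (l in seq_len(L)) {
      calls <- g$A[idx, l, , drop = FALSE]
      ok <- which(!is.na(calls[, 1, 1]))
      if (!length(ok)) next
      keys <- paste(calls[ok, 1, 1], calls[ok, 1, 2])
      het <- calls[ok, 1, 1] != calls[ok, 1, 2]
      pick <- if (any(het)) names(which.max(table(keys[het])))
              else names(which.max(table(keys)))
      A[k, l, ] <- as.integer(strsplit(pick, " ")[[1]])
    }
  }
  names(map) <- ids(g)
  list(individuals = genotype_table(A, sex, n_samples = nsamp),
       map = map,
       n_samples = stats::setNames(nsamp, dimnames(A)[[1]]),
       mean_samples = mean(nsamp),
       fraction_single = mean(nsamp == 1L),
       flagged_pairs = flagged)
}

#' Assign an mtDNA control-region haplotype by exact matching
#'
#' The query is matched against each reference by exact identity over the
#' overlapping window: a match means the query equals the reference or is
#' a contiguous substring of it (or vice versa), mirroring the two primer
#' systems that yield 250- and 390-bp fragments of the same region.
#'
#' @param query a single DNA string (ACGTN), length >= 200 bp
#' @param refs named character vector of reference haplotype sequences
#' @return the matching haplotype name, or "NO_MATCH"
#' @export
assign_mtdna_haplotype <- function(query, refs) {
  q <- toupper(gsub("[^ACGTN]", "", query))
  q <- gsub("^N+|N+$", "", q)        # trim terminal ambiguities
  if (nchar(q) < 200L) stop("query shorter than 200 bp after trimming")
  refs <- toupper(refs)
  if (anyDuplicated(names(refs))) stop("duplicate reference names")
  hit <- vapply(refs, function(r) {
    grepl(q, r, fixed = TRUE) || grepl(r, q, fixed = TRUE)
  }, logical(1))
  if (sum(hit) > 1L)
    stop("query matches multiple references: ",
         paste(names(refs)[hit], collapse = ", "))
  if (any(hit)) names(refs)[hit] else "NO_MATCH"
}

#' Read reference haplotypes from a FASTA file
#' @param path FASTA file
#' @return named character vector of uppercase sequences
#' @export
read_haplotypes <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  names(seqs) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(seqs))) stop("duplicate haplotype names in FASTA")
  seqs
}
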