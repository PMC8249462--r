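## Genotype container and I/O for multilocus microsatellite data.
##
## A `genotype_table` holds one consensus diploid genotype per row:
## an integer array `A` of dim (n, L, 2) with fragment lengths in bp
## (NA = locus missing), allele pairs stored sorted ascending, plus
## per-individual sex ("M"/"F"/"UNKNOWN") and mtDNA haplotype.

#' Construct a genotype table
#'
#' @param alleles integer array of dim `(n, n_loci, 2)`; `dimnames[[1]]` are
#'   individual ids and `dimnames[[2]]` locus names. Allele pairs are
#'   canonicalized so that the first allele is the smaller. A locus call with
#'   any `NA` is treated as wholly missing.
#' @param sex character vector ("M", "F" or "UNKNOWN"), recycled if length 1
#' @param mtdna character vector of haplotype names (or "UNKNOWN")
#' @param n_samples integer vector, number of samples merged per individual
#' @return an object of class `genotype_table`
#' @export
genotype_table <- function(alleles, sex = "UNKNOWN", mtdna = "UNKNOWN",
                           n_samples = 1L) {
  stopifnot(length(dim(alleles)) == 3L, dim(alleles)[3] == 2L)
  n <- dim(alleles)[1]
  if (is.null(dimnames(alleles)[[1]]))
    dimnames(alleles)[[1]] <- sprintf("IND%03d", seq_len(n))
  if (is.null(dimnames(alleles)[[2]]))
    dimnames(alleles)[[2]] <- sprintf("L%02d", seq_len(dim(alleles)[2]))
  ## canonical order, and NA-in-one-slot means the whole call is missing
  a <- pmin(alleles[, , 1, drop = FALSE], alleles[, , 2, drop = FALSE])
  b <- pmax(alleles[, , 1, drop = FALSE], alleles[, , 2, drop = FALSE])
  alleles[, , 1] <- a
  alleles[, , 2] <- b
  miss <- is.na(alleles[, , 1]) | is.na(alleles[, , 2])
  alleles[, , 1][miss] <- NA_integer_
  alleles[, , 2][miss] <- NA_integer_
  obj <- list(
    A = alleles,
    sex = rep_len(as.character(sex), n),
    mtdna = rep_len(as.character(mtdna), n),
    n_samples = rep_len(as.integer(n_samples), n)
  )
  class(obj) <- "genotype_table"
  ## id suffix (m/f) is advisory; marker-based sex wins but disagreement is flagged
  sfx <- substring(ids(obj), nchar(ids(obj)))
  bad <- (sfx == "m" & obj$sex == "F") | (sfx == "f" & obj$sex == "M")
  if (any(bad))
    warning("id suffix disagrees with sex call for: ",
            paste(ids(obj)[bad], collapse = ", "))
  obj
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci\n",
              nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' Individual ids of a genotype table
#' @param g a `genotype_table`
#' @return character vector
#' @export
ids <- function(g) dimnames(g$A)[[1]]

#' Locus names of a genotype table
#' @param g a `genotype_table`
#' @return character vector
#' @export
loci <- function(g) dimnames(g$A)[[2]]

#' Number of loci typed per individual
#' @param g a `genotype_table`
#' @return integer vector
#' @export
n_loci_typed <- function(g) rowSums(!is.na(g$A[, , 1, drop = FALSE]))

#' Subset a genotype table by individual
#' @param g a `genotype_table`
#' @param i index or id vector
#' @return a `genotype_table`
#' @export
subset_genotypes <- function(g, i) {
  genotype_table(g$A[i, , , drop = FALSE], g$sex[match_idx(g, i)],
                 g$mtdna[match_idx(g, i)], g$n_samples[match_idx(g, i)])
}

match_idx <- function(g, i) {
  if (is.character(i)) match(i, ids(g)) else i
}

#' Convert a genotype table to a data frame
#'
#' One row per individual with columns `individual_id`, `sex`, `haplotype`,
#' `n_samples`, `n_loci_typed` and two columns per locus (`<locus>_a`,
#' `<locus>_b`).
#'
#' @param x a `genotype_table`
#' @param ... unused
#' @return data.frame
#' @export
as.data.frame.genotype_table <- function(x, ...) {
  out <- data.frame(individual_id = ids(x), sex = x$sex, haplotype = x$mtdna,
                    n_samples = x$n_samples, n_loci_typed = n_loci_typed(x),
                    stringsAsFactors = FALSE)
  for (l in loci(x)) {
    out[[paste0(l, "_a")]] <- x$A[, l, 1]
    out[[paste0(l, "_b")]] <- x$A[, l, 2]
  }
  rownames(out) <- NULL
  out
}

#' Build a genotype table from a data frame
#'
#' Inverse of [as.data.frame.genotype_table()]: expects `individual_id` and
#' `<locus>_a`/`<locus>_b` column pairs; `sex`, `haplotype`, `n_samples`
#' are optional.
#'
#' @param df data.frame
#' @return a `genotype_table`
#' @export
as_genotype_table <- function(df) {
  lc <- locus_columns(df)
  A <- array(NA_integer_, dim = c(nrow(df), length(lc), 2),
             dimnames = list(df$individual_id, lc, c("a", "b")))
  for (l in lc) {
    A[, l, 1] <- as.integer(df[[paste0(l, "_a")]])
    A[, l, 2] <- as.integer(df[[paste0(l, "_b")]])
  }
  genotype_table(A, df$sex %||% "UNKNOWN", df$haplotype %||% "UNKNOWN",
                 df$n_samples %||% 1L)
}

locus_columns <- function(df) {
  fixed <- c("sample_id", "individual_id", "date", "lat", "lon", "type",
             "dbx6", "dby7", "sex", "haplotype", "n_samples", "n_loci_typed",
             "replicate")
  ca <- grep("_a$", setdiff(names(df), fixed), value = TRUE)
  lc <- sub("_a$", "", ca)
  lc[paste0(lc, "_b") %in% names(df)]
}

#' Read / write the individual genotype table
#' @param path CSV file path
#' @return `read_individual_table`: a `genotype_table`
#' @export
read_individual_table <- function(path) {
  as_genotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_individual_table
#' @param g a `genotype_table`
#' @export
write_individual_table <- function(g, path) {
  utils::write.csv(as.data.frame(g), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a replicate-level sample table
#'
#' One row per PCR replicate per sample: `sample_id`, `date`, `lat`, `lon`,
#' `type`, `dbx6`, `dby7` (0/1 amplification flags) and `<locus>_a`/
#' `<locus>_b` fragment lengths (empty = no amplification). Tab- or
#' comma-separated, sniffed from the header line.
#'
#' @param path file path
#' @return data.frame with a `replicate` column numbering rows within sample
#' @export
read_sample_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample table needs a 'sample_id' column")
  if (any(!is.na(df$lat) & (df$lat < -90 | df$lat > 90)) ||
      any(!is.na(df$lon) & (df$lon < -180 | df$lon > 180)))
    stop("coordinates outside WGS84 bounds")
  df$replicate <- stats::ave(seq_len(nrow(df)), df$sample_id, FUN = seq_along)
  df
}

#' Export consensus genotypes in GenePop format
#'
#' Three-digit allele coding, single population block. Fragment lengths
#' above 999 bp cannot be represented and raise an error.
#'
#' @param g a `genotype_table`
#' @param path output file
#' @param title header line
#' @export
write_genepop <- function(g, path, title = "wolfped export") {
  if (any(g$A > 999, na.rm = TRUE)) stop("allele length > 999 bp; 3-digit coding impossible")
  code <- function(x) ifelse(is.na(x), "000", sprintf("%03d", x))
  lines <- c(title, loci(g), "POP")
  for (i in seq_len(nrow(g$A))) {
    gt <- paste0(code(g$A[i, , 1]), code(g$A[i, , 2]), collapse = " ")
    lines <- c(lines, paste0(ids(g)[i], " ,  ", gt))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-population GenePop file written by [write_genepop()]
#' @param path file path
#' @return a `genotype_table`
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  pop <- which(toupper(trimws(lines)) == "POP")[1]
  if (is.na(pop)) stop("no POP line found")
  lnames <- trimws(lines[2:(pop - 1)])
  ## loci may also be comma-separated on one line
  if (length(lnames) == 1L && grepl(",", lnames))
    lnames <- trimws(strsplit(lnames, ",")[[1]])
  body <- lines[(pop + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  A <- array(NA_integer_, dim = c(n, length(lnames), 2),
             dimnames = list(NULL, lnames, c("a", "b")))
  id <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(body[i], ",")[[1]]
    id[i] <- trimws(parts[1])
    gts <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    a <- as.integer(substr(gts, 1, 3))
    b <- as.integer(substr(gts, 4, 6))
    a[a == 0L] <- NA_integer_
    b[b == 0L] <- NA_integer_
    A[i, , 1] <- a
    A[i, , 2] <- b
  }
  dimnames(A)[[1]] <- id
  genotype_table(A)
}
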