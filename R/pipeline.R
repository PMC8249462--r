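## Pipeline orchestration: consensus -> identification -> statistics
## (-> parentage when monitoring candidate pairs are supplied).

#' Pipeline configuration
#'
#' @param min_loci,het_min,hom_min consensus thresholds
#'   (see [call_consensus()])
#' @param max_mismatch_loci,min_comparable identification thresholds
#'   (see [identify_individuals()])
#' @param max_mendelian_mismatches parentage tolerance
#'   (see [assign_parentage()])
#' @param fp_threshold elevated-inbreeding threshold for summaries
#' @param seed RNG seed recorded in every output
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(min_loci = 10L, het_min = 2L, hom_min = 3L,
                            max_mismatch_loci = 1L, min_comparable = 8L,
                            max_mendelian_mismatches = 1L,
                            fp_threshold = 0.156, seed = 1L) {
  stopifnot(min_loci >= 1L, het_min >= 1L, hom_min >= het_min,
            max_mismatch_loci >= 0L, max_mendelian_mismatches >= 0L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the monitoring pipeline on a replicate-level sample table
#'
#' Stages: multiple-tube consensus genotyping, individual identification,
#' sex summary, allele-frequency diversity and identity statistics, and
#' (when `candidates` is given) Mendelian-exclusion parentage for every
#' identified individual. Deterministic for a fixed config seed.
#'
#' @param samples replicate-level sample table ([read_sample_table()])
#' @param config a [pipeline_config]
#' @param candidates optional breeding-pair table whose `male`/`female`
#'   ids refer to individuals identified in this run or supplied in
#'   `known_genotypes`
#' @param known_genotypes optional [genotype_table] of reference
#'   (parental) genotypes for the parentage stage
#' @param out_dir optional directory: writes individual table, diversity
#'   and summary CSVs, each stamped with the config hash and seed
#' @return list: `consensus`, `identification`, `individuals`
#'   ([genotype_table]), `diversity`, `identity`, `parentage`, `summary`
#' @export
run_pipeline <- function(samples, config = pipeline_config(),
                         candidates = NULL, known_genotypes = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  log_stage <- function(stage, n)
    message(sprintf("[%s] %s: %d records (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                    stage, n, as.numeric(Sys.time() - t0, units = "secs")))
  cons <- consensus_genotypes(samples, config$min_loci, config$het_min,
                              config$hom_min)
  log_stage("consensus", nrow(cons$genotypes$A))
  idn <- identify_individuals(cons$genotypes, config$max_mismatch_loci,
                              config$min_comparable)
  log_stage("identify", nrow(idn$individuals$A))
  g <- idn$individuals
  div <- diversity_summary(g)
  idstat <- probability_of_identity(allele_frequencies(g))
  parentage <- NULL
  if (!is.null(candidates)) {
    ref <- known_genotypes %||% g
    parentage <- lapply(ids(g), function(i)
      assign_parentage(i, candidates, ref,
                       max_mendelian_mismatches = config$max_mendelian_mismatches))
    names(parentage) <- ids(g)
    log_stage("parentage", length(parentage))
  }
  summary <- list(
    n_samples_accepted = nrow(cons$genotypes$A),
    n_samples_rejected = length(cons$rejected),
    n_individuals = nrow(g$A),
    mean_samples_per_individual = idn$mean_samples,
    fraction_single_capture = idn$fraction_single,
    sex_counts = table(g$sex),
    PID = idstat$PID, PIDsib = idstat$PIDsib,
    seed = config$seed)
  out <- list(consensus = cons, identification = idn, individuals = g,
              diversity = div, identity = idstat, parentage = parentage,
              summary = summary, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("# wolfped config_hash=%s seed=%d",
                     config_hash(config), config$seed)
    wr <- function(df, file) {
      p <- file.path(out_dir, file)
      writeLines(stamp, p)
      suppressWarnings(utils::write.table(df, p, append = TRUE, sep = ",",
                                          row.names = FALSE, na = ""))
    }
    wr(as.data.frame(g), "individuals.csv")
    wr(div, "diversity.csv")
    wr(idstat$per_locus, "identity.csv")
  }
  out
}

## order-stable hash of the configuration (no external digest dependency)
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 15), collapse = ";"), character(1)),
    collapse = "|", sep = "=")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}
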