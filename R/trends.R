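## Yearly breeder-cohort series, Mann-Kendall/Sen trend tests and the
## exponential growth fit for breeding-pair counts.

#' Yearly series of a breeder-cohort statistic
#'
#' The cohort of a monitoring year is the set of pairs (or breeders)
#' reproducing in that year. Supported statistics: `breeding_pair_count`,
#' `mean_Fp` (mean over that year's litters), `unknown_origin_freq`
#' (fraction of genotyped breeders without a known natal pack),
#' `haplotype_freq` (fraction of breeders carrying `haplotype`), and the
#' genotype-based `Na`, `Ho`, `He`, `Ar` (require `genotypes`).
#'
#' @param pairs breeding-pair table (`male`, `female`, `first_year`,
#'   `last_year`)
#' @param ped a [pedigree] (for Fp and natal-pack information)
#' @param statistic one of the names above
#' @param years year range (default 2005:2015)
#' @param genotypes optional [genotype_table] of breeders for the
#'   genotype-based statistics and `haplotype_freq`
#' @param haplotype haplotype name for `haplotype_freq`
#' @return object of class `yearly_series`: data.frame `year`, `value`
#'   with a `label` attribute; empty cohort years are `NA`
#' @export
yearly_series <- function(pairs, ped, statistic = "breeding_pair_count",
                          years = 2005:2015, genotypes = NULL,
                          haplotype = NULL) {
  K <- if (statistic == "mean_Fp") kinship_matrix(ped) else NULL
  np <- stats::setNames(ped$natal_pack, ped$id)
  val <- vapply(years, function(y) {
    act <- pairs$first_year <= y & pairs$last_year >= y
    if (!any(act)) return(NA_real_)
    py <- pairs[act, , drop = FALSE]
    breeders <- unique(c(py$male, py$female))
    breeders <- breeders[grepl("^GW", breeders)]
    switch(statistic,
      breeding_pair_count = sum(act),
      mean_Fp = mean(mapply(function(m, f)
        if (all(c(m, f) %in% rownames(K))) K[m, f] else 0,
        py$male, py$female)),
      unknown_origin_freq = mean(is.na(np[breeders])),
      haplotype_freq = {
        stopifnot(!is.null(genotypes), !is.null(haplotype))
        hp <- genotypes$mtdna[match(breeders, ids(genotypes))]
        mean(hp == haplotype, na.rm = TRUE)
      },
      Na = , Ho = , He = , Ar = {
        stopifnot(!is.null(genotypes))
        gb <- subset_genotypes(genotypes,
                               intersect(breeders, ids(genotypes)))
        ds <- diversity_summary(gb)
        ds[[statistic]][ds$locus == "mean"]
      },
      stop("unknown statistic: ", statistic))
  }, numeric(1))
  structure(data.frame(year = years, value = val),
            label = statistic, class = c("yearly_series", "data.frame"))
}

#' Mann-Kendall trend test with Sen's slope
#'
#' S = sum over pairs of sign(x_j - x_i); the variance uses the standard
#' tie correction, the Z statistic the +/-1 continuity correction, and the
#' two-sided p the normal approximation. Sen's slope is the median of all
#' pairwise slopes (x_j - x_i)/(t_j - t_i). Missing values are dropped.
#'
#' @param series a `yearly_series`, or a numeric vector (time = index)
#' @param time optional time vector when `series` is numeric
#' @return list with `S`, `var_S`, `Z`, `p_value`, `tau`, `sen_slope`, `n`
#' @export
trend_test <- function(series, time = NULL) {
  if (inherits(series, "yearly_series")) {
    time <- series$year; x <- series$value
  } else x <- series
  if (is.null(time)) time <- seq_along(x)
  ok <- !is.na(x)
  x <- x[ok]; time <- time[ok]
  n <- length(x)
  if (n < 2L) stop("need >= 2 non-missing points")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dt <- time[ij[2, ]] - time[ij[1, ]]
  S <- sum(sign(dx))
  ties <- table(x)
  var_S <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  Z <- if (var_S == 0) 0
       else if (S > 0) (S - 1) / sqrt(var_S)
       else if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- if (var_S == 0) 1
       else if (n >= 3L) min(1, 2 * stats::pnorm(-abs(Z))) else NA_real_
  list(S = S, var_S = var_S, Z = Z, p_value = p,
       tau = S / (n * (n - 1) / 2),
       sen_slope = stats::median(dx / dt), n = n)
}

#' Exponential growth fit for yearly counts
#'
#' Fits N(t) = N0 * exp(r t) by nonlinear least squares on the counts
#' (t = years since the first year), seeded by the log-linear OLS
#' estimate, which is also reported for comparison. Annual growth rate is
#' exp(r) - 1.
#'
#' @param series a `yearly_series` of positive counts, or numeric vector
#' @param time optional time vector when `series` is numeric
#' @return list with `N0`, `r`, `annual_growth`, `rss`, `r_loglinear`,
#'   `annual_growth_loglinear`
#' @export
growth_fit <- function(series, time = NULL) {
  if (inherits(series, "yearly_series")) {
    time <- series$year; x <- series$value
  } else x <- series
  if (is.null(time)) time <- seq_along(x)
  ok <- !is.na(x)
  x <- x[ok]; time <- time[ok]
  if (length(x) < 3L) stop("need >= 3 counts")
  if (any(x <= 0)) stop("non-positive counts; exclude or offset before fitting")
  t <- time - time[1]
  ols <- stats::lm(log(x) ~ t)
  r0 <- unname(stats::coef(ols)[2]); n0 <- exp(unname(stats::coef(ols)[1]))
  ## zero-residual (noiseless) inputs make the nls gradient singular;
  ## the log-linear solution is already exact there
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(x ~ N0 * exp(r * t), start = list(N0 = n0, r = r0),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    N0 <- n0; r <- r0
    rss <- sum((x - N0 * exp(r * t))^2)
  } else {
    cf <- stats::coef(fit)
    N0 <- unname(cf["N0"]); r <- unname(cf["r"])
    rss <- sum(stats::resid(fit)^2)
  }
  list(N0 = N0, r = r, annual_growth = exp(r) - 1, rss = rss,
       r_loglinear = r0, annual_growth_loglinear = exp(r0) - 1)
}
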