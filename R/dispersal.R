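## Dispersal distances and sex-biased dispersal tests.

#' Geodesic distance on the WGS84 ellipsoid (Vincenty inverse)
#'
#' Vectorized Vincenty inverse solution with WGS84 parameters
#' (a = 6378137 m, f = 1/298.257223563). Returns kilometres. Nearly
#' antipodal pairs that fail to converge return `NA` with a warning.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees
#' @return distance in km
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  a <- 6378137; f <- 1 / 298.257223563; b <- a * (1 - f)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (lat1[i] == lat2[i] && lon1[i] == lon2[i]) { out[i] <- 0; next }
    U1 <- atan((1 - f) * tan(lat1[i] * pi / 180))
    U2 <- atan((1 - f) * tan(lat2[i] * pi / 180))
    L <- (lon2[i] - lon1[i]) * pi / 180
    sU1 <- sin(U1); cU1 <- cos(U1); sU2 <- sin(U2); cU2 <- cos(U2)
    lam <- L; conv <- FALSE
    for (it in 1:200) {
      sl <- sin(lam); cl <- cos(lam)
      sinSig <- sqrt((cU2 * sl)^2 + (cU1 * sU2 - sU1 * cU2 * cl)^2)
      cosSig <- sU1 * sU2 + cU1 * cU2 * cl
      sig <- atan2(sinSig, cosSig)
      sinAlpha <- cU1 * cU2 * sl / sinSig
      cos2Alpha <- 1 - sinAlpha^2
      cos2SigM <- if (cos2Alpha == 0) 0 else cosSig - 2 * sU1 * sU2 / cos2Alpha
      C <- f / 16 * cos2Alpha * (4 + f * (4 - 3 * cos2Alpha))
      lamPrev <- lam
      lam <- L + (1 - C) * f * sinAlpha *
        (sig + C * sinSig * (cos2SigM + C * cosSig * (-1 + 2 * cos2SigM^2)))
      if (abs(lam - lamPrev) < 1e-12) { conv <- TRUE; break }
    }
    if (!conv) { warning("Vincenty failed to converge"); out[i] <- NA; next }
    u2 <- cos2Alpha * (a^2 - b^2) / b^2
    A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
    B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
    dSig <- B * sinSig * (cos2SigM + B / 4 *
      (cosSig * (-1 + 2 * cos2SigM^2) -
       B / 6 * cos2SigM * (-3 + 4 * sinSig^2) * (-3 + 4 * cos2SigM^2)))
    out[i] <- b * A * (sig - dSig) / 1000
  }
  out
}

#' Natal-to-first-breeding dispersal distances
#'
#' One record per breeder with known natal pack, using the centroid of the
#' natal territory and of the territory of the first reproduction
#' (breeders reproducing in several territories contribute only the first).
#'
#' @param breeders data.frame with `id`, `sex`, `natal_pack`, `territory`,
#'   `first_year` (year of that reproduction)
#' @param territories data.frame with `code`, `lat`, `lon`
#' @param include_philopatric keep breeders whose first reproduction was in
#'   the natal territory (distance 0)?
#' @return data.frame: `id`, `sex`, `natal`, `breeding`, `distance_km`,
#'   `philopatric`
#' @export
dispersal_distances <- function(breeders, territories,
                                include_philopatric = TRUE) {
  b <- breeders[!is.na(breeders$natal_pack), , drop = FALSE]
  b <- b[order(b$first_year), , drop = FALSE]
  b <- b[!duplicated(b$id), , drop = FALSE]       # first reproduction only
  idx_n <- match(b$natal_pack, territories$code)
  idx_t <- match(b$territory, territories$code)
  if (anyNA(idx_n) || anyNA(idx_t))
    stop("missing territory centroid for: ",
         paste(unique(c(b$natal_pack[is.na(idx_n)],
                        b$territory[is.na(idx_t)])), collapse = ", "))
  d <- geodesic_distance(territories$lat[idx_n], territories$lon[idx_n],
                         territories$lat[idx_t], territories$lon[idx_t])
  rec <- data.frame(id = b$id, sex = b$sex, natal = b$natal_pack,
                    breeding = b$territory, distance_km = d,
                    philopatric = b$natal_pack == b$territory,
                    stringsAsFactors = FALSE)
  if (!include_philopatric) rec <- rec[!rec$philopatric, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Chi-square test of the breeder sex ratio against parity
#'
#' Goodness of fit against 1:1 without continuity correction;
#' closed form chi2 = (nf - nm)^2 / (nf + nm), df = 1.
#'
#' @param n_females,n_males non-negative counts, not both zero
#' @return list with `statistic`, `df`, `p_value`
#' @export
sex_ratio_test <- function(n_females, n_males) {
  stopifnot(n_females >= 0, n_males >= 0, n_females + n_males > 0)
  chi2 <- (n_females - n_males)^2 / (n_females + n_males)
  list(statistic = chi2, df = 1L, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test for dispersal distances
#'
#' W is the rank sum of the first group minus n1(n1+1)/2 (the Mann-Whitney
#' U of group 1, the convention under which R's `wilcox.test` reports W).
#' Midranks are used for ties; the two-sided p-value uses the normal
#' approximation with tie-corrected variance.
#'
#' @param x,y numeric vectors (group 1 = females by convention)
#' @return list with `W`, `p_value`, `n1`, `n2`
#' @export
distance_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  list(W = W, p_value = min(1, 2 * stats::pnorm(-abs(z))), n1 = n1, n2 = n2)
}

#' Corrected assignment indices (AIc)
#'
#' AI_i is the sum over the individual's typed loci of log10 of the
#' Hardy-Weinberg expected frequency of its genotype (p^2 for a
#' homozygote, 2pq for a heterozygote), with allele frequencies computed
#' from the full analysed sample. AIc centers AI on the overall mean, so
#' AIc sums to zero; negative values mark genotypes unlikely to originate
#' locally (immigrants).
#'
#' @param g a [genotype_table]
#' @param freqs optional external `allele_freqs`; alleles absent from it
#'   are guarded by a 1/(2N) pseudo-frequency
#' @return numeric vector of AIc, one per individual
#' @export
assignment_index <- function(g, freqs = NULL) {
  internal <- is.null(freqs)
  if (internal) freqs <- allele_frequencies(g)
  n <- nrow(g$A)
  AI <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (l in loci(g)) {
      a <- g$A[i, l, 1]; b <- g$A[i, l, 2]
      if (is.na(a) || is.null(freqs[[l]])) next
      pa <- freqs[[l]]$freq[as.character(a)]
      pb <- freqs[[l]]$freq[as.character(b)]
      if (is.na(pa) || is.na(pb)) {
        if (internal) stop("allele missing from internally computed frequencies")
        guard <- 1 / (2 * n)
        if (is.na(pa)) pa <- guard
        if (is.na(pb)) pb <- guard
      }
      s <- s + if (a == b) log10(pa * pb) else log10(2 * pa * pb)
    }
    AI[i] <- s
  }
  AI - mean(AI)
}

#' mAIc permutation test for sex-biased dispersal
#'
#' Compares the mean corrected assignment index between the sexes; under
#' sex-biased dispersal the dispersing sex contains more immigrants and
#' shows the lower mAIc. The statistic is mAIc(F) - mAIc(M); its two-sided
#' p-value comes from random permutations of the sex labels with the
#' add-one estimator (b + 1)/(n + 1).
#'
#' @param g a [genotype_table] with sexes "M"/"F" set
#' @param n_permutations number of label permutations (default 10000)
#' @param seed RNG seed (mandatory)
#' @return list with `mAIc_f`, `mAIc_m`, `statistic`, `p_value`
#' @export
maic_test <- function(g, n_permutations = 10000L, seed) {
  stopifnot_scalar(seed, "seed")
  sex <- g$sex
  keep <- sex %in% c("M", "F")
  if (sum(sex[keep] == "M") < 5L || sum(sex[keep] == "F") < 5L)
    stop("need >= 5 individuals per sex")
  gg <- subset_genotypes(g, which(keep))
  sex <- sex[keep]
  aic <- assignment_index(gg)
  stat <- function(lbl) mean(aic[lbl == "F"]) - mean(aic[lbl == "M"])
  obs <- stat(sex)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_permutations),
                 function(i) stat(sample(sex)), numeric(1))
  p <- (sum(abs(perm) >= abs(obs)) + 1) / (n_permutations + 1)
  list(mAIc_f = mean(aic[sex == "F"]), mAIc_m = mean(aic[sex == "M"]),
       statistic = obs, p_value = p)
}
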