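## Windowed diversity and differentiation statistics.
##
## F_ST follows Hudson (1992) with ratio-of-sums ("ratio of averages")
## aggregation per window; pi and d_xy use unbiased per-site estimators
## divided by window width (default) or by callable-site count; Tajima's
## D follows the 1989 formulas with the standard a1..e2 constants.

## Per-site alternate-allele frequencies for a sample subset.
## Returns p (freq), n (called allele copies).
groupFreqs <- function(gm, samples) {
  j <- match(samples, gm@samples)
  if (anyNA(j)) stop("unknown sample(s): ",
                     paste(samples[is.na(j)], collapse = ", "))
  g <- gm@geno[, j, drop = FALSE]
  called <- !is.na(g)
  n <- 2L * rowSums(called)
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n > 0L, alt / n, NA_real_)
  list(p = p, n = n)
}

#' Per-site Hudson F_ST components
#'
#' Numerator \eqn{(p_a-p_b)^2 - p_a(1-p_a)/(n_a-1) - p_b(1-p_b)/(n_b-1)}
#' and denominator \eqn{p_a(1-p_b) + p_b(1-p_a)}, with n the number of
#' called allele copies. \code{na = nb = Inf} gives the population
#' (infinite-sample) limit, under which a fully sex-differentiated site
#' (p = 0.5 in the heterogametic sex, 1.0 in the homogametic sex)
#' attains F_ST = 0.5.
#'
#' @param pa,pb alternate-allele frequencies in the two groups.
#' @param na,nb called allele copies (Inf for the population limit).
#' @return list with vectors \code{num} and \code{den}.
#' @export
hudsonComponents <- function(pa, pb, na = Inf, nb = Inf) {
  corrA <- ifelse(is.finite(na), pa * (1 - pa) / (na - 1), 0)
  corrB <- ifelse(is.finite(nb), pb * (1 - pb) / (nb - 1), 0)
  list(num = (pa - pb)^2 - corrA - corrB,
       den = pa * (1 - pb) + pb * (1 - pa))
}

#' Hudson's F_ST in windows
#'
#' Per-site Hudson numerator and denominator combined per window as the
#' ratio of sums. A window with zero summed denominator (no
#' between-group variation) is NA.
#'
#' @param gm GenotypeMatrix.
#' @param groupA,groupB disjoint character vectors of sample ids.
#' @param windows window table from \code{makeWindows}.
#' @return \code{windows} with columns n_sites and fst appended.
#' @export
fstWindows <- function(gm, groupA, groupB, windows) {
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  fa <- groupFreqs(gm, groupA)
  fb <- groupFreqs(gm, groupB)
  if (max(fa$n) < 2L || max(fb$n) < 2L)
    stop("each group needs >= 2 called allele copies")
  ok <- fa$n >= 2L & fb$n >= 2L
  hc <- hudsonComponents(fa$p, fb$p, fa$n, fb$n)
  wi <- windowIndex(gm@contig, gm@pos, windows)
  use <- ok & !is.na(wi)
  num <- sumByWindow(hc$num[use], wi[use], nrow(windows))
  den <- sumByWindow(hc$den[use], wi[use], nrow(windows))
  cnt <- sumByWindow(rep(1, sum(use)), wi[use], nrow(windows))
  out <- windows
  out$n_sites <- as.integer(cnt)
  out$fst <- ifelse(den > 0, num / den, NA_real_)
  out
}

sumByWindow <- function(x, idx, nWindows) {
  out <- numeric(nWindows)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Nucleotide diversity (pi) in windows
#'
#' Per-site unbiased heterozygosity (n/(n-1)) * 2p(1-p) summed per
#' window, divided by window width (\code{denominator = "width"}) or by
#' the callable-site count (\code{"sites"}).
#'
#' @param gm GenotypeMatrix.
#' @param group character vector of sample ids.
#' @param windows window table.
#' @param denominator "width" or "sites".
#' @return \code{windows} with columns n_sites and pi appended.
#' @export
piWindows <- function(gm, group, windows, denominator = c("width", "sites")) {
  denominator <- match.arg(denominator)
  f <- groupFreqs(gm, group)
  ok <- f$n >= 2L
  h <- (f$n / (f$n - 1)) * 2 * f$p * (1 - f$p)
  wi <- windowIndex(gm@contig, gm@pos, windows)
  use <- ok & !is.na(wi)
  tot <- sumByWindow(h[use], wi[use], nrow(windows))
  cnt <- sumByWindow(rep(1, sum(use)), wi[use], nrow(windows))
  out <- windows
  out$n_sites <- as.integer(cnt)
  out$pi <- if (denominator == "width") tot / (windows$end - windows$start)
    else ifelse(cnt > 0, tot / cnt, NA_real_)
  out
}

#' Absolute divergence (d_xy) in windows
#'
#' Per-site \eqn{p_a(1-p_b) + p_b(1-p_a)} summed per window, divided per
#' \code{denominator} as in \code{\link{piWindows}}.
#'
#' @inheritParams fstWindows
#' @param denominator "width" or "sites".
#' @return \code{windows} with columns n_sites and dxy appended.
#' @export
dxyWindows <- function(gm, groupA, groupB, windows,
                       denominator = c("width", "sites")) {
  denominator <- match.arg(denominator)
  fa <- groupFreqs(gm, groupA)
  fb <- groupFreqs(gm, groupB)
  ok <- fa$n >= 1L & fb$n >= 1L
  d <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
  wi <- windowIndex(gm@contig, gm@pos, windows)
  use <- ok & !is.na(wi)
  tot <- sumByWindow(d[use], wi[use], nrow(windows))
  cnt <- sumByWindow(rep(1, sum(use)), wi[use], nrow(windows))
  out <- windows
  out$n_sites <- as.integer(cnt)
  out$dxy <- if (denominator == "width") tot / (windows$end - windows$start)
    else ifelse(cnt > 0, tot / cnt, NA_real_)
  out
}

#' Nei-Li net divergence
#'
#' \eqn{d_a = d_{xy} - (\pi_a + \pi_b)/2}.
#'
#' @param dxy,piA,piB finite numeric (vectorized).
#' @return net divergence.
#' @export
netDivergence <- function(dxy, piA, piB) dxy - (piA + piB) / 2

## Tajima (1989) constants for n sampled chromosomes
tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

## D from segregating-site count and mean pairwise differences
tajimaDFromSK <- function(S, k, n) {
  if (S < 3) return(NA_real_)
  cst <- tajimaConstants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Tajima's D in windows
#'
#' Computed per window from the number of segregating sites S within the
#' group and the mean number of pairwise differences (the unbiased
#' per-site heterozygosity summed over sites). Windows with S < 3 are
#' NA. Sites with any missing call in the group are excluded so that n
#' is constant within a window.
#'
#' @param gm GenotypeMatrix.
#' @param group character vector of sample ids (>= 2 diploids).
#' @param windows window table.
#' @return \code{windows} with columns n_snps and tajima_d appended.
#' @export
tajimasDWindows <- function(gm, group, windows) {
  j <- match(group, gm@samples)
  if (anyNA(j)) stop("unknown sample(s)")
  n <- 2L * length(j)
  if (n < 4L) stop("group needs >= 4 allele copies")
  g <- gm@geno[, j, drop = FALSE]
  full <- rowSums(is.na(g)) == 0L
  alt <- rowSums(g)
  seg <- full & alt > 0L & alt < n
  p <- alt / n
  h <- (n / (n - 1)) * 2 * p * (1 - p)
  wi <- windowIndex(gm@contig, gm@pos, windows)
  use <- seg & !is.na(wi)
  S <- sumByWindow(rep(1, sum(use)), wi[use], nrow(windows))
  K <- sumByWindow(h[use], wi[use], nrow(windows))
  out <- windows
  out$n_snps <- as.integer(S)
  out$tajima_d <- vapply(seq_len(nrow(windows)), function(w)
    tajimaDFromSK(S[w], K[w], n), numeric(1))
  out
}

#' Welch's two-sample t test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value; a thin wrapper around \code{t.test}.
#'
#' @param a,b numeric vectors (>= 2 finite values each).
#' @return list(t, df, p).
#' @export
welchTest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each vector needs >= 2 finite values")
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Combined window statistics table
#'
#' One pass over a cohort: Hudson F_ST between two groups, pi per group,
#' pi_diff, d_xy, d_a and Tajima's D per group, in the column layout
#' used by the pipeline TSV output.
#'
#' @param gm GenotypeMatrix.
#' @param groupA,groupB sample id vectors (e.g. males and females, or
#'   two populations).
#' @param windows window table.
#' @param denominator "width" or "sites" for pi/d_xy.
#' @return data.frame: contig, start, end, n_sites, fst, pi_a, pi_b,
#'   pi_diff, dxy, da, tajd_a, tajd_b.
#' @export
windowStats <- function(gm, groupA, groupB, windows,
                        denominator = "width") {
  fst <- fstWindows(gm, groupA, groupB, windows)
  pa <- piWindows(gm, groupA, windows, denominator)
  pb <- piWindows(gm, groupB, windows, denominator)
  dxy <- dxyWindows(gm, groupA, groupB, windows, denominator)
  ta <- if (2L * length(groupA) >= 4L)
    tajimasDWindows(gm, groupA, windows)$tajima_d else NA_real_
  tb <- if (2L * length(groupB) >= 4L)
    tajimasDWindows(gm, groupB, windows)$tajima_d else NA_real_
  data.frame(contig = windows$contig, start = windows$start,
             end = windows$end, n_sites = fst$n_sites, fst = fst$fst,
             pi_a = pa$pi, pi_b = pb$pi, pi_diff = pa$pi - pb$pi,
             dxy = dxy$dxy, da = netDivergence(dxy$dxy, pa$pi, pb$pi),
             tajd_a = ta, tajd_b = tb, stringsAsFactors = FALSE)
}

#' Genome-wide summaries of window statistics
#'
#' Both aggregation conventions, labeled: the mean of window values and
#' the pooled (ratio-of-sums over all sites) value for F_ST.
#'
#' @param gm GenotypeMatrix.
#' @param groupA,groupB sample id vectors.
#' @param windows window table.
#' @return list(fst_mean_windows, fst_pooled, pi_a, pi_b, dxy, da).
#' @export
genomeWideStats <- function(gm, groupA, groupB, windows) {
  ws <- windowStats(gm, groupA, groupB, windows)
  fa <- groupFreqs(gm, groupA)
  fb <- groupFreqs(gm, groupB)
  ok <- fa$n >= 2L & fb$n >= 2L
  hc <- hudsonComponents(fa$p[ok], fb$p[ok], fa$n[ok], fb$n[ok])
  list(fst_mean_windows = mean(ws$fst, na.rm = TRUE),
       fst_pooled = sum(hc$num) / sum(hc$den),
       pi_a = mean(ws$pi_a, na.rm = TRUE),
       pi_b = mean(ws$pi_b, na.rm = TRUE),
       dxy = mean(ws$dxy, na.rm = TRUE),
       da = mean(ws$da, na.rm = TRUE))
}
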