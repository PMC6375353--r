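## Genotype-pattern evidence for a sex chromosome: XY-patterned sites,
## per-individual and windowed normalized F_IS, F_IS-F_ST correlation,
## PCA, Ajk relatedness.

#' Detect sex-patterned (XY or ZW) sites
#'
#' XY pattern: every called female homozygous (0 or 2), every called
#' male heterozygous (1) - the genotype signature of fixed X/Y
#' differentiation. ZW is the sex-swapped mirror. In strict mode
#' (default) a site with any missing call in either sex is excluded; in
#' lenient mode a site is evaluated on called samples only, requiring at
#' least \code{minCalled} per sex.
#'
#' @param gm GenotypeMatrix.
#' @param males,females character vectors of sample ids.
#' @param pattern "XY" or "ZW".
#' @param strict drop sites with any missing call (default TRUE).
#' @param minCalled minimum called samples per sex in lenient mode.
#' @return list: \code{sites} (data.frame contig/pos of passing sites),
#'   \code{pattern}, and \code{perContig} (data.frame contig, n_xy,
#'   n_total, normalized = n_xy/n_total).
#' @export
detectSexPatternedSites <- function(gm, males, females,
                                    pattern = c("XY", "ZW"),
                                    strict = TRUE, minCalled = 1L) {
  pattern <- match.arg(pattern)
  if (!length(males) || !length(females))
    stop("need at least one male and one female")
  het <- if (pattern == "XY") males else females
  hom <- if (pattern == "XY") females else males
  gHet <- gm@geno[, match(het, gm@samples), drop = FALSE]
  gHom <- gm@geno[, match(hom, gm@samples), drop = FALSE]
  if (anyNA(match(c(het, hom), gm@samples))) stop("unknown sample(s)")
  naHet <- rowSums(is.na(gHet))
  naHom <- rowSums(is.na(gHom))
  allHet <- rowSums(gHet == 1L, na.rm = TRUE) == ncol(gHet) - naHet
  allHom <- rowSums(gHom != 1L, na.rm = TRUE) == ncol(gHom) - naHom
  if (strict) {
    pass <- naHet == 0L & naHom == 0L & allHet & allHom
  } else {
    pass <- (ncol(gHet) - naHet) >= minCalled &
      (ncol(gHom) - naHom) >= minCalled &
      (ncol(gHet) - naHet) > 0L & (ncol(gHom) - naHom) > 0L &
      allHet & allHom
  }
  sites <- data.frame(contig = gm@contig[pass], pos = gm@pos[pass],
                      stringsAsFactors = FALSE)
  tot <- table(factor(gm@contig, levels = unique(gm@contig)))
  nxy <- table(factor(sites$contig, levels = unique(gm@contig)))
  perContig <- data.frame(contig = names(tot),
                          n_sites = as.integer(nxy),
                          n_total = as.integer(tot),
                          normalized = as.integer(nxy) / as.integer(tot),
                          stringsAsFactors = FALSE)
  list(sites = sites, pattern = pattern, perContig = perContig)
}

#' Bin sex-patterned sites in windows
#'
#' @param sexSites result of \code{detectSexPatternedSites}.
#' @param windows window table.
#' @return \code{windows} with an \code{n_xy} count column.
#' @export
binSexSites <- function(sexSites, windows) {
  wi <- windowIndex(sexSites$sites$contig, sexSites$sites$pos, windows)
  cnt <- tabulate(wi[!is.na(wi)], nbins = nrow(windows))
  out <- windows
  out$n_xy <- cnt
  out
}

#' Per-individual inbreeding coefficient F_IS
#'
#' Method-of-moments F = (O_hom - E_hom) / (N - E_hom) per individual,
#' over sites polymorphic within the population subset. E_hom sums
#' 1 - 2p(1-p) * 2n/(2n-1) across the individual's called sites, with p
#' the subset allele frequency and n the per-site count of called
#' diploids in the subset (the conventional small-sample correction).
#'
#' @param gm GenotypeMatrix.
#' @param subset sample ids of the population the frequencies are
#'   estimated in (>= 2 individuals); F is reported for each of them.
#' @param sites optional logical/integer site selector.
#' @return data.frame: sample, o_hom, e_hom, n_sites, fis.
#' @export
individualFis <- function(gm, subset, sites = NULL) {
  if (length(subset) < 2L) stop("subset needs >= 2 individuals")
  if (!is.null(sites)) gm <- gm[sites, ]
  j <- match(subset, gm@samples)
  if (anyNA(j)) stop("unknown sample(s)")
  g <- gm@geno[, j, drop = FALSE]
  called <- !is.na(g)
  nInd <- rowSums(called)              # called diploids per site
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(nInd > 0, alt / (2 * nInd), NA_real_)
  poly <- nInd >= 2L & alt > 0L & alt < 2L * nInd
  eSite <- 1 - 2 * p * (1 - p) * (2 * nInd) / (2 * nInd - 1)
  out <- lapply(seq_along(subset), function(k) {
    use <- poly & called[, k]
    N <- sum(use)
    O <- sum(g[use, k] != 1L)
    E <- sum(eSite[use])
    f <- if (isTRUE(all.equal(N, E))) {
      warning("degenerate F_IS (N == E_hom) for ", subset[k])
      NA_real_
    } else (O - E) / (N - E)
    data.frame(sample = subset[k], o_hom = O, e_hom = E, n_sites = N,
               fis = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Windowed, baseline-normalized F_IS per sex
#'
#' For every window of the focal contig, each individual's F_IS on the
#' window sites minus that individual's genome-wide F_IS excluding the
#' focal contig; the normalized values are then averaged within each
#' sex. On a young XY region males (heterozygote excess) go negative and
#' females positive.
#'
#' @param gm GenotypeMatrix.
#' @param males,females sample ids; together they form the population
#'   subset the allele frequencies are estimated in.
#' @param focalContig contig the windows live on.
#' @param windows window table (rows on other contigs are ignored).
#' @return data.frame: contig, start, end, fis_m, fis_f (NA where a
#'   window has no usable polymorphic site).
#' @export
normalizedFisWindows <- function(gm, males, females, focalContig, windows) {
  if (!focalContig %in% gm@contig) stop("focal contig not present")
  subset <- c(males, females)
  base <- individualFis(gm, subset, sites = gm@contig != focalContig)
  baseF <- base$fis[match(subset, base$sample)]
  win <- windows[windows$contig == focalContig, , drop = FALSE]
  onFocal <- gm@contig == focalContig
  gmF <- gm[onFocal, ]
  wi <- windowIndex(gmF@contig, gmF@pos, win)
  res <- data.frame(contig = win$contig, start = win$start, end = win$end,
                    fis_m = NA_real_, fis_f = NA_real_)
  isM <- subset %in% males
  for (w in seq_len(nrow(win))) {
    sel <- which(wi == w)
    if (!length(sel)) next
    fw <- tryCatch(
      suppressWarnings(individualFis(gmF, subset, sites = sel)$fis),
      error = function(e) rep(NA_real_, length(subset)))
    norm <- fw - baseF
    if (any(is.finite(norm[isM])))
      res$fis_m[w] <- mean(norm[isM], na.rm = TRUE)
    if (any(is.finite(norm[!isM])))
      res$fis_f[w] <- mean(norm[!isM], na.rm = TRUE)
  }
  res
}

#' Correlation between windowed F_IS and male-female F_ST
#'
#' Pearson correlation per sex with a two-sided p-value, over windows
#' where both tracks are finite. On an XY chromosome the heterogametic
#' sex shows a negative correlation.
#'
#' @param fisWin result of \code{normalizedFisWindows}.
#' @param fstWin result of \code{fstWindows} on the same windows
#'   (male vs female).
#' @return data.frame: sex, r, p, n.
#' @export
fisFstCorrelation <- function(fisWin, fstWin) {
  stopifnot(nrow(fisWin) == nrow(fstWin))
  one <- function(fis, sex) {
    ok <- is.finite(fis) & is.finite(fstWin$fst)
    if (sum(ok) < 3L)
      return(data.frame(sex = sex, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    if (sd(fis[ok]) == 0 || sd(fstWin$fst[ok]) == 0)
      return(data.frame(sex = sex, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    ct <- cor.test(fis[ok], fstWin$fst[ok])
    data.frame(sex = sex, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  }
  rbind(one(fisWin$fis_m, "M"), one(fisWin$fis_f, "F"))
}

#' Principal component analysis of genotypes
#'
#' Sites are centered by twice the allele frequency and scaled by
#' sqrt(2p(1-p)) (Patterson normalization); monomorphic sites are
#' dropped and missing values mean-imputed (zero after centering).
#'
#' @param gm GenotypeMatrix.
#' @param dropContigs contigs to exclude before the decomposition.
#' @param nComponents number of components returned.
#' @return list: \code{coords} (samples x components matrix),
#'   \code{explained} (fraction of variance per component).
#' @export
pcaGenotypes <- function(gm, dropContigs = character(0), nComponents = 10L) {
  if (length(gm@samples) < 2L) stop("need >= 2 samples")
  keep <- !(gm@contig %in% dropContigs)
  g <- gm@geno[keep, , drop = FALSE]
  p <- rowMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all sites monomorphic")
  g <- g[poly, , drop = FALSE]
  p <- p[poly]
  z <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  z[is.na(z)] <- 0
  sv <- svd(t(z))
  k <- min(nComponents, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  rownames(coords) <- gm@samples
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, explained = sv$d^2 / sum(sv$d^2))
}

#' Pairwise Ajk relatedness
#'
#' Unadjusted method-of-moments statistic: for j != k, the mean over
#' polymorphic sites with both calls of
#' (g_j - 2p)(g_k - 2p) / (2p(1-p)). The diagonal uses the standard
#' self-relatedness form (g^2 - (1+2p)g + 2p^2) / (2p(1-p)).
#'
#' @param gm GenotypeMatrix.
#' @param sites optional site selector (logical or integer).
#' @return symmetric samples x samples matrix (NA for pairs with no
#'   shared called polymorphic site).
#' @export
ajkRelatedness <- function(gm, sites = NULL) {
  if (length(gm@samples) < 2L) stop("need >= 2 samples")
  if (!is.null(sites)) gm <- gm[sites, ]
  g <- gm@geno
  p <- rowMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[poly, , drop = FALSE]
  p <- p[poly]
  w <- 2 * p * (1 - p)
  z <- (g - 2 * p) / sqrt(w)
  called <- !is.na(z)
  z0 <- z; z0[!called] <- 0
  S <- crossprod(called)               # shared called sites per pair
  A <- crossprod(z0) / S
  A[S == 0L] <- NA_real_
  ## diagonal: self-relatedness form
  gd <- g
  num <- gd^2 - (1 + 2 * p) * gd + 2 * p^2
  diagv <- colSums(num / w, na.rm = TRUE) / colSums(!is.na(gd))
  diag(A) <- diagv
  dimnames(A) <- list(gm@samples, gm@samples)
  A
}
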