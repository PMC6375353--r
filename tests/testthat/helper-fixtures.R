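# Small in-code fixtures shared across test files.

# genotype matrix from a plain integer matrix (sites x samples)
gmFrom <- function(g, contig = "chr1", pos = seq_len(nrow(g)),
                   samples = paste0("s", seq_len(ncol(g)))) {
  GenotypeMatrix(contig, pos, g, samples = samples)
}

# a deterministic toy cohort: 3 males het, 3 females hom at "xy" rows
toySexCohort <- function(nM = 5, nF = 5, nXY = 4, nAuto = 6) {
  g <- rbind(
    matrix(rep(c(rep(1L, nM), rep(0L, nF)), nXY), nrow = nXY, byrow = TRUE),
    matrix(rep(c(rep(0L, nM + nF)), nAuto), nrow = nAuto, byrow = TRUE))
  g[nXY + 1, 1] <- 2L  # one autosomal variant so matrix isn't degenerate
  gm <- gmFrom(g, samples = c(paste0("M", seq_len(nM)),
                              paste0("F", seq_len(nF))))
  list(gm = gm, males = paste0("M", seq_len(nM)),
       females = paste0("F", seq_len(nF)))
}

# brute-force per-site Hudson components (independent of the package path)
bruteHudson <- function(g, ja, jb) {
  num <- den <- 0
  for (i in seq_len(nrow(g))) {
    ga <- g[i, ja]; gb <- g[i, jb]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    na <- 2 * length(ga); nb <- 2 * length(gb)
    if (na < 2 || nb < 2) next
    pa <- sum(ga) / na; pb <- sum(gb) / nb
    num <- num + (pa - pb)^2 - pa * (1 - pa) / (na - 1) -
      pb * (1 - pb) / (nb - 1)
    den <- den + pa * (1 - pb) + pb * (1 - pa)
  }
  c(num = num, den = den)
}

# literal two-pass F_IS oracle (per-site loop, then per-individual loop)
bruteFis <- function(g) {
  nSite <- nrow(g); nInd <- ncol(g)
  res <- data.frame(o = numeric(nInd), e = numeric(nInd), n = numeric(nInd))
  for (k in seq_len(nInd)) {
    O <- 0; E <- 0; N <- 0
    for (i in seq_len(nSite)) {
      gi <- g[i, ]
      called <- !is.na(gi)
      n <- sum(called)
      alt <- sum(gi[called])
      if (n < 2 || alt == 0 || alt == 2 * n) next
      if (is.na(g[i, k])) next
      p <- alt / (2 * n)
      O <- O + (g[i, k] != 1)
      E <- E + (1 - 2 * p * (1 - p) * (2 * n) / (2 * n - 1))
      N <- N + 1
    }
    res$o[k] <- O; res$e[k] <- E; res$n[k] <- N
  }
  res$fis <- (res$o - res$e) / (res$n - res$e)
  res
}

# straight-from-the-1989-formulas Tajima's D (independent reimplementation)
bruteTajimaD <- function(g) {
  n <- 2 * ncol(g)
  alt <- rowSums(g)
  seg <- alt > 0 & alt < n
  S <- sum(seg)
  if (S < 3) return(NA_real_)
  # mean pairwise differences by explicit pairwise haplotype comparison
  haps <- g  # diploid genotypes: expand analytically via allele counts
  k <- 0
  for (i in which(seg)) {
    a <- alt[i]
    k <- k + a * (n - a) / choose(n, 2)
  }
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

smallSimConfig <- function(...) {
  simConfig(contigs = c(sexChr = 4e5, auto1 = 3e5),
            sdRegion = list(contig = "sexChr", start = 1e5, end = 3e5),
            ...)
}
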