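## Window-based quartet topology weighting across four groups.
##
## For each quartet (one sequence per group) the unrooted topology is
## chosen by the four-point condition on Hamming distances over the
## window's variant sites: the smallest of d(AB)+d(CD), d(AC)+d(BD),
## d(AD)+d(BC) selects T1 = (AB|CD), T2 = (AC|BD), T3 = (AD|BC); ties
## are split equally. For quartets and additive distances this is
## equivalent to inferring the quartet tree, which keeps the stage
## dependency-free; it is a deliberate reimplementation at quartet
## scale, not a port of the original subtree-weighting tool.

#' Split unphased genotypes into pseudo-haplotypes
#'
#' Each diploid contributes two pseudo-haplotypes; at heterozygous sites
#' the two alleles are assigned to the haplotypes at random per site
#' (seeded). Phased haplotypes should be supplied directly to
#' \code{\link{windowWeights}} instead.
#'
#' @param gm GenotypeMatrix.
#' @param seed integer seed for the per-site assignments.
#' @return list: \code{mat} (0/1 matrix, sites x 2*samples),
#'   \code{sample} (sample id per haplotype column), plus contig/pos.
#' @export
pseudoHaplotypes <- function(gm, seed = 1L) {
  set.seed(seed)
  g <- gm@geno
  nS <- nrow(g); nI <- ncol(g)
  h1 <- matrix(0L, nS, nI); h2 <- matrix(0L, nS, nI)
  h1[g == 2L] <- 1L; h2[g == 2L] <- 1L
  het <- which(g == 1L)
  flip <- runif(length(het)) < 0.5
  h1[het[flip]] <- 1L
  h2[het[!flip]] <- 1L
  mat <- matrix(0L, nS, 2L * nI)
  mat[, seq(1L, 2L * nI, 2L)] <- h1
  mat[, seq(2L, 2L * nI, 2L)] <- h2
  list(mat = mat, sample = rep(gm@samples, each = 2L),
       contig = gm@contig, pos = gm@pos)
}

#' Quartet topology weights per window
#'
#' @param haps 0/1 haplotype matrix (sites x haplotypes) restricted or
#'   not to a window; with \code{contig}/\code{pos} + \code{window}
#'   given, rows are subset to the window first.
#' @param groups list of four integer/logical column selectors (groups
#'   A, B, C, D), each non-empty.
#' @param contig,pos optional per-row coordinates.
#' @param window optional single-row window (contig, start, end).
#' @param maxExhaustive enumerate all quartets when their number is at
#'   most this (default 10000), else sample.
#' @param nSamples quartets drawn in sampling mode (default 1000).
#' @param seed seed for sampling mode.
#' @return list: \code{w} (numeric length 3: T1 = (AB|CD), T2 = (AC|BD),
#'   T3 = (AD|BC)), \code{nQuartets}, \code{nSites}. Weights are NA when
#'   the window has no variant site.
#' @export
windowWeights <- function(haps, groups, contig = NULL, pos = NULL,
                          window = NULL, maxExhaustive = 10000L,
                          nSamples = 1000L, seed = 1L) {
  if (length(groups) != 4L || any(!lengths(groups)))
    stop("need four non-empty groups")
  if (!is.null(window)) {
    sel <- contig == window$contig & pos - 1L >= window$start &
      pos - 1L < window$end
    haps <- haps[sel, , drop = FALSE]
  }
  nSites <- nrow(haps)
  if (nSites == 0L)
    return(list(w = rep(NA_real_, 3L), nQuartets = 0L, nSites = 0L))
  D <- as.matrix(dist(t(haps), method = "manhattan"))
  gi <- lapply(groups, function(g) seq_len(ncol(haps))[g])
  nQ <- prod(lengths(gi))
  if (nQ <= maxExhaustive) {
    q <- as.matrix(expand.grid(gi[[1]], gi[[2]], gi[[3]], gi[[4]]))
  } else {
    set.seed(seed)
    q <- cbind(sample(gi[[1]], nSamples, TRUE),
               sample(gi[[2]], nSamples, TRUE),
               sample(gi[[3]], nSamples, TRUE),
               sample(gi[[4]], nSamples, TRUE))
    nQ <- nSamples
  }
  s1 <- D[cbind(q[, 1], q[, 2])] + D[cbind(q[, 3], q[, 4])]
  s2 <- D[cbind(q[, 1], q[, 3])] + D[cbind(q[, 2], q[, 4])]
  s3 <- D[cbind(q[, 1], q[, 4])] + D[cbind(q[, 2], q[, 3])]
  m <- pmin(s1, s2, s3)
  t1 <- s1 == m; t2 <- s2 == m; t3 <- s3 == m
  nt <- t1 + t2 + t3
  w <- c(sum(t1 / nt), sum(t2 / nt), sum(t3 / nt)) / nrow(q)
  list(w = w, nQuartets = nrow(q), nSites = nSites)
}

#' Topology weights for every window
#'
#' @param gm GenotypeMatrix (unphased; pseudo-haplotypes are formed) or
#'   a list as returned by \code{pseudoHaplotypes}.
#' @param groupSamples list of four character vectors of sample ids.
#' @param windows window table.
#' @param ... passed to \code{windowWeights}.
#' @param seed seed for pseudo-haplotype assignment and sampling.
#' @return data.frame: contig, start, end, w1, w2, w3, n_quartets,
#'   n_sites.
#' @export
topologyWeightsWindows <- function(gm, groupSamples, windows, seed = 1L,
                                   ...) {
  ph <- if (is(gm, "GenotypeMatrix")) pseudoHaplotypes(gm, seed) else gm
  groups <- lapply(groupSamples, function(s) which(ph$sample %in% s))
  if (any(!lengths(groups))) stop("empty group")
  out <- windows
  out$w1 <- out$w2 <- out$w3 <- NA_real_
  out$n_quartets <- 0L; out$n_sites <- 0L
  for (i in seq_len(nrow(windows))) {
    r <- windowWeights(ph$mat, groups, contig = ph$contig, pos = ph$pos,
                       window = windows[i, ], seed = seed, ...)
    out$w1[i] <- r$w[1]; out$w2[i] <- r$w[2]; out$w3[i] <- r$w[3]
    out$n_quartets[i] <- r$nQuartets; out$n_sites[i] <- r$nSites
  }
  out
}

#' Count windows supporting each topology at support thresholds
#'
#' Threshold semantics: at 1.00 the weight must equal 1 (within 1e-12);
#' at the other thresholds the weight must be strictly greater.
#'
#' @param weights data.frame from \code{topologyWeightsWindows}.
#' @param thresholds numeric (default 1.00, 0.75, 0.66).
#' @return data.frame: topology, threshold, n_windows.
#' @export
summarizeSupport <- function(weights, thresholds = c(1.00, 0.75, 0.66)) {
  out <- expand.grid(topology = c("T1", "T2", "T3"),
                     threshold = thresholds, stringsAsFactors = FALSE)
  out$n_windows <- mapply(function(tp, th) {
    w <- weights[[c(T1 = "w1", T2 = "w2", T3 = "w3")[tp]]]
    w <- w[is.finite(w)]
    if (th >= 1) sum(abs(w - 1) < 1e-12) else sum(w > th)
  }, out$topology, out$threshold)
  out
}
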