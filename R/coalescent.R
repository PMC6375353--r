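## Hudson single-population coalescent without recombination within a
## block, infinite-sites mutations. Time is scaled in units of 4N
## generations, so theta = 4*N*mu*blockLength and the expected number of
## segregating sites for n haplotypes is theta * sum(1/i, i = 1..n-1).

## Simulate the genealogy of n lineages; returns every branch as the set
## of leaves below it plus its length.
coalescentTree <- function(n) {
  sets <- as.list(seq_len(n))
  birth <- rep(0, n)
  t <- 0
  nb <- 2L * n - 2L
  branchSets <- vector("list", nb)
  branchLen <- numeric(nb)
  bi <- 0L
  while (length(sets) > 1L) {
    k <- length(sets)
    t <- t + rexp(1L, k * (k - 1) / 2)
    pr <- sample.int(k, 2L)
    for (ix in pr) {
      bi <- bi + 1L
      branchSets[[bi]] <- sets[[ix]]
      branchLen[bi] <- t - birth[ix]
    }
    merged <- c(sets[[pr[1L]]], sets[[pr[2L]]])
    sets <- c(sets[-pr], list(merged))
    birth <- c(birth[-pr], t)
  }
  list(sets = branchSets, len = branchLen)
}

## Drop infinite-sites mutations on a genealogy: 0/1 haplotype matrix,
## one row per segregating site (unordered; caller assigns positions).
mutateTree <- function(tree, theta) {
  total <- sum(tree$len)
  S <- rpois(1L, theta * total / 2)
  n <- length(unique(unlist(tree$sets)))
  if (S == 0L)
    return(matrix(0L, 0L, n))
  br <- sample.int(length(tree$len), S, replace = TRUE, prob = tree$len)
  haps <- matrix(0L, S, n)
  for (b in unique(br)) {
    rows <- which(br == b)
    haps[rows, tree$sets[[b]]] <- 1L
  }
  haps
}

#' Simulate one neutral coalescent block
#'
#' Standard Hudson coalescent for \code{n} haplotypes without
#' recombination, with infinite-sites mutations at population-scaled rate
#' \code{theta} (per block), assigned uniform distinct integer positions
#' within the block.
#'
#' @param nHaplotypes number of sampled haplotypes (>= 2).
#' @param theta population-scaled mutation rate of the whole block.
#' @param blockLength block length in bp (positions are 1..blockLength).
#' @param seed optional integer seed (set only when non-NULL).
#' @return list with \code{pos} (sorted 1-based positions) and
#'   \code{haps} (0/1 integer matrix, sites x haplotypes).
#' @export
simulateAutosomalBlock <- function(nHaplotypes, theta, blockLength = 10000L,
                                   seed = NULL) {
  if (nHaplotypes < 2L) stop("need at least 2 haplotypes")
  if (theta <= 0) stop("theta must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- coalescentTree(nHaplotypes)
  haps <- mutateTree(tree, theta)
  S <- nrow(haps)
  if (S > blockLength)
    stop("more segregating sites than positions in block")
  pos <- sort(sample.int(blockLength, S))
  list(pos = pos, haps = haps)
}
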