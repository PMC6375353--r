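## Synthetic populations carrying a known, tunable XX-XY region.
##
## The generator emulates the study system the package is built for: one
## outbred population in which males are X/Y heterogametic over a region
## of suppressed recombination on one chromosome (a young Y, diverged on
## the order of 10^-3 substitutions per bp), optionally a second,
## bottlenecked population without its own sex chromosome, Y-specific
## insertion sequences absent from females, and Poisson sequencing depth
## in two alignment-filter dialects where perfect alignments halve male
## coverage over differentiated X segments.

#' Simulation configuration with study-scale defaults
#'
#' Defaults describe the reference scenario used throughout the test
#' suite: a ~20 Mb three-contig genome, 5 males + 5 females, nucleotide
#' diversity ~0.005 (theta = 10 per 2 kb block), a 4 Mb sex-determining
#' region on contig \code{sexChr}, Y divergence tau = 1.5e-3 expected
#' Y-specific mutations per bp (the density a young Y some hundreds of
#' thousands of generations old leaves in a differentiated region),
#' 12 Y-specific insertions of 1.5 kb, and Poisson depth lambda = 20.
#'
#' @param nMales,nFemales diploid counts for population 1.
#' @param nPopulations 1 or 2.
#' @param nMales2,nFemales2 diploid counts for population 2 (bottlenecked).
#' @param contigs named integer vector of contig lengths (bp).
#' @param blockLength non-recombining coalescent block length (bp).
#' @param theta population-scaled mutation rate per block.
#' @param sdRegion list(contig, start, end), 0-based half-open, or NULL.
#' @param tau expected Y-specific derived mutations per bp.
#' @param yInternalTheta diversity among Y copies (per block scale).
#' @param xFounders distinct X haplotype lineages segregating inside the
#'   sd region (NULL to disable): suppressed recombination regions carry
#'   reduced haplotype diversity, which raises homozygosity - and hence
#'   F_IS - of the homogametic sex there.
#' @param yMode "pop1" (only population 1 has the XY system),
#'   "independent" (each population an independently arisen Y),
#'   "shared" (one ancestral Y shared by both populations' males),
#'   or "none".
#' @param founders2 number of founder haplotypes for the bottlenecked
#'   population (drift by resampling few founders).
#' @param splitThetaScale scale of population-private fixed differences
#'   (expected count per block per population = splitThetaScale*theta/2).
#' @param depthLambda mean per-position sequencing depth.
#' @param readLength,fragment read and fragment lengths (bp).
#' @param readCoverage per-individual read-simulation coverage (x).
#' @param yInsertionCount,yInsertionLength Y-specific insertions.
#' @param insertionFlank X-derived flank length around each insertion in
#'   the male-assembly coordinate space.
#' @param sdDifferentiation "variants" (X-specific positions are those
#'   within a read length of an X/Y difference) or "full" (the whole sd
#'   region is treated as X/Y-differentiated).
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(nMales = 5L, nFemales = 5L, nPopulations = 1L,
                      nMales2 = 4L, nFemales2 = 3L,
                      contigs = c(sexChr = 8e6, auto1 = 6e6, auto2 = 6e6),
                      blockLength = 2000L, theta = 10,
                      sdRegion = list(contig = "sexChr",
                                      start = 1e6, end = 5e6),
                      tau = 1.5e-3, yInternalTheta = 1, xFounders = 6L,
                      yMode = c("pop1", "independent", "shared", "none"),
                      founders2 = 4L, splitThetaScale = 0.8,
                      depthLambda = 20, readLength = 150L, fragment = 350L,
                      readCoverage = 15,
                      yInsertionCount = 12L, yInsertionLength = 1500L,
                      insertionFlank = 1000L,
                      sdDifferentiation = c("variants", "full")) {
  yMode <- match.arg(yMode)
  sdDifferentiation <- match.arg(sdDifferentiation)
  if (!is.null(sdRegion)) {
    if (!sdRegion$contig %in% names(contigs))
      stop("sdRegion contig not among contigs")
    if (sdRegion$start < 0 || sdRegion$end > contigs[[sdRegion$contig]])
      stop("sdRegion outside its contig")
  }
  if (tau < 0) stop("tau must be >= 0")
  stopifnot(nMales >= 0, nFemales >= 0, nPopulations %in% c(1L, 2L),
            readLength <= fragment)
  cfg <- list(nMales = nMales, nFemales = nFemales,
              nPopulations = nPopulations,
              nMales2 = nMales2, nFemales2 = nFemales2,
              contigs = contigs, blockLength = as.integer(blockLength),
              theta = theta, sdRegion = sdRegion, tau = tau,
              yInternalTheta = yInternalTheta, xFounders = xFounders,
              yMode = yMode,
              founders2 = founders2, splitThetaScale = splitThetaScale,
              depthLambda = depthLambda, readLength = as.integer(readLength),
              fragment = as.integer(fragment), readCoverage = readCoverage,
              yInsertionCount = as.integer(yInsertionCount),
              yInsertionLength = as.integer(yInsertionLength),
              insertionFlank = as.integer(insertionFlank),
              sdDifferentiation = sdDifferentiation)
  class(cfg) <- "SimConfig"
  cfg
}

## One master seed drives every stage through a fixed splitting scheme, so
## outputs are reproducible stage by stage.
splitSeed <- function(seed, stage) {
  offsets <- c(genotypes = 11L, depth = 23L, reads = 37L, reference = 53L,
               maleassembly = 71L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% 2147483587L
}

#' Sample sheet for a simulated cohort
#'
#' Population 1 samples are \code{P1M*}/\code{P1F*}; population 2 (when
#' present) \code{P2M*}/\code{P2F*}.
#'
#' @param config SimConfig.
#' @return data.frame with sample, sex, population.
#' @export
simSampleSheet <- function(config) {
  sh <- data.frame(
    sample = c(sprintf("P1M%d", seq_len(config$nMales)),
               sprintf("P1F%d", seq_len(config$nFemales))),
    sex = c(rep("M", config$nMales), rep("F", config$nFemales)),
    population = "pop1", stringsAsFactors = FALSE)
  if (config$nPopulations == 2L) {
    sh2 <- data.frame(
      sample = c(sprintf("P2M%d", seq_len(config$nMales2)),
                 sprintf("P2F%d", seq_len(config$nFemales2))),
      sex = c(rep("M", config$nMales2), rep("F", config$nFemales2)),
      population = "pop2", stringsAsFactors = FALSE)
    sh <- rbind(sh, sh2)
  }
  sh
}

## Does [bs, be) (0-based half-open block span) overlap the sd region?
blockSdOverlap <- function(config, contigName, blockStart) {
  sd <- config$sdRegion
  if (is.null(sd) || config$yMode == "none" || sd$contig != contigName)
    return(NULL)
  bs <- blockStart
  be <- blockStart + config$blockLength
  lo <- max(bs, sd$start)
  hi <- min(be, sd$end)
  if (lo >= hi) return(NULL)
  list(lo = lo, hi = hi)   # 0-based half-open, absolute coordinates
}

#' Simulate genotypes, sample sheet and truth for a whole cohort
#'
#' Runs the block coalescent across all contigs, overlays the XY region
#' (a single ancestral Y haplotype carrying shared Y-specific derived
#' mutations plus low internal Y diversity) in the configured mode, adds
#' population-private fixed differences and founder-resampling drift for
#' the bottlenecked second population, and returns the cohort genotypes
#' together with a machine-readable truth record.
#'
#' @param config SimConfig.
#' @param seed integer master seed.
#' @return list with \code{gm} (\linkS4class{GenotypeMatrix}),
#'   \code{sheet} (sample sheet data.frame) and \code{truth} (list:
#'   sdRegion, ySites data.frame, sampleHaplotypes, ...).
#' @export
simulateGenotypes <- function(config, seed) {
  set.seed(splitSeed(seed, "genotypes"))
  sheet <- simSampleSheet(config)
  n1 <- config$nMales + config$nFemales
  n2 <- if (config$nPopulations == 2L) config$nMales2 + config$nFemales2 else 0L
  twoPop <- config$nPopulations == 2L
  nAnc <- 2L * n1 + if (twoPop) config$founders2 else 0L

  ## haplotype column layout for population 1: individual i owns columns
  ## (2i-1, 2i); males come first, their second column is the Y slot
  ## inside the sd region.
  maleYCols <- 2L * seq_len(config$nMales)
  allCols1 <- seq_len(2L * n1)

  perContig <- vector("list", length(config$contigs))
  names(perContig) <- names(config$contigs)
  ySitesAll <- list()

  for (cn in names(config$contigs)) {
    len <- config$contigs[[cn]]
    nBlocks <- ceiling(len / config$blockLength)
    blockOut <- vector("list", nBlocks)
    for (b in seq_len(nBlocks)) {
      bStart <- (b - 1L) * config$blockLength
      bLen <- min(config$blockLength, len - bStart)
      sim <- simulateAutosomalBlock(nAnc, config$theta * bLen /
                                      config$blockLength, bLen)
      hap1 <- sim$haps[, allCols1, drop = FALSE]
      pos <- sim$pos
      usedPos <- pos

      hap2 <- NULL
      if (twoPop) {
        fCols <- 2L * n1 + seq_len(config$founders2)
        pick <- sample(fCols, 2L * n2, replace = TRUE)
        hap2 <- sim$haps[, pick, drop = FALSE]
      }

      ## population-private fixed differences (two-population mode)
      if (twoPop && config$splitThetaScale > 0) {
        for (popi in 1:2) {
          nPriv <- rpois(1L, config$splitThetaScale * config$theta / 2 *
                           bLen / config$blockLength)
          if (nPriv > 0L) {
            avail <- setdiff(seq_len(bLen), usedPos)
            nPriv <- min(nPriv, length(avail))
            pp <- sort(sample(avail, nPriv))
            usedPos <- c(usedPos, pp)
            z1 <- matrix(if (popi == 1L) 1L else 0L, nPriv, ncol(hap1))
            z2 <- matrix(if (popi == 2L) 1L else 0L, nPriv, ncol(hap2))
            hap1 <- rbind(hap1, z1)
            hap2 <- rbind(hap2, z2)
            pos <- c(pos, pp)
          }
        }
      }

      ## XY overlay
      ov <- blockSdOverlap(config, cn, bStart)
      yNew <- integer(0)
      if (!is.null(ov)) {
        ovLen <- ov$hi - ov$lo
        ovLo <- ov$lo - bStart         # 0-based within block
        nCoal <- nrow(sim$haps)        # rows 1..nCoal of hap1 are coalescent
        ovRows <- which(sim$pos > ovLo & sim$pos <= ovLo + ovLen)
        pick1 <- function(x) x[sample.int(length(x), 1L)]
        drawPos <- function(nWanted) {
          avail <- setdiff(seq.int(ovLo + 1L, ovLo + ovLen), usedPos)
          n <- min(nWanted, length(avail))
          if (n == 0L) return(integer(0))
          sort(avail[sample.int(length(avail), n)])
        }
        ## reduced X-haplotype diversity inside the non-recombining
        ## region: the X slots draw from a founder subset of the panel
        xSlots <- setdiff(allCols1, maleYCols)
        if (!is.null(config$xFounders) &&
            config$xFounders < length(xSlots) && length(ovRows)) {
          founders <- xSlots[sample.int(length(xSlots), config$xFounders)]
          draw <- founders[sample.int(length(founders), length(xSlots),
                                      replace = TRUE)]
          hap1[ovRows, xSlots] <- sim$haps[ovRows, draw, drop = FALSE]
          yAnc1 <- pick1(founders)
        } else {
          yAnc1 <- pick1(xSlots)
        }
        ## population-1 Y: one ancestral haplotype from the X pool
        if (length(ovRows))
          hap1[ovRows, maleYCols] <-
            sim$haps[ovRows, rep(yAnc1, length(maleYCols)), drop = FALSE]
        ## Y-specific shared derived mutations
        yPos <- drawPos(rpois(1L, config$tau * ovLen))
        if (length(yPos)) {
          nY <- length(yPos)
          usedPos <- c(usedPos, yPos)
          yRows1 <- matrix(0L, nY, ncol(hap1))
          yRows1[, maleYCols] <- 1L
          hap1 <- rbind(hap1, yRows1)
          if (twoPop) {
            yRows2 <- matrix(0L, nY, ncol(hap2))
            if (config$yMode == "shared" && config$nMales2 >= 1L)
              yRows2[, 2L * seq_len(config$nMales2)] <- 1L
            hap2 <- rbind(hap2, yRows2)
          }
          pos <- c(pos, yPos)
          yNew <- bStart + yPos
        }
        ## shared mode: population-2 males carry the same ancestral Y
        if (twoPop && config$yMode == "shared" && config$nMales2 >= 1L) {
          maleYCols2 <- 2L * seq_len(config$nMales2)
          ovRows2 <- ovRows   # same coalescent rows in hap2
          if (length(ovRows2))
            hap2[ovRows2, maleYCols2] <-
              sim$haps[ovRows2, rep(yAnc1, length(maleYCols2)), drop = FALSE]
        }
        ## internal Y diversity among population-1 Y copies
        if (config$yInternalTheta > 0 && length(maleYCols) >= 2L) {
          yin <- simulateAutosomalBlock(length(maleYCols),
                                        config$yInternalTheta * ovLen /
                                          config$blockLength, bLen)
          keep <- !(yin$pos %in% usedPos) & yin$pos > ovLo &
            yin$pos <= ovLo + ovLen
          if (any(keep)) {
            ipos <- yin$pos[keep]
            usedPos <- c(usedPos, ipos)
            iRows1 <- matrix(0L, sum(keep), ncol(hap1))
            iRows1[, maleYCols] <- yin$haps[keep, , drop = FALSE]
            hap1 <- rbind(hap1, iRows1)
            if (twoPop) hap2 <- rbind(hap2, matrix(0L, sum(keep), ncol(hap2)))
            pos <- c(pos, ipos)
          }
        }
        ## independently arisen Y in population 2
        if (twoPop && config$yMode == "independent" && config$nMales2 >= 1L) {
          maleYCols2 <- 2L * seq_len(config$nMales2)
          yAnc2 <- pick1(setdiff(seq_len(2L * n2), maleYCols2))
          if (length(ovRows))
            hap2[ovRows, maleYCols2] <-
              hap2[ovRows, rep(yAnc2, length(maleYCols2)), drop = FALSE]
          yPos2 <- drawPos(rpois(1L, config$tau * ovLen))
          if (length(yPos2)) {
            usedPos <- c(usedPos, yPos2)
            r1 <- matrix(0L, length(yPos2), ncol(hap1))
            r2 <- matrix(0L, length(yPos2), ncol(hap2))
            r2[, maleYCols2] <- 1L
            hap1 <- rbind(hap1, r1)
            hap2 <- rbind(hap2, r2)
            pos <- c(pos, yPos2)
          }
        }
      }

      ## haplotypes -> diploid genotypes
      ord <- order(pos)
      pos <- pos[ord]
      hap1 <- hap1[ord, , drop = FALSE]
      g1 <- hap1[, seq(1L, 2L * n1, by = 2L), drop = FALSE] +
        hap1[, seq(2L, 2L * n1, by = 2L), drop = FALSE]
      if (twoPop) {
        hap2 <- hap2[ord, , drop = FALSE]
        g2 <- hap2[, seq(1L, 2L * n2, by = 2L), drop = FALSE] +
          hap2[, seq(2L, 2L * n2, by = 2L), drop = FALSE]
        g <- cbind(g1, g2)
      } else g <- g1
      blockOut[[b]] <- list(pos = bStart + pos, g = g,
                            haps = if (twoPop) cbind(hap1, hap2) else hap1)
      if (length(yNew)) ySitesAll[[length(ySitesAll) + 1L]] <-
        data.frame(contig = cn, pos = yNew, stringsAsFactors = FALSE)
    }
    perContig[[cn]] <- blockOut
  }

  cList <- list(); pList <- list(); gList <- list(); hapList <- list()
  for (cn in names(perContig)) {
    for (blk in perContig[[cn]]) {
      if (!length(blk$pos)) next
      k <- length(gList) + 1L
      cList[[k]] <- rep(cn, length(blk$pos))
      pList[[k]] <- blk$pos
      gList[[k]] <- blk$g
      hapList[[k]] <- blk$haps
    }
  }
  contigVec <- unlist(cList, use.names = FALSE)
  posVec <- unlist(pList, use.names = FALSE)
  g <- do.call(rbind, gList)
  haps <- do.call(rbind, hapList)
  ## keep only sites variant somewhere in the cohort (reference = ancestral)
  seg <- rowSums(g) > 0L
  g <- g[seg, , drop = FALSE]
  haps <- haps[seg, , drop = FALSE]
  contigVec <- contigVec[seg]; posVec <- posVec[seg]

  ySites <- if (length(ySitesAll)) do.call(rbind, ySitesAll) else
    data.frame(contig = character(0), pos = integer(0))
  gm <- GenotypeMatrix(contigVec, posVec, g, samples = sheet$sample)
  truth <- list(
    sdRegion = config$sdRegion,
    ySites = ySites,
    sampleHaplotypes = ifelse(sheet$sex == "M" &
                                ((sheet$population == "pop1" &
                                    config$yMode != "none") |
                                 (sheet$population == "pop2" &
                                    config$yMode %in% c("independent", "shared"))),
                              "XY", "XX"),
    yMode = config$yMode, seed = seed)
  list(gm = gm, sheet = sheet, truth = truth,
       haplotypes = list(mat = haps, contig = contigVec, pos = posVec))
}

#' Simulate per-sample depth tracks
#'
#' Depth is Poisson(\code{depthLambda}) per position and sample. Under
#' the \code{perfect} dialect, positions of the sd region that are
#' X/Y-differentiated within a read length carry male depth
#' Poisson(lambda/2) (the Y-derived read half fails the zero-mismatch
#' filter); under \code{all}, male depth is unreduced because Y reads
#' cross-map.
#'
#' @param config SimConfig.
#' @param truth truth list from \code{simulateGenotypes} (used for the
#'   X/Y-difference positions); may be NULL when
#'   \code{config$sdDifferentiation == "full"}.
#' @param dialect "all" or "perfect".
#' @param seed integer seed.
#' @param contigs optional subset of contig names to simulate.
#' @return named list of \linkS4class{DepthTrack}.
#' @export
simulateDepth <- function(config, truth = NULL,
                          dialect = c("all", "perfect"), seed,
                          contigs = names(config$contigs)) {
  dialect <- match.arg(dialect)
  set.seed((splitSeed(seed, "depth") + (dialect == "perfect")) %% 2147483587L)
  sheet <- simSampleSheet(config)
  sheet <- sheet[sheet$population == "pop1", ]
  maleCols <- which(sheet$sex == "M")
  lam <- config$depthLambda
  out <- list()
  for (cn in contigs) {
    len <- as.integer(config$contigs[[cn]])
    d <- matrix(rpois(len * nrow(sheet), lam), nrow = len)
    if (dialect == "perfect" && !is.null(config$sdRegion) &&
        config$sdRegion$contig == cn && config$yMode != "none") {
      flag <- xSpecificPositions(config, truth, cn, len)
      if (any(flag))
        d[flag, maleCols] <- rpois(sum(flag) * length(maleCols), lam / 2)
    }
    out[[cn]] <- DepthTrack(cn, d, samples = sheet$sample, dialect = dialect)
  }
  out
}

## logical vector over positions 1..len: is the position X-specific, i.e.
## does a read covering it span an X/Y difference?
xSpecificPositions <- function(config, truth, contigName, len) {
  sd <- config$sdRegion
  flag <- rep(FALSE, len)
  inSd <- seq_len(len) > sd$start & seq_len(len) <= sd$end
  if (config$sdDifferentiation == "full") return(inSd)
  ys <- truth$ySites
  ys <- ys$pos[ys$contig == contigName]
  if (!length(ys)) return(flag)
  rl <- config$readLength
  ir <- IRanges::reduce(IRanges::IRanges(pmax(ys - rl + 1L, 1L),
                                         pmin(ys + rl - 1L, len)))
  for (i in seq_along(ir))
    flag[IRanges::start(ir)[i]:IRanges::end(ir)[i]] <- TRUE
  flag & inSd
}

#' Simulate the male-assembly coordinate space: Y insertions
#'
#' Each Y-specific insertion is represented as its own male-assembly
#' contig \code{Yins_i}: an X-derived flank, the Y-only insertion, and a
#' second flank. Females have Poisson(lambda) depth on the flanks and
#' zero over the insertion; hemizygous males have Poisson(lambda/2) over
#' the insertion.
#'
#' @param config SimConfig.
#' @param seed integer seed.
#' @return list with \code{tracks} (list of DepthTrack), \code{truth}
#'   (data.frame contig/start/end of each insertion, 0-based half-open),
#'   and \code{sequences} (named character; full contig sequences with
#'   the insertion part recorded separately in \code{insertionSeq}).
#' @export
simulateMaleAssembly <- function(config, seed) {
  set.seed(splitSeed(seed, "maleassembly"))
  sheet <- simSampleSheet(config)
  sheet <- sheet[sheet$population == "pop1", ]
  maleCols <- which(sheet$sex == "M")
  femaleCols <- which(sheet$sex == "F")
  lam <- config$depthLambda
  fl <- config$insertionFlank
  il <- config$yInsertionLength
  tracks <- list(); seqs <- character(0); insSeq <- character(0)
  tr <- data.frame(contig = character(0), start = integer(0),
                   end = integer(0))
  for (i in seq_len(config$yInsertionCount)) {
    cn <- sprintf("Yins_%d", i)
    len <- 2L * fl + il
    d <- matrix(rpois(len * nrow(sheet), lam), nrow = len)
    ins <- seq.int(fl + 1L, fl + il)
    d[ins, femaleCols] <- 0L
    d[ins, maleCols] <- rpois(il * length(maleCols), lam / 2)
    tracks[[cn]] <- DepthTrack(cn, d, samples = sheet$sample,
                               dialect = "all")
    seqs[cn] <- randomDna(len)
    insSeq[cn] <- substr(seqs[cn], fl + 1L, fl + il)
    tr <- rbind(tr, data.frame(contig = cn, start = fl, end = fl + il))
  }
  list(tracks = tracks, truth = tr, sequences = seqs, insertionSeq = insSeq)
}

randomDna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Simulate the female-assembly reference sequences
#'
#' Random uniform DNA per configured contig; the coordinate space all
#' genotype positions refer to.
#'
#' @param config SimConfig.
#' @param seed integer seed.
#' @param contigs optional subset of contig names.
#' @return named character vector of sequences.
#' @export
simulateReference <- function(config, seed, contigs = names(config$contigs)) {
  set.seed(splitSeed(seed, "reference"))
  out <- character(0)
  for (cn in names(config$contigs)) {
    s <- randomDna(as.integer(config$contigs[[cn]]))
    if (cn %in% contigs) out[cn] <- s
  }
  out
}

#' Simulate paired-end reads for every population-1 individual
#'
#' Fragments are sampled uniformly from each individual's two haplotypes
#' of every contig. Males carry one X haplotype (the reference) and one Y
#' haplotype: the reference with Y-specific alleles substituted and the
#' Y insertions inserted inside the sd region. Mate 1 is the fragment
#' 5' end; mate 2 the reverse complement of its 3' end; qualities are
#' constant. Read names carry an origin tag \code{|Yins} when the
#' fragment overlaps Y-insertion sequence; the same pair ids are listed
#' in the returned truth.
#'
#' @param config SimConfig.
#' @param seed integer seed.
#' @param dir output directory for \code{<sample>_1.fastq} /
#'   \code{<sample>_2.fastq}.
#' @param contigs optional subset of contig names (defaults to all; use a
#'   small config for read-level work).
#' @return list with \code{files} (data.frame sample/mate1/mate2) and
#'   \code{truth} (list: yInsertionPairs per sample, insertion records).
#' @export
simulateReads <- function(config, seed, dir, contigs = names(config$contigs)) {
  set.seed(splitSeed(seed, "reads"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- simulateReference(config, seed, contigs)
  sheet <- simSampleSheet(config)
  sheet <- sheet[sheet$population == "pop1", ]
  rl <- config$readLength; fr <- config$fragment
  sd <- config$sdRegion

  ## Build the Y haplotype per contig (males): substitute Y-specific
  ## alleles and insert insertions; track insertion intervals in Y coords.
  yIns <- NULL
  yRefs <- refs
  insIntervals <- list()   # per contig: data.frame start/end in Y coords
  if (!is.null(sd) && config$yMode != "none" &&
      sd$contig %in% names(refs) && config$yInsertionCount > 0L) {
    n <- config$yInsertionCount
    insSeqs <- vapply(seq_len(n), function(i)
      randomDna(config$yInsertionLength), character(1))
    span <- sd$end - sd$start
    at <- sort(sample.int(span - 1L, n)) + sd$start  # 0-based insertion points
    x <- refs[[sd$contig]]
    pieces <- character(0); iv <- NULL
    prev <- 0L; off <- 0L
    for (i in seq_len(n)) {
      pieces <- c(pieces, substr(x, prev + 1L, at[i]), insSeqs[i])
      ys <- at[i] + off          # 0-based start in Y coords
      iv <- rbind(iv, data.frame(start = ys,
                                 end = ys + config$yInsertionLength))
      off <- off + config$yInsertionLength
      prev <- at[i]
    }
    pieces <- c(pieces, substr(x, prev + 1L, nchar(x)))
    yRefs[[sd$contig]] <- paste(pieces, collapse = "")
    insIntervals[[sd$contig]] <- iv
    yIns <- data.frame(xPos = at, seq = insSeqs)
  }

  files <- data.frame(sample = character(0), mate1 = character(0),
                      mate2 = character(0), stringsAsFactors = FALSE)
  yPairs <- list()
  for (si in seq_len(nrow(sheet))) {
    samp <- sheet$sample[si]
    isMale <- sheet$sex[si] == "M"
    r1 <- character(0); r2 <- character(0); nm <- character(0)
    for (cn in contigs) {
      hapSeqs <- list(refs[[cn]], if (isMale) yRefs[[cn]] else refs[[cn]])
      L <- nchar(refs[[cn]])
      nFrag <- ceiling(config$readCoverage * L / (2 * rl))
      for (h in 1:2) {
        hs <- hapSeqs[[h]]
        hl <- nchar(hs)
        nf <- if (h == 1L) ceiling(nFrag / 2) else floor(nFrag / 2)
        if (nf == 0L || hl < fr) next
        st <- sample.int(hl - fr + 1L, nf, replace = TRUE)
        frag <- substring(hs, st, st + fr - 1L)
        strand <- runif(nf) < 0.5
        frag[strand] <- revcomp(frag[strand])
        m1 <- substr(frag, 1L, rl)
        m2 <- revcomp(substring(frag, fr - rl + 1L, fr))
        tag <- rep("", nf)
        if (isMale && h == 2L && !is.null(insIntervals[[cn]])) {
          iv <- insIntervals[[cn]]
          hit <- rep(FALSE, nf)
          for (k in seq_len(nrow(iv)))
            hit <- hit | (st <= iv$end[k] & (st + fr - 1L) > iv$start[k])
          tag[hit] <- "|Yins"
        }
        ids <- sprintf("%s_%s_h%d_%06d%s", samp, cn, h, seq_len(nf), tag)
        r1 <- c(r1, m1); r2 <- c(r2, m2); nm <- c(nm, ids)
      }
    }
    f1 <- file.path(dir, paste0(samp, "_1.fastq"))
    f2 <- file.path(dir, paste0(samp, "_2.fastq"))
    writeFastq(nm, r1, f1)
    writeFastq(nm, r2, f2)
    files <- rbind(files, data.frame(sample = samp, mate1 = f1, mate2 = f2,
                                     stringsAsFactors = FALSE))
    yPairs[[samp]] <- nm[endsWith(nm, "|Yins")]
  }
  list(files = files,
       truth = list(yInsertionPairs = yPairs, insertions = yIns,
                    insertionIntervals = insIntervals))
}

revcomp <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

writeFastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ids))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits VCF 4.2, the sample sheet TSV, depth TSVs in both dialects,
#' reference FASTA and a truth JSON, mirroring the formats a real study
#' would provide.
#'
#' @param sim result of \code{simulateGenotypes}.
#' @param config SimConfig used.
#' @param dir output directory.
#' @param seed master seed (depth tracks are derived from it).
#' @param depthContigs contigs for which depth is written (defaults to
#'   the sd contig only, to keep files small).
#' @return named list of written paths.
#' @export
writeSimulation <- function(sim, config, dir, seed,
                            depthContigs = if (!is.null(config$sdRegion))
                              config$sdRegion$contig else
                              names(config$contigs)[1]) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                sheet = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth.json"))
  writeVcfGenotypes(sim$gm, paths$vcf)
  writeSampleSheet(sim$sheet, paths$sheet)
  for (dl in c("all", "perfect")) {
    tr <- simulateDepth(config, sim$truth, dl, seed, contigs = depthContigs)
    p <- file.path(dir, paste0("depth.", dl, ".depth.tsv"))
    writeDepthTsv(tr, p)
    paths[[paste0("depth_", dl)]] <- p
  }
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  paths
}

#' Haplotype-column groups of a simulated cohort
#'
#' The haplotype matrix returned by \code{simulateGenotypes} stores two
#' columns per individual (population 1 first, males before females;
#' within a male, column 2 is the Y slot inside the sd region). This
#' helper returns named column-index groups for topology-weighting
#' analyses on the true haplotypes: per population, the male Y columns,
#' male X columns and female X columns.
#'
#' @param config SimConfig the cohort was simulated under.
#' @return named list of integer column indices: pop1_maleY, pop1_maleX,
#'   pop1_female (and pop2_* in two-population mode).
#' @export
simHaplotypeGroups <- function(config) {
  n1 <- config$nMales + config$nFemales
  out <- list(
    pop1_maleY = 2L * seq_len(config$nMales),
    pop1_maleX = 2L * seq_len(config$nMales) - 1L,
    pop1_female = 2L * config$nMales + seq_len(2L * config$nFemales))
  if (config$nPopulations == 2L) {
    off <- 2L * n1
    out$pop2_maleY <- off + 2L * seq_len(config$nMales2)
    out$pop2_maleX <- off + 2L * seq_len(config$nMales2) - 1L
    out$pop2_female <- off + 2L * config$nMales2 +
      seq_len(2L * config$nFemales2)
  }
  out
}
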