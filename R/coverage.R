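## Sex-differential sequencing-depth evidence.
##
## Normalization follows the median convention: one grand median per sex
## over all positions and individuals, a per-position per-sex median
## across individuals divided by it, window means of that ratio, log2
## for plotting (log2(0) stays NA: "no coverage" is categorically
## distinct from "low coverage").

#' Median-normalized windowed coverage per sex
#'
#' Steps: (1) sex median M_s over all positions x individuals of sex s
#' (across all supplied tracks); (2) per position, the per-sex median
#' across individuals divided by M_s; (3) window mean of (2); (4) log2
#' of (3), NA at 0.
#'
#' @param tracks named list of \linkS4class{DepthTrack} (one dialect).
#' @param sheet sample sheet; samples of sex M/F present in the tracks
#'   are used.
#' @param windows window table.
#' @return data.frame: contig, start, end, norm_m, norm_f, log2_m,
#'   log2_f, dialect.
#' @export
normalizeAndWindow <- function(tracks, sheet, windows) {
  if (is(tracks, "DepthTrack")) tracks <- setNames(list(tracks),
                                                   tracks@contig)
  samples <- tracks[[1]]@samples
  males <- intersect(sheet$sample[sheet$sex == "M"], samples)
  females <- intersect(sheet$sample[sheet$sex == "F"], samples)
  if (!length(males) || !length(females))
    stop("need >= 1 sample per sex")
  jm <- match(males, samples); jf <- match(females, samples)
  ## grand median per sex via a depth histogram (depths are small
  ## integers; avoids sorting hundreds of millions of values)
  sexMedian <- function(js) {
    counts <- integer(0); nzero <- 0
    for (t in tracks) for (j in js) {
      v <- t@depth[, j]
      nzero <- nzero + sum(v == 0L)
      tb <- tabulate(v)
      if (length(tb) > length(counts))
        counts <- c(counts, integer(length(tb) - length(counts)))
      counts[seq_along(tb)] <- counts[seq_along(tb)] + tb
    }
    n <- nzero + sum(counts)
    cum <- nzero + cumsum(as.numeric(counts))
    lo <- if (nzero >= (n + 1) %/% 2) 0L else
      which(cum >= (n + 1) %/% 2)[1]
    hi <- if (nzero >= n %/% 2 + 1) 0L else
      which(cum >= n %/% 2 + 1)[1]
    (lo + hi) / 2
  }
  Mm <- sexMedian(jm)
  Mf <- sexMedian(jf)
  if (Mm == 0 || Mf == 0) stop("degenerate input: sex median is 0")
  out <- list()
  for (tr in tracks) {
    win <- windows[windows$contig == tr@contig, , drop = FALSE]
    if (!nrow(win)) next
    pm <- matrixStats::rowMedians(tr@depth[, jm, drop = FALSE]) / Mm
    pf <- matrixStats::rowMedians(tr@depth[, jf, drop = FALSE]) / Mf
    pos <- seq_len(nrow(tr@depth))
    wi <- windowIndex(rep(tr@contig, length(pos)), pos, win)
    ok <- !is.na(wi)
    nm <- sumByWindow(pm[ok], wi[ok], nrow(win))
    nf <- sumByWindow(pf[ok], wi[ok], nrow(win))
    cnt <- sumByWindow(rep(1, sum(ok)), wi[ok], nrow(win))
    win$norm_m <- ifelse(cnt > 0, nm / cnt, NA_real_)
    win$norm_f <- ifelse(cnt > 0, nf / cnt, NA_real_)
    win$log2_m <- ifelse(win$norm_m > 0, log2(win$norm_m), NA_real_)
    win$log2_f <- ifelse(win$norm_f > 0, log2(win$norm_f), NA_real_)
    win$dialect <- tr@dialect
    out[[tr@contig]] <- win
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Call male-only-coverage regions
#'
#' A position passes when at least \code{minMalesCovered} males have
#' nonzero depth, the pooled male depth exceeds \code{maleTotalGt}, and
#' the pooled female depth is below \code{femaleTotalLt}. Maximal runs
#' of passing positions of length >= \code{minLen} are emitted as
#' 0-based half-open regions. When the male count differs from five,
#' \code{minMalesCovered} defaults to ceiling(0.8 * n_males).
#'
#' @param track a \linkS4class{DepthTrack} on the male assembly.
#' @param sheet sample sheet.
#' @param minLen minimum region length (bp).
#' @param minMalesCovered males with depth >= 1 required per position.
#' @param maleTotalGt pooled male depth must be strictly greater.
#' @param femaleTotalLt pooled female depth must be strictly smaller.
#' @return data.frame: contig, start, end, length, male_mean_depth,
#'   female_mean_depth.
#' @export
callMaleOnlyRegions <- function(track, sheet, minLen = 1000L,
                                minMalesCovered = NULL,
                                maleTotalGt = 5L, femaleTotalLt = 3L) {
  samples <- track@samples
  jm <- match(intersect(sheet$sample[sheet$sex == "M"], samples), samples)
  jf <- match(intersect(sheet$sample[sheet$sex == "F"], samples), samples)
  if (is.null(minMalesCovered))
    minMalesCovered <- if (length(jm) == 5L) 4L else
      ceiling(0.8 * length(jm))
  dm <- track@depth[, jm, drop = FALSE]
  df <- track@depth[, jf, drop = FALSE]
  pass <- rowSums(dm >= 1L) >= minMalesCovered &
    rowSums(dm) > maleTotalGt &
    rowSums(df) < femaleTotalLt
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= minLen)
  if (!length(sel))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      male_mean_depth = numeric(0),
                      female_mean_depth = numeric(0)))
  out <- data.frame(contig = track@contig,
                    start = starts[sel] - 1L,   # 0-based half-open
                    end = ends[sel],
                    length = r$lengths[sel])
  out$male_mean_depth <- vapply(sel, function(i)
    mean(dm[starts[i]:ends[i], ]), numeric(1))
  out$female_mean_depth <- vapply(sel, function(i)
    mean(df[starts[i]:ends[i], ]), numeric(1))
  out
}

#' Filter candidate Y contigs on coverage profiles
#'
#' Drops a contig if any single male has depth above \code{maxMalePos}
#' at any position (likely an individual-specific repeat), or if the
#' pooled female depth reaches \code{femalePosCut} at any position
#' (present in females, hence not Y-specific). With
#' \code{pooledFemales = FALSE} the female rule applies per individual
#' instead.
#'
#' @param tracks named list of \linkS4class{DepthTrack}, one per contig.
#' @param sheet sample sheet.
#' @param maxMalePos per-male single-position depth cutoff (drop if
#'   strictly above).
#' @param femalePosCut female depth cutoff (drop if >= at any position).
#' @param pooledFemales pool female depth across individuals (default).
#' @return character vector of kept contig ids.
#' @export
filterYContigs <- function(tracks, sheet, maxMalePos = 50L,
                           femalePosCut = 5L, pooledFemales = TRUE) {
  keep <- vapply(tracks, function(tr) {
    samples <- tr@samples
    jm <- match(intersect(sheet$sample[sheet$sex == "M"], samples), samples)
    jf <- match(intersect(sheet$sample[sheet$sex == "F"], samples), samples)
    dm <- tr@depth[, jm, drop = FALSE]
    df <- tr@depth[, jf, drop = FALSE]
    if (length(dm) && max(dm) > maxMalePos) return(FALSE)
    fem <- if (pooledFemales) rowSums(df) else df
    if (length(fem) && max(fem) >= femalePosCut) return(FALSE)
    TRUE
  }, logical(1))
  names(tracks)[keep]
}
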