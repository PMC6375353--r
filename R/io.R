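## Readers/writers for the standard formats the pipeline touches, and the
## windowing primitives shared by every stage.
##
## Coordinate convention: VCF and depth TSVs are 1-based; all windows and
## BED output are 0-based half-open. A site at VCF position P belongs to
## window floor((P - 1) / width).

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file and returns the biallelic records as a
#' \linkS4class{GenotypeMatrix} with alternate-allele-count codes
#' (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA). Multiallelic records are
#' dropped with a message. Indels are retained as single biallelic
#' presence/absence sites.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param sampleSheet optional data.frame with a \code{sample} column; the
#'   returned matrix is restricted to (and ordered as) these samples, and
#'   a sheet sample absent from the VCF is an error.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readVcfGenotypes <- function(path, sampleSheet = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    message("readVcfGenotypes: dropping ", sum(multi), " multiallelic record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (!is.null(sampleSheet)) {
    missing <- setdiff(sampleSheet$sample, samples)
    if (length(missing))
      stop("sample(s) in sheet absent from VCF: ",
           paste(missing, collapse = ", "))
    gt <- gt[, sampleSheet$sample, drop = FALSE]
    samples <- sampleSheet$sample
  }
  code <- gtToCode(gt, contig = fix[, "CHROM"], pos = fix[, "POS"])
  GenotypeMatrix(contig = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]),
                 geno = code, samples = samples,
                 ref = fix[, "REF"], alt = fix[, "ALT"])
}

## GT strings -> 0/1/2/NA codes; errors name the offending record
gtToCode <- function(gt, contig, pos) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- vapply(u, function(s) {
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2L) return(-2L)
    if (any(al == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai) || any(ai > 1L) || any(ai < 0L)) return(-2L)
    sum(ai)
  }, integer(1))
  code <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  bad <- which(!is.na(code) & code == -2L, arr.ind = TRUE)
  if (nrow(bad))
    stop("malformed GT at ", contig[bad[1, 1]], ":", pos[bad[1, 1]])
  code
}

#' Write a GenotypeMatrix as a minimal VCF 4.2 file
#'
#' @param gm GenotypeMatrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVcfGenotypes <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm@samples), collapse = "\t")), con)
  if (nSites(gm) == 0L) return(invisible(path))
  gtstr <- matrix(c("0/0", "0/1", "1/1")[gm@geno + 1L], nrow = nSites(gm))
  gtstr[is.na(gtstr)] <- "./."
  body <- paste(gm@contig, gm@pos, ".", gm@ref, gm@alt, ".", "PASS", ".",
                "GT", apply(gtstr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' Tab-separated with header columns \code{sample}, \code{sex}
#' (M/F/J/U), \code{population}. Sample ids must be unique.
#'
#' @param path TSV path.
#' @return data.frame with columns sample, sex, population.
#' @export
readSampleSheet <- function(path) {
  sh <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  validateSampleSheet(sh)
}

#' @rdname readSampleSheet
#' @param sheet data.frame to validate or write.
#' @export
writeSampleSheet <- function(sheet, path) {
  validateSampleSheet(sheet)
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateSampleSheet <- function(sheet) {
  need <- c("sample", "sex", "population")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample))
    stop("duplicated sample id(s) in sheet")
  if (!all(sheet$sex %in% c("M", "F", "J", "U")))
    stop("sex must be one of M, F, J, U")
  sheet[need]
}

#' Read / write per-site depth tables
#'
#' The layout of \code{samtools depth -aa}: contig, 1-based position, one
#' integer depth column per sample. Every contig must be densely covered
#' from position 1 to its last listed position.
#'
#' @param path TSV path (with header: contig, pos, then sample ids).
#' @param dialect alignment-filter dialect of the file.
#' @return A named list of \linkS4class{DepthTrack}, one per contig.
#' @export
readDepthTsv <- function(path, dialect = c("all", "perfect")) {
  dialect <- match.arg(dialect)
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  samples <- names(d)[-(1:2)]
  out <- lapply(split(d, d[[1]]), function(dd) {
    dd <- dd[order(dd[[2]]), , drop = FALSE]
    if (!identical(as.integer(dd[[2]]), seq_len(nrow(dd))))
      stop("depth table not dense from position 1 for contig ", dd[[1]][1])
    DepthTrack(as.character(dd[[1]][1]),
               as.matrix(dd[, -(1:2), drop = FALSE]),
               samples = samples, dialect = dialect)
  })
  out[unique(as.character(d[[1]]))]
}

#' @rdname readDepthTsv
#' @param tracks named list of DepthTrack (or a single DepthTrack).
#' @export
writeDepthTsv <- function(tracks, path) {
  if (is(tracks, "DepthTrack")) tracks <- list(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("contig", "pos", tracks[[1]]@samples), collapse = "\t"),
             con)
  for (tr in tracks) {
    m <- tr@depth
    body <- paste(tr@contig, seq_len(nrow(m)),
                  apply(m, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Tile a contig with fixed-width windows
#'
#' Windows are 0-based half-open intervals \code{[start, end)} of the
#' given width; the last window may be partial.
#'
#' @param contigLengths named integer vector of contig lengths, or a
#'   single unnamed length (contig then named "contig").
#' @param width window width in bp (default 10 kb).
#' @return data.frame with columns contig, start, end.
#' @export
makeWindows <- function(contigLengths, width = 10000L) {
  if (width <= 0) stop("width must be > 0")
  if (is.null(names(contigLengths)))
    names(contigLengths) <- if (length(contigLengths) == 1L) "contig" else
      paste0("contig", seq_along(contigLengths))
  out <- lapply(names(contigLengths), function(cn) {
    len <- contigLengths[[cn]]
    if (len <= 0) stop("contig length must be > 0")
    starts <- seq(0L, len - 1L, by = width)
    data.frame(contig = cn, start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map 1-based site positions to window rows
#'
#' @param contig,pos site coordinates (1-based positions).
#' @param windows window table from \code{makeWindows}.
#' @return integer row index into \code{windows} (NA when outside).
#' @export
windowIndex <- function(contig, pos, windows) {
  idx <- rep(NA_integer_, length(pos))
  p0 <- pos - 1L   # 0-based
  for (cn in unique(contig)) {
    wsel <- which(windows$contig == cn)
    if (!length(wsel)) next
    csel <- which(contig == cn)
    j <- findInterval(p0[csel], windows$start[wsel])
    ok <- j >= 1L & p0[csel] < windows$end[wsel][pmax(j, 1L)]
    idx[csel[ok]] <- wsel[j[ok]]
  }
  idx
}

#' Remove sites with excessive missingness
#'
#' Sites whose missing-genotype fraction strictly exceeds the threshold
#' are removed (a site at exactly the threshold is kept).
#'
#' @param gm GenotypeMatrix.
#' @param maxMissing maximum tolerated missing fraction in [0, 1].
#' @return Filtered GenotypeMatrix.
#' @export
filterMissingness <- function(gm, maxMissing = 0.5) {
  if (maxMissing < 0 || maxMissing > 1) stop("maxMissing must be in [0,1]")
  frac <- rowMeans(is.na(gm@geno))
  gm[frac <= maxMissing, ]
}

#' Write 0-based half-open intervals as BED3
#'
#' @param regions data.frame with contig, start, end (0-based half-open).
#' @param path output path.
#' @export
writeBed <- function(regions, path) {
  write.table(regions[, c("contig", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a window/statistics table as TSV (NA encoded as "NA")
#' @param tab data.frame.
#' @param path output path.
#' @export
writeTsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
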