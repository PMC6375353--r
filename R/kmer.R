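## Alignment-free sex-specific sequence discovery via trigger-reduced
## k-mer catalogs.
##
## Words are counted as written in the reads - no reverse-complement
## canonicalization - because the trigger-prefix scheme operates on raw
## read orientation; a word and its reverse complement are distinct
## catalog entries. This halves per-strand sensitivity and is
## compensated by searching both strands in placeKmers().

## All k-length words starting with the trigger, from a character vector
## of read sequences. Words containing non-ACGT are skipped.
extractTriggerKmers <- function(seqs, k, trigger) {
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) return(character(0))
  tl <- nchar(trigger)
  hits <- gregexpr(trigger, seqs, fixed = TRUE)
  idx <- rep(seq_along(seqs), lengths(hits))
  st <- unlist(hits)
  keep <- st > 0L & st + k - 1L <= nchar(seqs)[idx]
  idx <- idx[keep]; st <- st[keep]
  if (!length(st)) return(character(0))
  w <- substring(seqs[idx], st, st + k - 1L)
  w[!grepl("[^ACGT]", w)]
}

readFastqSeqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Build a pooled k-mer catalog from FASTQ files
#'
#' Tallies every k-length window starting with the trigger prefix across
#' all reads of all files (one sex pooled), then drops words below
#' \code{minCount}.
#'
#' @param fastqPaths character vector of FASTQ paths (gzip transparent).
#' @param k word length (default 37).
#' @param trigger prefix (default "AG").
#' @param minCount minimum pooled count to retain (default 5).
#' @return A \linkS4class{KmerCatalog}.
#' @export
countKmers <- function(fastqPaths, k = 37L, trigger = "AG", minCount = 5L) {
  tabs <- lapply(unname(fastqPaths), function(p) {
    w <- extractTriggerKmers(readFastqSeqs(p), k, trigger)
    if (!length(w)) return(NULL)
    table(w)
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (!length(tabs)) {
    warning("empty input: no k-mers counted")
    counts <- integer(0)
  } else {
    all <- unlist(lapply(tabs, function(t) setNames(as.integer(t),
                                                    names(t))))
    counts <- vapply(split(all, names(all)), sum, integer(1))
    counts <- counts[counts >= minCount]
  }
  if (length(counts)) counts <- counts[order(names(counts))]
  new("KmerCatalog", k = as.integer(k), trigger = trigger,
      minCount = as.integer(minCount), counts = counts)
}

#' Classify k-mers as Y-mers, X-mers, shared or other
#'
#' Y-mer: pooled male count >= \code{yMaleMin} and female count <=
#' \code{yFemaleMax} (a word absent from a catalog counts 0). X-mer
#' (tested after the Y rule): present in males with female/male ratio in
#' [\code{xRatioLo}, \code{xRatioHi}] - the 2:1 dosage signature of
#' X-linked sequence. When male and female sample sizes differ, set
#' \code{femaleScale = n_males/n_females} to rescale female counts
#' before the ratio.
#'
#' @param maleCatalog,femaleCatalog KmerCatalog objects with identical
#'   k and trigger.
#' @param yMaleMin,yFemaleMax Y-mer thresholds (defaults 10 and 4,
#'   i.e. >9 in males and <5 in females).
#' @param xRatioLo,xRatioHi X-mer female/male ratio band.
#' @param femaleScale multiplier applied to female counts before the
#'   X-ratio (default 1).
#' @return data.frame: kmer, male, female, class.
#' @export
classifyKmers <- function(maleCatalog, femaleCatalog,
                          yMaleMin = 10L, yFemaleMax = 4L,
                          xRatioLo = 1.75, xRatioHi = 2.25,
                          femaleScale = 1) {
  if (maleCatalog@k != femaleCatalog@k ||
      maleCatalog@trigger != femaleCatalog@trigger)
    stop("catalogs built with different k or trigger")
  words <- sort(union(names(maleCatalog@counts),
                      names(femaleCatalog@counts)))
  m <- maleCatalog@counts[words]; m[is.na(m)] <- 0L
  f <- femaleCatalog@counts[words]; f[is.na(f)] <- 0L
  isY <- m >= yMaleMin & f <= yFemaleMax
  ratio <- ifelse(m >= 1L, (f * femaleScale) / m, NA_real_)
  isX <- !isY & !is.na(ratio) & ratio >= xRatioLo & ratio <= xRatioHi
  cls <- ifelse(isY, "Y-mer",
         ifelse(isX, "X-mer",
         ifelse(m > 0L & f > 0L, "shared", "other")))
  data.frame(kmer = words, male = as.integer(m), female = as.integer(f),
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract read pairs matching a k-mer set
#'
#' A pair is kept when either mate contains at least one set k-mer as an
#' exact substring (as written); both mates are emitted in input order.
#'
#' @param fastq1,fastq2 paired FASTQ paths (consistent mate order).
#' @param kmers character vector of k-mers (equal length, sharing the
#'   catalog trigger prefix).
#' @param out1,out2 output FASTQ paths (optional; omit to only return
#'   ids).
#' @param trigger trigger prefix of the k-mer scheme (used to locate
#'   candidate word starts; default "AG").
#' @return character vector of kept read ids (name of mate 1), invisibly
#'   when writing files.
#' @export
extractReadsByKmers <- function(fastq1, fastq2, kmers,
                                out1 = NULL, out2 = NULL, trigger = "AG") {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2)) stop("unpaired files")
  if (!length(kmers)) stop("empty k-mer set")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers must share one length")
  hasHit <- function(ds) {
    s <- as.character(ds)
    raw <- extractTriggerKmersRaw(s, k, trigger)
    hit <- logical(length(s))
    if (length(raw$words)) {
      mh <- !grepl("[^ACGT]", raw$words) & raw$words %in% kmers
      hit[unique(raw$idx[mh])] <- TRUE
    }
    hit
  }
  keep <- hasHit(r1) | hasHit(r2)
  ids <- names(r1)[keep]
  if (!is.null(out1)) {
    copyFastqSubset(fastq1, keep, out1)
    copyFastqSubset(fastq2, keep, out2)
    return(invisible(ids))
  }
  ids
}

extractTriggerKmersRaw <- function(seqs, k, trigger) {
  hits <- gregexpr(trigger, seqs, fixed = TRUE)
  idx <- rep(seq_along(seqs), lengths(hits))
  st <- unlist(hits)
  keep <- st > 0L & st + k - 1L <= nchar(seqs)[idx]
  idx <- idx[keep]; st <- st[keep]
  list(words = substring(seqs[idx], st, st + k - 1L), idx = idx)
}

copyFastqSubset <- function(path, keep, out) {
  lines <- readLines(path)
  rec <- rep(seq_len(length(lines) / 4L), each = 4L)
  writeLines(lines[keep[rec]], out)
  invisible(out)
}

#' Place k-mers on an assembly by exact match
#'
#' Exact substring matches of every k-mer (forward, and the reverse
#' complement of the k-mer reported on the minus strand) against each
#' assembly sequence.
#'
#' @param kmers character vector of equal-length k-mers.
#' @param assembly named character vector of sequences, or a FASTA path.
#' @return data.frame: contig, start (0-based), end, strand, kmer.
#' @export
placeKmers <- function(kmers, assembly) {
  if (length(assembly) == 1L && file.exists(assembly[1]) &&
      is.null(names(assembly)))
    assembly <- as.character(Biostrings::readDNAStringSet(assembly))
  if (!length(kmers))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kmer = character(0)))
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1L)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  rcSet <- Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers))
  pdRc <- Biostrings::PDict(rcSet)
  out <- list()
  for (cn in names(assembly)) {
    subj <- Biostrings::DNAString(assembly[[cn]])
    for (str in c("+", "-")) {
      m <- Biostrings::matchPDict(if (str == "+") pd else pdRc, subj)
      st <- Biostrings::startIndex(m)
      hit <- which(lengths(st) > 0L)
      if (!length(hit)) next
      starts <- unlist(st[hit])
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = starts - 1L, end = starts - 1L + k,
        strand = str, kmer = rep(kmers[hit], lengths(st[hit])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kmer = character(0)))
  do.call(rbind, out)
}

#' Bin k-mer placements per window
#'
#' @param placements result of \code{placeKmers}.
#' @param windows window table.
#' @return \code{windows} with an \code{n_kmers} count column.
#' @export
binKmerPlacements <- function(placements, windows) {
  wi <- windowIndex(placements$contig, placements$start + 1L, windows)
  out <- windows
  out$n_kmers <- tabulate(wi[!is.na(wi)], nbins = nrow(windows))
  out
}
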