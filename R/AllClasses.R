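#' @import methods
#' @importFrom stats median rbinom rexp rpois runif sd var cor cor.test
#'   t.test setNames dist
#' @importFrom utils read.table write.table
NULL

#' GenotypeMatrix: biallelic variant sites by diploid samples
#'
#' Holds hard genotype calls at biallelic sites as alternate-allele counts
#' (0, 1, 2; \code{NA} for missing), together with site coordinates
#' (1-based, as in VCF), REF/ALT alleles and ordered sample identifiers.
#' Sites from several contigs may be stacked; within a contig positions
#' are strictly increasing.
#'
#' @slot contig character vector, one entry per site.
#' @slot pos integer vector of 1-based site positions.
#' @slot ref,alt character vectors of reference / alternate alleles.
#' @slot geno integer matrix, sites x samples, entries in \{0,1,2,NA\}.
#' @slot samples character vector of sample identifiers (column order).
#'
#' @export
setClass("GenotypeMatrix",
  representation(
    contig  = "character",
    pos     = "integer",
    ref     = "character",
    alt     = "character",
    geno    = "matrix",
    samples = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  ns <- length(object@contig)
  if (length(object@pos) != ns) msg <- c(msg, "pos length != contig length")
  if (nrow(object@geno) != ns) msg <- c(msg, "geno rows != number of sites")
  if (ncol(object@geno) != length(object@samples))
    msg <- c(msg, "geno cols != number of samples")
  if (length(object@ref) != ns || length(object@alt) != ns)
    msg <- c(msg, "ref/alt length mismatch")
  g <- object@geno
  if (length(g) && !all(g %in% c(0L, 1L, 2L) | is.na(g)))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (ns > 1) {
    same <- object@contig[-1] == object@contig[-ns]
    if (any(same & diff(object@pos) <= 0))
      msg <- c(msg, "positions must be strictly increasing within contig")
  }
  if (anyDuplicated(object@samples)) msg <- c(msg, "duplicated sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param contig character vector (recycled if scalar), one per site.
#' @param pos integer vector of 1-based positions.
#' @param geno integer matrix sites x samples with codes 0/1/2/NA.
#' @param samples sample identifiers; defaults to geno column names.
#' @param ref,alt allele strings; default placeholders A/T.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(contig, pos, geno, samples = colnames(geno),
                           ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ns <- nrow(geno)
  if (length(contig) == 1L) contig <- rep(contig, ns)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep("T", ns)
  dimnames(geno) <- NULL
  new("GenotypeMatrix", contig = as.character(contig), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      geno = geno, samples = as.character(samples))
}

#' DepthTrack: dense per-position sequencing depth for one contig
#'
#' Per-sample integer read depth at every position 1..L of a named
#' sequence, in one of two alignment-filter dialects: \code{"all"}
#' (every alignment counted) or \code{"perfect"} (only alignments
#' without any mismatch).
#'
#' @slot contig scalar contig name.
#' @slot depth integer matrix, positions x samples.
#' @slot samples character sample identifiers.
#' @slot dialect \code{"all"} or \code{"perfect"}.
#' @export
setClass("DepthTrack",
  representation(
    contig  = "character",
    depth   = "matrix",
    samples = "character",
    dialect = "character"
  )
)

setValidity("DepthTrack", function(object) {
  msg <- character()
  if (length(object@contig) != 1L) msg <- c(msg, "contig must be scalar")
  if (!object@dialect %in% c("all", "perfect"))
    msg <- c(msg, "dialect must be 'all' or 'perfect'")
  if (ncol(object@depth) != length(object@samples))
    msg <- c(msg, "depth cols != samples")
  if (length(object@depth) && min(object@depth, na.rm = TRUE) < 0)
    msg <- c(msg, "depths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DepthTrack
#' @param contig contig name.
#' @param depth integer matrix positions x samples.
#' @param samples sample ids; defaults to column names.
#' @param dialect "all" or "perfect".
#' @return A \linkS4class{DepthTrack}.
#' @export
DepthTrack <- function(contig, depth, samples = colnames(depth),
                       dialect = c("all", "perfect")) {
  dialect <- match.arg(dialect)
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(depth)))
  dimnames(depth) <- NULL
  new("DepthTrack", contig = contig, depth = depth,
      samples = as.character(samples), dialect = dialect)
}

#' KmerCatalog: pooled k-mer counts for one sex
#'
#' Counts of fixed-length nucleotide words beginning with a trigger
#' prefix, pooled over all individuals of one sex and pruned at a
#' minimum count.
#'
#' @slot k word length.
#' @slot trigger prefix every stored word starts with.
#' @slot minCount words below this pooled count were dropped.
#' @slot counts named integer vector, word -> count.
#' @export
setClass("KmerCatalog",
  representation(k = "integer", trigger = "character",
                 minCount = "integer", counts = "integer")
)

setValidity("KmerCatalog", function(object) {
  msg <- character()
  w <- names(object@counts)
  if (length(w)) {
    if (!all(nchar(w) == object@k)) msg <- c(msg, "word length != k")
    if (!all(startsWith(w, object@trigger)))
      msg <- c(msg, "word does not start with trigger")
    if (any(object@counts < object@minCount))
      msg <- c(msg, "count below minCount retained")
    if (any(grepl("[^ACGT]", w))) msg <- c(msg, "non-ACGT word")
  }
  if (length(msg)) msg else TRUE
})

## ---- accessors ------------------------------------------------------------

#' @rdname GenotypeMatrix-class
#' @param object,x a GenotypeMatrix.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) {
  g <- x@geno
  dimnames(g) <- list(NULL, x@samples)
  g
})

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@samples)
#' @rdname DepthTrack-class
#' @export
setMethod("sampleIds", "DepthTrack", function(x) x@samples)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("siteTable", "GenotypeMatrix", function(x)
  data.frame(contig = x@contig, pos = x@pos, ref = x@ref, alt = x@alt,
             stringsAsFactors = FALSE))

#' Number of variant sites
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) nrow(x@geno))

#' @rdname DepthTrack-class
#' @param x a DepthTrack.
#' @export
setGeneric("depthMatrix", function(x) standardGeneric("depthMatrix"))
#' @rdname DepthTrack-class
#' @export
setMethod("depthMatrix", "DepthTrack", function(x) {
  d <- x@depth
  dimnames(d) <- list(NULL, x@samples)
  d
})

#' @rdname KmerCatalog-class
#' @param x a KmerCatalog.
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname KmerCatalog-class
#' @export
setMethod("kmerCounts", "KmerCatalog", function(x) x@counts)

## ---- subsetting -----------------------------------------------------------

#' Subset a GenotypeMatrix by sites and/or samples
#'
#' @param x GenotypeMatrix.
#' @param i site index (logical or integer).
#' @param j sample index (logical, integer or character ids).
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSites(x))
  if (missing(j)) j <- seq_along(x@samples)
  if (is.character(j)) {
    jj <- match(j, x@samples)
    if (anyNA(jj)) stop("unknown sample(s): ",
                        paste(j[is.na(jj)], collapse = ", "))
    j <- jj
  }
  new("GenotypeMatrix", contig = x@contig[i], pos = x@pos[i],
      ref = x@ref[i], alt = x@alt[i],
      geno = x@geno[i, j, drop = FALSE], samples = x@samples[j])
})

## ---- show -----------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nSites(object), "sites x",
      length(object@samples), "samples\n")
  cat("  contigs:", paste(unique(object@contig), collapse = ", "), "\n")
  nm <- mean(is.na(object@geno))
  cat(sprintf("  missingness: %.2f%%\n", 100 * nm))
})

setMethod("show", "DepthTrack", function(object) {
  cat("DepthTrack:", object@contig, "-", nrow(object@depth), "positions x",
      length(object@samples), "samples (dialect:", object@dialect, ")\n")
})

setMethod("show", "KmerCatalog", function(object) {
  cat("KmerCatalog: k =", object@k, ", trigger =", object@trigger,
      ", minCount =", object@minCount, "\n")
  cat("  ", length(object@counts), "distinct words, total count",
      sum(object@counts), "\n")
})
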