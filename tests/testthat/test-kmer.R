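writeFq <- function(seqs, path, ids = sprintf("r%03d", seq_along(seqs))) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  path
}

test_that("k-mer counting respects trigger, alphabet and minCount boundary", {
  word <- paste0("AG", paste(rep("C", 35), collapse = ""))  # 37-mer
  fq5 <- writeFq(rep(word, 5), tempfile(fileext = ".fastq"))
  cat5 <- countKmers(fq5)
  expect_equal(unname(kmerCounts(cat5)[word]), 5L)
  fq4 <- writeFq(rep(word, 4), tempfile(fileext = ".fastq"))
  expect_length(kmerCounts(countKmers(fq4)), 0L)
  # a read without the trigger contributes nothing (empty catalog warns)
  noAg <- paste(rep("C", 50), collapse = "")
  expect_warning(c1 <- countKmers(writeFq(rep(noAg, 9),
                                          tempfile(fileext = ".fastq"))),
                 "empty")
  expect_length(kmerCounts(c1), 0L)
  # words containing non-ACGT are skipped
  wn <- paste0("AG", paste(rep("C", 30), collapse = ""), "NAGTC")
  expect_warning(c2 <- countKmers(writeFq(rep(wn, 6),
                                          tempfile(fileext = ".fastq"))),
                 "empty")
  expect_length(kmerCounts(c2), 0L)
})

test_that("catalog counts are additive over input shards", {
  set.seed(44)
  reads <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
    character(1))
  f1 <- writeFq(reads[1:30], tempfile(fileext = ".fastq"))
  f2 <- writeFq(reads[31:60], tempfile(fileext = ".fastq"))
  fAll <- writeFq(reads, tempfile(fileext = ".fastq"))
  sharded <- countKmers(c(f1, f2), k = 11, minCount = 1)
  whole <- countKmers(fAll, k = 11, minCount = 1)
  expect_identical(kmerCounts(sharded), kmerCounts(whole))
})

test_that("Y-mer and X-mer classification boundaries are exact", {
  mkCat <- function(counts)
    new("KmerCatalog", k = 37L, trigger = "AG", minCount = 1L,
        counts = counts)
  words <- vapply(1:6, function(i)
    paste0("AG", paste(sample(c("A", "C", "G", "T"), 35, TRUE),
                       collapse = "")), character(1))
  male <- setNames(c(10L, 9L, 10L, 10L, 10L, 10L), words)
  female <- setNames(c(4L, 1L, 20L, 17L, 23L, 5L), words)
  cl <- classifyKmers(mkCat(male), mkCat(female))
  cls <- setNames(cl$class, cl$kmer)
  expect_equal(unname(cls[words[1]]), "Y-mer")     # 10 male / 4 female
  expect_equal(unname(cls[words[2]]), "shared")    # 9 male: below >9
  expect_equal(unname(cls[words[3]]), "X-mer")     # ratio 2.0
  expect_equal(unname(cls[words[4]]), "shared")    # 1.7 < 1.75
  expect_equal(unname(cls[words[5]]), "shared")    # 2.3 > 2.25
  expect_equal(unname(cls[words[6]]), "shared")    # female 5 breaks Y rule
  # a word absent from the female catalog counts zero (still not Y at 9)
  m2 <- mkCat(setNames(9L, words[1]))
  f2 <- mkCat(setNames(integer(0), character(0)))
  expect_equal(classifyKmers(m2, f2)$class, "other")
  # female-scale rescales the X ratio for unequal sample sizes
  clS <- classifyKmers(mkCat(male), mkCat(female), femaleScale = 2)
  expect_equal(clS$class[clS$kmer == words[1]], "Y-mer")  # Y rule unscaled
  expect_equal(clS$class[clS$kmer == words[4]], "shared")
  expect_error(classifyKmers(mkCat(male),
                             new("KmerCatalog", k = 21L, trigger = "AG",
                                 minCount = 1L,
                                 counts = integer(0))), "different k")
})

test_that("read-pair extraction keeps a pair when either mate matches", {
  k <- 37
  yWord <- paste0("AG", strrep("T", 17), strrep("G", 18))
  bg <- function() paste(sample(c("A", "C"), 60, TRUE), collapse = "")
  set.seed(12)
  m1 <- c(bg(), bg(), bg())
  m2 <- c(bg(), paste0("CCC", yWord, "CCC"), bg())
  f1 <- writeFq(m1, tempfile(fileext = ".fastq"), ids = c("p1", "p2", "p3"))
  f2 <- writeFq(m2, tempfile(fileext = ".fastq"), ids = c("p1", "p2", "p3"))
  out1 <- tempfile(fileext = ".fastq"); out2 <- tempfile(fileext = ".fastq")
  ids <- extractReadsByKmers(f1, f2, yWord, out1, out2)
  expect_equal(ids, "p2")
  expect_equal(length(readLines(out1)), 4L)
  expect_equal(length(readLines(out2)), 4L)
  expect_match(readLines(out2)[2], yWord)
  # unpaired input errors
  f3 <- writeFq(m2[1:2], tempfile(fileext = ".fastq"))
  expect_error(extractReadsByKmers(f1, f3, yWord), "unpaired")
})

test_that("k-mer placement reports exact matches on both strands", {
  set.seed(90)
  asm <- c(ctg = paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                       collapse = ""))
  km <- substr(asm, 101, 137)
  hits <- placeKmers(km, asm)
  expect_equal(hits$start, 100L)
  expect_equal(hits$strand, "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(km)))
  hitsRc <- placeKmers(rc, asm)
  expect_equal(hitsRc$start, 100L)
  expect_equal(hitsRc$strand, "-")
  none <- placeKmers(strrep("A", 37), asm)
  expect_true(is.data.frame(none))
})

test_that("simulated Y-mers recover Y-insertion read pairs", {
  cfg <- simConfig(contigs = c(sexChr = 4e4),
                   sdRegion = list(contig = "sexChr", start = 5e3,
                                   end = 3.5e4),
                   yInsertionCount = 3L, yInsertionLength = 1200L,
                   readCoverage = 12, tau = 2e-3)
  dir <- tempfile()
  rs <- simulateReads(cfg, seed = 21, dir = dir)
  isM <- startsWith(rs$files$sample, "P1M")
  maleCat <- countKmers(unlist(rs$files[isM, c("mate1", "mate2")]))
  femCat <- countKmers(unlist(rs$files[!isM, c("mate1", "mate2")]))
  cl <- classifyKmers(maleCat, femCat)
  yMers <- cl$kmer[cl$class == "Y-mer"]
  expect_gt(length(yMers), 100)

  hit <- 0; tot <- 0; femaleHits <- 0
  for (i in seq_len(nrow(rs$files))) {
    ids <- extractReadsByKmers(rs$files$mate1[i], rs$files$mate2[i], yMers)
    if (isM[i]) {
      truthIds <- rs$truth$yInsertionPairs[[rs$files$sample[i]]]
      tot <- tot + length(truthIds)
      hit <- hit + sum(truthIds %in% ids)
    } else {
      femaleHits <- femaleHits + length(ids)
    }
  }
  expect_gt(hit / tot, 0.8)       # recall of truth Y-insertion pairs
  expect_equal(femaleHits, 0L)    # no female pair carries a Y-mer
  # X-mer density peaks inside the sd region on the female assembly
  ref <- simulateReference(cfg, seed = 21)
  xMers <- cl$kmer[cl$class == "X-mer"]
  expect_gt(length(xMers), 20)
  pl <- placeKmers(xMers, ref)
  bins <- binKmerPlacements(pl, makeWindows(c(sexChr = 4e4), 5e3))
  best <- which.max(bins$n_kmers)
  expect_true(bins$start[best] >= 5e3 && bins$end[best] <= 3.5e4)
})
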