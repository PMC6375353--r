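test_that("coalescent blocks are deterministic under a fixed seed", {
  a <- simulateAutosomalBlock(10, 5, 1e4, seed = 99)
  b <- simulateAutosomalBlock(10, 5, 1e4, seed = 99)
  expect_identical(a, b)
  expect_error(simulateAutosomalBlock(1, 5))
  expect_error(simulateAutosomalBlock(4, 0))
})

test_that("simulated cohorts are reproducible and respect the truth file", {
  cfg <- smallSimConfig()
  s1 <- simulateGenotypes(cfg, seed = 3)
  s2 <- simulateGenotypes(cfg, seed = 3)
  expect_identical(s1$gm@geno, s2$gm@geno)
  expect_identical(s1$truth$ySites, s2$truth$ySites)
  # every truth Y-specific site: all males het, all females hom
  g <- genotypes(s1$gm)
  key <- paste(s1$gm@contig, s1$gm@pos)
  ySel <- match(paste(s1$truth$ySites$contig, s1$truth$ySites$pos), key)
  expect_false(anyNA(ySel))
  males <- s1$sheet$sex == "M"
  expect_true(all(g[ySel, males] == 1L))
  expect_true(all(g[ySel, !males] != 1L))
  # Y-specific sites lie inside the sd region
  expect_true(all(s1$truth$ySites$contig == "sexChr"))
  expect_true(all(s1$truth$ySites$pos > 1e5 & s1$truth$ySites$pos <= 3e5))
})

test_that("tau = 0 with no internal Y diversity yields no XY sites beyond chance", {
  cfg <- smallSimConfig(tau = 0, yInternalTheta = 0)
  sim <- simulateGenotypes(cfg, seed = 8)
  expect_equal(nrow(sim$truth$ySites), 0L)
  r <- detectSexPatternedSites(sim$gm, paste0("P1M", 1:5), paste0("P1F", 1:5))
  # chance rate only: a handful of sites at most across ~10k sites
  expect_lt(nrow(r$sites) / nSites(sim$gm), 0.01)
})

test_that("expected Y-specific site count matches the Poisson mean", {
  cfg <- simConfig(contigs = c(sexChr = 5e4),
                   sdRegion = list(contig = "sexChr", start = 0, end = 5e4),
                   tau = 1e-3, yInternalTheta = 0, theta = 10)
  counts <- vapply(1:200, function(i)
    nrow(simulateGenotypes(cfg, seed = i)$truth$ySites), numeric(1))
  expected <- 1e-3 * 5e4
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("genotypes at non-sd sites satisfy Hardy-Weinberg in expectation", {
  cfg <- simConfig(contigs = c(auto1 = 1e4), sdRegion = NULL, theta = 10)
  oh <- eh <- 0
  for (i in 1:300) {
    sim <- simulateGenotypes(cfg, seed = i)
    g <- sim$gm@geno
    p <- rowMeans(g) / 2
    poly <- p > 0 & p < 1
    oh <- oh + sum(rowMeans(g[poly, , drop = FALSE] == 1L))
    eh <- eh + sum(2 * p[poly] * (1 - p[poly]) * 20 / 19)
  }
  expect_gt(oh / eh, 0.95)
  expect_lt(oh / eh, 1.05)
})

test_that("bottleneck mode yields positive Tajima's D", {
  cfg <- simConfig(contigs = c(auto1 = 1e4), sdRegion = NULL, theta = 10,
                   nPopulations = 2L, nMales2 = 4L, nFemales2 = 3L,
                   founders2 = 4L, splitThetaScale = 0)
  w <- makeWindows(c(auto1 = 1e4))
  d2 <- vapply(1:100, function(i) {
    sim <- simulateGenotypes(cfg, seed = 1000 + i)
    p2 <- sim$sheet$sample[sim$sheet$population == "pop2"]
    tajimasDWindows(sim$gm[, p2], p2, w)$tajima_d
  }, numeric(1))
  expect_gt(mean(d2, na.rm = TRUE), 0)
})

test_that("depth dialects reproduce hemizygous male coverage", {
  cfg <- simConfig(contigs = c(sexChr = 6e4),
                   sdRegion = list(contig = "sexChr", start = 2e4, end = 5e4),
                   sdDifferentiation = "full", depthLambda = 20)
  males <- paste0("P1M", 1:5)
  for (dl in c("all", "perfect")) {
    tr <- simulateDepth(cfg, NULL, dl, seed = 4)$sexChr
    d <- depthMatrix(tr)
    inSd <- seq_len(nrow(d)) > 2e4 & seq_len(nrow(d)) <= 5e4
    mMean <- mean(d[inSd, males])
    fMean <- mean(d[inSd, paste0("P1F", 1:5)])
    expect_equal(fMean, 20, tolerance = 0.05)
    expect_equal(mMean, if (dl == "perfect") 10 else 20, tolerance = 0.05)
    # outside the region both sexes at lambda
    expect_equal(mean(d[!inSd, males]), 20, tolerance = 0.05)
  }
})

test_that("read simulation honours the coverage identity and truth tags", {
  cfg <- simConfig(contigs = c(sexChr = 3e4),
                   sdRegion = list(contig = "sexChr", start = 5e3, end = 2.5e4),
                   yInsertionCount = 2L, yInsertionLength = 800L,
                   readCoverage = 8, nMales = 2L, nFemales = 2L)
  dir <- tempfile()
  rs <- simulateReads(cfg, seed = 6, dir = dir)
  expect_equal(nrow(rs$files), 4L)
  # female read names never carry a Y-insertion tag
  for (s in c("P1F1", "P1F2"))
    expect_length(rs$truth$yInsertionPairs[[s]], 0L)
  for (s in c("P1M1", "P1M2"))
    expect_gt(length(rs$truth$yInsertionPairs[[s]]), 0L)
  # coverage identity: 2 * nFrag * readLength / genomeLength per individual
  l1 <- readLines(rs$files$mate1[1])
  nFrag <- length(l1) / 4
  cov <- 2 * nFrag * cfg$readLength / 3e4
  expect_equal(cov, 8, tolerance = 0.05)
  # same seed -> byte-identical FASTQ
  dir2 <- tempfile()
  rs2 <- simulateReads(cfg, seed = 6, dir = dir2)
  expect_identical(readLines(rs$files$mate1[1]), readLines(rs2$files$mate1[1]))
  expect_identical(readLines(rs$files$mate2[3]), readLines(rs2$files$mate2[3]))
})

test_that("written simulations round-trip through the standard formats", {
  cfg <- simConfig(contigs = c(sexChr = 3e4, auto1 = 2e4),
                   sdRegion = list(contig = "sexChr", start = 0, end = 2e4),
                   theta = 10)
  sim <- simulateGenotypes(cfg, seed = 12)
  dir <- tempfile()
  paths <- writeSimulation(sim, cfg, dir, seed = 12)
  sheet <- readSampleSheet(paths$sheet)
  expect_equal(sheet, sim$sheet)
  gm <- readVcfGenotypes(paths$vcf, sheet)
  expect_identical(genotypes(gm), genotypes(sim$gm))
  tr <- readDepthTsv(paths$depth_perfect, "perfect")
  expect_equal(names(tr), "sexChr")
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$sdRegion$end, 2e4)
})
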