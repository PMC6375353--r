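test_that("XY pattern matches its definition on toy cohorts", {
  co <- toySexCohort()
  r <- detectSexPatternedSites(co$gm, co$males, co$females)
  expect_equal(r$sites$pos, 1:4)
  # one male homozygous breaks the pattern
  g <- genotypes(co$gm)
  g[1, "M1"] <- 0L
  gm2 <- gmFrom(g, samples = colnames(g))
  r2 <- detectSexPatternedSites(gm2, co$males, co$females)
  expect_equal(r2$sites$pos, 2:4)
  # ZW is the mirror
  rzw <- detectSexPatternedSites(co$gm, co$males, co$females, pattern = "ZW")
  expect_equal(nrow(rzw$sites), 0L)
  gSwap <- g[2:4, ]
  gm3 <- gmFrom(cbind(gSwap[, 6:10], gSwap[, 1:5]),
                samples = colnames(g))  # females now het
  expect_equal(nrow(detectSexPatternedSites(gm3, co$males, co$females,
                                            pattern = "ZW")$sites), 3L)
  expect_error(detectSexPatternedSites(co$gm, character(0), co$females))
})

test_that("XY detection agrees with exhaustive enumeration for 3M+3F", {
  # all 3^6 genotype configurations at one site
  cfgs <- as.matrix(expand.grid(rep(list(0:2), 6)))
  males <- paste0("m", 1:3); females <- paste0("f", 1:3)
  oracle <- apply(cfgs, 1, function(row)
    all(row[1:3] == 1) && all(row[4:6] != 1))
  gm <- gmFrom(cfgs, pos = seq_len(nrow(cfgs)),
               samples = c(males, females))
  r <- detectSexPatternedSites(gm, males, females)
  expect_setequal(r$sites$pos, which(oracle))
  # strict mode excludes sites with missing calls; lenient keeps them
  gNA <- cfgs[oracle, , drop = FALSE]
  gNA[, 4] <- NA
  gmNA <- gmFrom(gNA, samples = c(males, females))
  expect_equal(nrow(detectSexPatternedSites(gmNA, males, females)$sites), 0L)
  expect_equal(nrow(detectSexPatternedSites(gmNA, males, females,
                                            strict = FALSE,
                                            minCalled = 2)$sites),
               nrow(gNA))
})

test_that("per-individual F_IS matches limits and a literal oracle", {
  # individual homozygous at every polymorphic site -> F = 1
  g <- cbind(c(0L, 2L, 0L), c(1L, 1L, 1L), c(1L, 0L, 1L))
  r <- individualFis(gmFrom(g), paste0("s", 1:3))
  expect_equal(r$fis[1], 1)
  # all-het individual at p = 0.5 sites, large n -> F -> -1
  nInd <- 60
  gg <- matrix(rep(c(rep(0L, nInd / 2 - 1), rep(2L, nInd / 2 - 1), 1L, 1L),
                   20), nrow = 20, byrow = TRUE)
  rr <- individualFis(gmFrom(gg), paste0("s", seq_len(nInd)))
  expect_lt(rr$fis[nInd], -0.9)
  # literal two-pass oracle on random matrices with missingness
  set.seed(9)
  for (rep in 1:3) {
    g <- matrix(sample(c(0:2, NA), 100 * 6, replace = TRUE,
                       prob = c(.35, .2, .35, .1)), 100)
    mine <- individualFis(gmFrom(g), paste0("s", 1:6))
    oracle <- bruteFis(g)
    expect_equal(mine$fis, oracle$fis, tolerance = 1e-12)
    expect_equal(mine$e_hom, oracle$e, tolerance = 1e-12)
  }
})

test_that("two-site hand computation of E_hom is exact", {
  # n = 3 diploids, fixed genotypes: site1 (0,1,2), site2 (1,1,0)
  g <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L))
  # site1: p = 3/6 = .5 -> e = 1 - 2(.25)(6/5) = 0.4
  # site2: p = 2/6 -> 2p(1-p) = 4/9 -> e = 1 - (4/9)(6/5) = 7/15
  r <- individualFis(gmFrom(g), paste0("s", 1:3))
  expect_equal(r$e_hom, rep(0.4 + 7 / 15, 3), tolerance = 1e-12)
  expect_equal(r$fis[1], (1 - (0.4 + 7 / 15)) / (2 - (0.4 + 7 / 15)),
               tolerance = 1e-12)
})

test_that("normalized windowed F_IS separates the sexes inside the sd region", {
  # heterozygote excess drives male values down at Y-differentiated sites;
  # reduced X-haplotype diversity drives female values up
  mAuto <- fAuto <- nAuto <- 0
  for (s in 1:3) {
    cfg <- smallSimConfig()
    sim <- simulateGenotypes(cfg, seed = s + 50)
    males <- sim$sheet$sample[sim$sheet$sex == "M"]
    females <- sim$sheet$sample[sim$sheet$sex == "F"]
    w <- makeWindows(cfg$contigs)
    nf <- normalizedFisWindows(sim$gm, males, females, "sexChr", w)
    inSd <- nf$start >= 1e5 & nf$end <= 3e5
    # per-window sign consistency: strong in males, majority in females
    expect_gt(mean(nf$fis_m[inSd] < 0, na.rm = TRUE), 0.75)
    expect_gt(mean(nf$fis_f[inSd] > 0, na.rm = TRUE), 0.6)
    # region-level separation is clear-cut
    expect_lt(mean(nf$fis_m[inSd], na.rm = TRUE), -0.1)
    expect_gt(mean(nf$fis_f[inSd], na.rm = TRUE), 0.02)
    mAuto <- mAuto + sum(nf$fis_m[!inSd], na.rm = TRUE)
    fAuto <- fAuto + sum(nf$fis_f[!inSd], na.rm = TRUE)
    nAuto <- nAuto + sum(is.finite(nf$fis_m[!inSd]))
    if (s == 1) {
      # correlation with male-female F_ST: negative in males, positive
      # in females (the heterogametic-sex signature)
      fw <- fstWindows(sim$gm, males, females, w[w$contig == "sexChr", ])
      ct <- fisFstCorrelation(nf, fw)
      expect_lt(ct$r[ct$sex == "M"], 0)
      expect_gt(ct$r[ct$sex == "F"], 0)
    }
  }
  # windows outside the sd region are centered near zero on average
  expect_lt(abs(mAuto / nAuto), 0.05)
  expect_lt(abs(fAuto / nAuto), 0.05)
})

test_that("F_IS-F_ST correlation handles exact and degenerate inputs", {
  fis <- data.frame(contig = "c", start = 0:9 * 10, end = 1:10 * 10,
                    fis_m = -(1:10) / 10, fis_f = rep(0.3, 10))
  fst <- fis[1:3]
  fst$fst <- (1:10) / 10
  r <- fisFstCorrelation(fis, fst)
  expect_equal(r$r[r$sex == "M"], -1, tolerance = 1e-12)
  expect_true(is.na(r$r[r$sex == "F"]))  # zero variance
})

test_that("genotype PCA separates clusters and is sign-invariant", {
  set.seed(2)
  base <- matrix(sample(0:2, 60, replace = TRUE), 30)  # 2 cluster profiles
  g <- cbind(base[, rep(1, 4)], base[, rep(2, 4)])
  g[1, 1] <- (g[1, 1] + 1L) %% 3L  # break exact degeneracy
  gm <- gmFrom(g, samples = paste0("s", 1:8))
  p <- pcaGenotypes(gm)
  pc1 <- p$coords[, 1]
  expect_gt(min(abs(mean(pc1[1:4]) - mean(pc1[5:8]))), 0)
  expect_true(all(sign(pc1[1:4]) != sign(pc1[5:8])))
  d1 <- dist(p$coords)
  p2 <- p$coords
  p2[, 1] <- -p2[, 1]
  expect_equal(as.vector(dist(p2)), as.vector(d1), tolerance = 1e-12)
  expect_error(pcaGenotypes(gmFrom(matrix(2L, 3, 4))), "monomorphic")
})

test_that("PCA recovers sex only when the sd region is included", {
  # with 10 samples the null maximum |cor| over several PCs sits around
  # 0.5, so the contrast is asserted per replicate and on the median
  rWith <- rWithout <- numeric(4)
  for (s in seq_along(rWith)) {
    cfg <- smallSimConfig()
    sim <- simulateGenotypes(cfg, seed = 16 + s)
    sexNum <- as.integer(sim$sheet$sex == "M")
    p1 <- pcaGenotypes(sim$gm)
    rWith[s] <- max(abs(cor(p1$coords[, 1:3], sexNum)))
    p0 <- pcaGenotypes(sim$gm, dropContigs = "sexChr")
    rWithout[s] <- max(abs(cor(p0$coords[, 1:3], sexNum)))
  }
  expect_gte(sum(rWith > 0.9), 3)
  expect_true(all(rWithout < rWith))
  expect_lt(median(rWithout), 0.6)
})

test_that("Ajk relatedness is symmetric and flags a duplicated individual", {
  set.seed(31)
  g <- matrix(rbinom(200 * 6, 2, 0.4), 200)
  g <- cbind(g, g[, 3])  # duplicate individual 3 as individual 7
  gm <- gmFrom(g, samples = paste0("s", 1:7))
  A <- ajkRelatedness(gm)
  expect_equal(A, t(A), tolerance = 1e-12)
  off <- A[7, -7]
  expect_equal(which.max(off), c(s3 = 3L))
  # unrelated individuals: mean off-diagonal near zero
  offAll <- A[1:6, 1:6][upper.tri(matrix(0, 6, 6))]
  expect_lt(abs(mean(offAll[-which.max(offAll)])), 0.2)
})
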