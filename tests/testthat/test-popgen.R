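w1k <- makeWindows(c(chr1 = 1000), 1000)

test_that("Hudson site components match hand evaluation", {
  # 5 diploids all het vs 5 diploids hom-alt
  g <- cbind(matrix(1L, 1, 5), matrix(2L, 1, 5))
  gm <- gmFrom(g)
  f <- fstWindows(gm, paste0("s", 1:5), paste0("s", 6:10), w1k)
  # num = 0.25 - 0.25/9, den = 0.5
  expect_equal(f$fst, (0.25 - 0.25 / 9) / 0.5, tolerance = 1e-12)
})

test_that("infinite-population limit at a fully sex-differentiated site is 0.5", {
  hc <- hudsonComponents(0.5, 1.0)
  expect_identical(hc$num / hc$den, 0.5)
})

test_that("windows fixed for the same allele give NA F_ST", {
  g <- cbind(matrix(2L, 3, 4), matrix(2L, 3, 4))
  gm <- gmFrom(g)
  f <- fstWindows(gm, paste0("s", 1:4), paste0("s", 5:8), w1k)
  expect_true(is.na(f$fst))
  expect_error(fstWindows(gm, paste0("s", 1:4), paste0("s", 1:4), w1k),
               "disjoint")
})

test_that("pi matches the closed form and is 0 for monomorphic windows", {
  # one site where two haplotypes differ (one het diploid... n=2 copies)
  w10k <- makeWindows(c(chr1 = 10000), 10000)
  g <- matrix(c(1L), 1, 1)
  gm <- gmFrom(g)
  p <- piWindows(gm, "s1", w10k)
  expect_equal(p$pi, 1e-4, tolerance = 1e-12)
  gm0 <- gmFrom(matrix(c(2L, 2L), 1))
  expect_equal(piWindows(gm0, c("s1", "s2"), w10k)$pi, 0)
})

test_that("dxy matches formula and reduces to pi up to n/(n-1)", {
  # fixed difference at 1 site in a 1000 bp window
  g <- cbind(matrix(0L, 1, 3), matrix(2L, 1, 3))
  gm <- gmFrom(g)
  d <- dxyWindows(gm, paste0("s", 1:3), paste0("s", 4:6), w1k)
  expect_equal(d$dxy, 1e-3, tolerance = 1e-12)
  # pa = pb = 0.5 -> per-site contribution 0.5
  g2 <- cbind(matrix(1L, 1, 4), matrix(1L, 1, 4))
  gm2 <- gmFrom(g2)
  d2 <- dxyWindows(gm2, paste0("s", 1:4), paste0("s", 5:8), w1k)
  expect_equal(d2$dxy * 1000, 0.5, tolerance = 1e-12)
  # same group on both sides: dxy = pi * (n-1)/n
  set.seed(3)
  g3 <- matrix(sample(0:2, 40, replace = TRUE), 10)
  gm3 <- gmFrom(g3)
  grp <- paste0("s", 1:4)
  dxy <- dxyWindows(gm3, grp, grp, w1k)$dxy
  pi <- piWindows(gm3, grp, w1k)$pi
  expect_equal(dxy, pi * 7 / 8, tolerance = 1e-12)
})

test_that("net divergence reproduces the published genome-wide value", {
  # d_a = d_xy - (pi_x + pi_y)/2 applied to printed population statistics
  expect_equal(round(netDivergence(0.00764, 0.00512, 0.00193), 5), 0.00411)
  expect_equal(netDivergence(0, 0, 0), 0)
  expect_equal(netDivergence(0.3, 0.3, 0.3), 0)
})

test_that("Tajima's D matches an independent 1989-formula implementation", {
  set.seed(21)
  w10k <- makeWindows(c(chr1 = 10000), 10000)
  for (rep in 1:5) {
    g <- matrix(rbinom(30 * 5, 2, runif(30 * 5, 0.05, 0.95)), 30)
    gm <- gmFrom(g, pos = sort(sample.int(10000, 30)))
    mine <- tajimasDWindows(gm, paste0("s", 1:5), w10k)$tajima_d
    oracle <- bruteTajimaD(g)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
  # S = 0 -> NA
  gm0 <- gmFrom(matrix(0L, 2, 5))
  expect_true(is.na(tajimasDWindows(gm0, paste0("s", 1:5), w10k)$tajima_d))
})

test_that("Welch test matches hand computation and base properties", {
  r <- welchTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_equal(r$p, 0.2878641, tolerance = 1e-6)
  same <- welchTest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shift <- welchTest(c(1, 2, 3) + 10, c(2, 3, 4) + 10)
  expect_equal(shift$t, r$t, tolerance = 1e-12)
  expect_error(welchTest(1, c(1, 2)))
})

test_that("window statistics agree with brute-force per-site loops", {
  set.seed(77)
  for (rep in 1:3) {
    g <- matrix(sample(c(0:2, NA), 50 * 10, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 50)
    gm <- gmFrom(g, pos = sort(sample.int(3000, 50)))
    w <- makeWindows(c(chr1 = 3000), 1000)
    ja <- 1:5; jb <- 6:10
    f <- fstWindows(gm, paste0("s", ja), paste0("s", jb), w)
    for (k in 1:3) {
      rows <- which(gm@pos - 1 >= w$start[k] & gm@pos - 1 < w$end[k])
      bh <- bruteHudson(g[rows, , drop = FALSE], ja, jb)
      expected <- if (bh["den"] > 0) bh[["num"]] / bh[["den"]] else NA_real_
      expect_equal(f$fst[k], expected, tolerance = 1e-12)
    }
    # pi against a literal loop
    p <- piWindows(gm, paste0("s", ja), w)
    for (k in 1:3) {
      rows <- which(gm@pos - 1 >= w$start[k] & gm@pos - 1 < w$end[k])
      tot <- 0
      for (i in rows) {
        gi <- g[i, ja]; gi <- gi[!is.na(gi)]
        n <- 2 * length(gi)
        if (n < 2) next
        pp <- sum(gi) / n
        tot <- tot + (n / (n - 1)) * 2 * pp * (1 - pp)
      }
      expect_equal(p$pi[k], tot / 1000, tolerance = 1e-12)
    }
  }
})

test_that("panmictic groups give window F_ST near zero", {
  set.seed(42)
  fsts <- replicate(200, {
    b <- simulateAutosomalBlock(20, 10, 1e4)
    g <- b$haps[, seq(1, 20, 2)] + b$haps[, seq(2, 20, 2)]
    gm <- gmFrom(g, pos = b$pos)
    fstWindows(gm, paste0("s", 1:5), paste0("s", 6:10),
               makeWindows(c(chr1 = 1e4), 1e4))$fst
  })
  expect_lt(abs(mean(fsts, na.rm = TRUE)), 0.02)
})

test_that("fully sex-differentiated F_ST rises with sample size toward 0.5", {
  # all-male-het / all-female-hom sites at increasing n
  est <- vapply(c(10, 50, 500), function(nhap) {
    nd <- nhap / 2
    g <- cbind(matrix(1L, 5, nd), matrix(0L, 5, nd))
    gm <- gmFrom(g, samples = c(paste0("m", 1:nd), paste0("f", 1:nd)))
    fstWindows(gm, paste0("m", 1:nd), paste0("f", 1:nd), w1k)$fst
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_true(all(est < 0.5))
  # exact finite-sample value at n = 500 haplotypes per group
  expect_equal(est[3], (0.25 - 0.25 / 499) / 0.5, tolerance = 1e-12)
})
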