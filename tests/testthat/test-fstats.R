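# Frequency statistics: D/f_d, jackknife, f4-ratio, WC84 F_ST, SV-SNP r2.

make_freqs <- function(p1, p2, p3, pO, positions = NULL) {
  structure(list(positions = if (is.null(positions))
    seq_along(p1) * 10 else positions,
    p1 = p1, p2 = p2, p3 = p3, pO = pO), class = "quartet_freqs")
}

test_that("window_dstats reproduces the worked examples", {
  # p1 = p2 at every site -> D = 0 by symmetry
  fr <- make_freqs(c(0.3, 0.7), c(0.3, 0.7), c(0.5, 0.9), c(0, 0))
  res <- window_dstats(fr, c(0, 100), min_sites = 1)
  expect_equal(unname(res["D"]), 0)
  expect_equal(unname(res["fd"]), 0)
  # single site (0, 1, 1, 0): ABBA = 1, BABA = 0
  fr <- make_freqs(0, 1, 1, 0)
  res <- window_dstats(fr, c(0, 100), min_sites = 1)
  expect_equal(unname(res["D"]), 1)
  expect_equal(unname(res["fd"]), 1)
  # two sites: D = 0.3/0.59, fd = 0.3/0.48
  fr <- make_freqs(c(0.2, 0.5), c(0.8, 0.5), c(0.5, 0.5), c(0, 0))
  res <- window_dstats(fr, c(0, 100), min_sites = 1)
  expect_equal(unname(res["D"]), 0.3 / 0.59, tolerance = 1e-12)
  expect_equal(unname(res["fd"]), 0.625, tolerance = 1e-12)
})

test_that("f_d is zeroed under negative D and missing under zero denom", {
  fr <- make_freqs(1, 0, 1, 0)  # BABA-only site
  res <- window_dstats(fr, c(0, 100), min_sites = 1)
  expect_true(res["D"] < 0)
  expect_identical(unname(res["fd"]), 0)
  fr0 <- make_freqs(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  res0 <- window_dstats(fr0, c(0, 100), min_sites = 1)
  expect_true(is.na(res0["D"]))
  # too few sites -> missing
  expect_true(is.na(window_dstats(fr, c(0, 100), min_sites = 5)["D"]))
})

test_that("window_dstats matches the direct-sum oracle on random windows", {
  set.seed(42)
  for (k in 1:300) {
    n <- sample(2:30, 1)
    p1 <- runif(n); p2 <- runif(n); p3 <- runif(n)
    pO <- runif(n, 0, 0.39)
    fr <- make_freqs(p1, p2, p3, pO)
    res <- window_dstats(fr, c(0, n * 10 + 1), min_sites = 1)
    ora <- oracle_dstats(p1, p2, p3, pO)
    expect_equal(unname(res["D"]), ora$D, tolerance = 1e-12)
    expect_equal(unname(res["fd"]), ora$fd, tolerance = 1e-12)
  }
})

test_that("f_d stays in [0,1] when D >= 0 and hits 1 when p2 == p3", {
  set.seed(7)
  for (k in 1:200) {
    n <- sample(3:20, 1)
    p1 <- runif(n); p2 <- runif(n); p3 <- runif(n); pO <- runif(n, 0, 0.3)
    res <- window_dstats(make_freqs(p1, p2, p3, pO), c(0, n * 10 + 1),
                         min_sites = 1)
    if (!is.na(res["D"]) && res["D"] >= 0 && !is.na(res["fd"]))
      expect_true(res["fd"] >= 0 && res["fd"] <= 1 + 1e-12)
    res2 <- window_dstats(make_freqs(p1, p2, p2, pO), c(0, n * 10 + 1),
                          min_sites = 1)
    if (!is.na(res2["D"]) && res2["D"] > 0)
      expect_equal(unname(res2["fd"]), 1, tolerance = 1e-12)
  }
})

test_that("jackknife_z handles degenerate and symmetric inputs", {
  expect_equal(jackknife_z(rep(0.2, 8))$Z, Inf)
  expect_equal(jackknife_z(rep(-0.2, 8))$Z, -Inf)
  expect_equal(jackknife_z(rep(0, 8))$Z, 0)
  z <- jackknife_z(c(-0.2, 0.2, -0.1, 0.1, -0.3, 0.3))
  expect_lt(abs(z$Z), 1e-10)
  expect_error(jackknife_z(c(1, 2, 3)), ">= 5")
})

test_that("equal-weight jackknife matches brute-force delete-one", {
  set.seed(11)
  d <- rnorm(20, 0.1, 0.05)
  expect_equal(jackknife_z(d)$Z, oracle_jackknife_z(d), tolerance = 1e-10)
})

test_that("f4_ratio boundary identities and degenerate denominator", {
  set.seed(5)
  pA <- runif(50); pO <- runif(50); pB <- runif(50); pC <- runif(50)
  expect_equal(f4_ratio(pA, pO, pB, pB, pC)$alpha, 1, tolerance = 1e-12)
  expect_equal(f4_ratio(pA, pO, pC, pB, pC)$alpha, 0, tolerance = 1e-12)
  expect_true(is.na(f4_ratio(pA, pO, pB, pC, pC)$alpha))
})

test_that("wc_fst reproduces the canonical cases", {
  # fixed alternate alleles, equal n, no heterozygotes
  expect_equal(wc_fst(c(10, 10), c(1, 0), c(0, 0)), 1)
  # identical frequencies with HWE heterozygosity: the raw WC84 estimate
  # is slightly negative at finite n (unbiased only in expectation); the
  # reported, floored value is 0
  raw <- wc_fst(c(10, 10), c(0.4, 0.4), c(0.48, 0.48))
  expect_lt(abs(raw), 0.06)
  expect_identical(max(raw, 0), 0)
  # n1 = n2 = 10 diploids, p = 0.8 vs 0.2, HWE
  comp <- wc_components(c(10, 10), c(0.8, 0.2), c(0.32, 0.32))
  expect_equal(comp$a, 0.17111, tolerance = 1e-4)
  expect_equal(comp$b, 0.00889, tolerance = 1e-3)
  expect_equal(comp$c, 0.16, tolerance = 1e-12)
  expect_equal(wc_fst(c(10, 10), c(0.8, 0.2), c(0.32, 0.32)), 0.5033,
               tolerance = 1e-4)
  # monomorphic across populations -> NA; zero-called population -> NA
  expect_true(is.na(wc_fst(c(10, 10), c(0, 0), c(0, 0))))
  expect_true(is.na(wc_fst(c(0, 10), c(0.5, 0.5), c(0.5, 0.5))))
})

test_that("wc_fst matches the component-wise oracle on random configs", {
  set.seed(13)
  for (k in 1:100) {
    r <- sample(2:4, 1)
    n <- sample(5:40, r, replace = TRUE)
    p <- runif(r, 0.05, 0.95)
    h <- pmin(2 * p * (1 - p) * runif(r, 0.5, 1.2), 1)
    expect_equal(wc_fst(n, p, h), oracle_wc(n, p, h)$fst,
                 tolerance = 1e-12)
  }
})

test_that("window_fst keeps negative raw estimates, floors reported", {
  # both pops: dosages {1,1,0,2} at each site -> p = 0.5, h = 0.5,
  # identical across pops -> WC84 a < 0 (within-pop excess structure)
  one_pop <- rbind(c(0L, 0L), c(1L, 1L),   # dosage 1
                   c(0L, 0L), c(1L, 1L),   # dosage 1
                   c(0L, 0L), c(0L, 0L),   # dosage 0
                   c(1L, 1L), c(1L, 1L))   # dosage 2
  p <- toy_panel(rbind(one_pop, one_pop), positions = c(100, 200),
                 chrom_length = 1000L)
  pm <- pop_map(stats::setNames(c(rep("A", 4), rep("B", 4)),
                                paste0("S", 1:8)))
  w <- data.frame(chrom = "chr1", start = 0, end = 1000)
  res <- window_fst(p, pm, c("A", "B"), w)
  expect_lt(res$fst_raw, 0)
  expect_identical(res$fst, 0)
  expect_equal(res$n_sites, 2L)
})

test_that("sv_snp_max_r2 matches brute-force Pearson and breaks ties low", {
  al <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L),  # S1 dosage 0,1,0
              c(0L, 0L, 0L), c(1L, 1L, 0L),  # S2 dosage 1,1,0
              c(1L, 0L, 0L), c(1L, 1L, 1L),  # S3 dosage 2,1,1
              c(0L, 0L, 1L), c(0L, 0L, 1L),  # S4 dosage 0,0,2
              c(0L, 1L, 0L), c(1L, 0L, 1L),  # S5 dosage 1,1,1
              c(1L, 1L, 1L), c(1L, 1L, 1L))  # S6 dosage 2,2,2
  p <- toy_panel(al, positions = c(1000, 2000, 3000), chrom_length = 1e5)
  sv <- c(S1 = 0, S2 = 1, S3 = 2, S4 = 0, S5 = 1, S6 = 2)
  res <- sv_snp_max_r2(sv, 1500, 1500, p, flank = 50000)
  dos <- rbind(c(0, 1, 0), c(1, 1, 0), c(2, 1, 1), c(0, 0, 2),
               c(1, 1, 1), c(2, 2, 2))
  r2s <- apply(dos, 2, function(x) cor(sv, x)^2)
  expect_equal(res$max_r2, max(r2s), tolerance = 1e-12)
  expect_equal(res$best_snp, c(1000, 2000, 3000)[which.max(r2s)])
  # snp column 2 of the derived example: r2 ~ 0.8
  expect_equal(cor(c(0, 1, 2, 0, 1, 2), c(0, 1, 1, 0, 1, 2))^2, 0.8,
               tolerance = 0.01)
  # identical dosages -> r2 = 1
  al1 <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 0L),
               c(1L, 1L), c(1L, 1L))
  p1 <- toy_panel(al1, positions = c(500, 800), chrom_length = 1e4)
  sv1 <- c(S1 = 0, S2 = 1, S3 = 2)
  expect_equal(sv_snp_max_r2(sv1, 600, 600, p1)$max_r2, 1,
               tolerance = 1e-12)
  # constant SV dosage -> missing
  expect_true(is.na(sv_snp_max_r2(c(S1 = 1, S2 = 1, S3 = 1), 600, 600,
                                  p1)$max_r2))
  # no SNPs in flank -> missing
  expect_true(is.na(sv_snp_max_r2(sv1, 9000, 9000, p1,
                                  flank = 10)$max_r2))
})

test_that("quartet_freqs polarizes with the outgroup and drops ambiguity", {
  # outgroup fixed ref at site 1 (keep), fixed alt at site 2 (flip),
  # at 0.5 at site 3 (drop)
  al <- rbind(c(0L, 1L, 0L), c(1L, 1L, 1L),   # A (p1)
              c(1L, 0L, 0L), c(1L, 0L, 1L),   # B (p2)
              c(0L, 0L, 0L), c(1L, 0L, 1L),   # C (p3)
              c(0L, 1L, 0L), c(0L, 1L, 1L))   # O
  p <- toy_panel(al, positions = c(10, 20, 30))
  pm <- pop_map(c(S1 = "A", S2 = "B", S3 = "C", S4 = "O"))
  fq <- quartet_freqs(p, pm, "A", "B", "C", "O")
  expect_equal(fq$positions, c(10, 20))
  expect_equal(fq$p1, c(0.5, 1 - 1))
  expect_equal(fq$p2, c(1, 1 - 0))
  expect_equal(fq$pO, c(0, 0))
})
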