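# IBD detection and the rIBD scan.

test_that("identical haplotypes yield one full-length tract", {
  al <- rbind(rep(0L, 60), rep(1L, 60),    # S1 (group a)
              rep(0L, 60), rep(0L, 60))    # S2 (group b)
  p <- toy_panel(al, positions = seq(10000, 600000, by = 10000),
                 chrom_length = 1000000L)
  tr <- detect_ibd(p, "S1", "S2", min_length = 100000, min_sites = 10)
  full <- tr[tr$start == 0 & tr$end == 1e6, ]
  # S1_1 matches both S2 haplotypes end to end
  expect_true(all(c("S1_1") %in% full$hap_a))
  expect_true(nrow(full) >= 2)
})

test_that("haplotypes differing everywhere yield no tracts", {
  al <- rbind(rep(0L, 50), rep(0L, 50), rep(1L, 50), rep(1L, 50))
  p <- toy_panel(al, positions = seq(1000, 50000, by = 1000),
                 chrom_length = 60000L)
  tr <- detect_ibd(p, "S1", "S2", min_length = 1000, min_sites = 5)
  expect_equal(nrow(tr), 0L)
})

test_that("a constructed mid-span match is recovered with snapping", {
  n <- 100
  pos <- seq(10000, 1000000, length.out = n)  # 10 kb spacing
  base <- rep(0L, n)
  other <- base
  # discordant outside [300 kb, 700 kb), identical inside
  outside <- pos < 300000 | pos >= 700000
  other[outside] <- 1L
  al <- rbind(base, base, other, other)
  p <- toy_panel(al, positions = pos, chrom_length = 1000000L)
  tr <- detect_ibd(p, "S1", "S2", min_length = 200000, min_sites = 20)
  expect_true(nrow(tr) >= 1)
  # span covers the constructed interval within one inter-site gap
  gap <- diff(pos)[1]
  expect_true(all(abs(tr$start - 300000) <= gap))
  expect_true(all(abs(tr$end - 700000) <= gap))
})

test_that("detect_ibd agrees with the quadratic reference scanner", {
  set.seed(21)
  for (rep in 1:6) {
    n_hap <- 10; n_sites <- 300
    L <- 300000
    pos <- sort(sample(seq_len(L - 1), n_sites))
    # block-copy structure so that real shared runs exist
    proto <- matrix(sample(0:1, 4 * n_sites, replace = TRUE), nrow = 4)
    al <- proto[sample(1:4, n_hap, replace = TRUE), ]
    flip <- matrix(runif(n_hap * n_sites) < 0.02, n_hap, n_sites)
    al[flip] <- 1L - al[flip]
    storage.mode(al) <- "integer"
    p <- toy_panel(al, positions = pos, chrom_length = L)
    grp_a <- p$sample_ids[1:2]; grp_b <- p$sample_ids[4:5]
    tr <- detect_ibd(p, grp_a, grp_b, min_length = 30000, min_sites = 20,
                     max_mismatch = 1, end_clearance = 10)
    rows_a <- which(p$sample_ids %in% grp_a)
    rows_b <- which(p$sample_ids %in% grp_b)
    expected <- 0L
    for (ia in as.vector(rbind(2 * rows_a - 1, 2 * rows_a)))
      for (ib in as.vector(rbind(2 * rows_b - 1, 2 * rows_b))) {
        ora <- oracle_pair_ibd(p$alleles[ia, ], p$alleles[ib, ], pos, L,
                               min_length = 30000, min_sites = 20,
                               max_mismatch = 1, clearance = 10)
        got <- tr[tr$hap_a == rownames(p$alleles)[ia] &
                    tr$hap_b == rownames(p$alleles)[ib], , drop = FALSE]
        if (is.null(ora)) {
          expect_equal(nrow(got), 0L)
        } else {
          expected <- expected + nrow(ora)
          expect_equal(nrow(got), nrow(ora))
          o <- order(ora[, "start"])
          g <- order(got$start)
          expect_equal(got$start[g], unname(ora[o, "start"]))
          expect_equal(got$end[g], unname(ora[o, "end"]))
          expect_equal(got$n_sites[g], unname(ora[o, "n_sites"]))
        }
      }
    expect_equal(nrow(tr), expected)
  }
})

test_that("detect_ibd rejects unphased panels and overlapping groups", {
  p <- toy_panel(matrix(0L, 4, 10))
  p$phased <- FALSE
  expect_error(detect_ibd(p, "S1", "S2"), "phased")
  p$phased <- TRUE
  expect_error(detect_ibd(p, "S1", "S1"), "disjoint")
})

test_that("nibd counts pair indicators over the window", {
  tr <- data.frame(
    hap_a = c("a1_1", "a1_1", "a2_2", "a1_2"),
    hap_b = c("b1_1", "b1_1", "b2_1", "b9_1"),
    sample_a = c("a1", "a1", "a2", "a1"),
    sample_b = c("b1", "b1", "b2", "b9"),
    chrom = "chr1",
    start = c(0, 10000, 5000, 0), end = c(20000, 30000, 25000, 50000),
    n_sites = 10L)
  ga <- c("a1", "a2"); gb <- c("b1", "b2")
  # 4x4 = 16 pairs; pairs (a1_1,b1_1) and (a2_2,b2_1) overlap [0,25000)
  # (the b9 tract is outside group b); multiple tracts of one pair count once
  expect_equal(nibd(tr, c(0, 25000), ga, gb), 2 / 16)
  expect_equal(nibd(tr[0, ], c(0, 25000), ga, gb), 0)
  expect_equal(nibd(tr, c(40000, 50000), ga, gb), 0)
  expect_error(nibd(tr, c(0, 1), character(0), gb), "non-empty")
})

test_that("nibd boundary cases: none share vs all share", {
  al <- rbind(rep(0L, 60), rep(0L, 60), rep(0L, 60), rep(0L, 60))
  p <- toy_panel(al, positions = seq(5000, 300000, by = 5000),
                 chrom_length = 300000L)
  tr <- detect_ibd(p, "S1", "S2", min_length = 100000, min_sites = 10)
  w <- c(0, 300000)
  expect_equal(nibd(tr, w, "S1", "S2"), 1)   # all four pairs identical
  al2 <- al; al2[3:4, ] <- 1L
  p2 <- toy_panel(al2, positions = seq(5000, 300000, by = 5000),
                  chrom_length = 300000L)
  tr2 <- detect_ibd(p2, "S1", "S2", min_length = 100000, min_sites = 10)
  expect_equal(nibd(tr2, w, "S1", "S2"), 0)
})

test_that("adding a tract for a new pair never decreases nIBD", {
  tr <- data.frame(hap_a = "a1_1", hap_b = "b1_1", sample_a = "a1",
                   sample_b = "b1", chrom = "chr1", start = 0, end = 10000,
                   n_sites = 5L)
  base <- nibd(tr, c(0, 10000), c("a1", "a2"), c("b1"))
  tr2 <- rbind(tr, data.frame(hap_a = "a2_1", hap_b = "b1_2",
                              sample_a = "a2", sample_b = "b1",
                              chrom = "chr1", start = 0, end = 10000,
                              n_sites = 5L))
  expect_gt(nibd(tr2, c(0, 10000), c("a1", "a2"), c("b1")), base)
})

test_that("ribd is zero when donor and background carry the same data", {
  # donor and background populations constructed identical haplotype-wise
  block <- rbind(rep(0L, 80), rep(1L, 80))
  al <- rbind(block, block,      # recipient R1, R2 (two samples)
              block,             # donor D1
              block)             # background B1
  p <- haplotype_panel("chr1", seq(5000, 400000, by = 5000), al,
                       c("R1", "R2", "D1", "B1"), chrom_length = 400000L)
  pm <- pop_map(c(R1 = "rec", R2 = "rec", D1 = "don", B1 = "bgr"),
                roles = list(recipient = "rec", donor = "don",
                             background = "bgr"))
  w <- make_windows(400000, 50000, 25000)
  rs <- ribd_scan(p, pm, w, min_length = 100000, min_sites = 10)
  expect_true(all(rs$ribd == 0))
  expect_true(all(rs$nibd_rd == rs$nibd_rb))
  expect_true(all(rs$nibd_rd >= 0 & rs$nibd_rd <= 1))
})

test_that("ribd_scan demands its roles", {
  p <- toy_panel(matrix(0L, 4, 10))
  pm <- pop_map(c(S1 = "x", S2 = "y"), roles = list(recipient = "x"))
  expect_error(ribd_scan(p, pm, make_windows(1000)), "role")
})
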