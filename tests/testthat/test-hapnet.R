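# Haplotype extraction, frequency tables and the minimum-spanning network.

test_that("identical haplotypes collapse into a single class", {
  al <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 0L))
  p <- toy_panel(al, positions = c(100, 200))
  haps <- extract_haplotypes(p, c(1, 300), maf_min = 0)
  expect_equal(nrow(haps$classes), 2L)
  expect_equal(haps$classes$count[1], 3L)
  expect_equal(haps$classes$label, c("I", "II"))
  # count conservation
  expect_equal(sum(haps$classes$count), 4L)
})

test_that("equal counts break ties lexicographically by allele string", {
  al <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 0L))
  p <- toy_panel(al, positions = c(100, 200))
  haps <- extract_haplotypes(p, c(1, 300), maf_min = 0)
  expect_equal(haps$classes$allele_string, c("00", "11"))
  expect_equal(haps$classes$label, c("I", "II"))
})

test_that("sites failing the MAF filter are excluded before classing", {
  # site MAFs over 4 haplotypes: 0.5, 0.25, 0 -> at maf_min = 0.3 only
  # the first site survives
  al <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L))
  p <- toy_panel(al, positions = c(10, 20, 30))
  haps <- extract_haplotypes(p, c(1, 100), maf_min = 0.3)
  expect_equal(haps$sites, 10)
  expect_equal(nrow(haps$classes), 2L)  # "0" x2 and "1" x2
  # at maf_min = 0.2 the 0.25-MAF site is kept and classes recompute
  expect_equal(nrow(extract_haplotypes(p, c(1, 100),
                                       maf_min = 0.2)$classes), 3L)
  # a haplotype with missing data over the region is excluded and logged
  al2 <- al; al2[1, 1] <- NA
  p2 <- toy_panel(al2, positions = c(10, 20, 30))
  haps2 <- extract_haplotypes(p2, c(1, 100), maf_min = 0.3)
  expect_equal(haps2$n_excluded, 1L)
  expect_equal(sum(haps2$classes$count), 3L)
})

test_that("hap_frequency_table counts per population", {
  # construct a panel with class counts 13/36 in one population
  n_s <- 18 + 11
  strings <- c(rep("11", 13), rep("00", 23),   # popX: 36 haplotypes
               rep("11", 15), rep("01", 7))    # popY: 22 haplotypes
  al <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  samples <- paste0("s", seq_len(n_s))
  p <- haplotype_panel("chr1", c(100, 200), al, samples)
  pm <- pop_map(stats::setNames(c(rep("X", 18), rep("Y", 11)), samples))
  haps <- extract_haplotypes(p, c(1, 300), maf_min = 0)
  tab <- hap_frequency_table(haps, pm)
  expect_equal(sum(tab$counts[, "X"]), 36)
  expect_equal(tab$counts["I", "X"], 13)    # "11" ranks first (28 total)
  expect_equal(tab$proportions["I", "X"], 13 / 36, tolerance = 1e-12)
  expect_equal(tab$counts["III", "X"], 0)
  expect_equal(colSums(tab$proportions), c(X = 1, Y = 1))
  # unknown sample -> mapping error
  pm2 <- pop_map(stats::setNames(rep("X", 10), samples[1:10]))
  expect_error(hap_frequency_table(haps, pm2), "missing from population")
})

test_that("build_network produces the expected path and star", {
  classes <- data.frame(label = c("I", "II", "III"),
                        allele_string = c("00", "01", "11"),
                        count = c(3L, 2L, 1L))
  net <- build_network(classes)
  mst <- net$edges[!net$edges$is_alternative, ]
  expect_equal(nrow(mst), 2L)
  expect_true(all(mst$hamming == 1L))
  # path: I-II and II-III (direct I-III link would cost 2)
  expect_setequal(paste(mst$node_a, mst$node_b),
                  c("I II", "II III"))
  # star: center at distance 1 to k others
  star <- data.frame(label = c("C", "A", "B", "D"),
                     allele_string = c("000", "100", "010", "001"),
                     count = c(5L, 1L, 1L, 1L))
  snet <- build_network(star)
  smst <- snet$edges[!snet$edges$is_alternative, ]
  expect_equal(nrow(smst), 3L)
  expect_true(all(smst$node_a == "C" | smst$node_b == "C"))
  # single class -> single node, no edges
  one <- build_network(classes[1, ])
  expect_equal(nrow(one$edges), 0L)
  expect_equal(one$nodes$label, "I")
})

test_that("equal-weight alternatives are retained as alternative links", {
  # square: 00 - 01 - 11 - 10 - 00, all unit edges; MST keeps 3,
  # the fourth unit edge returns as an alternative link
  classes <- data.frame(label = c("I", "II", "III", "IV"),
                        allele_string = c("00", "01", "11", "10"),
                        count = c(2L, 2L, 2L, 2L))
  net <- build_network(classes)
  unit <- net$edges[net$edges$hamming == 1L, ]
  expect_equal(nrow(unit), 4L)
  expect_equal(sum(unit$is_alternative), 1L)
  expect_equal(sum(!unit$is_alternative), 3L)
})

test_that("MST weight matches the igraph oracle on random classes", {
  skip_if_not_installed("igraph")
  set.seed(51)
  for (rep in 1:10) {
    k <- sample(4:10, 1)
    strs <- unique(apply(matrix(sample(0:1, k * 6, replace = TRUE),
                                ncol = 6), 1, paste, collapse = ""))
    classes <- data.frame(label = as.character(utils::as.roman(
                            seq_along(strs))),
                          allele_string = strs,
                          count = rep(1L, length(strs)))
    if (nrow(classes) < 2) next
    net <- build_network(classes)
    mst <- net$edges[!net$edges$is_alternative, ]
    d <- as.matrix(utils::combn(nrow(classes), 2))
    g <- igraph::make_full_graph(nrow(classes))
    w <- apply(d, 2, function(ij)
      sum(strsplit(classes$allele_string[ij[1]], "")[[1]] !=
            strsplit(classes$allele_string[ij[2]], "")[[1]]))
    igraph::E(g)$weight <- w
    ref <- igraph::mst(g)
    expect_equal(sum(mst$hamming), sum(igraph::E(ref)$weight))
    # connectivity
    expect_equal(nrow(mst), nrow(classes) - 1L)
  }
})

test_that("haplogroup bipartition cuts the largest MST edge", {
  # two tight clusters separated by a long branch
  classes <- data.frame(label = c("I", "II", "III", "IV"),
                        allele_string = c("000000", "000001",
                                          "111110", "111111"),
                        count = c(4L, 3L, 2L, 1L))
  net <- build_network(classes)
  grp <- hap_groups(net)
  expect_equal(unname(grp[c("I", "II")]), c("A", "A"))
  expect_equal(unname(grp[c("III", "IV")]), c("B", "B"))
})

test_that("two major haplogroups separate deeply diverged panels", {
  # on simulated diverged panels the bipartition should separate the two
  # domestic populations' majority haplotypes in most replicates
  hit <- 0L; n_rep <- 10L
  for (s in seq_len(n_rep)) {
    sim <- simulate_history(mini_config(seed = 300 + s, n_sites = 800))
    panel <- bind_panels(sim$panels[c("P_A", "P_B")])
    haps <- extract_haplotypes(panel, c(1, 2e5), maf_min = 0.05)
    if (nrow(haps$classes) < 2) next
    grp <- hap_groups(build_network(haps$classes))
    major <- function(pop) {
      keep <- grepl(pop, names(haps$assignment))
      names(sort(table(haps$assignment[keep]), decreasing = TRUE))[1]
    }
    if (grp[major("^P_A")] != grp[major("^P_B")]) hit <- hit + 1L
  }
  expect_gte(hit, 8L)
})
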