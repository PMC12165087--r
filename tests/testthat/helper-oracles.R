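# Independent reference implementations ("oracles") used to cross-check the
# package's statistics, plus small fixture builders. These deliberately use
# direct, naive formulations so that agreement with the package is a real
# dual-route check.

# direct ABBA/BABA sums for one window of per-site frequencies
oracle_dstats <- function(p1, p2, p3, pO) {
  abba <- baba <- abba_d <- baba_d <- 0
  for (i in seq_along(p1)) {
    abba <- abba + (1 - p1[i]) * p2[i] * p3[i] * (1 - pO[i])
    baba <- baba + p1[i] * (1 - p2[i]) * p3[i] * (1 - pO[i])
    pd <- max(p2[i], p3[i])
    abba_d <- abba_d + (1 - p1[i]) * pd * pd * (1 - pO[i])
    baba_d <- baba_d + p1[i] * (1 - pd) * pd * (1 - pO[i])
  }
  D <- (abba - baba) / (abba + baba)
  fd <- (abba - baba) / (abba_d - baba_d)
  if (!is.na(D) && D < 0) fd <- 0
  list(D = D, fd = fd)
}

# Weir & Cockerham (1984) components, transcribed independently from the
# published equations (r populations, biallelic locus)
oracle_wc <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# plain delete-one jackknife (equal weights)
oracle_jackknife_z <- function(d) {
  n <- length(d)
  loo <- vapply(seq_len(n), function(j) mean(d[-j]), 0)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  mean(d) / se
}

# quadratic reference IBD scanner: for one haplotype pair, enumerate all
# (a, b) merged-run combinations directly and keep maximal qualifying runs.
# Independent restructuring of the matcher's semantics.
oracle_pair_ibd <- function(hap_i, hap_j, pos, L, min_length = 200000,
                            min_sites = 50, max_mismatch = 1,
                            clearance = 10) {
  usable <- which(!is.na(hap_i) & !is.na(hap_j))
  if (length(usable) < min_sites) return(NULL)
  mm <- which(hap_i[usable] != hap_j[usable])
  K <- length(mm)
  cands <- list()
  for (a in 0:K) for (b in a:min(K, a + max_mismatch)) {
    first <- if (a == 0) 1L else mm[a] + 1L
    last <- if (b == K) length(usable) else mm[b + 1L] - 1L
    if (first > last) next
    ok <- TRUE
    # usable sites strictly between the merge boundary and each tolerated
    # mismatch (earlier tolerated mismatches count as sites)
    if (b > a) for (t in (a + 1):b) {
      left <- mm[t] - first
      right <- last - mm[t]
      if (left < clearance || right < clearance) ok <- FALSE
    }
    if (!ok) next
    cands[[length(cands) + 1L]] <- c(a, b, first, last)
  }
  if (!length(cands)) return(NULL)
  m <- do.call(rbind, cands)
  maximal <- vapply(seq_len(nrow(m)), function(i)
    !any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
           (m[, 1] != m[i, 1] | m[, 2] != m[i, 2])), TRUE)
  m <- m[maximal, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(m))) {
    a <- m[i, 1]; b <- m[i, 2]; first <- m[i, 3]; last <- m[i, 4]
    n_run <- last - first + 1L
    if (n_run < min_sites) next
    start <- if (a == 0) 0 else floor((pos[usable[mm[a]]] +
                                         pos[usable[first]]) / 2)
    end <- if (b == K) L else floor((pos[usable[last]] +
                                       pos[usable[mm[b + 1L]]]) / 2)
    if (end - start < min_length) next
    out <- rbind(out, c(start = start, end = end, n_sites = n_run))
  }
  out
}

# fixture builders -----------------------------------------------------------

toy_panel <- function(alleles, positions = NULL, chrom = "chr1",
                      chrom_length = NA, sample_prefix = "S") {
  alleles <- as.matrix(alleles)
  if (is.null(positions)) positions <- seq_len(ncol(alleles)) * 100
  n_s <- nrow(alleles) / 2
  haplotype_panel(chrom, positions, alleles,
                  paste0(sample_prefix, seq_len(n_s)),
                  phased = TRUE, chrom_length = chrom_length)
}

# a small, fast simulation world for tests that only need mechanics, not
# the full statistical structure of the default configuration
mini_config <- function(seed = 1, pulses = list(), n_sites = 600,
                        L = 1e6) {
  sim_config(chromosome_length = L, n_sites = n_sites,
             pop_sizes = c(P_A = 16, P_B = 16, W_A = 12, W_B = 12,
                           OUT = 8),
             split_generations = 300,
             wild_split_generations = 60,
             outgroup_split_generations = 450,
             census_sizes = c(terminal = 40, wild = 60, ancestral = 60,
                              OUT = 30),
             time_scale = 5, pulse_specs = pulses, seed = seed)
}

# cached default-world simulations shared across expensive tests
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed, f = 0, n_sites = 24000) {
  key <- paste(seed, f, n_sites, sep = "_")
  if (is.null(sim_cache[[key]])) {
    pulses <- if (f > 0) list(pulse_spec(30, "P_A", "P_B", f)) else list()
    cfg <- sim_config(seed = seed, n_sites = n_sites, pulse_specs = pulses)
    sim_cache[[key]] <- list(cfg = cfg, sim = simulate_history(cfg))
  }
  sim_cache[[key]]
}
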