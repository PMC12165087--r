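# Frequency-based population statistics: windowed Patterson's D and f_d,
# weighted block-jackknife Z, f4-ratio admixture proportion, Weir-Cockerham
# (1984) F_ST, and SV-SNP linkage tagging.
#
# All D/f_d computation is frequency-based (the windowed estimator of
# Martin, Davey & Jiggins 2015): with per-site derived-allele frequencies
# p1 (background / recipient's sister), p2 (recipient), p3 (donor) and pO
# (outgroup),
#   ABBA = (1 - p1) p2 p3 (1 - pO),  BABA = p1 (1 - p2) p3 (1 - pO)
#   D   = sum(ABBA - BABA) / sum(ABBA + BABA)
#   f_d = sum(ABBA - BABA) / sum(ABBA_D - BABA_D),  p_D = max(p2, p3)
# and f_d is set to 0 wherever D < 0.

#' Per-site derived-allele frequencies for a (P1, P2; P3, O) quartet
#'
#' Sites are polarized with the outgroup: the derived allele is the allele
#' at frequency < 0.5 in the outgroup; sites whose outgroup alt-allele
#' frequency lies in `[0.4, 0.6]` or is missing are dropped as
#' unpolarizable.
#'
#' @param panel A `HaplotypePanel` containing all four groups.
#' @param popmap A `PopulationMap`.
#' @param p1_pop,p2_pop,p3_pop,out_pop Population labels: background,
#'   recipient, donor, outgroup.
#' @return A `quartet_freqs` list with `positions`, `p1`, `p2`, `p3`, `pO`.
#' @export
quartet_freqs <- function(panel, popmap, p1_pop, p2_pop, p3_pop, out_pop) {
  freq <- function(pops) {
    rows <- panel_hap_rows(panel, pop_samples(popmap, pops))
    colMeans(panel$alleles[rows, , drop = FALSE], na.rm = TRUE)
  }
  f1 <- freq(p1_pop); f2 <- freq(p2_pop); f3 <- freq(p3_pop)
  fo <- freq(out_pop)
  polarizable <- !is.na(fo) & (fo < 0.4 | fo > 0.6) &
    !is.na(f1) & !is.na(f2) & !is.na(f3)
  flip <- polarizable & fo > 0.6
  res <- list(positions = panel$positions[polarizable],
              p1 = ifelse(flip, 1 - f1, f1)[polarizable],
              p2 = ifelse(flip, 1 - f2, f2)[polarizable],
              p3 = ifelse(flip, 1 - f3, f3)[polarizable],
              pO = ifelse(flip, 1 - fo, fo)[polarizable])
  class(res) <- "quartet_freqs"
  res
}

panel_hap_rows <- function(panel, samples) {
  idx <- match(samples, panel$sample_ids)
  if (anyNA(idx))
    stop("samples not in panel: ",
         paste(samples[is.na(idx)], collapse = ", "))
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

abba_baba_terms <- function(fr) {
  list(abba = (1 - fr$p1) * fr$p2 * fr$p3 * (1 - fr$pO),
       baba = fr$p1 * (1 - fr$p2) * fr$p3 * (1 - fr$pO))
}

#' Patterson's D and f_d for one window
#'
#' @param freqs A [quartet_freqs()] object.
#' @param window One-row window `data.frame` (`start`, `end`, 0-based
#'   half-open) or a numeric `c(start, end)`.
#' @param min_sites Minimum informative (polarized) sites for a window to
#'   be scored; fewer yields `NA` statistics.
#' @return Named numeric vector `c(D, fd, n_sites)`; `fd` is zeroed when
#'   `D < 0` and `NA` when its denominator is zero.
#' @export
window_dstats <- function(freqs, window, min_sites = 10) {
  if (is.data.frame(window)) window <- c(window$start[1], window$end[1])
  idx <- which(freqs$positions > window[1] & freqs$positions <= window[2])
  n <- length(idx)
  if (n < min_sites)
    return(c(D = NA_real_, fd = NA_real_, n_sites = n))
  fr <- lapply(freqs[c("p1", "p2", "p3", "pO")], `[`, idx)
  tt <- abba_baba_terms(fr)
  num <- sum(tt$abba - tt$baba)
  den <- sum(tt$abba + tt$baba)
  D <- if (den == 0) NA_real_ else num / den
  pd <- pmax(fr$p2, fr$p3)
  frd <- list(p1 = fr$p1, p2 = pd, p3 = pd, pO = fr$pO)
  td <- abba_baba_terms(frd)
  dend <- sum(td$abba - td$baba)
  fd <- if (dend == 0) NA_real_ else num / dend
  if (!is.na(D) && D < 0) fd <- 0
  c(D = D, fd = fd, n_sites = n)
}

#' Windowed D/f_d scan over a window grid
#'
#' @inheritParams window_dstats
#' @param windows Window `data.frame` from [make_windows()].
#' @return `data.frame` with `chrom`, `start`, `end`, `n_sites`, `D`, `fd`.
#' @export
dstat_scan <- function(freqs, windows, min_sites = 10) {
  res <- t(vapply(seq_len(nrow(windows)), function(i)
    window_dstats(freqs, c(windows$start[i], windows$end[i]), min_sites),
    c(D = 0, fd = 0, n_sites = 0)))
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_sites = as.integer(res[, "n_sites"]),
             D = res[, "D"], fd = res[, "fd"])
}

#' Weighted block-jackknife Z score
#'
#' Delete-one block jackknife over per-block statistics, weighted by block
#' size (Busing, Meijer & van der Leeden 1999). With equal weights this
#' reduces to the standard delete-one jackknife.
#'
#' @param per_block Per-block statistic values (e.g. block D).
#' @param block_weights Positive block weights (e.g. spans or site counts);
#'   equal weights when `NULL`.
#' @return List with `estimate`, `se`, `Z`, `n_blocks`; `Z` is a signed
#'   `Inf` sentinel when the jackknife SE is exactly zero.
#' @export
jackknife_z <- function(per_block, block_weights = NULL) {
  ok <- !is.na(per_block)
  d <- per_block[ok]
  w <- if (is.null(block_weights)) rep(1, length(d)) else block_weights[ok]
  jackknife_ratio(w * d, w, w)
}

# Ratio-statistic jackknife: theta = sum(num)/sum(den), delete-one blocks
# weighted by m (Busing et al. 1999 weighted jackknife variance).
jackknife_ratio <- function(num, den, m) {
  n <- length(num)
  if (n < 5) stop("jackknife: need >= 5 non-missing blocks, got ", n)
  if (any(m <= 0)) stop("jackknife: block weights must be positive")
  theta <- sum(num) / sum(den)
  theta_mj <- (sum(num) - num) / (sum(den) - den)
  M <- sum(m)
  h <- M / m
  theta_J <- n * theta - sum((1 - m / M) * theta_mj)
  v <- sum((h * theta - (h - 1) * theta_mj - theta_J)^2 / (h - 1)) / n
  se <- sqrt(v)
  z <- if (se == 0) sign(theta) * Inf else theta / se
  if (se == 0 && theta == 0) z <- 0
  list(estimate = theta, se = se, Z = z, n_blocks = n)
}

#' Genome-wide Patterson's D with block-jackknife Z
#'
#' Computes D from the full-chromosome ABBA/BABA sums and its standard
#' error by delete-one jackknife over contiguous blocks, weighted by the
#' number of informative sites per block.
#'
#' @param freqs A [quartet_freqs()] object.
#' @param chrom_length Chromosome length in bp.
#' @param block_size Jackknife block size in bp (default 1 Mb).
#' @return List with `D`, `se`, `Z`, `n_blocks`.
#' @export
genome_dstat <- function(freqs, chrom_length, block_size = 1e6) {
  tt <- abba_baba_terms(freqs)
  blk <- pmin(floor((freqs$positions - 1) / block_size),
              ceiling(chrom_length / block_size) - 1)
  num <- tapply(tt$abba - tt$baba, blk, sum)
  den <- tapply(tt$abba + tt$baba, blk, sum)
  nsit <- tapply(tt$abba, blk, length)
  ok <- den > 0
  jk <- jackknife_ratio(as.numeric(num[ok]), as.numeric(den[ok]),
                        as.numeric(nsit[ok]))
  list(D = jk$estimate, se = jk$se, Z = jk$Z, n_blocks = jk$n_blocks)
}

#' f4-ratio admixture proportion
#'
#' `alpha = f4(A, O; X, C) / f4(A, O; B, C)` estimates the proportion of
#' ancestry that the admixed population X derives from the source related
#' to B (the remainder coming from the source related to C). A must be a
#' sister of B relative to X and C.
#'
#' @param pA,pO,pX,pB,pC Per-site derived-allele frequency vectors over the
#'   same sites.
#' @param tol Denominator magnitude below which the ratio is reported `NA`.
#' @return List with `alpha`, `f4_num`, `f4_den`.
#' @export
f4_ratio <- function(pA, pO, pX, pB, pC, tol = 1e-12) {
  num <- mean((pA - pO) * (pX - pC))
  den <- mean((pA - pO) * (pB - pC))
  list(alpha = if (abs(den) < tol) NA_real_ else num / den,
       f4_num = num, f4_den = den)
}

# ---------------------------------------------------------------------------
# Weir-Cockerham (1984) F_ST

#' Weir-Cockerham variance components for one biallelic site
#'
#' @param n Called diploid sample sizes per population.
#' @param p Alternate-allele frequencies per population.
#' @param h Observed heterozygote proportions per population.
#' @return List with components `a` (among populations), `b` (among
#'   individuals within populations), `c` (within individuals), or `NULL`
#'   for sites that cannot be scored (a population with no called alleles,
#'   or monomorphic across all populations).
#' @export
wc_components <- function(n, p, h) {
  if (any(n <= 0) || anyNA(p) || anyNA(h)) return(NULL)
  r <- length(n)
  if (r < 2) stop("wc_components: need >= 2 populations")
  nbar <- mean(n)
  pbar <- sum(n * p) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(NULL)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Per-site Weir-Cockerham F_ST
#' @inheritParams wc_components
#' @return `a / (a + b + c)` or `NA` for unscorable sites.
#' @export
wc_fst <- function(n, p, h) {
  comp <- wc_components(n, p, h)
  if (is.null(comp)) return(NA_real_)
  tot <- comp$a + comp$b + comp$c
  if (tot == 0) return(NA_real_)
  comp$a / tot
}

# Per-population per-site (n, p, h) from a dosage matrix (sites handled
# column-wise; dosage rows = samples).
pop_site_summary <- function(dosage) {
  called <- !is.na(dosage)
  n <- colSums(called)
  p <- colSums(dosage, na.rm = TRUE) / (2 * pmax(n, 1L))
  h <- colSums(dosage == 1L, na.rm = TRUE) / pmax(n, 1L)
  list(n = n, p = p, h = h)
}

panel_dosage <- function(panel, samples) {
  rows <- panel_hap_rows(panel, samples)
  a1 <- panel$alleles[rows[c(TRUE, FALSE)], , drop = FALSE]
  a2 <- panel$alleles[rows[c(FALSE, TRUE)], , drop = FALSE]
  a1 + a2
}

#' Windowed Weir-Cockerham F_ST between two (or more) populations
#'
#' Per-window values are the ratio of sums of variance components over the
#' window's scorable sites (not the mean of per-site ratios). Negative
#' estimates are kept as computed in `fst_raw` and floored at zero in
#' `fst`.
#'
#' @param panel A `HaplotypePanel`.
#' @param popmap A `PopulationMap`.
#' @param pops Two or more population labels.
#' @param windows Window `data.frame` from [make_windows()].
#' @return `data.frame` with `chrom`, `start`, `end`, `n_sites`, `fst_raw`,
#'   `fst`.
#' @export
window_fst <- function(panel, popmap, pops, windows) {
  summ <- lapply(pops, function(pp)
    pop_site_summary(panel_dosage(panel, pop_samples(popmap, pp))))
  n_sites <- length(panel$positions)
  av <- bv <- cv <- rep(NA_real_, n_sites)
  for (s in seq_len(n_sites)) {
    comp <- wc_components(vapply(summ, function(x) x$n[s], 0),
                          vapply(summ, function(x) x$p[s], 0),
                          vapply(summ, function(x) x$h[s], 0))
    if (!is.null(comp)) { av[s] <- comp$a; bv[s] <- comp$b; cv[s] <- comp$c }
  }
  idx <- window_site_index(panel$positions, windows)
  res <- lapply(idx, function(ii) {
    ii <- ii[!is.na(av[ii])]
    if (!length(ii)) return(c(n = 0L, raw = NA_real_))
    tot <- sum(av[ii] + bv[ii] + cv[ii])
    c(n = length(ii), raw = if (tot == 0) NA_real_ else sum(av[ii]) / tot)
  })
  raw <- vapply(res, `[[`, 0, "raw")
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end,
             n_sites = as.integer(vapply(res, `[[`, 0, "n")),
             fst_raw = raw, fst = pmax(raw, 0))
}

# ---------------------------------------------------------------------------
# SV-SNP linkage tagging

#' Maximum r-squared between an SV and SNPs in its flanks
#'
#' Squared Pearson correlation between the SV's alt-allele dosage and each
#' SNP dosage within `flank` bp of the SV span, over samples called in
#' both. Ties are broken toward the smallest SNP position.
#'
#' @param sv_genotypes Named (by sample) SV dosage vector.
#' @param sv_pos,sv_end SV span (1-based inclusive; `sv_end = sv_pos` for
#'   insertions).
#' @param panel A `HaplotypePanel` providing the SNPs.
#' @param flank Flank size in bp (default 50 kb).
#' @return List with `max_r2` and `best_snp` (position), both `NA` when the
#'   SV is monomorphic or no flank SNP exists.
#' @export
sv_snp_max_r2 <- function(sv_genotypes, sv_pos, sv_end, panel,
                          flank = 50000) {
  shared <- intersect(names(sv_genotypes), panel$sample_ids)
  svd <- sv_genotypes[shared]
  if (length(unique(svd[!is.na(svd)])) < 2)
    return(list(max_r2 = NA_real_, best_snp = NA_real_))
  in_flank <- which(panel$positions >= sv_pos - flank &
                      panel$positions <= sv_end + flank)
  if (!length(in_flank))
    return(list(max_r2 = NA_real_, best_snp = NA_real_))
  snp <- panel_dosage(panel, shared)[, in_flank, drop = FALSE]
  r2 <- suppressWarnings(
    as.vector(stats::cor(svd, snp, use = "pairwise.complete.obs"))^2)
  if (all(is.na(r2)))
    return(list(max_r2 = NA_real_, best_snp = NA_real_))
  best <- which(r2 >= max(r2, na.rm = TRUE) - 1e-12)[1]
  list(max_r2 = r2[best], best_snp = panel$positions[in_flank][best])
}

#' Tag every SV in an `SVSet` with its maximum flank r-squared
#'
#' @param svs An `SVSet`.
#' @param panel A `HaplotypePanel`.
#' @param flank Flank size in bp.
#' @param r2_tag Threshold above which an SV counts as tagged by a SNP
#'   (default 0.7).
#' @return `data.frame` with `sv_id`, `max_r2`, `best_snp`, `tagged`.
#' @export
sv_tagging <- function(svs, panel, flank = 50000, r2_tag = 0.7) {
  res <- lapply(seq_len(nrow(svs$info)), function(i) {
    g <- svs$genotypes[i, ]
    sv_snp_max_r2(stats::setNames(as.numeric(g), colnames(svs$genotypes)),
                  svs$info$pos[i], svs$info$end[i], panel, flank)
  })
  r2 <- vapply(res, `[[`, 0, "max_r2")
  data.frame(sv_id = svs$info$sv_id, max_r2 = r2,
             best_snp = vapply(res, `[[`, 0, "best_snp"),
             tagged = !is.na(r2) & r2 > r2_tag)
}
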